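#' Derive a stage seed from the top-level seed
#'
#' Every source of randomness in a pipeline run is keyed by a single
#' top-level seed: stage `name` uses
#' `(seed * 69069 + sum(utf8ToInt(name) * 31^k)) mod (2^31 - 1)`
#' (k = 0, 1, ...; result forced positive), so stage streams are
#' decoupled, deterministic, and stay within R's 32-bit integer range.
#'
#' @param seed Top-level integer seed.
#' @param name Stage name.
#' @return A positive integer seed below `2^31`.
#' @export
derive_seed <- function(seed, name) {
  m <- 2147483647
  h <- sum(as.numeric(utf8ToInt(name)) *
             31^(seq_along(utf8ToInt(name)) - 1) %% m) %% m
  out <- (abs(as.numeric(seed)) * 69069 + h) %% m
  as.integer(max(1, out))
}

#' Run the synthetic-analysis pipeline
#'
#' Orchestrates the stages synth -> observations -> dnms -> saturation ->
#' abc in dependency order, writing TSV/JSON artifacts and a run manifest
#' to `out_dir`. Identical configurations (including the seed) reproduce
#' byte-identical numeric outputs.
#'
#' @param config A named list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{seed}{top-level seed (default 1).}
#'     \item{stages}{character vector among
#'       `c("synth", "observations", "dnms", "saturation", "abc")`
#'       (default: all but `abc`).}
#'     \item{classes}{optional class table overriding [default_classes()].}
#'     \item{n_chromosomes, n_trios}{sample sizes (defaults 780000, 2976).}
#'     \item{model}{demography preset name or model file (default
#'       `"eur_recent10M"`).}
#'     \item{engine}{observation engine (default `"poisson_tree"` when all
#'       classes are neutral, else `"forward"`).}
#'     \item{neutral_class}{annotation treated as neutral (default
#'       `"synonymous"`).}
#'     \item{abc}{optional list: `u`, `v`, `n_sample`, `condition`,
#'       `proposals`, `threshold_hs`, `prior` (arguments to
#'       [prior_spec()]).}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  defaults <- list(seed = 1L,
                   stages = c("synth", "observations", "dnms", "saturation"),
                   n_chromosomes = 780000, n_trios = 2976,
                   model = "eur_recent10M", engine = NULL,
                   neutral_class = "synonymous", abc = NULL)
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stages <- config$stages
  results <- list()
  outputs <- character(0)

  classes <- if (is.null(config$classes)) {
    default_classes()
  } else {
    as.data.frame(config$classes, stringsAsFactors = FALSE)
  }

  tsv <- function(x, name) {
    path <- file.path(out_dir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  if ("synth" %in% stages) {
    sc <- synthetic_config(classes = classes, n_trios = config$n_trios,
                           n_chromosomes = config$n_chromosomes,
                           seed = derive_seed(seed, "synth"))
    results$synth <- generate_site_table(sc)
    tsv(results$synth$sites, "sites.tsv")
    tsv(results$synth$truth, "truth.tsv")
  }

  if ("observations" %in% stages) {
    if (is.null(results$synth)) stop("observations stage needs synth output")
    engine <- config$engine
    if (is.null(engine)) {
      engine <- if (all(results$synth$truth$s_true == 0)) {
        "poisson_tree"
      } else {
        "forward"
      }
    }
    results$synth$sites <- simulate_observations(
      results$synth$sites, results$synth$truth, model = config$model,
      n_chromosomes = config$n_chromosomes,
      seed = derive_seed(seed, "observations"), engine = engine)
    tsv(results$synth$sites, "sites.tsv")
  }

  if ("dnms" %in% stages) {
    if (is.null(results$synth)) stop("dnms stage needs synth output")
    results$synth$sites <- simulate_dnms(results$synth$sites,
                                         n_trios = config$n_trios,
                                         seed = derive_seed(seed, "dnms"))
    tsv(results$synth$sites, "sites.tsv")
  }

  if ("saturation" %in% stages) {
    sites <- results$synth$sites
    if (is.null(sites$segregating)) {
      stop("saturation stage needs observation output")
    }
    summ <- fraction_segregating(sites, "annotation")
    summ <- rescale_to_neutral(summ, config$neutral_class)
    results$saturation <- summ
    tsv(summ, "summary.tsv")
  }

  if ("abc" %in% stages) {
    a <- utils::modifyList(
      list(u = 1.2e-7, v = 5e-9, condition = "zero", proposals = 1000,
           threshold_hs = 5e-4, n_sample = config$n_chromosomes,
           prior = list(family = "log_uniform_s")),
      if (is.null(config$abc)) list() else config$abc)
    prior <- do.call(prior_spec, a$prior)
    tmpl <- site_sim_config(u = a$u, v = a$v, model = config$model,
                            n_sample = a$n_sample)
    post <- abc_posterior(prior, tmpl, observed = a$condition,
                          proposals = a$proposals,
                          seed = derive_seed(seed, "abc"))
    results$abc <- list(posterior = post,
                        odds = bayes_odds(post, prior, a$threshold_hs))
    tsv(data.frame(accepted_s = post$accepted_s), "posterior.tsv")
    odds_path <- file.path(out_dir, "odds.json")
    jsonlite::write_json(results$abc$odds, odds_path, auto_unbox = TRUE,
                         digits = NA)
    outputs <- c(outputs, odds_path)
  }

  cfg_path <- file.path(out_dir, "run_config.json")
  save_cfg <- config[setdiff(names(config), "engine")]
  jsonlite::write_json(save_cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "satcpg",
    version = as.character(utils::packageVersion("satcpg")),
    seed = seed,
    stage_seeds = stats::setNames(
      lapply(stages, function(st) derive_seed(seed, st)), stages),
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest,
                 out_dir = out_dir))
}

#' Command-line entry point
#'
#' Dispatches `satcpg <subcommand> [options]` for the subcommands `synth`,
#' `simulate`, `treelength`, `saturation`, `abc` and `pipeline`. Numeric
#' results go to stdout or `--out` files; log messages go to stderr. An
#' executable wrapper is installed at `inst/cli/satcpg`.
#'
#' @param args Character vector of arguments (defaults to the command
#'   line).
#' @return Invisibly, the subcommand's result.
#' @export
satcpg_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: satcpg {synth|simulate|treelength|saturation|abc|pipeline} [options]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- parse_kv(args[-1])
  num <- function(x, d = NULL) if (is.null(x)) d else as.numeric(x)
  chr <- function(x, d = NULL) if (is.null(x)) d else x
  res <- switch(cmd,
    synth = {
      cfg <- if (!is.null(opts$config)) {
        jsonlite::fromJSON(opts$config)
      } else {
        list()
      }
      sc <- synthetic_config(
        classes = if (is.null(cfg$classes)) default_classes() else
          as.data.frame(cfg$classes),
        n_trios = num(opts$`n-trios`, 2976),
        n_chromosomes = num(opts$n, 780000),
        seed = num(opts$seed, 1))
      tabs <- generate_site_table(sc)
      utils::write.table(tabs$sites, chr(opts$out, "sites.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(tabs$truth, chr(opts$truth, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tabs
    },
    simulate = {
      cfg <- site_sim_config(u = num(opts$u), v = num(opts$v, 0),
                             s = num(opts$s, 0), h = num(opts$h, 0.5),
                             model = chr(opts$model, "eur_recent10M"),
                             n_sample = num(opts$n),
                             seed = num(opts$seed, 1))
      sims <- simulate_site_replicates(cfg, reps = num(opts$reps, 100))
      out <- chr(opts$out)
      if (is.null(out)) {
        utils::write.table(sims, stdout(), sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else {
        utils::write.table(sims, out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
      sims
    },
    treelength = {
      tl <- simulate_tree_length(chr(opts$model, "eur_recent10M"),
                                 n = num(opts$n), reps = num(opts$reps, 20),
                                 seed = num(opts$seed, 1))
      out <- list(n = tl$n, mean_length = tl$mean_length, se = tl$se,
                  reps = tl$reps)
      cat(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), "\n")
      tl
    },
    saturation = {
      sites <- utils::read.delim(opts$sites)
      summ <- fraction_segregating(sites, chr(opts$`group-by`, "annotation"))
      if (!is.null(opts$neutral)) {
        summ <- rescale_to_neutral(summ, opts$neutral)
      }
      utils::write.table(summ, chr(opts$out, "summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summ
    },
    abc = {
      prior <- prior_spec(chr(opts$prior, "log_uniform_s"))
      tmpl <- site_sim_config(u = num(opts$u, 1.2e-7), v = num(opts$v, 5e-9),
                              model = chr(opts$model, "eur_recent10M"),
                              n_sample = num(opts$n))
      post <- abc_posterior(prior, tmpl,
                            observed = chr(opts$condition, "zero"),
                            proposals = num(opts$proposals, 1000),
                            seed = num(opts$seed, 1))
      utils::write.table(data.frame(accepted_s = post$accepted_s),
                         chr(opts$out, "posterior.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      odds <- bayes_odds(post, prior, num(opts$threshold, 5e-4))
      cat(jsonlite::toJSON(odds, auto_unbox = TRUE, digits = NA), "\n")
      list(posterior = post, odds = odds)
    },
    pipeline = {
      run_pipeline(config = if (is.null(opts$config)) {
        list(seed = num(opts$seed, 1))
      } else {
        opts$config
      }, out_dir = chr(opts$`out-dir`, "satcpg_run"))
    },
    stop("unknown subcommand '", cmd, "'"))
  invisible(res)
}

# Parse "--key value" and "--flag" argument pairs into a named list.
parse_kv <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      out[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      out[[key]] <- TRUE
      i <- i + 1
    }
  }
  out
}
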