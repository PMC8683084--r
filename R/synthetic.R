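#' Default annotation classes for the synthetic site table
#'
#' One row per annotation class: site count, mutation-rate class with its
#' per-site rate (methylated CpG transitions 1.17e-7, other C>T 0.9e-8,
#' T>A 1.2e-9 per site per generation), and a two-point distribution of
#' fitness effects (a fraction `prop_selected` of sites carries
#' heterozygous effect `h * hs_selected / h`, the rest are neutral). The
#' default mixture mirrors the depletion structure of large-sample exome
#' data: synonymous sites neutral, ~5\% of missense and ~27\% of
#' loss-of-function opportunities under strong selection.
#'
#' @return A data.frame with columns `annotation`, `n_sites`,
#'   `mutation_class`, `u`, `v`, `prop_selected`, `s_selected`.
#' @export
default_classes <- function() {
  data.frame(
    annotation = c("synonymous", "missense", "LOF"),
    n_sites = c(350000, 700000, 30000),
    mutation_class = "mCpG_transition",
    u = 1.17e-7, v = 5e-9,
    prop_selected = c(0, 0.05, 0.27),
    s_selected = 0.1, # hs = 0.05 at h = 0.5
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic site-table generator
#'
#' The generator emulates the statistical structure of an annotated
#' per-mutational-opportunity table: annotation classes with class-specific
#' mutation rates and distributions of fitness effects, germline
#' methylation for the methylated-CpG class (mass at `>= 0.65`),
#' trinucleotide contexts, an optional constraint score correlated with
#' the true selection coefficient, an optional confounding covariate, and
#' Poisson de novo mutation counts from `n_trios` sequenced trios.
#'
#' @param classes Class table as in [default_classes()].
#' @param n_trios Number of trios for DNM simulation (default 2976).
#' @param n_chromosomes Present-day sample size (default 780000).
#' @param h Dominance coefficient (default 0.5).
#' @param u_jitter_sd Lognormal SD of optional per-site rate jitter around
#'   the class mean (default 0: per-site rate is the class constant, since
#'   rate variation among methylated CpGs is small relative to the mean).
#' @param score_cor Rank correlation target between the score column and
#'   the true `hs` (default 0.8); `NA` omits the score.
#' @param covariate_model Optional function
#'   `f(annotation, is_selected, n)` returning a numeric covariate (e.g.
#'   a linked-selection statistic); `NULL` draws an independent standard
#'   normal.
#' @param seed Integer seed.
#' @return A list of class `"satcpg_synth_config"`.
#' @export
synthetic_config <- function(classes = default_classes(), n_trios = 2976,
                             n_chromosomes = 780000, h = 0.5,
                             u_jitter_sd = 0, score_cor = 0.8,
                             covariate_model = NULL, seed = 1L) {
  need <- c("annotation", "n_sites", "mutation_class", "u", "v",
            "prop_selected", "s_selected")
  if (!all(need %in% names(classes))) {
    stop("classes needs columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(classes$n_sites >= 0), all(classes$u > 0),
            all(classes$prop_selected >= 0), all(classes$prop_selected <= 1),
            n_trios >= 0, n_chromosomes >= 0, u_jitter_sd >= 0)
  structure(list(classes = classes, n_trios = n_trios,
                 n_chromosomes = n_chromosomes, h = h,
                 u_jitter_sd = u_jitter_sd, score_cor = score_cor,
                 covariate_model = covariate_model,
                 seed = as.numeric(seed)),
            class = "satcpg_synth_config")
}

#' Generate a synthetic site table with a separate truth table
#'
#' Emits one row per mutational opportunity. The observable table carries
#' annotation, mutation class, trinucleotide context, methylation level,
#' per-site mutation rate, optional score and covariate. The true per-site
#' selection coefficients live in a separate truth table (side file), so
#' statistics code cannot accidentally read them.
#'
#' @param config A [synthetic_config()].
#' @return A list with `sites` (observable columns) and `truth`
#'   (`site_id`, `s_true`, `hs_true`, `is_selected`).
#' @export
generate_site_table <- function(config) {
  stopifnot(inherits(config, "satcpg_synth_config"))
  cl <- config$classes
  with_local_seed(config$seed, {
    rows <- lapply(seq_len(nrow(cl)), function(i) {
      n <- cl$n_sites[i]
      if (n == 0) return(NULL)
      is_mcpg <- cl$mutation_class[i] == "mCpG_transition"
      meth <- if (is_mcpg) {
        0.65 + 0.35 * stats::rbeta(n, 5, 2) # methylated: mass on [0.65, 1]
      } else {
        stats::rbeta(n, 1, 8)
      }
      ctx <- if (is_mcpg) {
        paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), "CG")
      } else {
        replicate(n, paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                           collapse = ""))
      }
      u_site <- if (config$u_jitter_sd > 0) {
        cl$u[i] * stats::rlnorm(n, -config$u_jitter_sd^2 / 2,
                                config$u_jitter_sd)
      } else {
        rep(cl$u[i], n)
      }
      sel <- stats::runif(n) < cl$prop_selected[i]
      data.frame(annotation = cl$annotation[i],
                 mutation_class = cl$mutation_class[i],
                 context = ctx, methylation = meth, u_site = u_site,
                 v_site = cl$v[i], s_true = ifelse(sel, cl$s_selected[i], 0),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$site_id <- sprintf("site_%07d", seq_len(nrow(tab)))
    hs_true <- config$h * tab$s_true
    if (!is.na(config$score_cor)) {
      # monotone in hs plus noise, tuned by the target rank correlation
      noise_sd <- sqrt(max(1 / max(config$score_cor, 1e-6)^2 - 1, 0))
      tab$score <- rank(hs_true, ties.method = "average") / nrow(tab) +
        stats::rnorm(nrow(tab), 0, noise_sd * stats::sd(rank(hs_true) /
                                                          nrow(tab)))
    }
    tab$covariate <- if (is.null(config$covariate_model)) {
      stats::rnorm(nrow(tab))
    } else {
      config$covariate_model(tab$annotation, tab$s_true > 0, nrow(tab))
    }
    truth <- data.frame(site_id = tab$site_id, s_true = tab$s_true,
                        hs_true = hs_true,
                        is_selected = tab$s_true > 0,
                        stringsAsFactors = FALSE)
    obs_cols <- c("site_id", "annotation", "mutation_class", "context",
                  "methylation", "u_site", "v_site", "score", "covariate")
    sites <- tab[, intersect(obs_cols, names(tab))]
    rownames(sites) <- rownames(truth) <- NULL
    list(sites = sites, truth = truth)
  })
}

#' Simulate per-site observations (segregating status and copy counts)
#'
#' Adds segregating flags (and, under the forward engine, derived copy
#' counts) to a synthetic site table. The `forward` engine delegates each
#' site to the Wright-Fisher simulator with the site's true selection
#' coefficient; the `poisson_tree` engine is a fast neutral-only shortcut
#' drawing per-site tree lengths from replicate coalescent genealogies and
#' setting `P(segregating) = 1 - exp(-u L)`.
#'
#' @param sites Site table from [generate_site_table()].
#' @param truth Matching truth table (required for the forward engine when
#'   any site is selected; `NULL` treats all sites as neutral).
#' @param model A [demographic_model()] or preset name.
#' @param n_chromosomes Present-day sample size.
#' @param seed Integer seed.
#' @param engine `"forward"` or `"poisson_tree"`.
#' @param tree_reps Replicate genealogies for the `poisson_tree` engine
#'   (default 100).
#' @return `sites` with added `segregating` (and `copies` under the
#'   forward engine).
#' @export
simulate_observations <- function(sites, truth = NULL, model,
                                  n_chromosomes, seed = 1L,
                                  engine = c("forward", "poisson_tree"),
                                  tree_reps = 100) {
  engine <- match.arg(engine)
  model <- resolve_model(model)
  n_sites <- nrow(sites)
  s_true <- if (is.null(truth)) {
    rep(0, n_sites)
  } else {
    truth$s_true[match(sites$site_id, truth$site_id)]
  }
  if (anyNA(s_true)) stop("truth table does not cover all sites")
  if (n_chromosomes == 0) {
    sites$segregating <- FALSE
    sites$copies <- 0L
    return(sites)
  }
  if (engine == "poisson_tree") {
    if (any(s_true > 0)) {
      stop("poisson_tree engine requires all-neutral truth")
    }
    tl <- simulate_tree_length(model, n_chromosomes, reps = tree_reps,
                               seed = derive_seed(seed, "tree"))
    sites$segregating <- with_local_seed(derive_seed(seed, "obs"), {
      L <- sample(tl$lengths, n_sites, replace = TRUE)
      stats::runif(n_sites) < 1 - exp(-sites$u_site * L)
    })
    return(sites)
  }
  # forward engine: batch sites through the C++ simulator, grouping by
  # (u, v) so each group is one call with a per-site s vector
  sites$copies <- NA_integer_
  key <- paste(sites$u_site, sites$v_site)
  for (k in unique(key)) {
    i <- which(key == k)
    cfg <- site_sim_config(u = sites$u_site[i[1]], v = sites$v_site[i[1]],
                           s = 0, model = model, n_sample = n_chromosomes,
                           seed = derive_seed(seed, paste0("fwd_", k)))
    sims <- simulate_site_replicates(cfg, reps = length(i), s = s_true[i])
    sites$copies[i] <- sims$copies
  }
  sites$segregating <- sites$copies > 0 & sites$copies < n_chromosomes
  sites
}

#' Simulate de novo mutation counts
#'
#' Independent Poisson counts per site at rate `2 * n_trios * u_site`
#' (each trio contributes two haploid transmissions).
#'
#' @param sites Site table with `u_site`.
#' @param n_trios Number of sequenced trios (`>= 0`).
#' @param seed Integer seed.
#' @param compartment Optional vector (or single label) written to a
#'   `compartment` column, so multi-hit comparisons can be constructed.
#' @return `sites` with an added `dnm_count` column.
#' @export
simulate_dnms <- function(sites, n_trios = 2976, seed = 1L,
                          compartment = NULL) {
  stopifnot(n_trios >= 0)
  sites$dnm_count <- with_local_seed(derive_seed(seed, "dnm"), {
    stats::rpois(nrow(sites), 2 * n_trios * sites$u_site)
  })
  if (!is.null(compartment)) sites$compartment <- compartment
  sites
}
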