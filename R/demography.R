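#' Construct a demographic epoch
#'
#' An epoch is a half-open interval of time before present,
#' `[t_end, t_start)`, with diploid effective size
#' `N(g) = N_start * exp(growth_rate * (t_start - g))` for a generation `g`
#' in the interval. `t_start` is the older bound, `t_end` the younger;
#' generation 0 is the present sampling generation. A `growth_rate` of 0
#' gives a constant-size epoch; a positive rate means the population grows
#' toward the present.
#'
#' @param t_start Generations before present, older bound (exclusive of the
#'   size evaluation beyond it).
#' @param t_end Generations before present, younger bound (`>= 0`).
#' @param N_start Diploid effective size at `t_start` (`>= 1`).
#' @param growth_rate Per-generation exponential rate (default 0).
#' @return A list of class `"satcpg_epoch"`.
#' @export
epoch <- function(t_start, t_end, N_start, growth_rate = 0) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), is.numeric(N_start))
  if (!(t_start > t_end && t_end >= 0)) {
    stop("epoch requires t_start > t_end >= 0 (got [",
         t_end, ", ", t_start, "))")
  }
  if (N_start < 1) stop("N_start must be >= 1")
  structure(list(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                 N_start = as.numeric(N_start),
                 growth_rate = as.numeric(growth_rate)),
            class = "satcpg_epoch")
}

#' Construct a piecewise demographic model
#'
#' Epochs must tile `[0, T_model)` with no gaps or overlaps; the youngest
#' epoch ends at generation 0. A neutral burn-in of
#' `burn_in_multiplier * N_ancestral` generations at constant size
#' `N_ancestral` is prepended before the oldest epoch by consumers that
#' simulate forward in time.
#'
#' @param epochs A list of [epoch()] objects (any order) or a data.frame
#'   with columns `t_start, t_end, N_start, growth_rate`.
#' @param N_ancestral Diploid size before the oldest epoch.
#' @param burn_in_multiplier Burn-in length in units of `N_ancestral`
#'   generations (default 10).
#' @param name Optional model name.
#' @return A list of class `"satcpg_demography"` with the epoch table
#'   ordered young to old.
#' @export
demographic_model <- function(epochs, N_ancestral, burn_in_multiplier = 10,
                              name = "custom") {
  tab <- as_epoch_table(epochs)
  tab <- tab[order(tab$t_end), , drop = FALSE]
  rownames(tab) <- NULL
  if (tab$t_end[1] != 0) stop("youngest epoch must end at generation 0")
  if (any(tab$t_start <= tab$t_end)) stop("each epoch needs t_start > t_end")
  if (nrow(tab) > 1 &&
      any(abs(tab$t_end[-1] - tab$t_start[-nrow(tab)]) > 1e-9)) {
    stop("epochs must tile time with no gaps or overlaps")
  }
  if (any(tab$N_start < 1)) stop("epoch sizes must be >= 1")
  stopifnot(N_ancestral >= 1, burn_in_multiplier >= 0)
  structure(list(name = name, epochs = tab,
                 N_ancestral = as.numeric(N_ancestral),
                 burn_in_multiplier = as.numeric(burn_in_multiplier)),
            class = "satcpg_demography")
}

as_epoch_table <- function(epochs) {
  if (is.data.frame(epochs)) {
    need <- c("t_start", "t_end", "N_start", "growth_rate")
    if (!all(need %in% names(epochs))) {
      stop("epoch table needs columns: ", paste(need, collapse = ", "))
    }
    return(as.data.frame(lapply(epochs[need], as.numeric)))
  }
  if (inherits(epochs, "satcpg_epoch")) epochs <- list(epochs)
  do.call(rbind, lapply(epochs, function(e) {
    as.data.frame(unclass(e))
  }))
}

#' @export
print.satcpg_demography <- function(x, ...) {
  cat("Demographic model:", x$name, "\n")
  cat("  N_ancestral:", x$N_ancestral,
      " burn-in:", x$burn_in_multiplier, "x N_ancestral generations\n")
  cat("  epochs (young -> old):\n")
  print(x$epochs, row.names = FALSE)
  invisible(x)
}

#' Span of the post-burn-in model, in generations
#' @param model A [demographic_model()].
#' @return Oldest epoch boundary (generations before present).
#' @export
model_span <- function(model) max(model$epochs$t_start)

#' Burn-in duration of a model, in generations
#' @param model A [demographic_model()].
#' @return `round(burn_in_multiplier * N_ancestral)`.
#' @export
burn_in_generations <- function(model) {
  round(model$burn_in_multiplier * model$N_ancestral)
}

#' Diploid effective size at a given generation before present
#'
#' Piecewise-exponential interpolation within epochs; any generation at or
#' beyond the oldest epoch boundary (including the burn-in) returns
#' `N_ancestral`.
#'
#' @param model A [demographic_model()].
#' @param g Vector of generations before present (`>= 0`); generation 0 is
#'   the present.
#' @return Numeric vector of diploid sizes.
#' @export
size_at <- function(model, g) {
  if (any(g < 0)) stop("g must be >= 0")
  ep <- model$epochs
  out <- rep(model$N_ancestral, length(g))
  for (i in seq_len(nrow(ep))) {
    in_ep <- g >= ep$t_end[i] & g < ep$t_start[i]
    if (any(in_ep)) {
      out[in_ep] <- ep$N_start[i] *
        exp(ep$growth_rate[i] * (ep$t_start[i] - g[in_ep]))
    }
  }
  out
}

# Per-generation diploid size trajectory ordered oldest -> present, one
# entry per generation of the post-burn-in span; used by the forward engine.
size_trajectory <- function(model) {
  span <- round(model_span(model))
  if (span < 1) return(numeric(0))
  size_at(model, seq(span - 1, 0))
}

stylized_table <- function(which = c("ceu", "yri")) {
  which <- match.arg(which)
  path <- system.file("extdata", "demography",
                      paste0(which, "_stylized.json"), package = "satcpg")
  jsonlite::fromJSON(path)
}

#' Build a preset demographic model
#'
#' Stylized variants of the European (and one Yoruba) piecewise size
#' history used for single-site simulations, each modified in the most
#' recent generations:
#' \describe{
#'   \item{eur_recent10M}{diploid size 1e7 for the past 50 generations.}
#'   \item{eur_recent100M}{diploid size 1e8 for the past 50 generations.}
#'   \item{eur_expgrowth}{4.5\% exponential growth per generation over the
#'     past 196 generations, reaching ~1e8 at present.}
#'   \item{yri_recent10M}{Yoruba-like history with size 1e7 for the past
#'     50 generations.}
#'   \item{constant}{constant size `N` everywhere (one epoch of `span`
#'     generations plus burn-in at the same size).}
#' }
#' The intermediate epoch table is a documented stylized default shipped as
#' a JSON config in `inst/extdata/demography/`; reproducing an archived
#' MSMC-inferred trajectory requires supplying it via `epoch_table`.
#' `structured_two_pop` is reserved and raises a not-implemented error.
#'
#' @param name One of `"eur_recent10M"`, `"eur_recent100M"`,
#'   `"eur_expgrowth"`, `"yri_recent10M"`, `"constant"`.
#' @param N Constant diploid size (required for `"constant"`).
#' @param span Epoch length in generations for `"constant"`
#'   (default `4 * N`).
#' @param epoch_table Optional override data.frame
#'   (`t_start, t_end, N_start, growth_rate`) replacing the stylized base
#'   table (recent modifications are still applied).
#' @param burn_in_multiplier Burn-in length in units of ancestral size
#'   (default 10).
#' @return A [demographic_model()].
#' @export
demography_preset <- function(name, N = NULL, span = NULL,
                              epoch_table = NULL, burn_in_multiplier = 10) {
  valid <- c("eur_recent10M", "eur_recent100M", "eur_expgrowth",
             "yri_recent10M", "constant")
  if (identical(name, "structured_two_pop")) {
    stop("structured_two_pop (two-deme scenario) is not implemented")
  }
  if (!name %in% valid) {
    stop("unknown preset '", name, "'; valid presets: ",
         paste(valid, collapse = ", "))
  }
  if (name == "constant") {
    if (is.null(N)) stop("constant preset requires N")
    if (is.null(span)) span <- max(1, round(4 * N))
    return(demographic_model(
      data.frame(t_start = span, t_end = 0, N_start = N, growth_rate = 0),
      N_ancestral = N, burn_in_multiplier = burn_in_multiplier,
      name = "constant"))
  }
  base <- if (!is.null(epoch_table)) {
    as_epoch_table(epoch_table)
  } else if (name == "yri_recent10M") {
    stylized_table("yri")$epochs
  } else {
    stylized_table("ceu")$epochs
  }
  N_anc <- if (name == "yri_recent10M") 20000 else 14448
  tab <- base[order(base$t_end), , drop = FALSE]
  if (name %in% c("eur_recent10M", "eur_recent100M", "yri_recent10M")) {
    recent_N <- if (name == "eur_recent100M") 1e8 else 1e7
    tab <- splice_recent(tab, cut = 50,
                         data.frame(t_start = 50, t_end = 0,
                                    N_start = recent_N, growth_rate = 0))
  } else if (name == "eur_expgrowth") {
    # 4.5% growth over 196 generations from the base size at generation 196
    base_model <- demographic_model(tab, N_anc, burn_in_multiplier, name)
    n196 <- size_at(base_model, 196)
    tab <- splice_recent(tab, cut = 196,
                         data.frame(t_start = 196, t_end = 0, N_start = n196,
                                    growth_rate = log(1.045)))
  }
  demographic_model(tab, N_ancestral = N_anc,
                    burn_in_multiplier = burn_in_multiplier, name = name)
}

# Replace everything younger than `cut` generations with `recent`, trimming
# the epoch that straddles the cut.
splice_recent <- function(tab, cut, recent) {
  keep <- tab[tab$t_start > cut, , drop = FALSE]
  if (nrow(keep) > 0 && keep$t_end[1] < cut) keep$t_end[1] <- cut
  out <- rbind(recent, keep)
  out[order(out$t_end), , drop = FALSE]
}

#' Read / write a demographic model as JSON
#'
#' The serialized form carries `name`, `N_ancestral`, `burn_in_multiplier`
#' and the epoch table; round-tripping reproduces [size_at()] exactly.
#'
#' @param model A [demographic_model()].
#' @param path File path.
#' @return `read_demography` returns a [demographic_model()];
#'   `write_demography` returns `path` invisibly.
#' @export
write_demography <- function(model, path) {
  jsonlite::write_json(
    list(name = model$name, N_ancestral = model$N_ancestral,
         burn_in_multiplier = model$burn_in_multiplier,
         epochs = model$epochs),
    path, auto_unbox = TRUE, digits = I(17)) # 17 digits: exact round trip
  invisible(path)
}

#' @rdname write_demography
#' @export
read_demography <- function(path) {
  x <- jsonlite::fromJSON(path)
  demographic_model(x$epochs, N_ancestral = x$N_ancestral,
                    burn_in_multiplier = x$burn_in_multiplier,
                    name = if (is.null(x$name)) "custom" else x$name)
}

# Resolve a model argument that may be a model object, a preset name, or a
# path to a serialized model.
resolve_model <- function(model) {
  if (inherits(model, "satcpg_demography")) return(model)
  if (is.character(model) && length(model) == 1) {
    if (file.exists(model)) return(read_demography(model))
    return(demography_preset(model))
  }
  stop("model must be a satcpg_demography, a preset name, or a JSON path")
}
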