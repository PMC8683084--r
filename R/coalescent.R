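#' Simulate the total genealogy length of a sample
#'
#' Single-locus Kingman coalescent under the piecewise-exponential size
#' function of `model` (burn-in regime = constant ancestral size): with `k`
#' lineages, pairwise coalescence occurs at instantaneous rate
#' `choose(k, 2) / (2 N(t))` per generation; waiting times are drawn by
#' time rescaling with closed-form integrated rates (no discretization),
#' carrying residual exponential deviates across epoch boundaries. The
#' total length is `sum(k * T_k)` over the inter-coalescent intervals.
#'
#' @param model A [demographic_model()], preset name, or model JSON path.
#' @param n Number of sampled chromosomes (`>= 2`).
#' @param reps Number of replicate genealogies (default 20).
#' @param seed Integer RNG seed.
#' @return A list of class `"satcpg_tree_length"` with `n`, `mean_length`
#'   (generations), `se` (Monte-Carlo standard error), `reps`, and the
#'   per-replicate `lengths`.
#' @export
simulate_tree_length <- function(model, n, reps = 20, seed = 1L) {
  stopifnot(n >= 2, reps >= 1)
  model <- resolve_model(model)
  lens <- coal_len_cpp(n = as.numeric(n),
                       ep = as.matrix(model$epochs[, c("t_start", "t_end",
                                                      "N_start",
                                                      "growth_rate")]),
                       N_anc = model$N_ancestral, reps = as.integer(reps),
                       seed = as.numeric(seed), rep_offset = 0)
  structure(list(n = as.numeric(n), mean_length = mean(lens),
                 se = stats::sd(lens) / sqrt(reps), reps = as.integer(reps),
                 lengths = lens),
            class = "satcpg_tree_length")
}

#' @export
print.satcpg_tree_length <- function(x, ...) {
  cat(sprintf("Mean total tree length: %.4g generations (SE %.3g, n = %g, %d reps)\n",
              x$mean_length, x$se, x$n, x$reps))
  invisible(x)
}

#' Expected total tree length under constant population size
#'
#' Closed form for the Kingman coalescent with constant diploid size `N`:
#' `E[L] = 4 N * sum_{i=1}^{n-1} 1/i` generations.
#'
#' @param N Diploid effective size.
#' @param n Sampled chromosomes (`>= 2`).
#' @return Expected length in generations.
#' @export
expected_tree_length_constant <- function(N, n) {
  if (n < 2) stop("n must be >= 2")
  4 * N * sum(1 / seq_len(n - 1))
}

#' Expected number of mutations on a genealogy
#'
#' `u * L`: a site mutating at rate `u` per generation on a genealogy of
#' total length `L` generations experiences `u * L` mutations in
#' expectation.
#'
#' @param u Mutation rate per site per generation (`>= 0`).
#' @param L Total tree length in generations (`>= 0`).
#' @return Expected mutation count.
#' @export
expected_mutations <- function(u, L) {
  stopifnot(u >= 0, L >= 0)
  u * L
}

#' Ratio of mean tree lengths at two sample sizes
#'
#' Paired-seed Monte-Carlo ratio `E[L(n_large)] / E[L(n_small)]` with a
#' delta-method standard error using the per-replicate pairing.
#'
#' @param model A [demographic_model()] or preset name.
#' @param n_small,n_large Sample sizes, `n_large > n_small >= 2`.
#' @param reps Replicates (default 20).
#' @param seed Integer RNG seed (shared between the two sizes).
#' @return A list with `ratio`, `se`, and both tree-length results.
#' @export
length_ratio <- function(model, n_small, n_large, reps = 20, seed = 1L) {
  stopifnot(n_large >= n_small, n_small >= 2)
  small <- simulate_tree_length(model, n_small, reps, seed)
  large <- simulate_tree_length(model, n_large, reps, seed)
  r <- large$mean_length / small$mean_length
  ls <- small$lengths
  ll <- large$lengths
  vr <- r^2 * (stats::var(ll) / mean(ll)^2 + stats::var(ls) / mean(ls)^2 -
                 2 * stats::cov(ll, ls) / (mean(ll) * mean(ls))) / reps
  list(ratio = r, se = sqrt(max(vr, 0)), small = small, large = large)
}
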