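#' Prior specification for the selection coefficient
#'
#' Families for the prior on the homozygous selection coefficient `s`
#' (dominance `h` fixed per run, so the heterozygous effect is `hs`):
#' \describe{
#'   \item{log_uniform_s}{`log10(s) ~ Uniform(log10(lo), log10(hi))`;
#'     defaults `lo = 1e-7`, `hi = 1`.}
#'   \item{beta_s}{`s ~ Beta(alpha, beta)`; defaults `alpha = 0.001`,
#'     `beta = 0.1`.}
#'   \item{lognormal_log_s}{`log(s) ~ Normal(meanlog, sdlog)`; defaults
#'     `meanlog = -6`, `sdlog = 2`, natural log (`base = "e"`; set
#'     `base = "10"` for a log10 reading).}
#'   \item{gamma_Nes}{`Ne_ref * s ~ Gamma(shape, scale)`; defaults
#'     `shape = 0.23`, `scale = 425 / 0.23`, `Ne_ref = 10000`.}
#'   \item{two_point}{point masses at `s` with weights `w` (a test oracle
#'     family with exact Bayes arithmetic).}
#' }
#' Draws above 1 (possible in the gamma/lognormal tails) are clamped to 1.
#'
#' @param family Family name (see above).
#' @param params Named list of family parameters; unspecified entries take
#'   the defaults listed.
#' @param h Dominance coefficient (default 0.5).
#' @param Ne_ref Diploid size scaling `gamma_Nes` (default 10000).
#' @return A list of class `"satcpg_prior"`.
#' @export
prior_spec <- function(family = c("log_uniform_s", "beta_s",
                                  "lognormal_log_s", "gamma_Nes",
                                  "two_point"),
                       params = list(), h = 0.5, Ne_ref = 1e4) {
  family <- match.arg(family)
  defaults <- switch(family,
    log_uniform_s = list(lo = 1e-7, hi = 1),
    beta_s = list(alpha = 0.001, beta = 0.1),
    lognormal_log_s = list(meanlog = -6, sdlog = 2, base = "e"),
    gamma_Nes = list(shape = 0.23, scale = 425 / 0.23),
    two_point = list(s = c(1e-6, 1e-2), w = c(0.5, 0.5)))
  params <- utils::modifyList(defaults, params)
  switch(family,
    log_uniform_s = {
      if (!(params$lo > 0 && params$hi <= 1 && params$lo < params$hi)) {
        stop("log_uniform_s needs 0 < lo < hi <= 1")
      }
    },
    beta_s = stopifnot(params$alpha > 0, params$beta > 0),
    lognormal_log_s = {
      stopifnot(params$sdlog > 0)
      if (!params$base %in% c("e", "10")) stop("base must be 'e' or '10'")
    },
    gamma_Nes = stopifnot(params$shape > 0, params$scale > 0),
    two_point = {
      stopifnot(length(params$s) == length(params$w), all(params$s > 0),
                all(params$s <= 1), all(params$w >= 0), sum(params$w) > 0)
      params$w <- params$w / sum(params$w)
    })
  stopifnot(h >= 0, h <= 1, Ne_ref >= 1)
  structure(list(family = family, params = params, h = h, Ne_ref = Ne_ref),
            class = "satcpg_prior")
}

#' Draw selection coefficients from a prior
#'
#' @param spec A [prior_spec()].
#' @param m Number of draws (`>= 1`).
#' @param seed Integer seed.
#' @return Numeric vector of `m` values of `s` in `(0, 1]`.
#' @export
sample_prior <- function(spec, m, seed = 1L) {
  stopifnot(m >= 1)
  p <- spec$params
  s <- with_local_seed(seed, switch(spec$family,
    log_uniform_s = 10^stats::runif(m, log10(p$lo), log10(p$hi)),
    beta_s = stats::rbeta(m, p$alpha, p$beta),
    lognormal_log_s = if (p$base == "e") {
      exp(stats::rnorm(m, p$meanlog, p$sdlog))
    } else {
      10^stats::rnorm(m, p$meanlog, p$sdlog)
    },
    gamma_Nes = stats::rgamma(m, shape = p$shape, scale = p$scale) /
      spec$Ne_ref,
    two_point = sample(p$s, m, replace = TRUE, prob = p$w)))
  n_clamp <- sum(s > 1)
  if (n_clamp > 0) {
    message(n_clamp, " draw(s) above s = 1 clamped to 1")
    s[s > 1] <- 1
  }
  s
}

#' Closed-form prior probability that hs exceeds a threshold
#'
#' `P(h * s >= threshold_hs)` under the prior family (clamping at 1 does
#' not change upper-tail probabilities for thresholds below `h`).
#'
#' @param spec A [prior_spec()].
#' @param threshold_hs Threshold on the `hs` scale (e.g. `5e-4`).
#' @return Probability in `[0, 1]`.
#' @export
prior_prob_threshold <- function(spec, threshold_hs) {
  stopifnot(threshold_hs >= 0)
  if (threshold_hs == 0) return(1)
  if (spec$h == 0) return(0)
  st <- threshold_hs / spec$h
  p <- spec$params
  switch(spec$family,
    log_uniform_s = {
      if (st <= p$lo) 1
      else if (st >= p$hi) 0
      else (log10(p$hi) - log10(st)) / (log10(p$hi) - log10(p$lo))
    },
    beta_s = stats::pbeta(st, p$alpha, p$beta, lower.tail = FALSE),
    lognormal_log_s = if (p$base == "e") {
      stats::plnorm(st, p$meanlog, p$sdlog, lower.tail = FALSE)
    } else {
      stats::pnorm(log10(st), p$meanlog, p$sdlog, lower.tail = FALSE)
    },
    gamma_Nes = stats::pgamma(st * spec$Ne_ref, shape = p$shape,
                              scale = p$scale, lower.tail = FALSE),
    two_point = sum(p$w[p$s >= st]))
}

#' ABC posterior of the selection coefficient given a copy-number class
#'
#' Rejection-sampling approximate Bayesian computation: for each proposal,
#' draw `s` from the prior, simulate the site forward in time under the
#' template configuration, and accept `s` when the simulated copy-number
#' class matches the conditioning observation. The accepted values are a
#' sample from the posterior of `s` given that observation.
#'
#' @param prior A [prior_spec()]; its `h` overrides the template's.
#' @param sim_template A [site_sim_config()] (its `s` is ignored).
#' @param observed Conditioning class: `"zero"` (invariant), `"low"`
#'   (1-10 copies), `"high"` (more than 10 copies), `"segregating"`
#'   (pooled `0 < copies < n`), or `"any"` (no conditioning; posterior
#'   equals prior).
#' @param proposals Number of prior proposals (`>= 1`). The full-scale
#'   analysis used 1e7 proposals; desk-scale runs use far fewer, so
#'   posterior tail summaries carry correspondingly larger Monte-Carlo
#'   error.
#' @param seed Integer seed (proposal draws and simulations both derive
#'   from it).
#' @return A list of class `"satcpg_posterior"` with `accepted_s`,
#'   `proposals`, `acceptance_rate`, `condition`, `n_sample`, `h`.
#' @export
abc_posterior <- function(prior, sim_template, observed = "zero",
                          proposals = 1e5, seed = 1L) {
  stopifnot(inherits(prior, "satcpg_prior"),
            inherits(sim_template, "satcpg_sim_config"), proposals >= 1)
  observed <- match.arg(observed,
                        c("zero", "low", "high", "segregating", "any"))
  proposals <- as.integer(proposals)
  s <- sample_prior(prior, proposals, seed = derive_seed(seed, "abc_prior"))
  cfg <- sim_template
  cfg$h <- prior$h
  cfg$seed <- derive_seed(seed, "abc_sim")
  sims <- simulate_site_replicates(cfg, reps = proposals, s = s)
  ok <- switch(observed,
               zero = sims$copies == 0,
               low = sims$copies >= 1 & sims$copies <= 10,
               high = sims$copies > 10,
               segregating = sims$segregating,
               any = rep(TRUE, proposals))
  if (!any(ok)) {
    warning("no proposals accepted; posterior is empty and downstream ",
            "odds are undefined")
  }
  structure(list(accepted_s = s[ok], proposals = proposals,
                 acceptance_rate = mean(ok), condition = observed,
                 n_sample = sim_template$n_sample, h = prior$h),
            class = "satcpg_posterior")
}

#' @export
print.satcpg_posterior <- function(x, ...) {
  cat(sprintf(
    "ABC posterior | condition '%s', n = %d: %d / %d proposals accepted (%.3g)\n",
    x$condition, x$n_sample, length(x$accepted_s), x$proposals,
    x$acceptance_rate))
  invisible(x)
}

#' Posterior probability that hs exceeds a threshold
#'
#' @param post A [abc_posterior()] result (non-empty).
#' @param threshold_hs Threshold on the `hs` scale.
#' @return Fraction of accepted draws with `h * s >= threshold_hs`.
#' @export
posterior_prob_threshold <- function(post, threshold_hs) {
  if (length(post$accepted_s) == 0) stop("posterior is empty")
  stopifnot(threshold_hs >= 0)
  mean(post$h * post$accepted_s >= threshold_hs)
}

#' Bayes odds of strong selection
#'
#' The posterior odds of `hs >= threshold_hs` (from the empirical ABC
#' posterior) divided by the prior odds (closed form per family). Odds of
#' 1 mean the observation did not move the prior; large odds mean the
#' observed copy-number class is strong evidence of selection above the
#' threshold.
#'
#' @param post A [abc_posterior()] result.
#' @param prior The [prior_spec()] the posterior was drawn under.
#' @param threshold_hs Threshold on the `hs` scale (default `5e-4`, i.e.
#'   `s > 1e-3` at `h = 0.5`).
#' @return A list with `threshold`, `posterior_prob`, `prior_prob`,
#'   `posterior_odds`, `prior_odds`, `bayes_odds` (0 or `Inf` flagged via
#'   `degenerate`).
#' @export
bayes_odds <- function(post, prior, threshold_hs = 5e-4) {
  pp <- posterior_prob_threshold(post, threshold_hs)
  qp <- prior_prob_threshold(prior, threshold_hs)
  if (qp <= 0 || qp >= 1) {
    stop("prior probability of exceeding the threshold must be in (0, 1)")
  }
  post_odds <- if (pp >= 1) Inf else pp / (1 - pp)
  prior_odds <- qp / (1 - qp)
  list(threshold = threshold_hs, posterior_prob = pp, prior_prob = qp,
       posterior_odds = post_odds, prior_odds = prior_odds,
       bayes_odds = post_odds / prior_odds,
       degenerate = (pp <= 0 || pp >= 1))
}

#' Expected frequency under deterministic mutation-selection balance
#'
#' A deleterious allele arising at rate `u` and removed from heterozygous
#' carriers at rate `hs` per generation equilibrates at frequency
#' `q = u / hs` (valid while `q` is small; capped at 1 with a warning when
#' `u >= hs`).
#'
#' @param u Mutation rate per site per generation (`>= 0`).
#' @param hs Heterozygous selection coefficient (`> 0`).
#' @return Expected population frequency.
#' @export
msb_expected_frequency <- function(u, hs) {
  if (hs <= 0) stop("hs must be > 0")
  stopifnot(u >= 0)
  if (u >= hs) {
    warning("u >= hs: the balance approximation is invalid; capping at 1")
    return(1)
  }
  u / hs
}

#' Expected copies in a sample under mutation-selection balance
#'
#' `n * u / hs`: e.g. `u = 1.2e-7`, `hs = 5e-4` in a sample of 780,000
#' chromosomes gives about 187 copies.
#'
#' @inheritParams msb_expected_frequency
#' @param n Sampled chromosomes (`>= 0`).
#' @return Expected derived-allele count in the sample.
#' @export
msb_expected_copies <- function(u, hs, n) {
  stopifnot(n >= 0)
  n * msb_expected_frequency(u, hs)
}

#' Fraction of de novo mutations that are strongly deleterious, from a
#' two-class mixture
#'
#' Weights the posterior probability of strong selection at invariant and
#' at segregating sites by the fraction of sites in each category:
#' `frac_invariant * p_del_given_invariant +
#'  (1 - frac_invariant) * p_del_given_segregating`.
#'
#' @param frac_invariant Fraction of the annotation's sites invariant, in
#'   `[0, 1]`.
#' @param p_del_given_invariant,p_del_given_segregating Posterior
#'   probabilities of `hs` above the strong-selection threshold for
#'   invariant and segregating sites, in `[0, 1]`.
#' @return Proportion of de novo mutations of the class that are strongly
#'   deleterious.
#' @export
dfe_mixture_fraction <- function(frac_invariant, p_del_given_invariant,
                                 p_del_given_segregating) {
  args <- c(frac_invariant, p_del_given_invariant, p_del_given_segregating)
  stopifnot(all(args >= 0), all(args <= 1))
  frac_invariant * p_del_given_invariant +
    (1 - frac_invariant) * p_del_given_segregating
}

#' Probability that a de novo point mutation is strongly deleterious
#'
#' Combines the per-class deleterious fractions with the genome-wide
#' proportions of de novo point mutations that are missense or
#' loss-of-function:
#' `frac_missense_del * p_missense + frac_lof_del * p_lof`.
#'
#' @param frac_missense_del,frac_lof_del Strongly deleterious fractions
#'   within each class, in `[0, 1]`.
#' @param p_missense,p_lof Proportions of all de novo point mutations in
#'   each class, in `[0, 1]`.
#' @return A list with `rate` (probability per de novo point mutation) and
#'   `one_in` (its reciprocal, `Inf` flagged when the rate is 0).
#' @export
per_mutation_deleterious_rate <- function(frac_missense_del, p_missense,
                                          frac_lof_del, p_lof) {
  args <- c(frac_missense_del, p_missense, frac_lof_del, p_lof)
  stopifnot(all(args >= 0), all(args <= 1))
  rate <- frac_missense_del * p_missense + frac_lof_del * p_lof
  list(rate = rate, one_in = if (rate > 0) 1 / rate else Inf)
}

#' Expected strongly deleterious de novo mutations per birth
#'
#' `per_mutation * mutations_per_birth`, also expressed as "1 in X
#' individuals" carries such a mutation.
#'
#' @param per_mutation Probability per de novo mutation (`>= 0`).
#' @param mutations_per_birth Mean new mutations per individual (default
#'   70).
#' @return A list with `expectation` and `one_in_individuals`.
#' @export
per_individual_rate <- function(per_mutation, mutations_per_birth = 70) {
  stopifnot(per_mutation >= 0, mutations_per_birth >= 0)
  e <- per_mutation * mutations_per_birth
  list(expectation = e,
       one_in_individuals = if (e > 0) 1 / e else Inf)
}
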