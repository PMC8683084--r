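#' Configuration for single-site Wright-Fisher forward simulation
#'
#' Describes one bi-allelic site evolving forward in time under recurrent
#' mutation (`u`, ancestral -> derived), back mutation (`v`), diploid
#' viability selection (fitnesses `1`, `1 - hs`, `1 - s` for ancestral
#' homozygote, heterozygote, derived homozygote) and binomial drift through
#' the burn-in and epochs of `model`, with `n_sample` chromosomes drawn at
#' present.
#'
#' @param u Forward mutation rate per site per generation (e.g. 1.2e-7 for
#'   a methylated CpG transition).
#' @param v Back mutation rate per site per generation (e.g. 5e-9).
#' @param s Selection coefficient against the derived homozygote, in
#'   `[0, 1]`.
#' @param h Dominance coefficient (default 0.5, so `hs` is the heterozygous
#'   selection coefficient).
#' @param model A [demographic_model()], preset name, or model JSON path.
#' @param n_sample Chromosomes sampled at present (`>= 1`).
#' @param seed Integer RNG seed (`< 2^31`); replicate `r` uses an
#'   independent substream keyed by `(seed, r)`.
#' @param sampling `"binomial"` (with replacement from the final frequency;
#'   default, appropriate while `n_sample` is small relative to `2N`) or
#'   `"hypergeometric"` (without replacement from the final population).
#' @return A list of class `"satcpg_sim_config"`.
#' @export
site_sim_config <- function(u, v = 0, s = 0, h = 0.5, model, n_sample,
                            seed = 1L,
                            sampling = c("binomial", "hypergeometric")) {
  sampling <- match.arg(sampling)
  stopifnot(u >= 0, u <= 1, v >= 0, v <= 1, n_sample >= 1)
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  if (h * s < 0 || h * s > 1) stop("h*s must lie in [0, 1]")
  model <- resolve_model(model)
  structure(list(u = u, v = v, s = s, h = h, model = model,
                 n_sample = as.integer(n_sample), seed = as.numeric(seed),
                 sampling = sampling),
            class = "satcpg_sim_config")
}

#' Classify a derived-allele copy number
#'
#' Copy-number classes used throughout: `"zero"` (0 copies), `"low"`
#' (1-10 copies, bounds inclusive), `"high"` (more than 10 copies).
#'
#' @param copies Integer vector of derived-allele counts.
#' @return Character vector of classes.
#' @export
copy_class_of <- function(copies) {
  out <- ifelse(copies == 0, "zero", ifelse(copies <= 10, "low", "high"))
  out[copies < 0] <- NA_character_
  out
}

# Run the C++ engine for `reps` replicates; s may be length 1 or reps.
wf_run <- function(config, reps, s = config$s, rep_offset = 0,
                   mock_ref = FALSE) {
  m <- config$model
  res <- wf_sim_cpp(n_burn = burn_in_generations(m),
                    N_burn = m$N_ancestral,
                    N_traj = size_trajectory(m),
                    u = config$u, v = config$v,
                    s_vec = as.numeric(s), h = config$h,
                    n_sample = config$n_sample,
                    hypergeom = config$sampling == "hypergeometric",
                    seed = config$seed, rep_offset = rep_offset,
                    reps = as.integer(reps), mock_ref = mock_ref)
  if (any(res$wbar_zero > 0)) {
    warning("mean fitness hit zero in ", sum(res$wbar_zero > 0),
            " replicate(s); derived allele reset to frequency 0 there")
  }
  res
}

#' Simulate a single site forward in time
#'
#' Starting from derived frequency 0, iterates generation by generation
#' through the burn-in and the demographic epochs; each generation applies
#' deterministic mutation pressure, deterministic viability selection, and
#' binomial drift at the generation's population size. Fixation is not
#' absorbing: recurrent mutation re-seeds lost or fixed alleles.
#'
#' @param config A [site_sim_config()].
#' @param replicate Replicate index (substream selector; default 0).
#' @return A list of class `"satcpg_sim_result"` with `copies` (derived
#'   count in the sample), `pop_freq` (final population frequency),
#'   `segregating` (`0 < copies < n_sample`) and `copy_class`.
#' @export
simulate_site <- function(config, replicate = 0) {
  res <- wf_run(config, reps = 1, rep_offset = replicate)
  copies <- res$copies[1]
  structure(list(copies = copies, pop_freq = res$pop_freq[1],
                 segregating = copies > 0 && copies < config$n_sample,
                 copy_class = copy_class_of(copies)),
            class = "satcpg_sim_result")
}

#' Simulate many replicates of one site
#'
#' @param config A [site_sim_config()].
#' @param reps Number of replicates.
#' @param s Optional per-replicate selection coefficients (length `reps`),
#'   e.g. ABC proposals; defaults to the config's `s`.
#' @return A data.frame with one row per replicate: `replicate`, `copies`,
#'   `pop_freq`, `segregating`, `copy_class`.
#' @export
simulate_site_replicates <- function(config, reps, s = config$s) {
  res <- wf_run(config, reps = reps, s = s)
  data.frame(replicate = seq_len(reps) - 1L, copies = res$copies,
             pop_freq = res$pop_freq,
             segregating = res$copies > 0 & res$copies < config$n_sample,
             copy_class = copy_class_of(res$copies))
}

#' Probability that a site is segregating
#'
#' Monte-Carlo estimate: the proportion of independent forward simulations
#' in which both alleles are present in the sample at present, with its
#' binomial standard error. Replicate `r` is reproducible independently of
#' `reps` (counter-based substreams).
#'
#' @param config A [site_sim_config()].
#' @param reps Number of replicates (`>= 1`).
#' @return A list with `estimate`, `se`, `reps`.
#' @export
segregating_probability <- function(config, reps) {
  stopifnot(reps >= 1)
  if (config$u == 0 && config$v == 0) {
    return(list(estimate = 0, se = 0, reps = as.integer(reps)))
  }
  sims <- simulate_site_replicates(config, reps)
  p <- mean(sims$segregating)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = as.integer(reps))
}

#' Mock-reference discordance rates
#'
#' Emulates conditioning on the reference allele: at the end of each
#' replicate a single chromosome is drawn as a mock haploid reference
#' genome. Reports (i) the proportion of replicates in which the derived
#' allele is the reference while the ancestral allele is still present in
#' the population, and (ii) under the reversed mutation regime (site starts
#' in the derived state, forward rate `v`, back rate `u`), the proportion
#' in which the original ancestral allele is the reference.
#'
#' @param config A [site_sim_config()].
#' @param reps Replicates per regime.
#' @return A list with `derived_reference` and `reversed_reference`, each
#'   `(estimate, se)`, plus `reps`.
#' @export
mock_reference_rates <- function(config, reps) {
  stopifnot(reps >= 1)
  res1 <- wf_run(config, reps = reps, mock_ref = TRUE)
  p1 <- mean(res1$ref_is_derived & res1$pop_freq < 1)
  rev_cfg <- config
  rev_cfg$u <- config$v
  rev_cfg$v <- config$u
  rev_cfg$seed <- config$seed + 1
  res2 <- wf_run(rev_cfg, reps = reps, mock_ref = TRUE)
  p2 <- mean(res2$ref_is_derived)
  list(derived_reference = list(estimate = p1,
                                se = sqrt(p1 * (1 - p1) / reps)),
       reversed_reference = list(estimate = p2,
                                 se = sqrt(p2 * (1 - p2) / reps)),
       reps = as.integer(reps))
}
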