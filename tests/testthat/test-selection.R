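test_that("prior families draw from their stated distributions", {
  lu <- prior_spec("log_uniform_s")
  s <- sample_prior(lu, 1e4, seed = 4)
  expect_true(all(s >= 1e-7 & s <= 1))
  expect_equal(mean(s > 10^-3.5), 0.5, tolerance = 0.03)
  expect_equal(mean(s > 1e-3), 3 / 7, tolerance = 0.03)

  ln <- prior_spec("lognormal_log_s")
  expect_equal(stats::median(sample_prior(ln, 2e4, seed = 5)), exp(-6),
               tolerance = 0.15)
  ln10 <- prior_spec("lognormal_log_s", params = list(base = "10"))
  expect_equal(stats::median(log10(sample_prior(ln10, 2e4, seed = 5))), -6,
               tolerance = 0.1)

  be <- sample_prior(prior_spec("beta_s"), 5000, seed = 6)
  expect_true(all(be >= 0 & be <= 1))
  suppressMessages(ga <- sample_prior(prior_spec("gamma_Nes"), 5000, seed = 7))
  expect_true(all(ga > 0 & ga <= 1)) # tail draws clamped to 1

  expect_error(prior_spec("beta_s", params = list(alpha = -1)))
  expect_error(prior_spec("log_uniform_s", params = list(lo = 2, hi = 3)))
})

test_that("closed-form prior tail probabilities match the families", {
  lu <- prior_spec("log_uniform_s")
  expect_equal(prior_prob_threshold(lu, 5e-4), 3 / 7) # s > 1e-3 at h = 0.5
  expect_equal(prior_prob_threshold(lu, 0), 1)
  expect_equal(prior_prob_threshold(lu, 0.6), 0) # above support (s <= 1)
  ln <- prior_spec("lognormal_log_s")
  expect_equal(prior_prob_threshold(ln, 5e-4),
               stats::plnorm(1e-3, -6, 2, lower.tail = FALSE))
  tp <- prior_spec("two_point", params = list(s = c(1e-6, 1e-2),
                                              w = c(0.25, 0.75)))
  expect_equal(prior_prob_threshold(tp, 5e-4), 0.75)
})

test_that("unconditional acceptance recovers the prior (KS < 0.02)", {
  prior <- prior_spec("log_uniform_s")
  tmpl <- site_sim_config(u = 1e-5, model = const_model(20, span = 50),
                          n_sample = 5)
  post <- abc_posterior(prior, tmpl, observed = "any", proposals = 1e4,
                        seed = 3)
  expect_equal(post$acceptance_rate, 1)
  ks <- suppressWarnings(
    stats::ks.test(log10(post$accepted_s), "punif", -7, 0)$statistic)
  expect_lt(as.numeric(ks), 0.02)
  # and the Bayes odds are ~1 when the posterior is the prior
  bo <- bayes_odds(post, prior, 5e-4)
  expect_equal(bo$bayes_odds, 1, tolerance = 0.1)
})

test_that("ABC matches the exact two-point-prior Bayes computation", {
  s1 <- 1e-6; s2 <- 0.05
  prior <- prior_spec("two_point", params = list(s = c(s1, s2),
                                                 w = c(0.5, 0.5)))
  m <- const_model(500, span = 1000)
  tmpl <- site_sim_config(u = 2e-4, model = m, n_sample = 200, seed = 1)
  post <- abc_posterior(prior, tmpl, observed = "zero", proposals = 3000,
                        seed = 17)
  n2 <- sum(post$accepted_s == s2); n1 <- sum(post$accepted_s == s1)
  expect_gt(n1, 0)
  abc_odds <- bayes_odds(post, prior, threshold_hs = 1e-3)$bayes_odds

  # oracle: P(zero | s_i) estimated by direct simulation, independent seeds
  p_zero <- vapply(c(s1, s2), function(s) {
    cfg <- site_sim_config(u = 2e-4, s = s, model = m, n_sample = 200,
                           seed = 900 + round(s * 1000))
    mean(simulate_site_replicates(cfg, 1500)$copies == 0)
  }, numeric(1))
  oracle <- p_zero[2] / p_zero[1]

  # 3 combined SEs on the log-ratio scale (delta method)
  v_abc <- (1 - n2 / (n1 + n2)) / n2 + (1 - n1 / (n1 + n2)) / n1
  v_or <- sum((1 - p_zero) / (p_zero * 1500))
  expect_lt(abs(log(abc_odds) - log(oracle)), 3 * sqrt(v_abc + v_or))
})

test_that("posterior threshold probabilities behave at the boundaries", {
  prior <- prior_spec("log_uniform_s")
  tmpl <- site_sim_config(u = 1e-5, model = const_model(20, span = 50),
                          n_sample = 5)
  post <- abc_posterior(prior, tmpl, observed = "any", proposals = 500,
                        seed = 2)
  expect_equal(posterior_prob_threshold(post, 0), 1)
  expect_equal(posterior_prob_threshold(post, 1), 0) # above prior support
  empty <- post
  empty$accepted_s <- numeric(0)
  expect_error(posterior_prob_threshold(empty, 1e-3), "empty")
  expect_error(bayes_odds(post, prior, 2), "in \\(0, 1\\)")
})

test_that("an impossible conditioning observation yields an empty posterior
           with a warning, not an error", {
  prior <- prior_spec("log_uniform_s")
  tmpl <- site_sim_config(u = 0, v = 0, model = const_model(20, span = 50),
                          n_sample = 5)
  expect_warning(post <- abc_posterior(prior, tmpl, observed = "high",
                                       proposals = 50, seed = 1),
                 "no proposals accepted")
  expect_length(post$accepted_s, 0)
})

test_that("mutation-selection-balance arithmetic matches the printed values", {
  expect_equal(msb_expected_frequency(1.2e-7, 5e-4), 2.4e-4)
  expect_equal(msb_expected_frequency(0, 1e-3), 0)
  expect_warning(capped <- msb_expected_frequency(1e-3, 1e-4), "capping")
  expect_equal(capped, 1)
  expect_error(msb_expected_frequency(1e-7, 0), "> 0")
  expect_equal(msb_expected_copies(1.2e-7, 5e-4, 780000), 187.2)
  expect_equal(msb_expected_copies(1.2e-7, 5e-4, 0), 0)
  expect_equal(msb_expected_copies(1.2e-7, 5e-4, 2 * 780000),
               2 * msb_expected_copies(1.2e-7, 5e-4, 780000))
})

test_that("DFE mixture arithmetic is affine and reproduces the worked cases", {
  expect_equal(dfe_mixture_fraction(0.27, 0.92, 0.37), 0.5185) # ~52%
  expect_equal(dfe_mixture_fraction(0.05, 0.92, 0.37), 0.3975) # ~40%
  expect_equal(dfe_mixture_fraction(0, 0.8, 0.3), 0.3)
  # affine in the first argument
  a <- dfe_mixture_fraction(0.2, 0.9, 0.3)
  b <- dfe_mixture_fraction(0.4, 0.9, 0.3)
  c <- dfe_mixture_fraction(0.3, 0.9, 0.3)
  expect_equal((a + b) / 2, c)
  expect_error(dfe_mixture_fraction(1.2, 0.5, 0.5))

  pm <- per_mutation_deleterious_rate(0.40, 0.0097, 0.52, 0.0007)
  expect_equal(pm$rate, 0.004244)
  expect_equal(pm$one_in, 1 / 0.004244) # ~236
  expect_equal(per_mutation_deleterious_rate(0.40, 0.0097, 0, 0)$rate,
               0.00388)
  pi70 <- per_individual_rate(pm$rate, 70)
  expect_equal(pi70$expectation, 70 * 0.004244)
  expect_equal(pi70$one_in_individuals, 1 / (70 * 0.004244)) # ~3.4
  expect_equal(per_individual_rate(0.5, 0)$expectation, 0)
  expect_equal(per_individual_rate(0.01, 100)$one_in_individuals, 1)
})
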