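test_that("fraction_segregating matches the exact binomial interval", {
  rec <- records_with_counts(c("syn", "mis"), c(100, 50), c(99, 0))
  s <- fraction_segregating(rec)
  mis <- s[s$group == "mis", ]
  syn <- s[s$group == "syn", ]
  expect_equal(syn$fraction, 0.99)
  # independent oracle: stats::binom.test
  bt <- stats::binom.test(99, 100)$conf.int
  expect_equal(c(syn$ci_low, syn$ci_high), as.numeric(bt), tolerance = 1e-10)
  expect_true(syn$ci_low > 0.94 && syn$ci_high <= 1)
  expect_equal(mis$fraction, 0)
  expect_equal(mis$ci_low, 0)
  expect_error(fraction_segregating(rec[0, ]), "non-empty")
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(501)
  n <- 50
  p <- 0.3
  x <- stats::rbinom(1e4, n, p)
  lo <- ifelse(x == 0, 0, stats::qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, stats::qbeta(0.975, x + 1, n - x))
  expect_gte(mean(lo <= p & p <= hi), 0.94)
})

test_that("rescaling to the neutral class reproduces the annotation deficits", {
  rec <- records_with_counts(c("missense", "LOF", "synonymous"),
                             c(10000, 10000, 10000),
                             c(9350, 7213, 9880))
  s <- rescale_to_neutral(fraction_segregating(rec), "synonymous")
  expect_equal(s$rescaled_fraction[s$group == "missense"], 0.935 / 0.988,
               tolerance = 1e-12) # ~5.3% deficit
  expect_equal(s$rescaled_fraction[s$group == "LOF"], 0.7213 / 0.988,
               tolerance = 1e-12) # ~27% deficit
  expect_equal(s$rescaled_fraction[s$group == "synonymous"], 1)
  expect_true(all(s$fet_p[s$group != "synonymous"] < 1e-5))
  expect_error(rescale_to_neutral(s, "absent"), "not in summary")
})

test_that("fisher_exact_2x2 equals the enumeration oracle", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(1, 9, 9, 1), oracle_fisher_enum(1, 9, 9, 1),
               tolerance = 1e-12)
  # exhaustive on small margins
  for (r1 in 0:6) for (r2 in 0:6) for (a in 0:r1) for (c in 0:r2) {
    b <- r1 - a; d <- r2 - c
    if (r1 + r2 == 0 || (a + c) == 0 || (b + d) == 0 || r1 == 0 || r2 == 0) next
    expect_equal(fisher_exact_2x2(a, b, c, d),
                 oracle_fisher_enum(a, b, c, d), tolerance = 1e-12)
  }
  # random tables with both margins <= 20
  set.seed(77)
  for (i in 1:200) {
    r1 <- sample(1:20, 1); r2 <- sample(1:20, 1)
    a <- sample(0:r1, 1); c <- sample(0:r2, 1)
    if ((a + c) == 0 || (r1 - a + r2 - c) == 0) next
    expect_equal(fisher_exact_2x2(a, r1 - a, c, r2 - c),
                 oracle_fisher_enum(a, r1 - a, c, r2 - c), tolerance = 1e-12)
  }
  expect_warning(p <- fisher_exact_2x2(0, 0, 3, 4), "margin")
  expect_equal(p, 1)
  expect_equal(fisher_exact_2x2(1, 9, 9, 1, bonferroni = 4),
               min(1, 4 * oracle_fisher_enum(1, 9, 9, 1)), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), "integers")
})

test_that("invariance p-values and FDRs follow the printed arithmetic", {
  expect_equal(neutral_invariance_pvalue(0.988), 0.012)
  expect_equal(neutral_invariance_pvalue(0.10), 0.9)
  expect_equal(neutral_invariance_pvalue(0.05), 0.95)
  expect_equal(neutral_invariance_pvalue(0.27), 0.73)
  s <- fraction_segregating(records_with_counts("syn", 1000, 988))
  expect_equal(neutral_invariance_pvalue(s), 0.012)

  expect_equal(fdr_invariant(1.2, 7.4), 100 * 1.2 / 7.4)
  expect_equal(fdr_invariant(3.3, 3.3), 100)
  expect_warning(f <- fdr_invariant(5, 2), "100%")
  expect_equal(f, 250)
  expect_error(fdr_invariant(1, 0), "> 0")
  # identity: fdr * class fraction = 100 * neutral fraction
  for (ab in list(c(1.2, 7.4), c(0.5, 3), c(2, 2))) {
    expect_equal(fdr_invariant(ab[1], ab[2]) * ab[2], 100 * ab[1])
  }
})

test_that("covariate matching undoes a constructed confound and reduces to
           the unmatched comparison with one stratum", {
  set.seed(31)
  n <- 3000
  stratum <- c(sample(1:2, n, TRUE, prob = c(0.5, 0.5)),       # neutral
               sample(1:2, n, TRUE, prob = c(0.8, 0.2)))       # class
  rec <- data.frame(
    annotation = rep(c("synonymous", "cls"), each = n),
    covariate = stratum + stats::runif(2 * n, 0, 0.1),
    segregating = stats::rbinom(2 * n, 1, ifelse(stratum == 1, 0.6, 0.9)))
  m <- matched_fraction_segregating(rec, n_strata = 2)
  unmatched <- rescale_to_neutral(fraction_segregating(rec), "synonymous")
  un_cls <- unmatched$rescaled_fraction[unmatched$group == "cls"]
  ma_cls <- m$rescaled_fraction[m$group == "cls"]
  # the class is not actually under selection: matching should recover ~1
  expect_lt(un_cls, 0.95)
  expect_gt(abs(un_cls - 1) - abs(ma_cls - 1), 0.02)
  expect_equal(ma_cls, 1, tolerance = 0.05)

  m1 <- matched_fraction_segregating(rec, n_strata = 1)
  expect_equal(m1$rescaled_fraction[m1$group == "cls"], un_cls,
               tolerance = 1e-12)

  # covariate independent of everything: matched ~ unmatched
  rec$covariate <- stats::rnorm(2 * n)
  m2 <- matched_fraction_segregating(rec, n_strata = 10)
  expect_equal(m2$rescaled_fraction[m2$group == "cls"],
               rescale_to_neutral(fraction_segregating(rec),
                                  "synonymous")$rescaled_fraction[1],
               tolerance = 0.05)
  rec$covariate[1] <- NA
  expect_error(matched_fraction_segregating(rec), "covariate")
})

test_that("bin_sites builds rate-matched bins of k sites", {
  set.seed(4)
  n <- 1000
  rec <- data.frame(mutation_class = "T>A", u_site = 1.2e-9,
                    segregating = stats::rbinom(n, 1, 0.05))
  bins <- bin_sites(rec, U = 1.17e-7, shuffle_seed = 2)
  expect_equal(unique(bins$k), round(1.17e-7 / 1.2e-9)) # k ~ 98, order 100
  expect_equal(nrow(bins), n %/% unique(bins$k))
  expect_equal(bins$total_rate, rep(unique(bins$k) * 1.2e-9, nrow(bins)),
               tolerance = 1e-12)
  one <- bin_sites(rec, U = 1.2e-9)
  expect_equal(unique(one$k), 1)
  expect_equal(nrow(one), n) # k = 1: bins are individual sites
  expect_equal(sum(one$any_segregating), sum(rec$segregating))
  expect_error(bin_sites(rec[1:10, ], U = 1.17e-7), "fewer records")
  rec$mutation_class[1] <- "other"
  expect_error(bin_sites(rec, U = 1.17e-7), "one mutation_class")
})

test_that("deterministic bin frequency is U over the harmonic mean of hs", {
  expect_equal(bin_frequency_deterministic(1e-7, c(1e-3, 1e-2)), 5.5e-5)
  hs <- rep(2e-3, 7)
  expect_equal(bin_frequency_deterministic(1e-7, hs), 1e-7 / 2e-3)
  set.seed(8)
  hs <- stats::rlnorm(50, -6, 1)
  hmean <- length(hs) / sum(1 / hs)
  expect_equal(bin_frequency_deterministic(3e-7, hs), 3e-7 / hmean,
               tolerance = 1e-14)
  expect_equal(bin_frequency_deterministic(3e-7, 2 * hs),
               bin_frequency_deterministic(3e-7, hs) / 2, tolerance = 1e-14)
  expect_error(bin_frequency_deterministic(1e-7, c(1e-3, 0)), "hs")
})

test_that("DNM rates carry exact Poisson intervals", {
  r0 <- dnm_rate(0, 2976, 1e6)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)
  expect_equal(r0$ci_high, stats::qgamma(0.975, 1) / (2 * 2976 * 1e6),
               tolerance = 1e-12) # 3.689 / denominator
  r <- dnm_rate(100, 2976, 1e6)
  expect_equal(r$rate, 100 / (2 * 2976 * 1e6)) # 1.68e-8
  expect_lt(r$ci_low, r$rate)
  expect_gt(r$ci_high, r$rate)
  expect_error(dnm_rate(10, 2976, 0), "n_sites")
})

test_that("multi-hit comparison detects rate differences and handles
           degenerate tables", {
  set.seed(91)
  n <- 40000
  rec <- data.frame(
    compartment = rep(c("exon", "nonexon"), each = n),
    dnm_count = c(stats::rpois(n, 0.02), stats::rpois(n, 0.2)))
  mh <- multihit_counts(rec)
  expect_equal(dim(mh$counts), c(2L, 3L))
  expect_lt(mh$p, 0.05) # 10x rate difference is detectable at this n
  rec0 <- data.frame(compartment = rep(c("a", "b"), each = 5),
                     dnm_count = c(1, 1, 0, 0, 0, 1, 0, 0, 0, 0))
  expect_warning(mh0 <- multihit_counts(rec0), "multi-hit")
  expect_equal(mh0$p, 1)
})

test_that("pathogenic enrichment odds follow the 2x2 ratio", {
  expect_equal(pathogenic_enrichment_odds(30, 5, 100, 100), 6)
  expect_equal(pathogenic_enrichment_odds(10, 10, 70, 70), 1)
  expect_warning(o <- pathogenic_enrichment_odds(3, 0, 10, 10), "infinite")
  expect_identical(o, Inf)
})

test_that("genealogy-length estimators invert the Poisson saturation formula", {
  L <- genealogy_length_from_saturation(0.99, 1.17e-7)
  expect_equal(L, -log(0.01) / 1.17e-7) # ~3.94e7
  expect_equal(genealogy_length_from_saturation(0, 1e-7), 0)
  expect_error(genealogy_length_from_saturation(1, 1e-7), "infinite")
  # inverse-function property
  for (f in c(0.05, 0.27, 0.5, 0.99)) {
    u <- 1.17e-7
    expect_equal(1 - exp(-u * genealogy_length_from_saturation(f, u)), f,
                 tolerance = 1e-12)
  }
  expect_equal(genealogy_length_threshold(1.17e-7), 1 / 1.17e-7)
  expect_equal(genealogy_length_threshold(1), 1)
})

test_that("score deciles track a constructed selection gradient and stay
           flat without one", {
  set.seed(55)
  n <- 5000
  score <- stats::runif(n)
  rec <- data.frame(score = score,
                    segregating = stats::rbinom(n, 1, 0.9 - 0.5 * score),
                    dnm_count = stats::rpois(n, 0.01))
  s <- score_decile_summary(rec, n_trios = 2976)
  expect_equal(nrow(s), 10)
  expect_lt(stats::cor(s$decile, s$fraction), -0.9)
  expect_true(all(c("dnm_rate") %in% names(s)))
  rec$segregating <- stats::rbinom(n, 1, 0.5)
  flat <- score_decile_summary(rec)
  expect_lt(diff(range(flat$fraction)), 0.15)
})
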