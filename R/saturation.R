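#' Fraction of sites segregating, by group
#'
#' For each level of `group_by`, the fraction of sites with `segregating`
#' set, with an exact (Clopper-Pearson) binomial confidence interval.
#' Groups with no sites are omitted.
#'
#' @param records Site table (data.frame) with at least a logical/0-1
#'   `segregating` column and the grouping column.
#' @param group_by Name of the grouping column (default `"annotation"`).
#' @param conf Confidence level (default 0.95).
#' @return A data.frame of class `"annotation_summary"` with columns
#'   `group`, `n_sites`, `n_segregating`, `fraction`, `ci_low`, `ci_high`.
#' @export
fraction_segregating <- function(records, group_by = "annotation",
                                 conf = 0.95) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data.frame")
  }
  if (!group_by %in% names(records)) stop("missing column: ", group_by)
  if (!"segregating" %in% names(records)) stop("missing column: segregating")
  g <- factor(records[[group_by]])
  n <- as.vector(table(g))
  x <- as.vector(tapply(as.logical(records$segregating), g, sum))
  x[is.na(x)] <- 0
  keep <- n > 0
  ci <- clopper_pearson(x[keep], n[keep], conf)
  out <- data.frame(group = levels(g)[keep], n_sites = n[keep],
                    n_segregating = x[keep], fraction = x[keep] / n[keep],
                    ci_low = ci$low, ci_high = ci$high,
                    stringsAsFactors = FALSE)
  class(out) <- c("annotation_summary", "data.frame")
  out
}

clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  low <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  high <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  list(low = low, high = high)
}

#' Rescale segregating fractions to a neutral class
#'
#' Divides each group's fraction (and its CI bounds) by the neutral class's
#' point estimate -- an approximation that treats the neutral fraction as
#' known, reasonable when the neutral class is large -- and attaches a
#' two-sided Fisher exact p-value for the group-vs-neutral 2x2 table.
#'
#' @param summary An `annotation_summary` (one or more rows).
#' @param neutral A single `annotation_summary` row (e.g. the synonymous
#'   class), or the name of a group present in `summary`.
#' @return `summary` with added columns `rescaled_fraction`,
#'   `rescaled_ci_low`, `rescaled_ci_high`, `fet_p`.
#' @export
rescale_to_neutral <- function(summary, neutral) {
  if (is.character(neutral)) {
    i <- match(neutral, summary$group)
    if (is.na(i)) stop("neutral group '", neutral, "' not in summary")
    neutral <- summary[i, ]
  }
  if (nrow(neutral) != 1) stop("neutral must be a single summary row")
  if (neutral$fraction <= 0) stop("neutral fraction must be > 0")
  f0 <- neutral$fraction
  summary$rescaled_fraction <- summary$fraction / f0
  summary$rescaled_ci_low <- summary$ci_low / f0
  summary$rescaled_ci_high <- summary$ci_high / f0
  summary$fet_p <- vapply(seq_len(nrow(summary)), function(i) {
    fisher_exact_2x2(summary$n_segregating[i],
                     summary$n_sites[i] - summary$n_segregating[i],
                     neutral$n_segregating,
                     neutral$n_sites - neutral$n_segregating)
  }, numeric(1))
  summary
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test on the table `rbind(c(a, b), c(c, d))`: with
#' margins fixed, the first cell is hypergeometric; the two-sided p-value
#' sums the probabilities of all tables no more probable than the observed
#' one (the point-probability rule).
#'
#' @param a,b,c,d Non-negative integer cell counts (first row `a, b`,
#'   second row `c, d`).
#' @param bonferroni Multiplier for a Bonferroni correction (default 1);
#'   the returned p is capped at 1.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, bonferroni = 1) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("a margin of the 2x2 table is zero; returning p = 1")
    return(1)
  }
  support <- max(0, c1 - r2):min(c1, r1)
  pr <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  min(1, p * bonferroni)
}

#' Neutral-invariance p-value for a single invariant site
#'
#' Under the neutral null the probability that a site is invariant equals
#' one minus the fraction of neutral sites segregating; observing an
#' invariant site therefore rejects neutrality at level
#' `p = 1 - neutral_fraction`.
#'
#' @param neutral An `annotation_summary` row or a numeric fraction
#'   segregating.
#' @return The p-value.
#' @export
neutral_invariance_pvalue <- function(neutral) {
  f <- if (is.data.frame(neutral)) neutral$fraction else neutral
  stopifnot(length(f) == 1, f >= 0, f <= 1)
  1 - f
}

#' False discovery rate for invariant sites in an annotation
#'
#' The expected fraction of an annotation's invariant sites that are
#' invariant merely by chance under neutrality:
#' `100 * frac_invariant_neutral / frac_invariant_class`, both arguments on
#' the percent scale (e.g. `fdr_invariant(1.2, 7.4)` is 16).
#'
#' @param frac_invariant_neutral Percent of neutral sites invariant.
#' @param frac_invariant_class Percent of the annotation's sites invariant
#'   (`> 0`).
#' @return FDR in percent.
#' @export
fdr_invariant <- function(frac_invariant_neutral, frac_invariant_class) {
  stopifnot(frac_invariant_neutral >= 0)
  if (frac_invariant_class <= 0) stop("class invariant fraction must be > 0")
  if (frac_invariant_neutral > frac_invariant_class) {
    warning("neutral invariant fraction exceeds the class's; FDR > 100%")
  }
  100 * frac_invariant_neutral / frac_invariant_class
}

#' Covariate-matched segregating fractions
#'
#' Guards the annotation comparison against confounding by a covariate
#' (e.g. a linked-selection B statistic): the pooled covariate is cut into
#' `n_strata` quantile strata; the matched neutral fraction for a class is
#' the stratum-wise neutral fraction weighted by the class's stratum
#' occupancy. Strata with no neutral sites are dropped and the class
#' weights renormalized (with a message). `n_strata = 1` reduces to the
#' unmatched comparison.
#'
#' @param records Site table with `segregating`, the grouping column and
#'   the covariate column (no missing covariate values among used rows).
#' @param covariate_field Covariate column name (default `"covariate"`).
#' @param n_strata Number of quantile strata (default 10).
#' @param group_by Grouping column (default `"annotation"`).
#' @param neutral Name of the neutral group (default `"synonymous"`).
#' @return A data.frame with one row per group: `group`, `n_sites`,
#'   `fraction`, `matched_neutral_fraction`, `rescaled_fraction`.
#' @export
matched_fraction_segregating <- function(records,
                                         covariate_field = "covariate",
                                         n_strata = 10,
                                         group_by = "annotation",
                                         neutral = "synonymous") {
  z <- records[[covariate_field]]
  if (is.null(z) || anyNA(z)) stop("covariate must be present for all records")
  brk <- unique(stats::quantile(z, probs = seq(0, 1, length.out = n_strata + 1)))
  stratum <- if (length(brk) > 2) {
    cut(z, breaks = brk, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, length(z))
  }
  g <- records[[group_by]]
  seg <- as.logical(records$segregating)
  is_neu <- g == neutral
  if (!any(is_neu)) stop("no records in neutral group '", neutral, "'")
  strata <- sort(unique(stratum))
  f_neu <- vapply(strata, function(s) {
    i <- is_neu & stratum == s
    if (!any(i)) NA_real_ else mean(seg[i])
  }, numeric(1))
  groups <- unique(g)
  rows <- lapply(groups, function(gr) {
    gi <- g == gr
    occ <- vapply(strata, function(s) sum(gi & stratum == s), numeric(1))
    w <- occ / sum(occ)
    usable <- !is.na(f_neu)
    if (!all(usable[w > 0])) {
      message("dropping ", sum(!usable), " stratum/strata with no neutral ",
              "sites for group '", gr, "'; weights renormalized")
    }
    w_use <- w[usable] / sum(w[usable])
    matched <- sum(w_use * f_neu[usable])
    data.frame(group = as.character(gr), n_sites = sum(gi),
               fraction = mean(seg[gi]),
               matched_neutral_fraction = matched,
               rescaled_fraction = mean(seg[gi]) / matched,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group sites into bins with a target total mutation rate
#'
#' Builds bins of `k = round(U / mean(u_site))` sites so that each bin's
#' total mutation rate is about `U` (e.g. the mean methylated-CpG
#' transition rate), making a bin of low-rate sites comparable to one
#' highly mutable site. Records are shuffled by `shuffle_seed` and chunked;
#' a trailing remainder smaller than `k` is dropped.
#'
#' @param records Site table, all rows sharing one `mutation_class`, with
#'   `u_site` and `segregating` columns.
#' @param U Target per-bin mutation rate per generation.
#' @param shuffle_seed Integer seed for the shuffle.
#' @return A data.frame with columns `bin_id`, `k`, `total_rate`,
#'   `any_segregating`.
#' @export
bin_sites <- function(records, U, shuffle_seed = 1L) {
  if ("mutation_class" %in% names(records) &&
      length(unique(records$mutation_class)) > 1) {
    stop("all records must share one mutation_class")
  }
  u_mean <- mean(records$u_site)
  stopifnot(u_mean > 0, U > 0)
  k <- max(1L, as.integer(round(U / u_mean)))
  n <- nrow(records)
  if (n < k) stop("fewer records (", n, ") than the bin size k = ", k)
  idx <- with_local_seed(shuffle_seed, sample.int(n))
  n_bins <- n %/% k
  idx <- idx[seq_len(n_bins * k)]
  bin <- rep(seq_len(n_bins), each = k)
  data.frame(bin_id = seq_len(n_bins), k = k,
             total_rate = as.vector(tapply(records$u_site[idx], bin, sum)),
             any_segregating = as.vector(
               tapply(as.logical(records$segregating[idx]), bin, any)))
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Deterministic aggregate frequency of a bin under mutation-selection
#' balance
#'
#' For a bin of `k` sites with shared per-site rate `U / k` and
#' heterozygous selection coefficients `hs_i`, the expected aggregate
#' derived frequency is `(U / k) * sum(1 / hs_i)`, i.e.
#' `U / harmonic_mean(hs)` -- the bin's frequency carries information only
#' about the harmonic mean of selection across its sites.
#'
#' @param U Total per-bin mutation rate per generation.
#' @param hs_list Per-site heterozygous selection coefficients (all `> 0`).
#' @return Expected aggregate derived frequency.
#' @export
bin_frequency_deterministic <- function(U, hs_list) {
  stopifnot(U >= 0, length(hs_list) >= 1)
  if (any(hs_list <= 0)) {
    stop("all hs must be > 0 (deterministic balance undefined at hs <= 0)")
  }
  (U / length(hs_list)) * sum(1 / hs_list)
}

#' De novo mutation rate with exact Poisson confidence interval
#'
#' `rate = dnm_total / (2 * n_trios * n_sites)` mutations per site per
#' generation; the interval applies exact Poisson bounds to the count and
#' divides by the same denominator.
#'
#' @param dnm_total Total de novo mutation count (`>= 0`).
#' @param n_trios Number of sequenced trios (`> 0`); the haploid sample
#'   size is `2 * n_trios`.
#' @param n_sites Number of mutational opportunities (`> 0`).
#' @param conf Confidence level (default 0.95).
#' @return A list with `rate`, `ci_low`, `ci_high`, `dnm_total`,
#'   `denominator`.
#' @export
dnm_rate <- function(dnm_total, n_trios, n_sites, conf = 0.95) {
  stopifnot(dnm_total >= 0, n_trios > 0, n_sites > 0)
  denom <- 2 * n_trios * n_sites
  a <- (1 - conf) / 2
  lo <- if (dnm_total == 0) 0 else stats::qgamma(a, dnm_total)
  hi <- stats::qgamma(1 - a, dnm_total + 1)
  list(rate = dnm_total / denom, ci_low = lo / denom, ci_high = hi / denom,
       dnm_total = dnm_total, denominator = denom)
}

#' Single- versus multi-hit de novo counts across two compartments
#'
#' Counts sites with exactly one and with two or more de novo mutations in
#' each compartment (the multi-hit rate reflects the variance in mutation
#' rates across sites) and compares the two compartments with a Fisher
#' exact test.
#'
#' @param records Site table with `dnm_count` and the compartment column.
#' @param compartment_field Column naming the two compartments (default
#'   `"compartment"`).
#' @return A list with the per-compartment `counts` data.frame
#'   (`single`, `multi`) and the FET `p`.
#' @export
multihit_counts <- function(records, compartment_field = "compartment") {
  if (!"dnm_count" %in% names(records)) stop("dnm_count must be populated")
  comp <- factor(records[[compartment_field]])
  if (nlevels(comp) != 2) stop("exactly two compartments are required")
  single <- tapply(records$dnm_count == 1, comp, sum)
  multi <- tapply(records$dnm_count >= 2, comp, sum)
  counts <- data.frame(compartment = levels(comp),
                       single = as.vector(single),
                       multi = as.vector(multi))
  if (sum(counts$multi) == 0) {
    warning("no multi-hit sites in either compartment; p = 1")
    p <- 1
  } else {
    p <- fisher_exact_2x2(counts$single[1], counts$multi[1],
                          counts$single[2], counts$multi[2])
  }
  list(counts = counts, p = p)
}

#' Enrichment odds of pathogenicity at invariant sites
#'
#' `[(path_inv / benign_inv)] / [(path_total / benign_total)]`: how much
#' more likely an invariant site is to be classified pathogenic versus
#' benign, relative to the marginal pathogenic:benign odds.
#'
#' @param path_inv,benign_inv Pathogenic / benign counts among invariant
#'   sites.
#' @param path_total,benign_total Pathogenic / benign counts overall
#'   (`> 0`).
#' @return The enrichment odds (possibly `Inf` when `benign_inv` is 0).
#' @export
pathogenic_enrichment_odds <- function(path_inv, benign_inv, path_total,
                                       benign_total) {
  stopifnot(path_inv >= 0, benign_inv >= 0, path_total > 0, benign_total > 0)
  if (benign_inv == 0) {
    warning("no benign invariant sites; enrichment odds are infinite")
    return(Inf)
  }
  (path_inv / benign_inv) / (path_total / benign_total)
}

#' Genealogy length implied by a saturation fraction
#'
#' Inverts the Poisson probability of at least one mutation,
#' `f = 1 - exp(-u L)`, giving `L = -log(1 - f) / u` generations. With
#' `f = 0.99` and `u = 1.17e-7` this is about 39 million generations.
#'
#' @param f Fraction of sites segregating, in `[0, 1)`.
#' @param u Mutation rate per site per generation (`> 0`).
#' @return Implied total genealogy length in generations.
#' @export
genealogy_length_from_saturation <- function(f, u) {
  stopifnot(u > 0, f >= 0)
  if (f >= 1) stop("f = 1 implies an infinite genealogy")
  -log(1 - f) / u
}

#' Genealogy length at which one mutation is expected
#'
#' `1 / u` generations: the tree length above which a site mutating at
#' rate `u` expects at least one mutation (about 8.5 million generations
#' for methylated CpG transitions).
#'
#' @param u Mutation rate per site per generation (`> 0`).
#' @return Length in generations.
#' @export
genealogy_length_threshold <- function(u) {
  stopifnot(u > 0)
  1 / u
}

#' Segregating fraction and DNM rate by score decile
#'
#' Cuts a constraint score into deciles of its pooled distribution (ties
#' spanning decile edges go to the lower decile) and reports the fraction
#' of sites segregating per decile, plus the per-decile de novo mutation
#' rate when `dnm_count` is available and `n_trios` given.
#'
#' @param records Site table with `segregating` and the score column.
#' @param score_field Score column name (default `"score"`).
#' @param n_trios Optional trio count for the DNM rate.
#' @param conf Confidence level for the binomial CI.
#' @return A data.frame with one row per decile.
#' @export
score_decile_summary <- function(records, score_field = "score",
                                 n_trios = NULL, conf = 0.95) {
  sc <- records[[score_field]]
  if (is.null(sc) || anyNA(sc)) stop("score must be present for all records")
  brk <- unique(stats::quantile(sc, probs = seq(0, 1, 0.1)))
  if (length(brk) < 11) {
    message("tied score quantiles collapsed: ", 11 - length(brk),
            " duplicate break(s) dropped; ties assigned to the lower decile")
  }
  dec <- cut(sc, breaks = brk, include.lowest = TRUE, labels = FALSE)
  seg <- as.logical(records$segregating)
  out <- do.call(rbind, lapply(sort(unique(dec)), function(d) {
    i <- dec == d
    ci <- clopper_pearson(sum(seg[i]), sum(i), conf)
    row <- data.frame(decile = d, n_sites = sum(i),
                      fraction = mean(seg[i]),
                      ci_low = ci$low, ci_high = ci$high)
    if (!is.null(n_trios) && "dnm_count" %in% names(records)) {
      row$dnm_rate <- dnm_rate(sum(records$dnm_count[i]), n_trios,
                               sum(i))$rate
    }
    row
  }))
  rownames(out) <- NULL
  out
}
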