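# Independent oracles and small fixture builders used across test files.

# Full-enumeration two-sided Fisher exact test: enumerate every 2x2 table
# with the observed margins, compute each table's probability from
# binomial coefficients, and sum those no more probable than the observed
# table. Independent of dhyper().
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(c1, r1)
  tab_prob <- function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  }
  probs <- vapply(ks, tab_prob, numeric(1))
  p_obs <- tab_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Constant-size model with a short epoch span (equilibration happens in
# the burn-in), keeping forward runs cheap.
const_model <- function(N, span = 1000) {
  demography_preset("constant", N = N, span = span)
}

# Site table with exact segregating counts per group.
records_with_counts <- function(groups, n_sites, n_seg) {
  do.call(rbind, Map(function(g, n, x) {
    data.frame(annotation = g,
               segregating = rep(c(TRUE, FALSE), c(x, n - x)),
               stringsAsFactors = FALSE)
  }, groups, n_sites, n_seg))
}
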