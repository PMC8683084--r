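---
title: "Mutation saturation at methylated CpG sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation saturation at methylated CpG sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satcpg)
```

## The problem

Exome reference panels now contain hundreds of thousands of individuals.
For the most mutable class of sites in the human genome -- CpG dinucleotides
methylated in the germline, which deaminate to T at roughly `1e-7` per site
per generation -- samples of this size are *saturated*: in the absence of
selection, essentially every such site would have experienced at least one
C>T mutation somewhere in the genealogical history of the sample. Observing
an invariant methylated CpG site is then itself evidence of purifying
selection, without any modelling of allele frequencies. `satcpg` implements
the machinery needed to reason quantitatively in this regime:

1. a single-site Wright-Fisher forward simulator under piecewise demography
   (`simulate_site()`, `segregating_probability()`);
2. coalescent total-genealogy lengths under the same demographies
   (`simulate_tree_length()`), linking saturation to mutation rate via
   `P(segregating) = 1 - exp(-uL)`;
3. site-table statistics: segregating fractions with exact binomial
   intervals, rescaling to a neutral class, Fisher exact tests, invariance
   p-values and false discovery rates, covariate-matched comparisons,
   rate-matched bins, de novo mutation (DNM) rates with Poisson intervals;
4. approximate Bayesian computation (ABC) for the strength of selection
   `hs` conditional on a site's copy-number class, with Bayes odds of
   strong selection and mutation-selection-balance arithmetic;
5. a synthetic-data generator so that every stage is testable without
   access to cohort data.

## The forward model

Each site is bi-allelic. Writing `q` for the derived (T) frequency, one
generation applies, in order:

1. **mutation pressure** `q' = q(1 - v) + (1 - q)u`, with forward rate `u`
   (default `1.2e-7` for methylated CpG transitions) and back rate `v`
   (default `5e-9`);
2. **viability selection** with genotype fitnesses `1`, `1 - hs`,
   `1 - s`: `q'' = [q'^2(1-s) + q'(1-q')(1-hs)] / wbar`;
3. **drift** `q <- Binomial(2N_t, q'') / 2N_t`.

The order mutation -> selection -> drift is a design choice (the recursion
order is not dictated by the model description); it is covered by the
mutation-selection-balance oracle test, which recovers `q = u/hs` in the
deterministic regime `N hs >> 1` within 10%. Fixation is not absorbing:
recurrent mutation re-seeds lost or fixed alleles. When `s = 1` drives the
mean fitness to zero (`q' = 1`), the derived allele is reset to frequency 0
and the event is reported via a warning rather than aborting the run.

Sampling at present is binomial with replacement from the final frequency,
appropriate while the sample is a small fraction of `2N` (below 4% under
the default recent epoch); a hypergeometric option covers samples
comparable to the population. Replicate `r` of a run uses an RNG substream
keyed by `(seed, r)`, so individual replicates are reproducible no matter
how many are run or in what order.

## Demography

Models are ordered epochs of diploid size, each constant or exponentially
growing, tiling `[0, T_model)` generations before present, preceded by a
neutral burn-in of `burn_in_multiplier * N_ancestral` generations (default
10, exposed rather than hard-coded because "about ten" ancestral sizes is a
convention, not a measurement). The European presets use
`N_ancestral = 14448` and span 55,000 generations.

The intermediate epoch table is *stylized*: the archived MSMC-inferred
trajectory behind the original analyses is not printed anywhere we can
read it from, so the package ships a documented piecewise-constant
stand-in (`inst/extdata/demography/ceu_stylized.json`: ancestral 14,448,
out-of-Africa bottleneck 3,000, recovery 10,000, pre-expansion 17,914)
modified in the most recent generations by each preset
(`eur_recent10M`, `eur_recent100M`, `eur_expgrowth`, `yri_recent10M`).
The pre-expansion size 17,914 equals `1e8 / 1.045^196`, so that the
4.5%-growth scenario (per-generation rate `log(1.045)`) reaches ~1e8 at
present -- the one internal consistency check the scenario definitions
provide. Every preset accepts an `epoch_table` override; all quantities
that depend on the deep trajectory (for example the ~34-million-generation
mean genealogy of 780K chromosomes, or the ~3.3x length ratio between 65K
and 780K samples) are trajectory-dependent and are *not* reproduced by the
stylized table (it gives ~28-30 million and a larger ratio). Tests
therefore assert only the trajectory-independent structure: agreement with
the constant-size closed form `4N * H_{n-1}`, strongly sublinear growth of
length with `n`, and exact piecewise-exponential interpolation.

A two-population structured scenario is deliberately not implemented
(`demography_preset("structured_two_pop")` raises a not-implemented
error).

## Coalescent lengths and saturation arithmetic

`simulate_tree_length()` draws inter-coalescence times by time rescaling
through the piecewise-exponential size function, with closed-form
integrated rates inside each epoch and residual exponential deviates
carried across boundaries, so there is no discretization error (a test
compares one growth epoch against a 196-step piecewise-constant
approximation of itself). The implementation is O(n) coalescent events per
replicate and comfortably handles `n = 780000` on one CPU.

Saturation arithmetic connects lengths to observations:
`expected_mutations(u, L) = uL`;
`genealogy_length_from_saturation(f, u) = -log(1 - f)/u` (about 39 million
generations at `f = 0.99`, `u = 1.17e-7`); and
`genealogy_length_threshold(u) = 1/u` (about 8.5 million generations for
one expected methylated-CpG transition).

## Site-table statistics

* **Binomial intervals** are exact Clopper-Pearson (via beta quantiles):
  conservative and parameter-free; simulated coverage is >= 94%.
* **Rescaled fractions** divide a class's fraction segregating (and its CI
  bounds) by the *point estimate* of the neutral class: with hundreds of
  thousands of synonymous sites the neutral uncertainty is negligible, and
  the approximation is documented rather than propagated.
* **Fisher exact tests** are two-sided by the point-probability rule
  (sum of conditional table probabilities no larger than the observed
  one); mid-p variants were considered and rejected to match the standard
  convention. An optional Bonferroni multiplier handles families of
  annotation comparisons.
* **Invariance p-values and FDRs**: an invariant site rejects neutrality
  at `p = 1 - f_neutral`; the invariant-site FDR for an annotation is the
  ratio of invariant fractions (neutral over annotation), reported on the
  percent scale as printed (e.g. `fdr_invariant(1.2, 7.4)` is 16).
* **Covariate matching** stratifies the pooled covariate (for example a
  linked-selection B statistic) into quantile strata (default 10, a
  granularity choice the source analyses leave unstated) and reweights the
  neutral fraction by each class's stratum occupancy; strata with no
  neutral sites are dropped with renormalized weights and a message.
* **Rate-matched bins** use `k = round(U / mean(u_site))` sites per bin
  and drop the trailing remainder -- a partial bin would have inflated
  invariance probability and no clean interpretation.
* **DNM rates** divide Poisson-distributed counts by
  `2 * n_trios * n_sites`, with exact Poisson bounds on the count.

## Selection inference

The ABC scheme proposes `s` from a prior (default
`log10(s) ~ Uniform(-7, 0)` with `h = 0.5`; alternatives: `Beta(0.001,
0.1)`, `log(s) ~ Normal(-6, 2)`, and `Ne s ~ Gamma(0.23, 425/0.23)` at
`Ne = 10000`), simulates the site forward, and accepts proposals whose
simulated copy-number class (0, 1-10, or >10 copies; "1-10" read as
inclusive) matches the conditioning observation. Bayes odds of strong
selection divide the empirical posterior odds of `hs >= 5e-4` by the prior
odds computed in closed form (for the log-uniform prior, interval lengths:
`P(s > 1e-3) = 3/7`).

Decisions on points the source description leaves open:

* `log(s) ~ N(-6, 2)` is read as the **natural** log (the default choice
  of `log` in both R and the population-genetics literature); a
  `base = "10"` switch is provided.
* The "segregating" conditioning class is exposed both pooled
  (`"segregating"`) and per-class (`"low"`, `"high"`).
* An empty posterior (no acceptances) returns a diagnostic with a warning
  instead of resampling until acceptance, keeping run cost bounded and
  reproducible.
* Proposal counts: the full-scale analysis used 1e7 proposals at
  `n = 780000` chromosomes; desk-scale runs here use 1e3-1e4, so posterior
  tail summaries are checked against structural properties (prior recovery
  under unconditional acceptance with Kolmogorov distance < 0.02; exact
  two-point-prior Bayes arithmetic; monotone growth of the odds with
  sample size under paired seeds) rather than against full-scale point
  values such as 15:1 odds.

Mutation-selection-balance arithmetic (`msb_expected_frequency(u, hs) =
u/hs`, capped at 1 with a warning when `u >= hs`) and the
mixture bookkeeping (`dfe_mixture_fraction()`,
`per_mutation_deleterious_rate()`, `per_individual_rate()`) are
deterministic and tested at the printed values (52%, 40%, 1 in 236, 1 in
3.4).

## The synthetic generator: what it emulates, and what a green test means

`generate_site_table()` emits a per-mutational-opportunity table with
annotation classes, class-specific mutation rates (defaults `1.17e-7`
methylated CpG transitions, `0.9e-8` other C>T, `1.2e-9` T>A), germline
methylation with all mass at >= 0.65 for the methylated class, CpG
trinucleotide contexts, an optional constraint score correlated with the
true `hs`, an optional confounding covariate, and Poisson DNM counts at
rate `2 * n_trios * u` (default 2,976 trios). Per-site rates default to
the class constant -- rate variation among methylated CpGs is small
relative to the mean -- with optional lognormal jitter for robustness
checks. The default DFE is a two-point mixture per class (neutral sites
plus a strongly selected fraction: 0 for synonymous, ~5% of missense,
~27% of loss-of-function opportunities at `hs = 0.05`), matching the
depletion structure the statistics are designed to detect.

True selection coefficients are emitted in a **separate truth table**, not
as hidden columns, so statistics code cannot read them even accidentally;
a test verifies that pipeline outputs are identical with and without the
truth table for neutral data.

The generator does **not** emulate sequencing error, coverage masks,
population structure, linkage, or variable trio ascertainment. A green
end-to-end test therefore establishes that the statistics recover
parameters from data satisfying the model's own assumptions -- not that
those assumptions hold in any real cohort.

## Numerical and scale choices

* **Stem-lineage turnover.** A forward simulation spanning `T` generations
  converts `1 - exp(-uT)` of sites to fixed-derived (monomorphic T), an
  outcome the coalescent formula `1 - E[exp(-uL)]` does not model. At the
  real parameters (`u ~ 1e-7`, `T ~ 2e5`) this is a ~2% effect; at
  desk-scaled mutation rates it can dominate. The forward-vs-coalescent
  cross-check therefore runs at `u = 3e-6`, `N = 1000`, `n = 100`, where
  turnover is negligible relative to Monte-Carlo error.
* **Monotonicity of P(segregating) in s** holds across the deleterious
  range (balance frequency `u/hs` falls with `s`) but *not* across
  `s = 0` at desk scale: weak selection prevents the fixations that make
  neutral sites monomorphic-derived. Tests assert the ordering where the
  theory predicts it.
* The constant-size preset puts most of its duration in the burn-in
  (epoch span defaults to `4N`, overridable), since equilibration is the
  burn-in's job.
* Demography JSON uses 17 significant digits so serialization round-trips
  `size_at()` exactly.
* Seeds: every stage seed derives from one top-level seed via
  `derive_seed()` (documented multiply-and-hash modulo `2^31 - 1`), and
  all seeds stay below `2^31`.

## Known limitations

Single panmictic population (no structure, migration, or linkage); `hs`
fixed over time; deleterious-only DFE support (`s` in `[0, 1]`); Kingman
coalescent even at sample sizes where multiple mergers become relevant;
stylized default demography as discussed above. These mirror the scope of
the framework the package implements.
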