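---
title: "Quantifying nuclear-envelope association from chromosome banding patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear-envelope association from chromosome banding patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topokaryo)
```

## The measurement and its statistical model

Proximity-dependent biotinylation of histones by a nuclear-envelope-anchored
biotin ligase leaves a covalent mark on chromatin that was close to the
envelope during interphase.  On mitotic spreads this mark appears as a
banding pattern: each emerin-associated domain (EAD) of a chromosome is
either labeled or unlabeled in each cell.  Scoring one chromosome across
hundreds of spreads yields single-cell observations of a binary vector over
the domains — one constant domain (`EAD_C`, labeled in every spread) and
`K` variable domains (`EAD_V1 ... EAD_VK`).

The package encodes a banding pattern (BP) as an integer id in
`[0, 2^K)` with bit `i-1` holding the state of `EAD_Vi`; the conventional
figure labels `BP1 ... BP2^K` order patterns by the number of labeled
domains and then by id.  A scored experiment reduces to a multinomial
sample over the `2^K` patterns, per condition and replicate.

Three quantities drive the analysis:

* **Marginals.**  The association frequency of `EAD_Vi` is the summed
  frequency of all patterns in which it is labeled,
  `P_i = sum_{s : s_i = 1} f(s)`, with complement `Q_i = 1 - P_i`
  (`marginals_from_patterns()`).
* **Independence expectation.**  If domains associate independently with
  probabilities `P`, pattern `s` has expected frequency
  `prod_i P_i^{s_i} Q_i^{1 - s_i}` (`expected_patterns_independent()`).
  These products always sum to one, and re-deriving marginals from them
  returns `P` exactly — both properties are tested.
* **Deviation.**  Observed counts are compared with the expectation per
  pattern and globally (`pattern_gof_test()`), and summarized as
  `log2(observed / expected)` scores (`deviation_scores()`).

For the published der19 worked example (`der19_observed_patterns()`), the
marginals are (0.36, 0.235, 0.14) and the independence products reproduce
the printed expectations (0.42, 0.237, 0.129, ...).  Two printed values
deserve a note, both visible in `vignette` code rather than asserted
prose: the published table rounds the V3-only expectation 0.068544 down to
0.068, and its marginal-sum and product blocks disagree about which of the
two doubly-labeled patterns is which; the package resolves the latter by
the marginal arithmetic, which is unambiguous (the V1+V3 pattern was
observed at 0.02, V2+V3 at 0.03).

```{r worked-example}
m <- marginals_from_patterns(der19_observed_patterns())
m
expected_patterns_independent(m)[c("pattern_id", "bp_label", "frequency")]
```

## The goodness-of-fit protocol

Per pattern the package reports three related statistics on pooled counts:
the Pearson component `(O - E)^2 / E` (summing to the global statistic),
the 1-df pattern-vs-rest chi-square, and an exact two-sided binomial
p-value.  The binomial p is primary; because `2^K` patterns are tested at
once, the `significant` flag applies a Holm correction at `alpha = 0.05`.
Star annotations follow the conventional bands (`*` to `****` for p below
0.05, 0.01, 0.001, 0.0001) on the unadjusted p, matching how such figures
are usually annotated.

The global Pearson statistic uses `df = 2^K - 1 - K` when the expectation
was derived from the same data (the marginals consume `K` degrees of
freedom) and `df = 2^K - 1` for an external expectation.  A calibration
test (1,000 simulated experiments of 600 spreads under independence)
checks that the global test holds its nominal 5% level.

One caveat is structural rather than statistical: when only `2^K - 1`
observed frequencies are published, the remaining (here, all-unlabeled)
frequency must be imputed as the complement to one.  Rounding in the
published values then accumulates entirely in that imputed cell, which can
push it across significance thresholds at realistic sample sizes.  The
per-pattern table makes this visible instead of hiding it; conclusions
about the baseline pattern should rest on raw counts, not on re-derived
published frequencies.

Replicates are pooled for testing (the experimental unit for the
multinomial is the spread); per-replicate frequencies are retained by
`aggregate_patterns()` and `condition_marginals()` so that means ± SEM
across replicates can be reported alongside, as is conventional.

## Three association models

`fit_association_models()` compares, by maximized multinomial likelihood
and AIC:

* **independence** — `K` free probabilities, an "affinity gradient"
  without interaction;
* **cooperative chain** — association spreads from the constant anchor
  along the domain order as a first-order Markov chain: `EAD_Vi`
  associates with one probability when its predecessor (the anchor for
  `i = 1`) is associated and another when it is not.  That gives `2K - 1`
  free parameters with closed-form transition-count MLEs;
* **mutual exclusion** — support restricted to the `K + 1` patterns with
  at most one labeled domain.  The support frequencies are a multinomial
  with a sum-to-one constraint, hence `K` free parameters enter the AIC
  penalty.  Observed mass off the support would make the log-likelihood
  infinite; it is instead priced at the pseudo-frequency `0.5 / n`, the
  same rule used for zero cells in the deviation scores.  This keeps the
  fit finite while still penalizing off-support mass by roughly
  `log(2n)` per observation, so the model loses decisively whenever
  doubly-labeled patterns are common.

Simulation tests check both directions of the comparison: data generated
from a strongly coupled chain select the cooperative model essentially
always, while data generated under independence keep the independence
model within 2 AIC units of the best fit in the large majority of runs
(the chain nests independence, so its advantage under the null is bounded
by the `2(K - 1)` penalty).

## The synthetic spread generator

`simulate_spreads()` draws spreads under any of the three models, with the
study's design as defaults: 200 spreads per replicate, 3 replicates, one
constant domain.  Stress (heat shock, irradiation) is modeled as a single
multiplicative factor in `[0, 1]` on the association propensities —
independence `P`s, chain conditionals, or mutual-exclusion labeled-pattern
probabilities — reflecting the observation that stress reduced association
frequencies without altering the relationship between domains.  The
generator emulates scoring noise only as multinomial sampling; it does not
model annotation error, spread-quality selection, or between-replicate
overdispersion, so passing tests demonstrate correctness of the calculus
and calibration under the stated model, not robustness to those real-data
effects.

## The genomic enrichment track

The sequencing-side pipeline mirrors a standard binned IP/input analysis:

1. **Binning** (`bin_fragments()`): fragments are assigned to fixed-width
   bins (default 10 kb) by their integer midpoint.  The midpoint rule is a
   package choice — it assigns every fragment to exactly one bin, so
   totals are conserved; at fragment lengths (150 bp default) far below
   the bin width the difference from overlap-weighting is negligible.
2. **Ratio** (`log2_ratio_track()`): both tracks are scaled to counts per
   million, a pseudocount of 0.5 (CPM scale) keeps empty bins finite, and
   the value is `log2((cpm_ip + pc) / (cpm_input + pc))`.  CPM
   normalization removes library-size effects; note it also recenters the
   track, so absolute levels are relative to the genome-wide average while
   differences between regions are preserved.
3. **Smoothing**: a centered moving average over 5 adjacent bins,
   truncated at chromosome edges (the window shrinks rather than padding),
   so constant tracks are fixed points and `smooth_bins = 1` is the
   identity.
4. **Windows** (`window_means()`): bin values are averaged into 100-kb
   windows (bins assigned by start coordinate; edge windows average what
   is available).
5. **Monte Carlo test** (`monte_carlo_enrichment()`): the observed
   statistic is the mean window value over LAD-overlapping windows
   (overlap of at least 1 bp).  Each of 10,000 default iterations draws
   the same number of windows uniformly without replacement genome-wide
   and records the mean; the one-sided empirical p-value is
   `(1 + #(null >= obs)) / (1 + iterations)`, so the smallest attainable
   p is `1 / (1 + iterations)`.  A mean-signal statistic (rather than an
   overlap count) matches the region-vs-genome boxplot style of
   comparison; a chromosome-matched sampler and a two-sided alternative
   are available as options.
6. **Region summaries** (`region_means()`, `fraction_positive()`):
   per-LAD mean signal and the fraction of LADs with strictly positive
   enrichment; regions overlapping no bin are excluded and counted.

`simulate_pubnchip()` provides the matching generator: input midpoints
uniform over the genome, IP midpoints at relative rate `fold` inside LADs,
depth matched, per-bin counts approximately Poisson.  The default toy
genome (`toy_genome()`) has 3 chromosomes of 5 Mb with ten LADs of
100–500 kb (about 23% coverage) with all boundaries on 10-kb multiples —
big enough to exercise multi-chromosome bookkeeping, small enough that the
full pipeline runs in seconds.

When measuring recovery of a planted fold change, the package's tests
compare mean smoothed signal between bins whose whole smoothing window
lies inside versus entirely outside the LADs: bins within two bins of a
boundary are mixtures by construction of the moving average, so including
them biases the contrast low by design, not by error.  At depth 50
fragments per bin the recovered contrast for a 4-fold planting is
log2(4) within ±0.1 (an acceptance-level test runs exactly this).

## Problem sizes and determinism

All stochastic components take an explicit integer seed and are
reproducible bit-for-bit.  The shipped test suite uses desk-scale sizes
chosen to keep the whole suite around a minute while leaving comfortable
statistical margins: 1,000 simulated experiments for chi-square
calibration, 200 runs of 199 draws for Monte Carlo calibration, 100 seeds
of 10,000 spreads for model selection, and one toy-genome pipeline run at
depth 50.  The study's own sequencing comparison against external LAD
annotations requires the deposited data and is deliberately out of scope;
the synthetic recovery suite stands in for it and is labeled as synthetic
throughout.

## Known limitations

* Per-pattern inference pools replicates; a replicate-level random-effects
  model (overdispersion) is not implemented, and published-figure
  reconstructions from rounded frequencies inherit rounding error in the
  imputed baseline cell (see above).
* The cooperative model is a first-order chain in the fixed domain order;
  longer-range or bidirectional coupling is not parameterized.
* The enrichment pipeline starts from fragment intervals; alignment,
  duplicate handling and mappability are upstream concerns.
* Monte Carlo draws treat windows as exchangeable (optionally within
  chromosomes); spatial autocorrelation of real tracks is not preserved by
  the null, which is the standard trade-off of this test.
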