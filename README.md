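# topokaryo

Quantitative analysis of nuclear-envelope association from single-cell
chromosome banding patterns, with a companion pipeline for binned
IP/input sequencing enrichment at lamina-associated domains (LADs).

## The problem

Proximity-dependent biotinylation (a nuclear-envelope protein fused to
the biotin ligase BirA, a histone fused to its acceptor peptide) leaves a
covalent mark on chromatin that sat near the envelope during interphase.
On mitotic spreads the mark shows up as a banding pattern: each
emerin-associated domain (EAD) of a chromosome is labeled or unlabeled in
each cell.  Scoring one identifiable chromosome across hundreds of
spreads gives single-cell binary observations over one constant domain
(`EAD_C`) and `K` variable domains (`EAD_V1 ... EAD_VK`) — a multinomial
over the `2^K` banding patterns (BPs).

This package answers the questions such data pose:

* What is each domain's association frequency
  (`P_i = Σ_{s: s_i = 1} f(s)`, `Q_i = 1 − P_i`)?
* Do domains associate **independently**?  Under independence, pattern
  `s` is expected with frequency `Π_i P_i^{s_i} Q_i^{1−s_i}`; observed
  counts are tested against this per pattern (exact binomial,
  Holm-corrected) and globally (Pearson chi-square with
  `df = 2^K − 1 − K` when the marginals come from the same data).
* If not independent, is the dependence **cooperative** (association
  spreading domain-to-domain from the constant anchor, a Markov chain
  with `2K − 1` parameters) or **mutually exclusive** (at most one
  variable domain associated)?  All three models have closed-form
  maximum-likelihood fits and are ranked by AIC.

The genomic half of the package implements the matching sequencing
computation: fragment counts in 10-kb bins, depth-normalized
`log2(IP/input)` with 5-bin smoothing, 100-kb window means, and a Monte
Carlo test of mean signal in LAD-overlapping windows against random
window sets (empirical `p = (1 + #{null ≥ obs}) / (1 + iterations)`).
Synthetic generators for both data modalities make every stage testable
without external data.

## Worked example

The package ships the published control-condition observed frequencies of
the der19 chromosome (`der19_observed_patterns()`; three variable
domains, eight patterns, seven printed frequencies plus the complement
for the all-unlabeled pattern, scored at ~200 spreads × 3 replicates):

```r
library(topokaryo)
obs <- der19_observed_patterns(n_total = 600)

marginals_from_patterns(obs)
#> # A tibble: 3 × 3
#>   domain     p     q
#>   <chr>  <dbl> <dbl>
#> 1 EAD_V1 0.36  0.64
#> 2 EAD_V2 0.235 0.765
#> 3 EAD_V3 0.14  0.86

glance(pattern_gof_test(obs))
#> # A tibble: 1 × 6
#>   statistic    df  p_value n_total     K expected_from_data
#>       <dbl> <dbl>    <dbl>   <dbl> <int> <lgl>
#> 1      174.     4 1.62e-36     600     3 TRUE

glance(fit_association_models(obs))
#> # A tibble: 3 × 6
#>   model             n_params log_lik   aic delta_aic  rank
#>   <chr>                <int>   <dbl> <dbl>     <dbl> <int>
#> 1 cooperative_chain        5   -902. 1815.        0      1
#> 2 independence             3   -962. 1930.      116.     2
#> 3 mutual_exclusion         3  -1275. 2557.      742.     3
```

Reading the output: the domain marginals reproduce the published 36%,
23.5% and 14% association frequencies; the global chi-square firmly
rejects independent association (the fully labeled pattern alone is seen
at 6% against an expected 1.2%); and among the three candidate modes the
cooperative chain fits best by AIC while mutual exclusion is far worse —
dependence with an element of stochasticity, not exclusion.
`tidy(pattern_gof_test(obs))` gives the per-pattern table with observed
and expected counts, chi-square components, exact binomial p-values and
significance flags; `autoplot()` on any fitted object draws the matching
figure.

A command-line wrapper for batch use lives at `inst/cli/topokaryo`
(`patterns`, `enrich`, `simulate` subcommands); it only forwards flags to
`run_patterns()`, `run_enrich()`, `simulate_spreads()` and
`simulate_pubnchip()`, which write TSV/bedGraph outputs plus a
provenance record.

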