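# Shared fixtures, built in code.

# Published control-condition banding frequencies by pattern id
# (0 = none, bit i-1 = EAD_Vi), doubly-labeled patterns assigned so the
# per-domain sums give marginals (0.36, 0.235, 0.14).
published_freq <- c(0.515, 0.20, 0.065, 0.08, 0.03, 0.02, 0.03, 0.06)
published_marginals <- c(0.36, 0.235, 0.14)

# Printed expected frequencies under independence, by pattern id.
printed_expected <- c(0.42, 0.237, 0.129, 0.073, 0.068, 0.04, 0.021, 0.012)

# A tiny deterministic spread table: 3 replicates x 4 spreads, K = 2.
tiny_spreads <- function() {
  tibble::tibble(
    spread_id = sprintf("s%02d", 1:12),
    condition = "control",
    replicate = rep(1:3, each = 4),
    EAD_C = 1L,
    EAD_V1 = rep(c(1L, 1L, 0L, 0L), 3),
    EAD_V2 = rep(c(1L, 0L, 0L, 0L), 3)
  )
}

# Single-chromosome toy genome for unit tests of the track machinery.
mini_genome <- function(len = 1000000L) {
  tibble::tibble(chrom = "chr1", length = len)
}
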