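# Synthetic IP/input fragment sets over a toy genome with planted
# LAD enrichment, emulating the statistical structure of a
# proximity-biotinylation native-ChIP sequencing experiment: input
# fragment midpoints uniform over the genome, IP midpoints drawn with
# relative rate `fold` inside LADs and 1 outside, matched total depth.

#' Toy genome with planted lamina-associated domains
#'
#' Three 5-Mb chromosomes carrying ten LADs of 100-500 kb (about 23% of
#' the genome), enough to exercise multi-chromosome bookkeeping at desk
#' scale.  The layout is fixed (no randomness) and all boundaries are
#' multiples of 10 kb.
#'
#' @return A list with `genome` (tibble `chrom`, `length`) and `lads`
#'   (interval tibble).
#' @export
toy_genome <- function() {
  genome <- tibble(chrom = c("chr1", "chr2", "chr3"), length = 5000000L)
  lads <- tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1",
              "chr2", "chr2", "chr2",
              "chr3", "chr3", "chr3"),
    start = c(500000L, 1500000L, 2500000L, 4000000L,
              300000L, 1500000L, 3000000L,
              800000L, 2200000L, 3600000L),
    end = c(1000000L, 1800000L, 2900000L, 4200000L,
            700000L, 1750000L, 3500000L,
            1100000L, 2400000L, 4050000L)
  )
  list(genome = genome, lads = lads)
}

sample_midpoints <- function(n, intervals) {
  len <- intervals$end - intervals$start
  idx <- sample.int(nrow(intervals), n, replace = TRUE, prob = len)
  # Continuous position within the chosen interval, floored to a base.
  pos <- intervals$start[idx] + floor(runif(n) * len[idx])
  tibble(chrom = intervals$chrom[idx], mid = as.integer(pos))
}

midpoints_to_fragments <- function(mids, genome, fragment_length) {
  len <- setNames(genome$length, genome$chrom)
  half <- fragment_length %/% 2L
  start <- pmax(0L, mids$mid - half)
  end <- pmin(len[mids$chrom], start + as.integer(fragment_length))
  start <- pmax(0L, end - as.integer(fragment_length))
  tibble(chrom = mids$chrom, start = as.integer(start), end = as.integer(end)) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

#' Simulate an IP/input fragment pair with planted LAD enrichment
#'
#' Input fragment midpoints are uniform over the genome at the stated
#' depth; IP midpoints are drawn with relative rate `fold` inside the
#' LADs and 1 outside, with total depth matched to the input by default.
#' Per-bin counts are then approximately Poisson around their
#' expectations.  Bit-for-bit reproducible given the arguments and `seed`.
#'
#' @param genome Chromosome-length tibble (`chrom`, `length`).
#' @param lads LAD interval tibble (within the genome bounds).
#' @param fold Relative IP rate inside LADs (> 0; 1 = no enrichment).
#' @param depth Mean fragments per bin of width `bin_width` (sets the
#'   total fragment number).
#' @param bin_width Bin width used to convert `depth` into a total.
#' @param fragment_length Fragment length in bp (irrelevant to midpoint
#'   binning; kept for format realism).
#' @param matched_depth Draw exactly as many IP as input fragments.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list with interval tibbles `ip` and `input`.
#' @examples
#' tg <- toy_genome()
#' frags <- simulate_pubnchip(tg$genome, tg$lads, fold = 4, depth = 5, seed = 1)
#' @export
simulate_pubnchip <- function(genome, lads, fold = 4, depth = 50,
                              bin_width = 10000, fragment_length = 150,
                              matched_depth = TRUE, seed = NULL) {
  if (sum(genome$length) < 1) rlang::abort("genome has zero length")
  if (fold <= 0) rlang::abort("fold must be positive")
  if (depth <= 0) rlang::abort("depth must be positive")
  lads <- validate_intervals(lads, genome, what = "LAD set")
  n_bins <- sum(ceiling(genome$length / bin_width))
  n_frags <- as.integer(round(depth * n_bins))

  whole <- tibble(chrom = genome$chrom, start = 0L, end = genome$length)
  outside <- complement_intervals(lads, genome)
  lad_len <- sum(lads$end - lads$start)
  out_len <- sum(outside$end - outside$start)
  p_lad <- fold * lad_len / (fold * lad_len + out_len)

  draw <- function() {
    input_mids <- sample_midpoints(n_frags, whole)
    n_ip <- if (matched_depth) n_frags else as.integer(round(depth * n_bins))
    in_lad <- runif(n_ip) < p_lad
    ip_mids <- dplyr::bind_rows(
      sample_midpoints(sum(in_lad), lads),
      sample_midpoints(sum(!in_lad), outside)
    )
    list(input = input_mids, ip = ip_mids)
  }
  mids <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  list(
    ip = midpoints_to_fragments(mids$ip, genome, fragment_length),
    input = midpoints_to_fragments(mids$input, genome, fragment_length)
  )
}
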