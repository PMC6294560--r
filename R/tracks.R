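# Fixed-width binned tracks: fragment counting, depth-normalized log2
# IP/input ratios with adjacent-bin smoothing, and window aggregation.
# A track is a tibble with one row per bin (chrom, start, end, value or
# count); bins tile each chromosome, the terminal bin possibly partial.

#' Tile a genome into fixed-width bins
#'
#' @param genome Chromosome-length tibble (`chrom`, `length`).
#' @param bin_width Bin width in bp.
#' @return A tibble with `chrom`, `start`, `end`, covering every base;
#'   each chromosome has `ceiling(length / bin_width)` bins and the last
#'   bin is truncated at the chromosome end.
#' @export
genome_bins <- function(genome, bin_width = 10000) {
  if (bin_width < 1) rlang::abort("bin_width must be at least 1")
  bin_width <- as.integer(bin_width)
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq.int(0L, len - 1L, by = bin_width)
    tibble(chrom = genome$chrom[i], start = starts,
           end = pmin(starts + bin_width, len))
  })
}

#' Count fragments into fixed-width bins
#'
#' Each fragment is assigned to exactly one bin by its midpoint (integer
#' midpoint `floor((start + end) / 2)`), which conserves totals and is
#' unambiguous for fragments spanning bin boundaries.  A `count` column
#' on the input (bedGraph-style aggregated records) is used as a weight.
#'
#' @param fragments Interval tibble (`chrom`, `start`, `end`, optional
#'   `count`).
#' @param genome Chromosome-length tibble; fragments beyond a chromosome
#'   end are an error.
#' @param bin_width Bin width in bp (the study used 10 kb).
#' @return A binned track tibble (`chrom`, `start`, `end`, `count`) with
#'   every bin present.
#' @export
bin_fragments <- function(fragments, genome, bin_width = 10000) {
  fragments <- validate_intervals(fragments, genome, what = "fragment set")
  bins <- genome_bins(genome, bin_width)
  w <- if (!is.null(fragments[["count"]])) as.numeric(fragments[["count"]]) else
    rep(1, nrow(fragments))
  mid <- (fragments$start + fragments$end) %/% 2L
  hits <- tibble(chrom = fragments$chrom,
                 start = (mid %/% as.integer(bin_width)) * as.integer(bin_width),
                 w = w) |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(count = sum(.data$w), .groups = "drop")
  bins |>
    dplyr::left_join(hits, by = c("chrom", "start")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0))
}

check_geometry <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) ||
      !identical(as.integer(a$start), as.integer(b$start)) ||
      !identical(as.integer(a$end), as.integer(b$end))) {
    rlang::abort("tracks have mismatching bin geometry")
  }
}

#' Depth-normalized, smoothed log2 IP/input ratio track
#'
#' Both tracks are depth-normalized to counts per million, a pseudocount
#' is added to numerator and denominator, and the per-bin value is
#' `log2((cpm_ip + pc) / (cpm_input + pc))`.  The result is then smoothed
#' with a centered moving average over `smooth_bins` adjacent bins,
#' truncated at chromosome edges (the window shrinks near the ends, so a
#' constant track is a fixed point and `smooth_bins = 1` is the
#' identity).
#'
#' @param ip,input Binned count tracks with identical geometry (from
#'   [bin_fragments()]).
#' @param pseudocount Positive pseudocount on the CPM scale (default
#'   0.5).
#' @param smooth_bins Odd number of adjacent bins for the moving average
#'   (the study smoothed over 5).
#' @return A track tibble (`chrom`, `start`, `end`, `value`) of smoothed
#'   log2 ratios.
#' @export
log2_ratio_track <- function(ip, input, pseudocount = 0.5, smooth_bins = 5) {
  check_geometry(ip, input)
  if (pseudocount <= 0) rlang::abort("pseudocount must be positive")
  ip_total <- sum(ip$count)
  input_total <- sum(input$count)
  if (ip_total <= 0 || input_total <= 0) {
    rlang::abort("both tracks need positive total counts")
  }
  cpm_ip <- ip$count / ip_total * 1e6
  cpm_input <- input$count / input_total * 1e6
  out <- dplyr::select(ip, "chrom", "start", "end")
  out$value <- log2((cpm_ip + pseudocount) / (cpm_input + pseudocount))
  smooth_track(out, smooth_bins)
}

#' Centered moving-average smoothing of a track
#'
#' @param track Track tibble with a `value` column.
#' @param smooth_bins Odd window width in bins; 1 is the identity.
#' @return The track with smoothed `value`, computed per chromosome with
#'   edge truncation.
#' @export
smooth_track <- function(track, smooth_bins = 5) {
  if (smooth_bins < 1 || smooth_bins %% 2 != 1) {
    rlang::abort("smooth_bins must be a positive odd integer")
  }
  if (smooth_bins == 1) return(track)
  track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(value = zoo::rollapply(.data$value, width = smooth_bins,
                                         FUN = mean, align = "center",
                                         partial = TRUE)) |>
    dplyr::ungroup()
}

#' Aggregate a binned track into fixed-width windows
#'
#' Each window value is the arithmetic mean of the bin values it covers
#' (bins are assigned by their start coordinate; edge windows average the
#' available bins).
#'
#' @param track Track tibble with a `value` column.
#' @param window_width Window width in bp (the study used 100 kb);
#'   a multiple of the bin width is recommended.
#' @return A window track tibble (`chrom`, `start`, `end`, `value`,
#'   `n_bins`).
#' @export
window_means <- function(track, window_width = 100000) {
  window_width <- as.integer(window_width)
  if (window_width < 1) rlang::abort("window_width must be at least 1")
  track |>
    dplyr::mutate(win = (.data$start %/% window_width) * window_width) |>
    dplyr::group_by(.data$chrom, .data$win) |>
    dplyr::summarise(end = max(.data$end), value = mean(.data$value),
                     n_bins = dplyr::n(), .groups = "drop") |>
    dplyr::rename(start = "win") |>
    dplyr::select("chrom", "start", "end", "value", "n_bins") |>
    dplyr::arrange(.data$chrom, .data$start)
}
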