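# Region-level enrichment: overlap masking of windows against an interval
# set (LADs), Monte Carlo significance of the mean window signal, and
# fraction-positive summaries.

#' Flag windows overlapping a region set
#'
#' A window is flagged when it overlaps any region by at least 1 bp, so a
#' region spanning a window boundary flags both windows.
#'
#' @param windows Window track tibble (`chrom`, `start`, `end`, ...).
#' @param regions Interval tibble (e.g. LADs); empty regions give an
#'   all-`FALSE` mask.
#' @return `windows` with an added logical `in_region` column.
#' @export
region_overlap_mask <- function(windows, regions) {
  windows <- as_tibble(windows)
  if (is.null(regions) || nrow(regions) == 0) {
    windows$in_region <- FALSE
    return(windows)
  }
  regions <- validate_intervals(regions, what = "region set")
  hits <- IRanges::overlapsAny(as_granges(windows), as_granges(regions),
                                     minoverlap = 1L)
  windows$in_region <- as.logical(hits)
  windows
}

#' Monte Carlo test of region-window enrichment
#'
#' The observed statistic is the mean track value over region-overlapping
#' windows.  Each of `iterations` null draws samples the same number of
#' windows uniformly without replacement from all windows (genome-wide by
#' default, or per chromosome with `chromosome_matched = TRUE`) and
#' records their mean.  The empirical p-value is
#' `(1 + #(null >= observed)) / (1 + iterations)` for the one-sided
#' enrichment alternative (`"greater"`, the default), with `"less"` and
#' `"two.sided"` available.  Deterministic given `seed`.
#'
#' @param windows Window track with `value` and `in_region` columns (see
#'   [region_overlap_mask()]).
#' @param iterations Number of null draws (the study used 10 000).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param alternative `"greater"` (enrichment), `"less"` or
#'   `"two.sided"`.
#' @param chromosome_matched Resample window sets with the same
#'   per-chromosome composition as the region-overlapping set.
#' @return An object of class `mc_enrichment`; `glance()` gives a
#'   one-row summary, `tidy()` the null sample, `autoplot()` the null
#'   distribution with the observed statistic.
#' @export
monte_carlo_enrichment <- function(windows, iterations = 10000, seed = NULL,
                                   alternative = c("greater", "less", "two.sided"),
                                   chromosome_matched = FALSE) {
  alternative <- match.arg(alternative)
  if (is.null(windows[["in_region"]]) || is.null(windows[["value"]])) {
    rlang::abort("windows need `value` and `in_region` columns; see region_overlap_mask()")
  }
  if (iterations < 1) rlang::abort("iterations must be at least 1")
  mask <- windows$in_region
  n <- length(mask)
  k <- sum(mask)
  if (k == 0 || k == n) {
    rlang::abort("region mask must flag at least one window and not all of them")
  }
  observed <- mean(windows$value[mask])

  draw_null <- function() {
    if (!chromosome_matched) {
      vapply(seq_len(iterations),
             function(i) mean(windows$value[sample.int(n, k)]), numeric(1))
    } else {
      groups <- split(seq_len(n), windows$chrom)
      k_per <- vapply(groups, function(ix) sum(mask[ix]), integer(1))
      vapply(seq_len(iterations), function(i) {
        picked <- unlist(purrr::map2(groups, k_per, function(ix, ki) {
          if (ki == 0) integer(0) else ix[sample.int(length(ix), ki)]
        }), use.names = FALSE)
        mean(windows$value[picked])
      }, numeric(1))
    }
  }
  null <- if (is.null(seed)) draw_null() else
    withr::with_seed(as.integer(seed), draw_null())

  p_greater <- (1 + sum(null >= observed)) / (1 + iterations)
  p_less <- (1 + sum(null <= observed)) / (1 + iterations)
  p_value <- switch(alternative,
    greater = p_greater,
    less = p_less,
    two.sided = min(1, 2 * min(p_greater, p_less))
  )
  structure(
    list(observed = observed, null = null, p_value = p_value,
         iterations = as.integer(iterations), seed = seed,
         alternative = alternative, chromosome_matched = chromosome_matched,
         n_windows = n, n_region_windows = k),
    class = "mc_enrichment"
  )
}

#' @export
print.mc_enrichment <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo enrichment test (%s)\nobserved mean over %d/%d windows = %.4f\nnull: %d draws, mean = %.4f\np = %.4g\n",
    x$alternative, x$n_region_windows, x$n_windows, x$observed,
    x$iterations, mean(x$null), x$p_value))
  invisible(x)
}

#' @rdname monte_carlo_enrichment
#' @param x An `mc_enrichment` object.
#' @param ... Unused.
#' @export
glance.mc_enrichment <- function(x, ...) {
  tibble(
    observed = x$observed, null_mean = mean(x$null), null_sd = sd(x$null),
    p_value = x$p_value, iterations = x$iterations,
    n_windows = x$n_windows, n_region_windows = x$n_region_windows,
    alternative = x$alternative
  )
}

#' @rdname monte_carlo_enrichment
#' @export
tidy.mc_enrichment <- function(x, ...) {
  tibble(iteration = seq_along(x$null), null_statistic = x$null)
}

#' Per-region mean track signal
#'
#' Averages the values of all bins overlapping each region (>= 1 bp).
#' Regions overlapping no bin get `NA` and `n_bins = 0`.
#'
#' @param track Track tibble with a `value` column.
#' @param regions Interval tibble.
#' @return `regions` with added `mean_value` and `n_bins` columns.
#' @export
region_means <- function(track, regions) {
  regions <- validate_intervals(regions, what = "region set")
  if (nrow(regions) == 0) rlang::abort("region set is empty")
  hits <- GenomicRanges::findOverlaps(as_granges(track), as_granges(regions),
                                      minoverlap = 1L)
  agg <- tibble(
    region = S4Vectors::subjectHits(hits),
    value = track$value[S4Vectors::queryHits(hits)]
  ) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mean_value = mean(.data$value), n_bins = dplyr::n(),
                     .groups = "drop")
  regions$mean_value <- NA_real_
  regions$n_bins <- 0L
  regions$mean_value[agg$region] <- agg$mean_value
  regions$n_bins[agg$region] <- agg$n_bins
  regions
}

#' Fraction of regions with positive mean enrichment
#'
#' Computes the per-region mean track value and reports the fraction of
#' scored regions whose mean is strictly positive (ties at zero are not
#' positive).  Regions overlapping no bin are excluded from the
#' denominator and counted in `n_excluded`.
#'
#' @inheritParams region_means
#' @return A one-row tibble: `n_regions`, `n_scored`, `n_excluded`,
#'   `n_positive`, `fraction_positive`.
#' @export
fraction_positive <- function(track, regions) {
  rm <- region_means(track, regions)
  scored <- rm$n_bins > 0
  tibble(
    n_regions = nrow(rm),
    n_scored = sum(scored),
    n_excluded = sum(!scored),
    n_positive = sum(rm$mean_value[scored] > 0),
    fraction_positive = if (any(scored)) mean(rm$mean_value[scored] > 0) else NA_real_
  )
}
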