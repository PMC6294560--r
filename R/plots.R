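# ggplot2 views of the main result types.

#' @rdname pattern_gof_test
#' @param object A `pattern_gof` object.
#' @export
autoplot.pattern_gof <- function(object, ...) {
  df <- object$patterns |>
    dplyr::select("bp_label", observed = "observed_freq",
                  expected = "expected_freq", "stars") |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "source", values_to = "frequency")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bp_label, y = .data$frequency,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_text(
      data = dplyr::distinct(df, .data$bp_label, .data$stars),
      ggplot2::aes(x = .data$bp_label, label = .data$stars,
                   y = max(df$frequency) * 1.05),
      inherit.aes = FALSE, size = 3
    ) +
    ggplot2::labs(x = "banding pattern", y = "frequency", fill = NULL,
                  title = "Observed vs expected banding-pattern frequencies") +
    ggplot2::theme_minimal()
}

#' @rdname fit_association_models
#' @param object An `ead_model_fits` object.
#' @export
autoplot.ead_model_fits <- function(object, ...) {
  obs <- object$observed
  n <- sum(obs$count)
  labels <- enumerate_patterns(object$K)$bp_label
  df <- purrr::map_dfr(object$models, function(f) {
    tibble(bp_label = labels, model = f$model, frequency = f$fitted_freq)
  }) |>
    dplyr::bind_rows(tibble(bp_label = labels, model = "observed",
                            frequency = obs$count / n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bp_label, y = .data$frequency,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "banding pattern", y = "frequency", fill = NULL,
                  title = "Observed vs model-fitted pattern frequencies") +
    ggplot2::theme_minimal()
}

#' @rdname monte_carlo_enrichment
#' @param object An `mc_enrichment` object.
#' @export
autoplot.mc_enrichment <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_statistic)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "null mean window signal", y = "draws",
      title = sprintf("Monte Carlo enrichment test (p = %.3g)", object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-condition domain association frequencies
#'
#' Means with SEM error bars across replicates, one bar group per domain,
#' mirroring the usual presentation of stress-condition comparisons.
#'
#' @param summary A tibble from [condition_marginals()].
#' @return A ggplot object.
#' @export
plot_condition_marginals <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$domain, y = .data$mean_freq,
                                        fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_freq - .data$sem,
                   ymax = .data$mean_freq + .data$sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2,
      na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "association frequency", fill = NULL,
                  title = "Nuclear-envelope association by domain and condition") +
    ggplot2::theme_minimal()
}

#' Line plot of a binned track
#'
#' @param track Track tibble with a `value` (or `count`) column.
#' @param regions Optional interval tibble highlighted as shaded boxes
#'   (e.g. LADs).
#' @return A ggplot object, faceted by chromosome.
#' @export
plot_track <- function(track, regions = NULL) {
  value <- if (!is.null(track[["value"]])) track[["value"]] else track[["count"]]
  df <- dplyr::mutate(track, .value = value,
                      mid = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(df)
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "grey85"
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(x = .data$mid, y = .data$.value)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1,
                        scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "signal") +
    ggplot2::theme_minimal()
}
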