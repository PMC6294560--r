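# Goodness-of-fit of observed banding-pattern spectra against an expected
# distribution (typically the independence expectation derived from the
# same data's marginals).

#' Test observed banding patterns against expected frequencies
#'
#' Compares pooled observed pattern counts with expected frequencies, both
#' per pattern and globally.
#'
#' Per pattern, three related quantities are reported: the Pearson
#' component `(O - E)^2 / E` (these sum to the global statistic), the 1-df
#' pattern-vs-rest chi-square statistic `(O - E)^2 * n / (E * (n - E))`,
#' and the exact two-sided binomial p-value of the observed count given
#' the expected frequency.  The binomial p is the primary per-pattern
#' p-value; because `2^K` patterns are tested simultaneously, significance
#' flags use Holm-adjusted binomial p-values at `alpha`, while the
#' conventional star bands (`*`, `**`, `***`, `****` for p < 0.05, 0.01,
#' 0.001, 0.0001) annotate the unadjusted p.
#'
#' Globally, the Pearson chi-square over all patterns is reported with
#' `df = 2^K - 1 - K` when the expected frequencies were estimated from
#' the same data (marginals fitted, the default) and `df = 2^K - 1` when
#' an external expectation is supplied.
#'
#' @param observed Pattern distribution with integer counts (a data frame
#'   with `pattern_id` and `count`; condition/replicate rows are pooled).
#' @param expected Expected distribution: a data frame with `pattern_id`
#'   and `frequency` (normalized if necessary).  Default `NULL` derives
#'   the independence expectation from the observed marginals.
#' @param alpha Significance level for the Holm-adjusted flags.
#' @param p_adjust_method Multiplicity correction passed to
#'   [stats::p.adjust()].
#' @param K Number of variable domains (inferred when `NULL`).
#' @return An object of class `pattern_gof`.  `tidy()` returns the
#'   per-pattern table; `glance()` the global test; `autoplot()` an
#'   observed-vs-expected bar chart.
#' @examples
#' gof <- pattern_gof_test(der19_observed_patterns(n_total = 600))
#' glance(gof)
#' tidy(gof)
#' @export
pattern_gof_test <- function(observed, expected = NULL, alpha = 0.05,
                             p_adjust_method = "holm", K = NULL) {
  pooled <- pool_patterns(observed)
  if (any(abs(pooled$value - round(pooled$value)) > 1e-8)) {
    rlang::abort("observed pattern distribution must contain integer counts")
  }
  K <- infer_k(pooled$pattern_id, K)
  pooled <- complete_patterns(pooled, K)
  o <- round(pooled$value)
  n <- sum(o)
  if (n < 1) rlang::abort("observed pattern counts must total at least 1")

  expected_from_data <- is.null(expected)
  if (expected_from_data) {
    expected <- expected_patterns_independent(
      marginals_from_patterns(tibble(pattern_id = pooled$pattern_id, count = o), K = K)
    )
  }
  epool <- complete_patterns(pool_patterns(expected), K)
  if (sum(epool$value) <= 0) rlang::abort("expected distribution has zero total mass")
  e <- epool$value / sum(epool$value)
  E <- n * e

  zero_exp <- e <= 0 & o > 0
  component <- ifelse(E > 0, (o - E)^2 / E, ifelse(o > 0, Inf, 0))
  statistic <- ifelse(
    E > 0 & E < n,
    (o - E)^2 * n / (E * (n - E)),
    ifelse(o == round(E), 0, Inf)
  )
  p_chisq <- pchisq(statistic, df = 1, lower.tail = FALSE)
  p_binom <- vapply(seq_along(o), function(i) {
    if (zero_exp[i]) return(.Machine$double.xmin)
    if (e[i] >= 1) return(if (o[i] == n) 1 else .Machine$double.xmin)
    binom.test(o[i], n, p = e[i])$p.value
  }, numeric(1))
  p_adj <- p.adjust(p_binom, method = p_adjust_method)

  pats <- enumerate_patterns(K)
  table <- tibble(
    pattern_id = pooled$pattern_id,
    bp_label = pats$bp_label,
    observed_count = as.integer(o),
    observed_freq = o / n,
    expected_freq = e,
    expected_count = E,
    chisq_component = component,
    statistic = statistic,
    p_chisq = p_chisq,
    p_binomial = p_binom,
    p_adjusted = p_adj,
    significant = p_adj < alpha,
    stars = significance_stars(p_binom),
    zero_expected = zero_exp
  )

  global_stat <- sum(component)
  df <- 2L^K - 1L - (if (expected_from_data) K else 0L)
  structure(
    list(
      patterns = table,
      statistic = global_stat,
      df = df,
      p_value = pchisq(global_stat, df = df, lower.tail = FALSE),
      n_total = n,
      K = K,
      alpha = alpha,
      expected_from_data = expected_from_data,
      p_adjust_method = p_adjust_method
    ),
    class = "pattern_gof"
  )
}

#' Significance stars for p-values
#'
#' Conventional bands: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, otherwise `ns`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
significance_stars <- function(p) {
  cut(p,
      breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"),
      right = FALSE) |>
    as.character()
}

#' @export
print.pattern_gof <- function(x, ...) {
  cat(sprintf(
    "Banding-pattern goodness of fit (K = %d, n = %d)\n", x$K, x$n_total))
  cat(sprintf(
    "Global Pearson chi-square = %.3f, df = %d, p = %.3g (%s expectation)\n\n",
    x$statistic, x$df, x$p_value,
    if (x$expected_from_data) "data-derived independence" else "external"))
  print(dplyr::select(
    x$patterns, "bp_label", "observed_count", "expected_count",
    "p_binomial", "p_adjusted", "significant", "stars"
  ), n = nrow(x$patterns))
  invisible(x)
}

#' @rdname pattern_gof_test
#' @param x A `pattern_gof` object.
#' @param ... Unused.
#' @export
tidy.pattern_gof <- function(x, ...) x$patterns

#' @rdname pattern_gof_test
#' @export
glance.pattern_gof <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    n_total = x$n_total, K = x$K,
    expected_from_data = x$expected_from_data
  )
}

#' Per-pattern log2 observed/expected deviation scores
#'
#' Summarizes over/under-representation of each banding pattern as
#' `log2(observed frequency / expected frequency)`.  Zero frequencies on
#' either side are replaced by the pseudo-frequency `0.5 / n_total` so the
#' scores stay finite without materially shifting large-count estimates.
#'
#' @param observed Pattern distribution with counts (pooled if grouped).
#' @param expected Expected distribution (`pattern_id` + `frequency` or
#'   `count`).  Default derives the independence expectation from the
#'   observed marginals.
#' @param pseudo_frequency Replacement for zero frequencies; default
#'   `0.5 / n_total`.
#' @param K Number of variable domains (inferred when `NULL`).
#' @return A tibble with `pattern_id`, `bp_label`, `observed_freq`,
#'   `expected_freq`, `log2_ratio` (positive = over-represented).
#' @export
deviation_scores <- function(observed, expected = NULL,
                             pseudo_frequency = NULL, K = NULL) {
  pooled <- pool_patterns(observed)
  K <- infer_k(pooled$pattern_id, K)
  pooled <- complete_patterns(pooled, K)
  n <- sum(pooled$value)
  if (n <= 0) rlang::abort("observed distribution has zero total mass")
  of <- pooled$value / n
  if (is.null(expected)) {
    expected <- expected_patterns_independent(
      marginals_from_patterns(pooled |> dplyr::rename(count = "value"), K = K))
  }
  epool <- complete_patterns(pool_patterns(expected), K)
  ef <- epool$value / sum(epool$value)
  pf <- if (is.null(pseudo_frequency)) 0.5 / n else pseudo_frequency
  tibble(
    pattern_id = pooled$pattern_id,
    bp_label = enumerate_patterns(K)$bp_label,
    observed_freq = of,
    expected_freq = ef,
    log2_ratio = log2(ifelse(of > 0, of, pf) / ifelse(ef > 0, ef, pf))
  )
}
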