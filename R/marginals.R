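# Per-domain association frequencies (marginals) and the independence
# expectation over banding patterns.
#
# The core identity: if EAD_Vi associates with the nuclear envelope with
# probability P_i independently of the other domains (Q_i = 1 - P_i), the
# expected frequency of a pattern s is the product over domains of P_i when
# s_i is labeled and Q_i otherwise.

#' Per-domain association frequencies from a pattern distribution
#'
#' The association (biotinylation) frequency `P_i` of variable domain
#' `EAD_Vi` is the sum of the frequencies of all observed banding patterns
#' in which that domain is labeled; `Q_i = 1 - P_i` is its complement.
#' Counts are pooled over any grouping columns (condition, replicate)
#' present in the input.
#'
#' @param dist A pattern distribution: data frame with a `pattern_id`
#'   column and either a `count` or a `frequency` column.  All `2^K` ids
#'   need not be present; missing ids are treated as zero.
#' @param K Number of variable domains.  Defaults to the smallest K whose
#'   id range covers the data.
#' @return A tibble with one row per domain: `domain`, `p`, `q`.
#' @examples
#' obs <- der19_observed_patterns()
#' marginals_from_patterns(obs)
#' @export
marginals_from_patterns <- function(dist, K = NULL) {
  dist <- pool_patterns(dist)
  K <- infer_k(dist$pattern_id, K)
  total <- sum(dist$value)
  if (total <= 0) {
    rlang::abort("pattern distribution has zero total mass")
  }
  freq <- dist$value / total
  states <- pattern_states(dist$pattern_id, K)
  p <- as.numeric(crossprod(states, freq))
  tibble(domain = paste0("EAD_V", seq_len(K)), p = p, q = 1 - p)
}

#' Expected pattern frequencies under independent association
#'
#' Under the independence model each banding pattern `s` has expected
#' frequency `prod_i (P_i if s_i labeled else Q_i)`.  The output sums to 1
#' for any valid `P`.
#'
#' @param marginals Either a numeric vector of association probabilities
#'   `P` (one per variable domain, values in `[0, 1]`) or a tibble as
#'   returned by [marginals_from_patterns()].
#' @return A tibble as [enumerate_patterns()] with an added `frequency`
#'   column.
#' @examples
#' expected_patterns_independent(c(0.36, 0.235, 0.14))
#' @export
expected_patterns_independent <- function(marginals) {
  p <- marginal_p(marginals)
  K <- length(p)
  pats <- enumerate_patterns(K)
  states <- as.matrix(pats[paste0("EAD_V", seq_len(K))])
  freq <- rep(1, nrow(pats))
  for (i in seq_len(K)) {
    freq <- freq * ifelse(states[, i] == 1L, p[i], 1 - p[i])
  }
  pats$frequency <- freq
  pats
}

marginal_p <- function(marginals) {
  p <- if (is.data.frame(marginals)) marginals$p else marginals
  if (is.null(p) || !is.numeric(p) || length(p) < 1L) {
    rlang::abort("supply marginal probabilities as a numeric vector or a tibble with a `p` column")
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    rlang::abort("marginal probabilities must lie in [0, 1]")
  }
  p
}

#' Pool a pattern distribution over grouping columns
#'
#' Sums counts (or frequencies) over all rows sharing a `pattern_id`,
#' collapsing condition/replicate structure.
#'
#' @param dist Data frame with `pattern_id` and `count` or `frequency`.
#' @return A tibble with columns `pattern_id` and `value`, one row per id,
#'   sorted by id.
#' @export
pool_patterns <- function(dist) {
  if (!is.data.frame(dist) || is.null(dist$pattern_id)) {
    rlang::abort("a pattern distribution needs a `pattern_id` column")
  }
  value <- if (!is.null(dist[["count"]])) dist[["count"]] else dist[["frequency"]]
  if (is.null(value)) {
    rlang::abort("a pattern distribution needs a `count` or `frequency` column")
  }
  if (any(is.na(value)) || any(value < 0)) {
    rlang::abort("pattern counts/frequencies must be non-negative and non-missing")
  }
  tibble(pattern_id = as.integer(dist$pattern_id), value = as.numeric(value)) |>
    dplyr::group_by(.data$pattern_id) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$pattern_id)
}

# Complete a pooled distribution to all 2^K ids (zeros allowed).
complete_patterns <- function(pooled, K) {
  tibble(pattern_id = 0:(2L^K - 1L)) |>
    dplyr::left_join(pooled, by = "pattern_id") |>
    dplyr::mutate(value = dplyr::coalesce(.data$value, 0))
}

#' Observed banding-pattern frequencies of the der19 chromosome
#'
#' The published control-condition frequencies of the eight banding
#' patterns of the der(19)t(3;19) chromosome (three variable domains).
#' Seven frequencies were reported directly; the all-unlabeled pattern BP1
#' is their complement to 1 (0.515).  Useful as a worked example and as a
#' fixture for tests.
#'
#' @param n_total If supplied, returns integer counts `round(n_total *
#'   frequency)` instead of frequencies (the study scored roughly 200
#'   spreads per replicate in three replicates, i.e. 600).
#' @return A tibble with `pattern_id`, `bp_label` and `frequency` (or
#'   `count`).
#' @export
der19_observed_patterns <- function(n_total = NULL) {
  pats <- enumerate_patterns(3)
  # Frequencies keyed by labeled-domain combination (pattern id).  The two
  # doubly-labeled patterns are assigned so that the per-domain sums
  # reproduce the published marginals (0.36, 0.235, 0.14): the V1+V3
  # pattern was seen at 0.02 and V2+V3 at 0.03.
  freq <- c(NA, 0.20, 0.065, 0.08, 0.03, 0.02, 0.03, 0.06)[pats$pattern_id + 1L]
  freq[1L] <- 1 - sum(freq, na.rm = TRUE)
  out <- dplyr::select(pats, "pattern_id", "bp_label")
  if (is.null(n_total)) {
    out$frequency <- freq
  } else {
    out$count <- as.integer(round(n_total * freq))
  }
  out
}
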