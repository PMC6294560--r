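# Banding-pattern bookkeeping: binary labeling states over K variable
# emerin-associated domains (EAD_V1..EAD_VK), encoded as integer ids with
# bit i-1 = state of EAD_Vi (id 0 = all unlabeled).

#' Enumerate all banding patterns over K variable domains
#'
#' A banding pattern (BP) is the combination of labeled/unlabeled states of
#' the K variable emerin-associated domains of a chromosome in one mitotic
#' spread.  There are `2^K` patterns; each is encoded as an integer
#' `pattern_id` in `[0, 2^K)` with bit `i-1` holding the state of `EAD_Vi`,
#' so the all-unlabeled pattern has id 0.  The conventional `BP` numbering
#' used for figures orders patterns by the number of labeled domains and
#' then by id, so for K = 3: BP1 = none, BP2 = V1, BP3 = V2, BP4 = V3,
#' BP5 = V1+V2, BP6 = V1+V3, BP7 = V2+V3, BP8 = all.
#'
#' @param K Number of variable domains, an integer in `[1, 16]`.
#' @return A tibble with `2^K` rows in `pattern_id` order and columns
#'   `pattern_id`, `bp_label`, `n_labeled`, and one 0/1 column per domain
#'   (`EAD_V1` ... `EAD_VK`).
#' @examples
#' enumerate_patterns(3)
#' @export
enumerate_patterns <- function(K) {
  K <- check_k(K)
  ids <- 0:(2L^K - 1L)
  states <- pattern_states(ids, K)
  n_labeled <- as.integer(rowSums(states))
  bp <- integer(length(ids))
  bp[order(n_labeled, ids)] <- seq_along(ids)
  out <- tibble(
    pattern_id = ids,
    bp_label = paste0("BP", bp),
    n_labeled = n_labeled
  )
  dplyr::bind_cols(out, as_tibble(states))
}

#' Convert pattern ids to a 0/1 state matrix
#'
#' @param ids Integer vector of pattern ids in `[0, 2^K)`.
#' @param K Number of variable domains.
#' @return Integer matrix with `length(ids)` rows and columns
#'   `EAD_V1` ... `EAD_VK`; entry 1 means the domain is labeled.
#' @export
pattern_states <- function(ids, K) {
  K <- check_k(K)
  ids <- as.integer(ids)
  if (any(is.na(ids)) || any(ids < 0L) || any(ids >= 2L^K)) {
    rlang::abort(sprintf("pattern ids must be integers in [0, %d)", 2L^K))
  }
  m <- vapply(seq_len(K), function(i) (ids %/% (2L^(i - 1L))) %% 2L,
              numeric(length(ids)))
  m <- matrix(as.integer(m), nrow = length(ids), ncol = K)
  colnames(m) <- paste0("EAD_V", seq_len(K))
  m
}

#' Convert a 0/1 state matrix to pattern ids
#'
#' @param states 0/1 matrix (or data frame) with one column per variable
#'   domain, column order `EAD_V1` ... `EAD_VK`.
#' @return Integer vector of pattern ids.
#' @export
pattern_ids <- function(states) {
  states <- as.matrix(states)
  if (!all(states %in% c(0, 1))) {
    rlang::abort("domain states must be 0 or 1")
  }
  K <- ncol(states)
  check_k(K)
  as.integer(states %*% 2L^(seq_len(K) - 1L))
}

check_k <- function(K) {
  if (length(K) != 1L || is.na(K) || K != as.integer(K) || K < 1L || K > 16L) {
    rlang::abort("K must be a single integer between 1 and 16")
  }
  as.integer(K)
}

# Infer K from a set of pattern ids (all ids in [0, 2^K) with the maximum
# id requiring K bits).
infer_k <- function(ids, K = NULL) {
  if (!is.null(K)) return(check_k(K))
  m <- max(ids)
  if (m < 1L) return(1L)
  as.integer(ceiling(log2(m + 1L)))
}
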