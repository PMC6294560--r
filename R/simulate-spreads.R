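# Generators for per-spread domain annotations under explicit association
# models, emulating the study design: ~200 spreads per condition in each
# of 3 replicates, one constant domain plus K variable domains, with an
# optional multiplicative "stress" reduction of association propensities.

#' Association model specifications
#'
#' Constructors for the three association modes used by
#' [simulate_spreads()] and fitted by [fit_association_models()].
#'
#' * `independence_model(p)`: each variable domain `EAD_Vi` associates
#'   with probability `p[i]`, independently.
#' * `cooperative_chain_model(p_given_labeled, p_given_unlabeled, K)`:
#'   association spreads from the constant anchor along the domain order;
#'   `EAD_Vi` associates with probability `p_given_labeled[i]` when the
#'   previous domain (the always-associated anchor, for i = 1) is
#'   associated, and `p_given_unlabeled[i]` otherwise.  Scalars are
#'   recycled to length `K`.
#' * `mutual_exclusion_model(prob)`: at most one variable domain
#'   associates per cell; `prob` has length `K + 1` and gives the
#'   probabilities of (none, only V1, ..., only VK).  Must sum to 1.
#'
#' @param p,p_given_labeled,p_given_unlabeled,prob Probabilities in
#'   `[0, 1]`.
#' @param K Number of variable domains.
#' @return A model specification object (class `ead_model_spec`).
#' @export
independence_model <- function(p) {
  check_prob(p, "p")
  new_model_spec("independence", K = length(p), p = p)
}

#' @rdname independence_model
#' @export
cooperative_chain_model <- function(p_given_labeled, p_given_unlabeled, K = NULL) {
  if (is.null(K)) K <- max(length(p_given_labeled), length(p_given_unlabeled))
  K <- check_k(K)
  pl <- rep_len(p_given_labeled, K)
  pu <- rep_len(p_given_unlabeled, K)
  check_prob(pl, "p_given_labeled")
  check_prob(pu, "p_given_unlabeled")
  new_model_spec("cooperative_chain", K = K,
                 p_given_labeled = pl, p_given_unlabeled = pu)
}

#' @rdname independence_model
#' @export
mutual_exclusion_model <- function(prob) {
  check_prob(prob, "prob")
  if (length(prob) < 3) {
    rlang::abort("mutual exclusion needs K >= 2, i.e. at least 3 pattern probabilities")
  }
  if (abs(sum(prob) - 1) > 1e-8) {
    rlang::abort("mutual-exclusion pattern probabilities must sum to 1")
  }
  new_model_spec("mutual_exclusion", K = length(prob) - 1L, prob = prob)
}

new_model_spec <- function(model, K, ...) {
  structure(list(model = model, K = check_k(K), ...), class = "ead_model_spec")
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) < 1 || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    rlang::abort(sprintf("`%s` must be probabilities in [0, 1]", what))
  }
  invisible(p)
}

#' @export
print.ead_model_spec <- function(x, ...) {
  cat(sprintf("<ead_model_spec: %s, K = %d>\n", x$model, x$K))
  utils::str(x[setdiff(names(x), c("model", "K"))], give.attr = FALSE)
  invisible(x)
}

# Stress is modeled as a multiplicative reduction of association
# propensities, leaving the dependence structure itself untouched.
apply_stress <- function(spec, stress_factor) {
  if (!is.numeric(stress_factor) || length(stress_factor) != 1 ||
      is.na(stress_factor) || stress_factor < 0 || stress_factor > 1) {
    rlang::abort("stress_factor must be a single number in [0, 1]")
  }
  if (stress_factor == 1) return(spec)
  switch(spec$model,
    independence = {
      spec$p <- spec$p * stress_factor
      spec
    },
    cooperative_chain = {
      spec$p_given_labeled <- spec$p_given_labeled * stress_factor
      spec$p_given_unlabeled <- spec$p_given_unlabeled * stress_factor
      spec
    },
    mutual_exclusion = {
      labeled <- spec$prob[-1L] * stress_factor
      spec$prob <- c(1 - sum(labeled), labeled)
      spec
    }
  )
}

#' Simulate per-spread domain annotations
#'
#' Draws single-cell banding observations under an explicit association
#' model.  Under independence each `EAD_Vi` is labeled with probability
#' `stress_factor * p[i]` independently; under the cooperative chain the
#' constant anchor is always labeled and the variable domains are drawn
#' sequentially, each conditional on its predecessor's state; under
#' mutual exclusion one of the K+1 allowed patterns is drawn per spread.
#' Output is bit-for-bit reproducible given `(spec, seed)`.
#'
#' @param spec An `ead_model_spec` from [independence_model()],
#'   [cooperative_chain_model()] or [mutual_exclusion_model()].
#' @param n_spreads Spreads per replicate (the study scored ~200).
#' @param n_replicates Number of independent replicates (study: 3).
#' @param condition Condition label stored with each spread.
#' @param stress_factor Multiplier in `[0, 1]` applied to the association
#'   propensities (1 = unstressed).
#' @param constant_domain Include the always-associated `EAD_C` column.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A spread annotation tibble (see [read_spread_table()]).
#' @examples
#' simulate_spreads(independence_model(c(0.36, 0.235, 0.14)),
#'                  n_spreads = 5, n_replicates = 1, seed = 1)
#' @export
simulate_spreads <- function(spec, n_spreads = 200, n_replicates = 3,
                             condition = "control", stress_factor = 1,
                             constant_domain = TRUE, seed = NULL) {
  if (!inherits(spec, "ead_model_spec")) {
    rlang::abort("`spec` must be an ead_model_spec (see independence_model() etc.)")
  }
  if (n_spreads < 1 || n_replicates < 1) {
    rlang::abort("n_spreads and n_replicates must be at least 1")
  }
  spec <- apply_stress(spec, stress_factor)
  total <- as.integer(n_spreads) * as.integer(n_replicates)
  K <- spec$K

  draw <- function() {
    switch(spec$model,
      independence = {
        u <- matrix(runif(total * K), total, K)
        matrix(as.integer(u < rep(spec$p, each = total)), total, K)
      },
      cooperative_chain = {
        s <- matrix(0L, total, K)
        prev <- rep(1L, total)  # constant anchor is always associated
        for (i in seq_len(K)) {
          pi <- ifelse(prev == 1L, spec$p_given_labeled[i], spec$p_given_unlabeled[i])
          s[, i] <- as.integer(runif(total) < pi)
          prev <- s[, i]
        }
        s
      },
      mutual_exclusion = {
        idx <- sample.int(K + 1L, total, replace = TRUE, prob = spec$prob)
        s <- matrix(0L, total, K)
        hit <- idx > 1L
        s[cbind(which(hit), idx[hit] - 1L)] <- 1L
        s
      }
    )
  }
  states <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  colnames(states) <- paste0("EAD_V", seq_len(K))

  replicate <- rep(seq_len(n_replicates), each = n_spreads)
  out <- tibble(
    spread_id = sprintf("%s_r%d_s%04d", condition, replicate,
                        rep(seq_len(n_spreads), times = n_replicates)),
    condition = condition,
    replicate = as.integer(replicate)
  )
  if (constant_domain) out$EAD_C <- 1L
  dplyr::bind_cols(out, as_tibble(states))
}
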