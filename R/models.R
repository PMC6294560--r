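# Maximum-likelihood comparison of three candidate modes of nuclear
# envelope association for the variable domains of a chromosome:
#
#   independence      each domain associates with its own probability P_i,
#                     independently of the others (affinity gradient);
#   cooperative_chain association spreads along the chromosome from the
#                     constant anchor domain: each EAD_Vi associates with
#                     one probability when EAD_V(i-1) (or the anchor, for
#                     i = 1) is associated and another when it is not
#                     (first-order Markov chain along the domain order);
#   mutual_exclusion  at most one variable domain can associate at a time
#                     (support restricted to the K+1 patterns with <= 1
#                     labeled domain).
#
# All three have closed-form multinomial MLEs, so fits are exact.

#' Fit and rank the three association models
#'
#' Fits the independence, cooperative-chain and mutual-exclusion models to
#' pooled banding-pattern counts by maximum likelihood and ranks them by
#' AIC (`AIC = 2 * n_params - 2 * logLik`).
#'
#' Parameter counts: independence has `K` free probabilities; the
#' cooperative chain has `2K - 1` (the anchor is always associated, so the
#' first step conditions on a labeled predecessor; each later step has a
#' labeled- and an unlabeled-predecessor probability); mutual exclusion
#' has `K` (K+1 support frequencies constrained to sum to one).  Observed
#' mass on patterns a model gives probability zero (mutual exclusion off
#' its support, or estimated zero cells) is handled with the
#' pseudo-frequency `0.5 / n_total` so log-likelihoods stay finite.
#'
#' @param observed Pattern distribution with counts (grouped rows are
#'   pooled); needs `K >= 2` variable domains.
#' @param K Number of variable domains (inferred when `NULL`).
#' @return An object of class `ead_model_fits`.  `glance()` returns the
#'   AIC ranking table, `tidy()` the parameter estimates, `autoplot()`
#'   observed vs fitted pattern frequencies.
#' @examples
#' fits <- fit_association_models(der19_observed_patterns(n_total = 600))
#' glance(fits)
#' @export
fit_association_models <- function(observed, K = NULL) {
  pooled <- pool_patterns(observed)
  K <- infer_k(pooled$pattern_id, K)
  if (K < 2L) rlang::abort("model comparison needs at least 2 variable domains")
  pooled <- complete_patterns(pooled, K)
  o <- round(pooled$value)
  n <- sum(o)
  if (n < 1) rlang::abort("observed pattern counts must total at least 1")
  states <- pattern_states(pooled$pattern_id, K)
  eps <- 0.5 / n

  fits <- list(
    fit_independence(o, states, n, K, eps),
    fit_cooperative_chain(o, states, n, K, eps),
    fit_mutual_exclusion(o, states, n, K, eps)
  )
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  ord <- order(aic)
  fits <- fits[ord]
  for (i in seq_along(fits)) {
    fits[[i]]$delta_aic <- fits[[i]]$aic - fits[[1]]$aic
    fits[[i]]$rank <- i
  }
  structure(
    list(models = fits, K = K, n_total = n,
         observed = tibble(pattern_id = pooled$pattern_id, count = as.integer(o))),
    class = "ead_model_fits"
  )
}

multinomial_loglik <- function(o, prob, eps) {
  keep <- o > 0
  sum(o[keep] * log(pmax(prob[keep], eps)))
}

new_model_fit <- function(name, params, prob, o, n, n_params, eps) {
  ll <- multinomial_loglik(o, prob, eps)
  list(
    model = name, params = params, fitted_freq = prob,
    log_lik = ll, n_params = n_params, aic = 2 * n_params - 2 * ll
  )
}

fit_independence <- function(o, states, n, K, eps) {
  p <- as.numeric(crossprod(states, o)) / n
  prob <- rep(1, nrow(states))
  for (i in seq_len(K)) {
    prob <- prob * ifelse(states[, i] == 1L, p[i], 1 - p[i])
  }
  new_model_fit("independence", setNames(p, paste0("p_V", seq_len(K))),
                prob, o, n, K, eps)
}

fit_cooperative_chain <- function(o, states, n, K, eps) {
  # Transition MLEs along the chain; the anchor (EAD_C) is always labeled,
  # so step 1 conditions on a labeled predecessor.
  p_given1 <- numeric(K)  # P(Vi labeled | previous labeled)
  p_given0 <- rep(NA_real_, K)  # P(Vi labeled | previous unlabeled); step 1 unused
  prev <- rep(1L, nrow(states))  # anchor state
  for (i in seq_len(K)) {
    n1 <- sum(o[prev == 1L])
    n0 <- sum(o[prev == 0L])
    p_given1[i] <- if (n1 > 0) sum(o[prev == 1L & states[, i] == 1L]) / n1 else NA_real_
    if (i > 1L) {
      p_given0[i] <- if (n0 > 0) sum(o[prev == 0L & states[, i] == 1L]) / n0 else NA_real_
    }
    prev <- states[, i]
  }
  prob <- rep(1, nrow(states))
  prev <- rep(1L, nrow(states))
  for (i in seq_len(K)) {
    pi <- ifelse(prev == 1L, p_given1[i], p_given0[i])
    # Undefined conditionals only occur on branches of model probability 0.
    pi[is.na(pi)] <- 0
    prob <- prob * ifelse(states[, i] == 1L, pi, 1 - pi)
    prev <- states[, i]
  }
  params <- c(
    setNames(p_given1, paste0("p_V", seq_len(K), "_given_prev_labeled")),
    setNames(p_given0[-1L], paste0("p_V", 2:K, "_given_prev_unlabeled"))
  )
  new_model_fit("cooperative_chain", params, prob, o, n, 2L * K - 1L, eps)
}

fit_mutual_exclusion <- function(o, states, n, K, eps) {
  support <- rowSums(states) <= 1L
  n_off <- sum(!support)
  on_total <- sum(o[support])
  prob <- numeric(length(o))
  # Off-support patterns get the pseudo-frequency; support frequencies are
  # the MLE on the support, scaled to keep the vector normalized.
  prob[!support] <- eps
  if (on_total > 0) {
    prob[support] <- o[support] / on_total * (1 - n_off * eps)
  } else {
    prob[support] <- (1 - n_off * eps) / sum(support)
  }
  # Support rows in pattern_id order are: none, only V1, only V2, ...
  params <- setNames(prob[support], c("p_none", paste0("p_only_V", seq_len(K))))
  new_model_fit("mutual_exclusion", params, prob, o, n, K, eps)
}

#' @export
print.ead_model_fits <- function(x, ...) {
  cat(sprintf("Association-model comparison (K = %d, n = %d)\n\n",
              x$K, x$n_total))
  print(glance(x))
  invisible(x)
}

#' @rdname fit_association_models
#' @param x An `ead_model_fits` object.
#' @param ... Unused.
#' @export
glance.ead_model_fits <- function(x, ...) {
  purrr::map_dfr(x$models, function(f) {
    tibble(model = f$model, n_params = f$n_params, log_lik = f$log_lik,
           aic = f$aic, delta_aic = f$delta_aic, rank = f$rank)
  })
}

#' @rdname fit_association_models
#' @export
tidy.ead_model_fits <- function(x, ...) {
  purrr::map_dfr(x$models, function(f) {
    tibble(model = f$model, term = names(f$params),
           estimate = unname(f$params))
  })
}

#' Best-fitting association model
#'
#' @param fits An `ead_model_fits` object.
#' @return The name of the model with the lowest AIC.
#' @export
best_model <- function(fits) {
  stopifnot(inherits(fits, "ead_model_fits"))
  fits$models[[1]]$model
}
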