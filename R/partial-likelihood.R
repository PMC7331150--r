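# Cox partial likelihood machinery (Breslow handling of tied event times).
#
# All risk-set computations share one precomputed index structure: subjects
# sorted by decreasing follow-up time, with `risk_end[i]` the last sorted
# position sharing subject i's time, so that positions 1..risk_end[i] form the
# risk set at that time (ties stay in each other's risk sets).

risk_index <- function(time, status) {
  ord <- order(time, decreasing = TRUE)
  to <- time[ord]
  so <- status[ord]
  risk_end <- ave(seq_along(to), to, FUN = max)
  ev <- which(so == 1)
  if (length(ev) == 0L)
    stop("partial likelihood undefined: no events (all status 0)", call. = FALSE)
  list(ord = ord, time = to, status = so, risk_end = risk_end, events = ev)
}

# log partial likelihood for one linear predictor, given a risk_index on the
# same subject order as `eta` (eta must already be in original subject order).
pll_from_eta <- function(eta, ri) {
  eo <- eta[ri$ord]
  eo <- eo - max(eo)                      # invariant to constant shifts
  s0 <- cumsum(exp(eo))
  sum(eo[ri$events]) - sum(log(s0[ri$risk_end[ri$events]]))
}

#' Cox partial log-likelihood
#'
#' Breslow-approximation partial log-likelihood of a coefficient vector for a
#' grouped survival dataset. At `beta = 0` with no tied times it equals minus
#' the sum of the logs of the risk-set sizes at the event times.
#'
#' @param beta Numeric coefficient vector of length `p` (log hazard ratios).
#' @param data A [survival_dataset()].
#' @return A single numeric value.
#' @export
cox_partial_loglik <- function(beta, data) {
  stopifnot(inherits(data, "survival_dataset"))
  if (length(beta) != ncol(data$x))
    stop("`beta` must have one coefficient per biomarker", call. = FALSE)
  ri <- risk_index(data$time, data$status)
  pll_from_eta(drop(data$x %*% beta), ri)
}

#' Gradient of the Cox partial log-likelihood
#'
#' The score vector of the Breslow partial log-likelihood, used for the
#' Karush-Kuhn-Tucker certificate of penalized fits and for the penalty bound
#' at which all coefficients vanish.
#'
#' @inheritParams cox_partial_loglik
#' @return Numeric vector of length `p`.
#' @export
cox_score <- function(beta, data) {
  stopifnot(inherits(data, "survival_dataset"))
  ri <- risk_index(data$time, data$status)
  xo <- data$x[ri$ord, , drop = FALSE]
  eo <- drop(xo %*% beta)
  w <- exp(eo - max(eo))
  s0 <- cumsum(w)
  s1 <- apply(xo * w, 2L, cumsum)
  re <- ri$risk_end[ri$events]
  colSums(xo[ri$events, , drop = FALSE]) -
    colSums(s1[re, , drop = FALSE] / s0[re])
}

# Partial log-likelihood for each column of a matrix of linear predictors,
# optionally restricted to a subset of subjects (used by the cvl machinery).
pll_eta_matrix <- function(eta, time, status, subset = NULL) {
  if (!is.null(subset)) {
    eta <- eta[subset, , drop = FALSE]
    time <- time[subset]
    status <- status[subset]
  }
  ri <- risk_index(time, status)
  apply(eta, 2L, function(e) pll_from_eta(e, ri))
}
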