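# Weighted L1-penalized Cox estimation.
#
# The estimator maximizes  l(beta) - lambda * sum_j W_j |beta_j|  with l the
# Breslow partial log-likelihood. Solutions are obtained through the exact
# rescaling identity: a weighted lasso on X equals an unweighted lasso on the
# design with columns divided by W, with coefficients divided back by W.
# Features with W_j = +Inf are removed from the design before fitting, so
# their coefficients are exact zeros. The solver is glmnet's cyclic
# coordinate descent with warm starts along the path; glmnet's lambda is the
# raw-scale lambda divided by the number of subjects.

# Normalize user-supplied weights (numeric vector, adaptive_weights tibble or
# NULL) to a strictly positive length-p vector, +Inf allowed, NaN rejected.
resolve_weights <- function(weights, data) {
  p <- ncol(data$x)
  if (is.null(weights)) return(rep(1, p))
  if (inherits(weights, "adaptive_weights") || is.data.frame(weights)) {
    if (!all(c("feature_id", "weight") %in% names(weights)))
      stop("weight table needs columns `feature_id` and `weight`", call. = FALSE)
    w <- weights$weight[match(data$feature_ids, weights$feature_id)]
    if (anyNA(w) && !anyNA(weights$weight))
      stop("weight table does not cover every biomarker", call. = FALSE)
  } else {
    w <- as.numeric(weights)
  }
  if (length(w) != p) stop("need one weight per biomarker", call. = FALSE)
  if (any(is.nan(w)) || anyNA(w)) stop("weights must not be NaN/NA", call. = FALSE)
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  w
}

#' Penalty bound and log-equispaced lambda path
#'
#' Computes the smallest penalty `lam_max` at which every coefficient of the
#' weighted lasso is zero -- the Karush-Kuhn-Tucker bound
#' \eqn{\max_j |\partial\ell/\partial\beta_j(0)| / W_j} over finite-weight
#' biomarkers -- and a decreasing log-equispaced grid from `lam_max` down to
#' `lam_max * min_ratio`.
#'
#' @param data A [survival_dataset()].
#' @param weights Penalty weights: `NULL` (all one), a numeric vector of
#'   length `p`, or an [adaptive_weights()] table. `+Inf` excludes a biomarker.
#' @param n_lambda Number of grid values (>= 2).
#' @param min_ratio Ratio of the smallest to the largest grid value, in (0,1).
#' @return Decreasing numeric vector of length `n_lambda` with attribute
#'   `lam_max`; lambda is on the raw partial-log-likelihood scale.
#' @export
lambda_path <- function(data, weights = NULL, n_lambda = 100L, min_ratio = 0.01) {
  stopifnot(inherits(data, "survival_dataset"))
  if (n_lambda < 2L) stop("`n_lambda` must be at least 2", call. = FALSE)
  if (min_ratio <= 0 || min_ratio >= 1) stop("`min_ratio` must be in (0, 1)", call. = FALSE)
  w <- resolve_weights(weights, data)
  fin <- is.finite(w)
  if (!any(fin)) stop("all weights are infinite", call. = FALSE)
  g0 <- cox_score(numeric(ncol(data$x)), data)
  lam_max <- max(abs(g0[fin]) / w[fin])
  if (lam_max == 0) stop("score at zero vanishes; no penalized path exists", call. = FALSE)
  path <- exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_lambda))
  attr(path, "lam_max") <- lam_max
  path
}

# Observed information of the Breslow partial log-likelihood restricted to
# the columns `cols`, evaluated at `beta` (full-length coefficient vector).
cox_info <- function(beta, data, cols) {
  ri <- risk_index(data$time, data$status)
  xo <- data$x[ri$ord, , drop = FALSE]
  eo <- drop(xo %*% beta)
  w <- exp(eo - max(eo))
  s0 <- cumsum(w)
  m <- xo[, cols, drop = FALSE]
  a <- length(cols)
  s1 <- apply(m * w, 2L, cumsum)
  xx <- m[, rep(seq_len(a), a), drop = FALSE] *
    m[, rep(seq_len(a), each = a), drop = FALSE] * w
  s2 <- apply(xx, 2L, cumsum)
  re <- ri$risk_end[ri$events]
  h <- matrix(0, a, a)
  for (i in re) {
    mu <- s1[i, ] / s0[i]
    h <- h + matrix(s2[i, ], a, a) / s0[i] - tcrossprod(mu)
  }
  h
}

# Active-set Newton polish: glmnet's stopping rule leaves gradient residuals
# of order 1e-4, so returned solutions are refined until the stationarity
# conditions hold on the gradient scale. The active set is kept fixed unless
# a coefficient crosses zero (dropped) or an inactive bound is violated
# (feature admitted); iterations are bounded.
polish_solution <- function(data, beta, w, lambda, tol = 1e-6, max_iter = 40L) {
  if (lambda <= 0) return(beta)
  for (iter in seq_len(max_iter)) {
    act <- which(beta != 0)
    g <- cox_score(beta, data)
    ok_inactive <- TRUE
    slack <- abs(g) - lambda * w
    slack[act] <- -Inf
    slack[!is.finite(w)] <- -Inf
    if (any(slack > tol)) {
      j <- which.max(slack)
      beta[j] <- sign(g[j]) * 1e-10
      act <- c(act, j)
      ok_inactive <- FALSE
    }
    if (!length(act)) return(beta)
    s <- sign(beta[act])
    r <- g[act] - lambda * w[act] * s
    if (ok_inactive && max(abs(r)) <= tol) return(beta)
    h <- cox_info(beta, data, act)
    step <- tryCatch(solve(h + diag(1e-10, length(act)), r),
                     error = function(e) r / (diag(h) + 1e-10))
    # damp so no coefficient overshoots through zero by more than a flip
    new <- beta[act] + step
    flip <- sign(new) != 0 & sign(new) != s
    new[flip] <- 0
    beta[act] <- new
  }
  beta
}

# Core path solver: returns a p x length(lambda) coefficient matrix on the
# original scale. Handles the one-finite-column case (glmnet needs >= 2
# columns) with a golden-section maximizer of the 1-D penalized objective.
weighted_lasso_path <- function(data, w, lambda, thresh = 1e-6, maxit = 1e5) {
  n <- nrow(data$x)
  p <- ncol(data$x)
  fin <- which(is.finite(w))
  beta <- matrix(0, p, length(lambda),
                 dimnames = list(data$feature_ids, NULL))
  if (length(fin) == 1L) {
    j <- fin
    ri <- risk_index(data$time, data$status)
    xj <- data$x[, j]
    for (k in seq_along(lambda)) {
      opt <- stats::optimize(function(b) {
        -(pll_from_eta(b * xj, ri) - lambda[k] * w[j] * abs(b))
      }, interval = c(-20, 20), tol = 1e-9)
      bk <- opt$minimum
      if (abs(bk) < 1e-6) bk <- 0
      beta[j, k] <- bk
    }
    return(beta)
  }
  xs <- sweep(data$x[, fin, drop = FALSE], 2L, w[fin], "/")
  fit <- glmnet::glmnet(
    xs, survival::Surv(data$time, data$status), family = "cox",
    lambda = lambda / n, standardize = FALSE, thresh = thresh, maxit = maxit
  )
  b <- as.matrix(fit$beta)
  if (ncol(b) < length(lambda)) {
    # glmnet stopped early; pad with the last solved column
    b <- cbind(b, b[, rep(ncol(b), length(lambda) - ncol(b)), drop = FALSE])
  }
  beta[fin, ] <- b / w[fin]
  beta
}

#' Weighted lasso Cox fit at fixed penalty
#'
#' Maximizes the weighted-penalized partial log-likelihood
#' \eqn{\ell(\beta) - \lambda \sum_j W_j |\beta_j|} at one or more penalty
#' values. Biomarkers with infinite weight are excluded from the design and
#' get exact zero coefficients.
#'
#' @inheritParams lambda_path
#' @param lambda Non-negative penalty value(s), raw scale.
#' @param thresh Coordinate-descent convergence threshold (glmnet `thresh`).
#' @param maxit Maximum coordinate-descent passes.
#' @return If `lambda` has length 1, a named numeric vector of `p`
#'   coefficients; otherwise a `p x length(lambda)` matrix.
#' @export
fit_weighted_lasso <- function(data, weights = NULL, lambda, thresh = 1e-6,
                               maxit = 1e5) {
  stopifnot(inherits(data, "survival_dataset"))
  if (any(lambda < 0)) stop("`lambda` must be non-negative", call. = FALSE)
  w <- resolve_weights(weights, data)
  if (!any(is.finite(w))) stop("all weights are infinite", call. = FALSE)
  lam <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
  beta <- weighted_lasso_path(data, w, lam, thresh = thresh, maxit = maxit)
  for (k in seq_along(lam))
    beta[, k] <- polish_solution(data, beta[, k], w, lam[k])
  out <- beta[, match(lambda, lam), drop = FALSE]
  if (length(lambda) == 1L) drop(out) else out
}

#' Karush-Kuhn-Tucker certificate of a weighted lasso solution
#'
#' Checks the stationarity conditions of the penalized objective at `beta`:
#' active coefficients must have score equal to `lambda * W_j * sign(beta_j)`
#' and inactive ones a score bounded by `lambda * W_j` in absolute value.
#'
#' @inheritParams fit_weighted_lasso
#' @param beta Coefficient vector to certify.
#' @return A list with `max_violation` (worst gradient-scale violation over
#'   finite-weight biomarkers) and `ok` at the supplied tolerance `tol`.
#' @export
kkt_check <- function(data, beta, weights = NULL, lambda, tol = 1e-5) {
  w <- resolve_weights(weights, data)
  g <- cox_score(beta, data)
  fin <- is.finite(w)
  act <- fin & beta != 0
  ina <- fin & beta == 0
  viol_act <- if (any(act)) max(abs(g[act] - lambda * w[act] * sign(beta[act]))) else 0
  viol_ina <- if (any(ina)) max(pmax(abs(g[ina]) - lambda * w[ina], 0)) else 0
  mv <- max(viol_act, viol_ina) / max(1, max(abs(g)))
  list(max_violation = mv, ok = mv <= tol,
       active_violation = viol_act, inactive_violation = viol_ina)
}
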