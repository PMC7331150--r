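# Cross-validated partial log-likelihood (Verweij & van Houwelingen) and the
# main fitting entry point.

# Event-stratified fold assignment: events and censored subjects are each
# dealt round-robin after a seeded shuffle, so every fold keeps events.
make_folds <- function(status, k_folds, seed = NULL) {
  n <- length(status)
  if (k_folds < 2L) stop("`k_folds` must be at least 2", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  fold <- integer(n)
  for (s in c(1L, 0L)) {
    idx <- which(status == s)
    fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  ev_per_train <- vapply(seq_len(k_folds), function(k) sum(status == 1 & fold != k), 0L)
  if (any(ev_per_train < 1L))
    stop("a training fold retains no events; reduce `k_folds`", call. = FALSE)
  fold
}

#' Fit an adaptive lasso Cox model with cvl-selected penalty
#'
#' The workhorse of the package: fits the weighted L1-penalized Cox model
#' over a decreasing lambda path, selects the penalty by maximizing the
#' cross-validated partial log-likelihood
#' \deqn{cvl(\lambda) = \sum_k \left[\ell(\hat\beta_{(-k)}(\lambda)) -
#'       \ell_{(-k)}(\hat\beta_{(-k)}(\lambda))\right],}
#' where \eqn{\ell} is the full-data and \eqn{\ell_{(-k)}} the
#' leave-fold-out-data partial log-likelihood, and refits on the full data at
#' the maximizing lambda. Folds are event-stratified and seed-deterministic.
#'
#' @param data A [survival_dataset()] (training data).
#' @param weights Penalty weights as in [lambda_path()]: `NULL` for the
#'   standard lasso, an [adaptive_weights()] table, or a numeric vector.
#'   `+Inf` forces a biomarker out of the model.
#' @param lambda Optional decreasing penalty grid (raw scale); computed by
#'   [lambda_path()] when `NULL`.
#' @param n_lambda,min_ratio Grid parameters passed to [lambda_path()].
#' @param k_folds Number of cross-validation folds (default 5).
#' @param seed Seed for the fold assignment; `NULL` uses the current RNG
#'   state.
#' @param thresh,maxit Solver controls, see [fit_weighted_lasso()].
#' @return An object of class `cox_alasso`: a list with `beta` (named,
#'   length `p`), `selected` (feature ids with nonzero coefficients),
#'   `lambda` (chosen penalty), `lambda_path`, `cvl` (curve, one value per
#'   path element), `weights`, `scheme`, `n`, `p`, `n_events`, `folds`.
#' @examples
#' sim <- simulate_dataset(scenario_config(3, p = 30, group_sizes = rep(10, 3),
#'                                         n_train = 80, n_valid = 0,
#'                                         q = 3, l = 1), seed = 7)
#' fit <- cox_adaptive_lasso(sim$train, seed = 1, n_lambda = 30)
#' glance(fit)
#' @export
cox_adaptive_lasso <- function(data, weights = NULL, lambda = NULL,
                               n_lambda = 100L, min_ratio = 0.01,
                               k_folds = 5L, seed = NULL,
                               thresh = 1e-6, maxit = 1e5) {
  stopifnot(inherits(data, "survival_dataset"))
  w <- resolve_weights(weights, data)
  scheme <- if (inherits(weights, "adaptive_weights")) attr(weights, "scheme")
            else if (is.null(weights)) "standard_lasso" else "custom"
  if (!any(is.finite(w))) stop("all weights are infinite", call. = FALSE)
  if (is.null(lambda)) lambda <- lambda_path(data, w, n_lambda, min_ratio)
  lambda <- as.numeric(lambda)
  if (is.unsorted(rev(lambda))) stop("`lambda` must be decreasing", call. = FALSE)

  fold <- make_folds(data$status, k_folds, seed)
  fin <- which(is.finite(w))
  xs <- sweep(data$x[, fin, drop = FALSE], 2L, w[fin], "/")

  cvl <- numeric(length(lambda))
  for (k in seq_len(k_folds)) {
    tr <- fold != k
    sub <- data
    sub$x <- data$x[tr, , drop = FALSE]
    sub$time <- data$time[tr]
    sub$status <- data$status[tr]
    bk <- weighted_lasso_path(sub, w, lambda, thresh = thresh, maxit = maxit)
    eta <- data$x %*% bk
    cvl <- cvl + (pll_eta_matrix(eta, data$time, data$status) -
                    pll_eta_matrix(eta, data$time, data$status, subset = tr))
  }

  best <- which.max(cvl)
  beta_path <- weighted_lasso_path(data, w, lambda, thresh = thresh, maxit = maxit)
  beta <- polish_solution(data, beta_path[, best], w, lambda[best])

  structure(list(
    beta = beta,
    selected = data$feature_ids[beta != 0],
    lambda = lambda[best],
    lambda_index = best,
    lambda_path = lambda,
    cvl = cvl,
    weights = w,
    scheme = scheme,
    feature_ids = data$feature_ids,
    groups = data$groups,
    n = nrow(data$x), p = ncol(data$x), n_events = sum(data$status),
    k_folds = k_folds, seed = seed, thresh = thresh
  ), class = "cox_alasso")
}

#' @export
print.cox_alasso <- function(x, ...) {
  cat(sprintf("<cox_alasso> %s weighting: %d of %d biomarkers selected\n",
              x$scheme, length(x$selected), x$p))
  cat(sprintf("  lambda = %.5g (path position %d/%d), cvl = %.3f, %d-fold CV\n",
              x$lambda, x$lambda_index, length(x$lambda_path),
              max(x$cvl), x$k_folds))
  invisible(x)
}

#' Tidy a fitted adaptive lasso Cox model
#'
#' @param x A [cox_adaptive_lasso()] fit.
#' @param ... Unused.
#' @return A tibble with one row per biomarker: `feature_id`, `group`,
#'   `weight` (penalty factor), `estimate` (log hazard ratio at the chosen
#'   lambda), `selected`.
#' @export
tidy.cox_alasso <- function(x, ...) {
  tibble::tibble(
    feature_id = x$feature_ids,
    group = x$groups,
    weight = x$weights,
    estimate = unname(x$beta),
    selected = x$beta != 0
  )
}

#' One-row summary of a fitted adaptive lasso Cox model
#'
#' @inheritParams tidy.cox_alasso
#' @return A one-row tibble: `scheme`, `n`, `p`, `n_events`, `lambda`,
#'   `n_selected`, `cvl_max`.
#' @method glance cox_alasso
#' @export
glance.cox_alasso <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, n = x$n, p = x$p, n_events = x$n_events,
    lambda = x$lambda, n_selected = length(x$selected), cvl_max = max(x$cvl)
  )
}

#' Linear predictor of a fitted model on new data
#'
#' @param object A `cox_alasso` fit.
#' @param newdata A [survival_dataset()] (or bare matrix) with the same
#'   biomarkers, in the same order.
#' @param ... Unused.
#' @return Numeric vector of prognostic scores (higher = higher hazard).
#' @export
predict.cox_alasso <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "survival_dataset")) newdata$x else as.matrix(newdata)
  if (ncol(x) != object$p) stop("`newdata` has the wrong number of biomarkers", call. = FALSE)
  drop(x %*% object$beta)
}

#' Serialize a fitted model to a JSON sidecar
#'
#' Writes the coefficients by feature id, the chosen penalty, the cvl curve
#' and the weighting scheme to a JSON file that [read_fit_json()] restores.
#'
#' @param fit A `cox_alasso` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cox_alasso"))
  obj <- list(
    scheme = fit$scheme,
    lambda = fit$lambda,
    lambda_path = fit$lambda_path,
    cvl = fit$cvl,
    beta = as.list(stats::setNames(unname(fit$beta), fit$feature_ids)),
    weights = as.list(stats::setNames(unname(fit$weights), fit$feature_ids)),
    groups = as.list(stats::setNames(as.character(fit$groups), fit$feature_ids)),
    n = fit$n, p = fit$p, n_events = fit$n_events, k_folds = fit$k_folds,
    standardization = "population-sd"
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted model written by [write_fit_json()]
#'
#' @param path Path to the JSON sidecar.
#' @return A `cox_alasso` object (without fold assignments).
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- stats::setNames(as.numeric(obj$beta), names(obj$beta))
  structure(list(
    beta = beta,
    selected = names(beta)[beta != 0],
    lambda = obj$lambda,
    lambda_index = which.min(abs(obj$lambda_path - obj$lambda)),
    lambda_path = obj$lambda_path,
    cvl = obj$cvl,
    weights = stats::setNames(as.numeric(obj$weights), names(obj$weights)),
    scheme = obj$scheme,
    feature_ids = names(beta),
    groups = factor(unlist(obj$groups), levels = unique(unlist(obj$groups))),
    n = obj$n, p = obj$p, n_events = obj$n_events, k_folds = obj$k_folds
  ), class = "cox_alasso")
}
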