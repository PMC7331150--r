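#' Selection accuracy against a known active set
#'
#' Confusion counts and rates of a selected biomarker set against the true
#' active set: `FDR = FP/(TP+FP)`, `FNR = FN/(TP+FN)`,
#' `F1 = 2TP/(2TP+FP+FN)`. Empty denominators yield 0 by default (so under a
#' complete null the mean FDR across replicates equals the proportion of
#' replicates selecting anything); `empty = "na"` yields `NA` instead.
#'
#' @param selected Integer indices or character feature ids of the selected
#'   biomarkers.
#' @param active The true active set, same form as `selected`.
#' @param p Total number of biomarkers, or a character vector of all feature
#'   ids when sets are given as ids.
#' @param empty `"zero"` (default) or `"na"`: value of a rate whose
#'   denominator is zero.
#' @return A one-row tibble: `level`, `tp`, `fp`, `fn`, `tn`, `fdr`, `fnr`,
#'   `f1`.
#' @examples
#' selection_metrics(c(1, 2, 3, 4), active = c(1, 2, 5:10), p = 20)
#' @export
selection_metrics <- function(selected, active, p, empty = c("zero", "na")) {
  empty <- match.arg(empty)
  if (is.character(p)) {
    universe <- p
    p <- length(universe)
    selected <- match(selected, universe)
    active <- match(active, universe)
    if (anyNA(selected) || anyNA(active))
      stop("selected/active ids not all present in the feature universe", call. = FALSE)
  } else {
    selected <- as.integer(selected)
    active <- as.integer(active)
    if (length(selected) && (min(selected) < 1L || max(selected) > p))
      stop("selected indices out of range 1..p", call. = FALSE)
    if (length(active) && (min(active) < 1L || max(active) > p))
      stop("active indices out of range 1..p", call. = FALSE)
  }
  selected <- unique(selected)
  active <- unique(active)
  tp <- length(intersect(selected, active))
  fp <- length(setdiff(selected, active))
  fn <- length(setdiff(active, selected))
  tn <- p - tp - fp - fn
  none <- if (empty == "zero") 0 else NA_real_
  tibble::tibble(
    level = "biomarker",
    tp = tp, fp = fp, fn = fn, tn = tn,
    fdr = if (tp + fp > 0) fp / (tp + fp) else none,
    fnr = if (tp + fn > 0) fn / (tp + fn) else none,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else none
  )
}

#' Group-level selection accuracy
#'
#' Lifts biomarker-level selection to the group level -- a group is active
#' iff it contains an active biomarker and selected iff it contains a
#' selected biomarker -- then applies [selection_metrics()] over the groups.
#'
#' @inheritParams selection_metrics
#' @param groups A factor of group labels (one per biomarker) or the
#'   `groups` element of a [survival_dataset()].
#' @export
group_metrics <- function(selected, active, groups, empty = c("zero", "na")) {
  groups <- as.factor(groups)
  p <- length(groups)
  to_idx <- function(s) if (is.character(s)) stop("use indices with `group_metrics`; ids need the dataset universe", call. = FALSE) else as.integer(s)
  selected <- to_idx(selected)
  active <- to_idx(active)
  if (length(selected) && (min(selected) < 1L || max(selected) > p))
    stop("selected indices out of range 1..p", call. = FALSE)
  if (length(active) && (min(active) < 1L || max(active) > p))
    stop("active indices out of range 1..p", call. = FALSE)
  sel_g <- which(levels(groups) %in% unique(as.character(groups[selected])))
  act_g <- which(levels(groups) %in% unique(as.character(groups[active])))
  out <- selection_metrics(sel_g, act_g, nlevels(groups), empty = match.arg(empty))
  out$level <- "group"
  out
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Product-limit estimator of the censoring survival function G (events and
#' censorings with roles swapped), used for inverse-probability-of-censoring
#' weights. Evaluation follows the left-continuous convention: `G_minus(t)`
#' is the probability of remaining uncensored just before `t`.
#'
#' @param time,status Survival outcome as in [survival_dataset()] (`status`
#'   is still the event indicator; censorings are its complement).
#' @return An object of class `censoring_km` with fields `times`, `surv` and
#'   evaluator functions `G(t)` (right-continuous) and `G_minus(t)`.
#' @export
km_censoring <- function(time, status) {
  fit <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  times <- fit$time
  surv <- fit$surv
  g_at <- function(t, left) {
    vapply(t, function(ti) {
      keep <- if (left) times < ti else times <= ti
      if (!any(keep)) 1 else surv[max(which(keep))]
    }, 0)
  }
  structure(list(
    times = times, surv = surv,
    G = function(t) g_at(t, left = FALSE),
    G_minus = function(t) g_at(t, left = TRUE)
  ), class = "censoring_km")
}

#' @export
print.censoring_km <- function(x, ...) {
  cat(sprintf("<censoring_km> %d time points; G(max) = %.3f\n",
              length(x$times), min(x$surv)))
  invisible(x)
}

#' Time-dependent AUC with inverse-probability-of-censoring weighting
#'
#' Cumulative-cases / dynamic-controls area under the time-dependent ROC
#' curve at a fixed horizon. Cases are subjects with an observed event by the
#' horizon, weighted by `1/G(time_i-)`; controls are subjects still at risk
#' after the horizon, weighted by `1/G(horizon)`; `G` is the Kaplan-Meier
#' censoring distribution of the same data. Ties in the marker count 1/2.
#' Subjects whose weight would divide by `G = 0` are dropped with a warning.
#'
#' @param marker Numeric prognostic score, higher = higher risk.
#' @param time,status Survival outcome.
#' @param horizon Evaluation time (years by default convention).
#' @return A one-row tibble: `horizon`, `auc`, `n_cases`, `n_controls`,
#'   `undefined` (TRUE when there are no cases or no controls; `auc` is `NA`
#'   then).
#' @examples
#' set.seed(1)
#' m <- rnorm(40)
#' t <- rexp(40, exp(m) / 8)
#' ipcw_auc(m, pmin(t, 6), as.integer(t <= 6), horizon = 5)
#' @export
ipcw_auc <- function(marker, time, status, horizon = 5) {
  stopifnot(length(marker) == length(time), length(time) == length(status))
  km <- km_censoring(time, status)
  cases <- which(time <= horizon & status == 1)
  controls <- which(time > horizon)
  if (!length(cases) || !length(controls)) {
    return(tibble::tibble(horizon = horizon, auc = NA_real_,
                          n_cases = length(cases), n_controls = length(controls),
                          undefined = TRUE))
  }
  w_case <- 1 / km$G_minus(time[cases])
  g_h <- km$G(horizon)
  if (any(!is.finite(w_case))) {
    warning("dropping cases with zero censoring-survival weight", call. = FALSE)
    cases <- cases[is.finite(w_case)]
    w_case <- w_case[is.finite(w_case)]
  }
  if (g_h <= 0) {
    warning("censoring survival is zero at the horizon; controls unweightable",
            call. = FALSE)
    return(tibble::tibble(horizon = horizon, auc = NA_real_,
                          n_cases = length(cases), n_controls = length(controls),
                          undefined = TRUE))
  }
  w_ctrl <- rep(1 / g_h, length(controls))
  mi <- marker[cases]
  mj <- marker[controls]
  comp <- outer(mi, mj, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- drop(crossprod(w_case, comp %*% w_ctrl)) / (sum(w_case) * sum(w_ctrl))
  tibble::tibble(horizon = horizon, auc = auc,
                 n_cases = length(cases), n_controls = length(controls),
                 undefined = FALSE)
}
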