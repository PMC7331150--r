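#' Group-informed adaptive lasso weights
#'
#' Builds the per-biomarker penalty factors for the adaptive lasso from a
#' training dataset and its group (pathway) structure. Eight schemes are
#' available; all produce strictly positive weights, with `+Inf` meaning "the
#' biomarker is forced out of the model":
#'
#' * `"AC"` -- reciprocal of the group mean of absolute univariable Cox
#'   coefficients; constant within a group.
#' * `"PCA"` -- reciprocal of the absolute univariable Cox coefficient of the
#'   group's first principal-component score; constant within a group.
#' * `"lasso_pca"` -- two steps: a standard lasso (cvl-selected penalty) run
#'   on all biomarkers picks a subset; groups containing selected biomarkers
#'   get the reciprocal absolute PC1 coefficient computed on their selected
#'   members only (a single selected member is its own score); biomarkers in
#'   groups with no selected member inherit the maximum weight among the
#'   selected groups.
#' * `"SW"` -- reciprocal of the biomarker's own univariable Wald statistic.
#' * `"ASW"` / `"MSW"` -- reciprocal of the group mean / maximum of member
#'   Wald statistics; constant within a group.
#' * `"ASWxSW"` / `"MSWxSW"` -- reciprocal of the product of the group
#'   summary (mean / max) and the biomarker's own Wald statistic, so that
#'   group-level and biomarker-level evidence both lower the penalty.
#'
#' @param data A [survival_dataset()] (training data).
#' @param scheme One of `"AC"`, `"PCA"`, `"lasso_pca"`, `"SW"`, `"ASW"`,
#'   `"MSW"`, `"ASWxSW"`, `"MSWxSW"`.
#' @param uni Optional precomputed [univariable_cox()] table (they are a pure
#'   function of the training data, so one table can be shared across
#'   schemes).
#' @param wald Wald statistic form, see [univariable_cox()].
#' @param k_folds,seed Cross-validation controls for the first-step lasso of
#'   `"lasso_pca"`; ignored by other schemes.
#' @param scale_pc_scores If `TRUE` (default) principal-component scores are
#'   rescaled to unit variance before their univariable Cox fit, putting the
#'   PC coefficient on the scale of a standardized biomarker.
#' @param weight_cap Optional finite cap applied to the weights (off by
#'   default); exact zero statistics otherwise yield `+Inf` weights.
#' @return A tibble of class `adaptive_weights` with columns `feature_id`,
#'   `group`, `weight` and attribute `scheme`.
#' @examples
#' sim <- simulate_dataset(scenario_config(3, p = 30, group_sizes = rep(10, 3),
#'                                         n_train = 80, n_valid = 0,
#'                                         q = 3, l = 1), seed = 7)
#' adaptive_weights(sim$train, "MSWxSW")
#' @export
adaptive_weights <- function(data,
                             scheme = c("MSWxSW", "AC", "PCA", "lasso_pca",
                                        "SW", "ASW", "MSW", "ASWxSW"),
                             uni = NULL, wald = c("chisq", "abs_z"),
                             k_folds = 5L, seed = NULL,
                             scale_pc_scores = TRUE, weight_cap = Inf) {
  stopifnot(inherits(data, "survival_dataset"))
  scheme <- match.arg(scheme)
  wald <- match.arg(wald)

  w <- switch(
    scheme,
    AC = weights_ac_(data, uni, wald),
    PCA = weights_pca_(data, scale_pc_scores),
    lasso_pca = weights_lasso_pca_(data, k_folds, seed, scale_pc_scores),
    weights_wald_(data, scheme, uni, wald)
  )
  if (is.finite(weight_cap)) w <- pmin(w, weight_cap)
  if (any(is.infinite(w)))
    warning(sprintf("%s weights: %d biomarker(s) received an infinite weight",
                    scheme, sum(is.infinite(w))), call. = FALSE)

  structure(
    tibble::tibble(feature_id = data$feature_ids, group = data$groups, weight = w),
    scheme = scheme,
    class = c("adaptive_weights", "tbl_df", "tbl", "data.frame")
  )
}

uni_or_fit <- function(data, uni, wald) {
  if (is.null(uni)) univariable_cox(data, wald = wald) else uni
}

weights_ac_ <- function(data, uni, wald) {
  uni <- uni_or_fit(data, uni, wald)
  m <- stats::ave(abs(uni$estimate), data$groups, FUN = mean)
  ifelse(m == 0, Inf, 1 / m)
}

weights_wald_ <- function(data, scheme, uni, wald) {
  uni <- uni_or_fit(data, uni, wald)
  sw <- uni$wald
  asw <- stats::ave(sw, data$groups, FUN = mean)
  msw <- stats::ave(sw, data$groups, FUN = max)
  stat <- switch(scheme,
                 SW = sw,
                 ASW = asw,
                 MSW = msw,
                 ASWxSW = asw * sw,
                 MSWxSW = msw * sw)
  ifelse(stat == 0, Inf, 1 / stat)
}

# PC1 score of a (sub)matrix: projection of the column-centred matrix on its
# first right singular vector, optionally rescaled to unit (population)
# variance. Returns NULL when the leading singular value vanishes.
pc1_score <- function(xsub, scale_pc_scores) {
  xc <- sweep(xsub, 2L, colMeans(xsub), "-")
  sv <- svd(xc, nu = 0L, nv = 1L)
  if (sv$d[1] < 1e-12) return(NULL)
  score <- drop(xc %*% sv$v[, 1])
  if (scale_pc_scores) {
    s <- sqrt(mean(score^2))
    if (s < 1e-12) return(NULL)
    score <- score / s
  }
  score
}

# Absolute univariable Cox coefficient of a group score; Inf weight if the
# score is degenerate or its effect is exactly zero.
score_weight <- function(score, time, status) {
  if (is.null(score)) return(Inf)
  b <- fit_univariable(score, time, status)$estimate
  if (b == 0) Inf else 1 / abs(b)
}

weights_pca_ <- function(data, scale_pc_scores) {
  w_group <- vapply(levels(data$groups), function(g) {
    score_weight(pc1_score(data$x[, data$groups == g, drop = FALSE], scale_pc_scores),
                 data$time, data$status)
  }, 0)
  unname(w_group[as.integer(data$groups)])
}

weights_lasso_pca_ <- function(data, k_folds, seed, scale_pc_scores) {
  step1 <- cox_adaptive_lasso(data, weights = NULL, k_folds = k_folds, seed = seed)
  sel <- step1$beta != 0
  p <- ncol(data$x)
  if (!any(sel)) {
    warning("first-step lasso selected nothing; lasso_pca weights are all infinite",
            call. = FALSE)
    return(rep(Inf, p))
  }
  lev <- levels(data$groups)
  sel_groups <- lev[lev %in% unique(as.character(data$groups[sel]))]
  w_group <- stats::setNames(rep(NA_real_, length(lev)), lev)
  for (g in sel_groups) {
    member <- data$groups == g & sel
    xg <- data$x[, member, drop = FALSE]
    # a single selected member is its own first principal component
    score <- pc1_score(xg, scale_pc_scores)
    w_group[g] <- score_weight(score, data$time, data$status)
  }
  w_max <- max(w_group[sel_groups][is.finite(w_group[sel_groups])], -Inf)
  if (!is.finite(w_max)) w_max <- Inf
  w_group[setdiff(lev, sel_groups)] <- w_max
  unname(w_group[as.integer(data$groups)])
}

#' Group-level summaries of univariable evidence
#'
#' For each group: the mean absolute univariable coefficient (the AC
#' denominator), and the mean (`asw`) and maximum (`msw`) of the member Wald
#' statistics.
#'
#' @inheritParams adaptive_weights
#' @return A tibble with one row per group: `group`, `size`, `mean_abs_beta`,
#'   `asw`, `msw`.
#' @export
group_wald_summaries <- function(data, uni = NULL, wald = c("chisq", "abs_z")) {
  uni <- uni_or_fit(data, uni, match.arg(wald))
  dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(group = data$groups,
                     abs_beta = abs(uni$estimate), sw = uni$wald),
      .data$group),
    size = dplyr::n(),
    mean_abs_beta = mean(.data$abs_beta),
    asw = mean(.data$sw),
    msw = max(.data$sw),
    .groups = "drop")
}

#' @export
print.adaptive_weights <- function(x, ...) {
  cat(sprintf("<adaptive_weights> scheme %s; %d finite of %d weights\n",
              attr(x, "scheme"), sum(is.finite(x$weight)), nrow(x)))
  NextMethod()
}
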