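#' Plot the cross-validated log-likelihood curve of a fit
#'
#' @param object A [cox_adaptive_lasso()] fit.
#' @param ... Unused.
#' @return A ggplot: cvl against log(lambda), with the selected penalty
#'   marked.
#' @method autoplot cox_alasso
#' @export
autoplot.cox_alasso <- function(object, ...) {
  df <- tibble::tibble(lambda = object$lambda_path, cvl = object$cvl)
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda), y = .data$cvl)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$lambda), linetype = 2) +
    ggplot2::labs(
      x = expression(log(lambda)),
      y = "cross-validated partial log-likelihood",
      title = sprintf("%s weighting: %d biomarkers selected",
                      object$scheme, length(object$selected))
    )
}

#' Plot adaptive weights by group
#'
#' @param object An [adaptive_weights()] table.
#' @param ... Unused.
#' @return A ggplot of log10 penalty weights by group (infinite weights are
#'   dropped from the panel).
#' @method autoplot adaptive_weights
#' @export
autoplot.adaptive_weights <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), is.finite(.data$weight))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = log10(.data$weight))) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "group", y = "log10 penalty weight",
                  title = sprintf("%s adaptive weights", attr(object, "scheme"))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot mean FDR against mean FNR per method
#'
#' Mirrors the usual way replicated selection benchmarks are displayed: each
#' point is a method in a scenario, the better methods sit near the origin.
#'
#' @param summary_tbl Output of [aggregate_benchmark()].
#' @param level `"biomarker"` or `"group"`.
#' @return A ggplot.
#' @export
plot_fdr_fnr <- function(summary_tbl, level = c("biomarker", "group")) {
  level <- match.arg(level)
  xcol <- if (level == "biomarker") "fdr_mean" else "group_fdr_mean"
  ycol <- if (level == "biomarker") "fnr_mean" else "group_fnr_mean"
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]],
                               label = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = sprintf("mean %s-level FDR", level),
                  y = sprintf("mean %s-level FNR", level))
}

#' Plot selection frequencies from split validation
#'
#' @param sv A [split_validate()] result.
#' @param min_freq Only biomarkers selected more often than this fraction of
#'   splits (by any method) are shown.
#' @return A ggplot of selection frequency by biomarker and method.
#' @export
plot_selection_frequency <- function(sv, min_freq = 0.1) {
  stopifnot(inherits(sv, "split_validation"))
  keep <- sv$selection |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::filter(max(.data$frequency) > min_freq) |>
    dplyr::ungroup()
  ggplot2::ggplot(keep, ggplot2::aes(x = .data$frequency,
                                     y = stats::reorder(.data$feature_id, .data$frequency),
                                     colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "selection frequency", y = NULL, colour = "group")
}
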