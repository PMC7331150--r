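#' Construct a grouped survival dataset
#'
#' Bundles an `n x p` biomarker matrix, right-censored survival outcomes and a
#' disjoint group (pathway) structure into a validated object that every other
#' function in the package accepts as its first argument.
#'
#' @param x Numeric matrix, patients in rows, biomarkers in columns. Column
#'   names are used as feature identifiers when `feature_ids` is missing.
#' @param time Positive, finite follow-up times (same units throughout; the
#'   default AUC horizon of 5 assumes years).
#' @param status Event indicator, coded 0 (censored) / 1 (event).
#' @param groups Group membership, one label per biomarker: either a vector of
#'   length `p`, or a two-column data frame with columns `feature_id` and
#'   `group`. Every biomarker must belong to exactly one group.
#' @param feature_ids Optional character vector of `p` unique identifiers.
#'
#' @return An object of class `survival_dataset`: a list with elements `x`,
#'   `time`, `status`, `feature_ids`, `groups` (a factor of length `p`).
#' @examples
#' x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
#' dat <- survival_dataset(x, time = rexp(10, 0.2) + 0.1,
#'                         status = rbinom(10, 1, 0.6),
#'                         groups = c("A", "A", "B", "B"))
#' dat
#' @export
survival_dataset <- function(x, time, status, groups, feature_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be a numeric matrix", call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("need at least 2 patients (rows)", call. = FALSE)
  if (p < 1L) stop("need at least 1 biomarker (column)", call. = FALSE)
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)
    stop(sprintf("`x` contains missing values (first at row %d, column %d)",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(x)
    if (is.null(feature_ids)) feature_ids <- paste0("bm", seq_len(p))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != p) stop("`feature_ids` must have one entry per column of `x`", call. = FALSE)
  if (anyDuplicated(feature_ids)) {
    stop(sprintf("duplicate feature ids: %s",
                 paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", ")),
         call. = FALSE)
  }
  colnames(x) <- feature_ids

  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) != n || length(status) != n)
    stop("`time` and `status` must have one entry per row of `x`", call. = FALSE)
  if (anyNA(time) || any(!is.finite(time)) || any(time <= 0)) {
    bad <- which(is.na(time) | !is.finite(time) | time <= 0)[1]
    stop(sprintf("`time` must be strictly positive and finite (row %d is not)", bad),
         call. = FALSE)
  }
  if (anyNA(status) || !all(status %in% c(0, 1))) {
    bad <- which(is.na(status) | !(status %in% c(0, 1)))[1]
    stop(sprintf("`status` must be 0/1 (row %d has value %s)", bad,
                 format(status[bad])), call. = FALSE)
  }

  groups <- resolve_groups(groups, feature_ids)

  structure(
    list(x = x, time = time, status = as.integer(status),
         feature_ids = feature_ids, groups = groups),
    class = "survival_dataset"
  )
}

# Accept a per-feature vector or a (feature_id, group) mapping table; enforce
# the disjoint-and-exhaustive partition invariant.
resolve_groups <- function(groups, feature_ids) {
  p <- length(feature_ids)
  if (is.data.frame(groups)) {
    nm <- names(groups)
    if (!all(c("feature_id", "group") %in% nm))
      stop("group mapping needs columns `feature_id` and `group`", call. = FALSE)
    if (anyDuplicated(groups$feature_id))
      stop("group mapping assigns some feature more than one group", call. = FALSE)
    miss <- setdiff(feature_ids, as.character(groups$feature_id))
    if (length(miss))
      stop(sprintf("feature without group: %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    groups <- groups$group[match(feature_ids, as.character(groups$feature_id))]
  }
  if (length(groups) != p)
    stop("`groups` must assign a group to each of the p biomarkers", call. = FALSE)
  if (anyNA(groups)) stop("feature without group (NA group label)", call. = FALSE)
  g <- factor(as.character(groups), levels = unique(as.character(groups)))
  if (any(tabulate(g) == 0)) stop("every group must be non-empty", call. = FALSE)
  g
}

#' @export
print.survival_dataset <- function(x, ...) {
  ev <- sum(x$status)
  cat(sprintf("<survival_dataset> %d patients, %d biomarkers in %d groups\n",
              nrow(x$x), ncol(x$x), nlevels(x$groups)))
  cat(sprintf("  events: %d (%.1f%% censored); follow-up %.3g-%.3g\n",
              ev, 100 * mean(x$status == 0), min(x$time), max(x$time)))
  tab <- table(x$groups)
  cat("  group sizes: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of patients, biomarkers and groups
#'
#' @param x A [survival_dataset()].
#' @param ... Unused.
#' @return A one-row tibble with `n`, `p`, `n_groups`, `n_events`.
#' @method glance survival_dataset
#' @export
glance.survival_dataset <- function(x, ...) {
  tibble::tibble(n = nrow(x$x), p = ncol(x$x),
                 n_groups = nlevels(x$groups), n_events = sum(x$status))
}

#' Read a grouped survival dataset from delimited files
#'
#' Reads the three CSV files that define an analysis: the biomarker matrix
#' (patients in rows, one column per biomarker, header row of feature ids),
#' the survival table (columns `id`, `time`, `status`; `id` optional), and the
#' group map (columns `feature_id`, `group`). Files must be comma-separated,
#' UTF-8, with a header row.
#'
#' @param matrix_path,survival_path,groups_path Paths to the three files.
#' @return A validated [survival_dataset()].
#' @export
read_survival_dataset <- function(matrix_path, survival_path, groups_path) {
  xmat <- readr::read_csv(matrix_path, show_col_types = FALSE, progress = FALSE)
  # base parser: correctly rounded doubles, so written times round-trip exactly
  surv <- utils::read.csv(survival_path)
  gmap <- readr::read_csv(groups_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time", "status") %in% names(surv)))
    stop("survival file needs columns `time` and `status`", call. = FALSE)
  x <- as.matrix(xmat)
  storage.mode(x) <- "double"
  survival_dataset(x, time = surv$time, status = surv$status, groups = gmap)
}

#' Write a grouped survival dataset to delimited files
#'
#' Inverse of [read_survival_dataset()]; the three files round-trip the
#' feature ids, group labels, times and statuses exactly.
#'
#' @param data A [survival_dataset()].
#' @param matrix_path,survival_path,groups_path Output paths.
#' @return `data`, invisibly.
#' @export
write_survival_dataset <- function(data, matrix_path, survival_path, groups_path) {
  stopifnot(inherits(data, "survival_dataset"))
  readr::write_csv(tibble::as_tibble(data$x), matrix_path, progress = FALSE)
  # times are written at full binary precision so the round trip is exact
  readr::write_csv(
    tibble::tibble(id = seq_along(data$time),
                   time = sprintf("%.17g", data$time), status = data$status),
    survival_path, progress = FALSE)
  readr::write_csv(
    tibble::tibble(feature_id = data$feature_ids, group = as.character(data$groups)),
    groups_path, progress = FALSE)
  invisible(data)
}

#' Centre and scale biomarker columns
#'
#' Each column is shifted to mean zero and scaled to unit standard deviation
#' using the population convention (divisor `n`, not `n - 1`), matching the
#' simulator's exact unit-variance contract. Idempotent up to rounding.
#'
#' @param x Numeric matrix with at least two rows and no constant column.
#' @return The standardized matrix.
#' @examples
#' standardize_columns(cbind(a = c(1, 2, 3)))
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("standardization needs at least 2 rows", call. = FALSE)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, "-")
  sdev <- sqrt(colMeans(xc^2))
  if (any(sdev == 0)) {
    bad <- which(sdev == 0)[1]
    nm <- colnames(x)[bad]
    stop(sprintf("constant column cannot be standardized: %s",
                 if (is.null(nm)) bad else nm), call. = FALSE)
  }
  sweep(xc, 2L, sdev, "/")
}

#' Standardize the biomarker matrix of a dataset
#'
#' @param data A [survival_dataset()].
#' @return The dataset with `x` replaced by its column-standardized version
#'   (population-SD convention, see [standardize_columns()]).
#' @export
standardize_dataset <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  data$x <- standardize_columns(data$x)
  data
}
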