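#' Method labels understood by the benchmark
#'
#' @return Character vector: `"standard_lasso"` plus the eight
#'   [adaptive_weights()] schemes.
#' @export
benchmark_methods <- function() {
  c("standard_lasso", "AC", "PCA", "lasso_pca", "SW", "ASW", "MSW",
    "ASWxSW", "MSWxSW")
}

# Fit one method on a training set (sharing the univariable table across
# schemes) and score it against the truth and the validation set.
run_one_method <- function(method, sim, uni, cv_seed, horizon, n_lambda,
                           min_ratio, k_folds, thresh) {
  train <- sim$train
  w <- if (method == "standard_lasso") NULL
       else adaptive_weights(train, scheme = method, uni = uni,
                             k_folds = k_folds, seed = cv_seed)
  fit <- cox_adaptive_lasso(train, weights = w, n_lambda = n_lambda,
                            min_ratio = min_ratio, k_folds = k_folds,
                            seed = cv_seed, thresh = thresh)
  sel_idx <- which(fit$beta != 0)
  bm <- selection_metrics(sel_idx, sim$active_idx, p = ncol(train$x))
  gm <- group_metrics(sel_idx, sim$active_idx, train$groups)
  auc <- NA_real_
  if (!is.null(sim$valid)) {
    marker <- predict(fit, sim$valid)
    auc <- ipcw_auc(marker, sim$valid$time, sim$valid$status, horizon)$auc
  }
  tibble::tibble(
    method = method, lambda = fit$lambda,
    n_selected = length(sel_idx),
    fdr = bm$fdr, fnr = bm$fnr, f1 = bm$f1,
    group_fdr = gm$fdr, group_fnr = gm$fnr, group_f1 = gm$f1,
    auc = auc, error = NA_character_
  )
}

#' Replicated simulation benchmark
#'
#' Runs the full pipeline -- simulate a training/validation pair, build
#' adaptive weights on the training set, fit each method with cvl-selected
#' penalty, score selection against the truth and discrimination on the
#' validation set -- for every combination of scenario, method and replicate.
#' Replicate seeds are spawned from `master_seed`, so results are
#' reproducible replicate by replicate and independent of the worker count.
#'
#' @param scenarios A [scenario_config()] or list of them.
#' @param methods Subset of [benchmark_methods()].
#' @param n_reps Replicates per scenario.
#' @param master_seed Integer master seed.
#' @param workers Number of parallel workers (forked; 1 = sequential).
#' @param horizon Validation AUC horizon, years.
#' @param n_lambda,min_ratio,k_folds,thresh Fitting controls, see
#'   [cox_adaptive_lasso()].
#' @return A tibble with one row per scenario x method x replicate:
#'   identifiers, seeds, the chosen `lambda`, `n_selected`, biomarker-level
#'   `fdr`/`fnr`/`f1`, group-level analogues, validation `auc`, and `error`
#'   (message when a method failed on a replicate; its metric columns are NA).
#' @examples
#' \donttest{
#' cfg <- scenario_config(3, p = 40, group_sizes = rep(10, 4), n_train = 80,
#'                        n_valid = 80, q = 4, l = 1)
#' run_benchmark(cfg, c("standard_lasso", "MSWxSW"), n_reps = 2,
#'               master_seed = 1, n_lambda = 30)
#' }
#' @export
run_benchmark <- function(scenarios, methods = benchmark_methods(),
                          n_reps = 50L, master_seed = 1L, workers = 1L,
                          horizon = 5, n_lambda = 100L, min_ratio = 0.01,
                          k_folds = 5L, thresh = 1e-6) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  methods <- match.arg(methods, benchmark_methods(), several.ok = TRUE)
  seeds <- with_seed(master_seed,
                     matrix(sample.int(.Machine$integer.max - 1L, 2L * n_reps * length(scenarios)),
                            ncol = 2L))

  jobs <- expand.grid(rep = seq_len(n_reps), scen = seq_along(scenarios))
  run_job <- function(j) {
    si <- jobs$scen[j]
    ri <- jobs$rep[j]
    row <- (si - 1L) * n_reps + ri
    sim_seed <- seeds[row, 1L]
    cv_seed <- seeds[row, 2L]
    config <- scenarios[[si]]
    sim <- simulate_dataset(config, seed = sim_seed)
    uni <- univariable_cox(sim$train)
    scen_id <- if (is.null(config$scenario)) as.character(si)
               else sprintf("%d%s", config$scenario, config$sizes)
    purrr::map_dfr(methods, function(m) {
      res <- tryCatch(
        run_one_method(m, sim, uni, cv_seed, horizon, n_lambda, min_ratio,
                       k_folds, thresh),
        error = function(e) tibble::tibble(
          method = m, lambda = NA_real_, n_selected = NA_integer_,
          fdr = NA_real_, fnr = NA_real_, f1 = NA_real_,
          group_fdr = NA_real_, group_fnr = NA_real_, group_f1 = NA_real_,
          auc = NA_real_, error = conditionMessage(e))
      )
      dplyr::bind_cols(
        tibble::tibble(scenario = scen_id, replicate = ri,
                       sim_seed = sim_seed, cv_seed = cv_seed),
        res)
    })
  }

  out <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(jobs)), run_job, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(jobs)), run_job)
  }
  dplyr::bind_rows(out)
}

#' Aggregate benchmark replicates
#'
#' Per scenario and method: the mean and empirical standard error (sample
#' standard deviation across replicates) of each metric, plus the number of
#' replicates and of recorded failures (failed replicates are excluded from
#' the means).
#'
#' @param results Output of [run_benchmark()].
#' @return A tibble with one row per scenario x method.
#' @export
aggregate_benchmark <- function(results) {
  stopifnot(nrow(results) > 0)
  metrics <- c("fdr", "fnr", "f1", "n_selected", "auc",
               "group_fdr", "group_fnr", "group_f1")
  results |>
    dplyr::group_by(.data$scenario, .data$method) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      n_failed = sum(!is.na(.data$error)),
      dplyr::across(dplyr::all_of(metrics),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         ese = ~stats::sd(.x, na.rm = TRUE))),
      .groups = "drop")
}

#' Split-sample validation on a real dataset
#'
#' Repeats random training/validation splits of one dataset: on each split
#' the chosen methods are fitted on the training part (with cvl-selected
#' penalty) and scored on the held-out part with the IPCW AUC. Reports
#' per-biomarker selection frequencies and per-method AUC summaries. Splits
#' where either side has no events are redrawn (counted in `n_resampled`).
#'
#' @param data A [survival_dataset()].
#' @param methods Subset of [benchmark_methods()].
#' @param n_splits Number of random splits.
#' @param train_frac Fraction of patients in the training part.
#' @param seed Master seed.
#' @param horizon AUC horizon, years.
#' @param standardize `"split"` (default) re-standardizes biomarkers within
#'   each training split (population-SD convention) and applies the training
#'   centring/scaling to the validation part; `"global"` standardizes once up
#'   front; `"none"` uses the data as supplied.
#' @param min_freq Reporting threshold for `frequent_features` (default 0.1:
#'   biomarkers selected in more than 10% of splits).
#' @param ... Fitting controls passed to [cox_adaptive_lasso()].
#' @return A list of class `split_validation`: `selection` (tibble with
#'   per-method, per-biomarker selection counts and frequencies), `auc`
#'   (tibble with per-method mean AUC and empirical SE), `frequent_features`
#'   (selection rows above `min_freq`), `n_splits`, `n_resampled`.
#' @export
split_validate <- function(data, methods = benchmark_methods(),
                           n_splits = 500L, train_frac = 0.6, seed = 1L,
                           horizon = 5,
                           standardize = c("split", "global", "none"),
                           min_freq = 0.1, ...) {
  stopifnot(inherits(data, "survival_dataset"))
  if (train_frac <= 0 || train_frac >= 1) stop("`train_frac` must be in (0, 1)", call. = FALSE)
  methods <- match.arg(methods, benchmark_methods(), several.ok = TRUE)
  standardize <- match.arg(standardize)
  if (standardize == "global") data <- standardize_dataset(data)
  n <- nrow(data$x)
  n_tr <- round(train_frac * n)
  n_resampled <- 0L

  counts <- matrix(0L, ncol(data$x), length(methods),
                   dimnames = list(data$feature_ids, methods))
  aucs <- matrix(NA_real_, n_splits, length(methods),
                 dimnames = list(NULL, methods))

  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      repeat {
        tr <- sample.int(n, n_tr)
        if (sum(data$status[tr]) >= 1L && sum(data$status[-tr]) >= 1L) break
        n_resampled <- n_resampled + 1L
      }
      take <- function(idx) {
        d <- data
        d$x <- data$x[idx, , drop = FALSE]
        d$time <- data$time[idx]
        d$status <- data$status[idx]
        d
      }
      train <- take(tr)
      valid <- take(setdiff(seq_len(n), tr))
      if (standardize == "split") {
        ctr <- colMeans(train$x)
        scl <- sqrt(colMeans(sweep(train$x, 2L, ctr, "-")^2))
        if (any(scl == 0)) stop("constant biomarker in a training split", call. = FALSE)
        train$x <- sweep(sweep(train$x, 2L, ctr, "-"), 2L, scl, "/")
        valid$x <- sweep(sweep(valid$x, 2L, ctr, "-"), 2L, scl, "/")
      }
      cv_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      uni <- univariable_cox(train)
      for (m in methods) {
        res <- tryCatch({
          w <- if (m == "standard_lasso") NULL
               else adaptive_weights(train, scheme = m, uni = uni, seed = cv_seed)
          fit <- cox_adaptive_lasso(train, weights = w, seed = cv_seed, ...)
          counts[fit$beta != 0, m] <- counts[fit$beta != 0, m] + 1L
          aucs[s, m] <- ipcw_auc(predict(fit, valid), valid$time,
                                  valid$status, horizon)$auc
          NULL
        }, error = function(e) e)
      }
    }
  })

  selection <- tibble::tibble(
    feature_id = rep(data$feature_ids, length(methods)),
    group = rep(data$groups, length(methods)),
    method = rep(methods, each = nrow(counts)),
    n_selected_times = as.integer(counts),
    frequency = as.numeric(counts) / n_splits
  )
  auc_tab <- tibble::tibble(
    method = methods,
    mean_auc = colMeans(aucs, na.rm = TRUE),
    ese = apply(aucs, 2L, stats::sd, na.rm = TRUE),
    n_splits = n_splits
  )
  structure(list(
    selection = selection,
    auc = auc_tab,
    frequent_features = dplyr::filter(selection, .data$frequency > min_freq),
    n_splits = n_splits, n_resampled = n_resampled
  ), class = "split_validation")
}

#' @export
print.split_validation <- function(x, ...) {
  cat(sprintf("<split_validation> %d splits (%d resampled)\n",
              x$n_splits, x$n_resampled))
  print(x$auc)
  invisible(x)
}
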