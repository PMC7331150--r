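#' Simulation scenario configuration
#'
#' Describes one survival-simulation scenario: grouped Gaussian biomarkers
#' with block-autoregressive correlation, exponential event times whose
#' hazard depends on a sparse set of active biomarkers, and independent
#' uniform censoring. Eight numbered scenarios are bundled, in two group-size
#' layouts:
#'
#' | scenario | active groups `l` | active biomarkers `q` | hazard-ratio range |
#' |---|---|---|---|
#' | 1 | 0 | 0 | -- |
#' | 2 | 20 | 100 | (0.85, 0.95) |
#' | 3 | 1 | 8 | (0.65, 0.75) |
#' | 4 | 2 | 8 | (0.65, 0.75) |
#' | 5 | 1 | 32 | (0.85, 0.95) |
#' | 6 | 2 | 32 | (0.85, 0.95) |
#' | 7 | 2 | 16 | (0.85, 0.95) |
#' | 8 | 2 | 8 | (0.85, 0.95) |
#'
#' Layout `"a"` uses 20 equal groups of 50 biomarkers; layout `"b"` uses 10
#' groups of 25 and 10 of 75. With one active group it is group 1; with two,
#' groups 1 and 2 in layout `"a"` and groups 1 and 11 in layout `"b"` (so the
#' active groups span both sizes). Active biomarkers are spread equally over
#' the active groups, occupying the leading positions of each.
#'
#' @param scenario Integer 1-8 selecting the preset above, or `NULL` to
#'   specify `l`, `q` and `hr_range` directly.
#' @param sizes `"a"` (20 equal groups of 50) or `"b"` (10 of 25 + 10 of 75);
#'   ignored when `group_sizes` is given.
#' @param n_train,n_valid Training and validation sample sizes (patients).
#'   The small-sample sensitivity setting uses `n_train = 50`.
#' @param p Number of biomarkers; must be divisible by `block_size`.
#' @param group_sizes Integer vector of group sizes summing to `p`.
#' @param l,q Number of active groups and active biomarkers (`q` divisible by
#'   `l`; `q/l` at most the smallest active group size).
#' @param hr_range Hazard-ratio interval `(lo, hi)` from which active-effect
#'   hazard ratios are drawn uniformly on the log scale bounds, i.e.
#'   `beta ~ U(log lo, log hi)`; both in (0, 1) for protective effects.
#' @param active_groups Labels (indices) of the active groups.
#' @param active_positions Within-group member positions of the active
#'   biomarkers (default: the first `q/l` of each active group).
#' @param rho Within-block autoregressive correlation base; `cor(x_i, x_j) =
#'   rho^|i-j|` inside a block.
#' @param block_size Size of the independent correlation blocks (consecutive
#'   biomarkers).
#' @param baseline_median Baseline median survival time, years.
#' @param censor_range Support `(lo, hi)` of the uniform censoring time,
#'   years; the default (2, 6) reflects a trial with two-year follow-up and
#'   four-year accrual.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = NULL, sizes = c("a", "b"),
                            n_train = 500L, n_valid = 500L, p = 1000L,
                            group_sizes = NULL, l = NULL, q = NULL,
                            hr_range = NULL, active_groups = NULL,
                            active_positions = NULL,
                            rho = 0.8, block_size = 5L,
                            baseline_median = 8, censor_range = c(2, 6)) {
  sizes <- match.arg(sizes)
  if (!is.null(scenario)) {
    preset <- list(
      `1` = list(l = 0L, q = 0L,   hr = NULL),
      `2` = list(l = 20L, q = 100L, hr = c(0.85, 0.95)),
      `3` = list(l = 1L, q = 8L,   hr = c(0.65, 0.75)),
      `4` = list(l = 2L, q = 8L,   hr = c(0.65, 0.75)),
      `5` = list(l = 1L, q = 32L,  hr = c(0.85, 0.95)),
      `6` = list(l = 2L, q = 32L,  hr = c(0.85, 0.95)),
      `7` = list(l = 2L, q = 16L,  hr = c(0.85, 0.95)),
      `8` = list(l = 2L, q = 8L,   hr = c(0.85, 0.95))
    )[[as.character(scenario)]]
    if (is.null(preset)) stop("`scenario` must be in 1..8", call. = FALSE)
    if (is.null(l)) l <- preset$l
    if (is.null(q)) q <- preset$q
    if (is.null(hr_range)) hr_range <- preset$hr
  }
  if (is.null(group_sizes)) {
    group_sizes <- if (sizes == "a") {
      rep(p / 20L, 20L)
    } else {
      c(rep(p / 40L, 10L), rep(3L * p / 40L, 10L))
    }
    if (any(group_sizes != round(group_sizes)))
      stop("`p` is not compatible with the default group layout; give `group_sizes`",
           call. = FALSE)
    group_sizes <- as.integer(group_sizes)
  }
  if (sum(group_sizes) != p) stop("`group_sizes` must sum to `p`", call. = FALSE)
  if (p %% block_size != 0) stop("`p` must be divisible by `block_size`", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("`rho` must be in [0, 1)", call. = FALSE)
  if (is.null(l)) l <- 0L
  if (is.null(q)) q <- 0L
  if (l > 0) {
    if (q %% l != 0)
      stop("`q` must be divisible by `l` (equal split over active groups)", call. = FALSE)
    if (is.null(active_groups)) {
      active_groups <- if (l == length(group_sizes)) seq_along(group_sizes)
                       else if (l == 1L) 1L
                       else if (l == 2L && sizes == "b") c(1L, 11L)
                       else seq_len(l)
    }
    if (length(active_groups) != l) stop("`active_groups` must have length `l`", call. = FALSE)
    if (any(q / l > group_sizes[active_groups]))
      stop("more active biomarkers per group than the group size", call. = FALSE)
    if (is.null(hr_range)) stop("active scenarios need `hr_range`", call. = FALSE)
    if (any(hr_range <= 0) || any(hr_range >= 1) || hr_range[1] > hr_range[2])
      stop("`hr_range` must satisfy 0 < lo <= hi < 1", call. = FALSE)
    if (is.null(active_positions)) active_positions <- seq_len(q / l)
    if (length(active_positions) != q / l)
      stop("`active_positions` must have length q/l", call. = FALSE)
  } else {
    q <- 0L
    active_groups <- integer(0)
    active_positions <- integer(0)
  }

  structure(list(
    scenario = scenario, sizes = sizes,
    n_train = as.integer(n_train), n_valid = as.integer(n_valid),
    p = as.integer(p), group_sizes = as.integer(group_sizes),
    l = as.integer(l), q = as.integer(q), hr_range = hr_range,
    active_groups = as.integer(active_groups),
    active_positions = as.integer(active_positions),
    rho = rho, block_size = as.integer(block_size),
    baseline_median = baseline_median, censor_range = censor_range
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %sp=%d in %d groups; l=%d active groups, q=%d active biomarkers\n",
              if (is.null(x$scenario)) "" else sprintf("scenario %d%s: ", x$scenario, x$sizes),
              x$p, length(x$group_sizes), x$l, x$q))
  if (x$l > 0)
    cat(sprintf("  HR ~ U(%.2f, %.2f) in groups {%s}\n", x$hr_range[1], x$hr_range[2],
                paste(x$active_groups, collapse = ", ")))
  cat(sprintf("  n_train=%d, n_valid=%d; baseline median %.3g y, censoring U(%g, %g)\n",
              x$n_train, x$n_valid, x$baseline_median,
              x$censor_range[1], x$censor_range[2]))
  invisible(x)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate the correlated biomarker matrix
#'
#' Draws `n` rows of `p` standard-Gaussian biomarkers in consecutive blocks
#' of `block_size`; within a block `cor(x_i, x_j) = rho^|i-j|`, across blocks
#' biomarkers are independent. Population column means are 0 and variances 1.
#'
#' @param config A [scenario_config()].
#' @param n Number of rows (defaults to `config$n_train`).
#' @param seed Optional seed; `NULL` draws from the current RNG state.
#' @return An `n x p` matrix.
#' @export
make_design <- function(config, n = config$n_train, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    p <- config$p
    b <- config$block_size
    sigma <- config$rho^abs(outer(seq_len(b), seq_len(b), "-"))
    cr <- chol(sigma)
    z <- matrix(stats::rnorm(n * p), n, p)
    for (k in seq_len(p / b)) {
      idx <- ((k - 1L) * b + 1L):(k * b)
      z[, idx] <- z[, idx] %*% cr
    }
    z
  })
}

#' Draw the true coefficient vector of a scenario
#'
#' Active biomarkers (the configured positions of each active group) get
#' independent log hazard ratios uniform on `(log hr_lo, log hr_hi)`; all
#' other coefficients are exactly zero.
#'
#' @inheritParams make_design
#' @return Numeric vector of length `p` with attribute `active` (indices of
#'   the active biomarkers).
#' @export
make_coefficients <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    beta <- numeric(config$p)
    active <- integer(0)
    if (config$l > 0) {
      start <- cumsum(c(0L, config$group_sizes))[config$active_groups]
      active <- as.integer(outer(config$active_positions, start, "+"))
      beta[active] <- stats::runif(length(active),
                                   log(config$hr_range[1]), log(config$hr_range[2]))
    }
    attr(beta, "active") <- sort(active)
    beta
  })
}

#' Simulate survival outcomes given biomarkers and effects
#'
#' Event times are exponential with rate
#' `log(2) / baseline_median * exp(X beta)` (so the baseline median survival
#' is `baseline_median` years); censoring times are uniform on
#' `censor_range`, independent of the event times. The observation is the
#' earlier of the two.
#'
#' @param x Biomarker matrix.
#' @param beta True log hazard ratios.
#' @inheritParams make_design
#' @return A tibble with columns `time` and `status`.
#' @export
make_survival <- function(x, beta, config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    n <- nrow(x)
    rate0 <- log(2) / config$baseline_median
    tt <- stats::rexp(n, rate = 1) / (rate0 * exp(drop(x %*% beta)))
    cc <- stats::runif(n, config$censor_range[1], config$censor_range[2])
    tibble::tibble(time = pmin(tt, cc), status = as.integer(tt <= cc))
  })
}

#' Simulate a training/validation pair under a scenario
#'
#' Draws one true coefficient vector and two independent datasets (training
#' and validation) from the identical generating law. Deterministic given
#' `seed`.
#'
#' @inheritParams make_design
#' @param fixed_beta Optional coefficient vector to reuse instead of drawing
#'   a fresh one (e.g. to hold effects fixed across replicates).
#' @return A list of class `grouped_cox_sim` with elements `train` and
#'   `valid` ([survival_dataset()]s; `valid` is `NULL` when `n_valid` is 0),
#'   `beta` (true coefficients) and `active` (active feature ids).
#' @export
simulate_dataset <- function(config, seed = NULL, fixed_beta = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    beta <- if (is.null(fixed_beta)) make_coefficients(config) else fixed_beta
    active <- attr(beta, "active")
    if (is.null(active)) active <- which(beta != 0)
    feature_ids <- sprintf("bm%04d", seq_len(config$p))
    groups <- rep(sprintf("grp%02d", seq_along(config$group_sizes)),
                  config$group_sizes)
    one <- function(n) {
      x <- make_design(config, n)
      colnames(x) <- feature_ids
      sv <- make_survival(x, beta, config)
      survival_dataset(x, sv$time, sv$status, groups)
    }
    train <- one(config$n_train)
    valid <- if (config$n_valid > 0) one(config$n_valid) else NULL
    structure(list(train = train, valid = valid, beta = as.numeric(beta),
                   active = feature_ids[active], active_idx = active,
                   config = config, seed = seed),
              class = "grouped_cox_sim")
  })
}

#' @export
print.grouped_cox_sim <- function(x, ...) {
  cat(sprintf("<grouped_cox_sim> %d active of %d biomarkers; train n=%d%s\n",
              length(x$active), x$config$p, nrow(x$train$x),
              if (is.null(x$valid)) "" else sprintf(", valid n=%d", nrow(x$valid$x))))
  invisible(x)
}

#' Write a simulated dataset to CSV files
#'
#' Writes the three data files of [write_survival_dataset()] for the training
#' set plus a truth file (`feature_id`, `group`, `beta`, `active`) into a
#' directory.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "grouped_cox_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_survival_dataset(sim$train,
                         file.path(dir, "biomarkers.csv"),
                         file.path(dir, "survival.csv"),
                         file.path(dir, "groups.csv"))
  readr::write_csv(tibble::tibble(
    feature_id = sim$train$feature_ids,
    group = as.character(sim$train$groups),
    beta = sim$beta,
    active = sim$train$feature_ids %in% sim$active
  ), file.path(dir, "truth.csv"), progress = FALSE)
  invisible(dir)
}
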