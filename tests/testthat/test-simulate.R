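test_that("scenario presets carry the published design parameters", {
  cfg3 <- scenario_config(3)
  expect_equal(c(cfg3$l, cfg3$q), c(1, 8))
  expect_equal(cfg3$hr_range, c(0.65, 0.75))
  expect_equal(cfg3$group_sizes, rep(50L, 20L))
  cfg2 <- scenario_config(2)
  expect_equal(c(cfg2$l, cfg2$q), c(20, 100))
  expect_equal(cfg2$active_groups, 1:20)
  cfgb <- scenario_config(4, sizes = "b")
  expect_equal(sort(unique(cfgb$group_sizes)), c(25L, 75L))
  expect_equal(cfgb$active_groups, c(1L, 11L))
  expect_equal(scenario_config(1)$q, 0)
  expect_error(scenario_config(9), "1..8")
  expect_error(scenario_config(3, rho = 1.2), "rho")
  expect_error(scenario_config(NULL, l = 3, q = 8, hr_range = c(0.7, 0.8),
                               p = 100, group_sizes = rep(25, 4)),
               "divisible")
})

test_that("design has the block-autoregressive correlation structure", {
  cfg <- scenario_config(1, p = 20, group_sizes = c(10, 10))
  x <- make_design(cfg, n = 100000, seed = 5)
  cm <- cor(x[, 1:6])
  # adjacent within-block pairs at rho = 0.8, lag 2 at 0.64
  expect_equal(cm[1, 2], 0.8, tolerance = 0.01)
  expect_equal(cm[2, 3], 0.8, tolerance = 0.01)
  expect_equal(cm[1, 3], 0.64, tolerance = 0.01)
  # features 5 and 6 straddle a block boundary
  expect_lt(abs(cm[5, 6]), 0.01)
  expect_equal(apply(x[, 1:6], 2, sd), rep(1, 6), tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("Cholesky construction matches an AR(1) recursion oracle", {
  cfg <- scenario_config(1, p = 5, group_sizes = 5L)
  x <- make_design(cfg, n = 50000, seed = 6)
  set.seed(6)
  rho <- 0.8
  z <- matrix(rnorm(50000 * 5), ncol = 5)
  ar <- z
  for (i in 2:5) ar[, i] <- rho * ar[, i - 1] + sqrt(1 - rho^2) * z[, i]
  expect_equal(cov(x), cov(ar), tolerance = 0.02)
})

test_that("coefficients land in the log hazard-ratio bounds at the right positions", {
  cfg <- scenario_config(3, p = 100, group_sizes = rep(25, 4), q = 8, l = 1)
  beta <- make_coefficients(cfg, seed = 3)
  active <- attr(beta, "active")
  expect_equal(active, 1:8)
  expect_true(all(beta[active] > log(0.65) & beta[active] < log(0.75)))
  expect_true(all(beta[-active] == 0))

  beta1 <- make_coefficients(scenario_config(1), seed = 3)
  expect_true(all(beta1 == 0))

  cfg2 <- scenario_config(2, p = 100, group_sizes = rep(5, 20))
  beta2 <- make_coefficients(cfg2, seed = 3)
  expect_equal(length(attr(beta2, "active")), 100)
  expect_equal(as.integer(table(rep(1:20, each = 5)[attr(beta2, "active")])),
               rep(5L, 20L))
})

test_that("baseline median survival is eight years", {
  cfg <- scenario_config(1, p = 5, group_sizes = 5L,
                         censor_range = c(1e9, 2e9))  # disable censoring
  x <- make_design(cfg, n = 1e6, seed = 8)
  sv <- make_survival(x, numeric(5), cfg, seed = 9)
  expect_equal(median(sv$time), 8, tolerance = 0.05)
  expect_true(all(sv$status == 1))
})

test_that("null-model censoring fraction matches the closed-form integral", {
  # P(censored) = E[exp(-lambda0 C)], C ~ U(2,6), lambda0 = log(2)/8
  closed <- (2 / log(2)) * (2^(-1 / 4) - 2^(-3 / 4))
  cfg <- scenario_config(1, p = 5, group_sizes = 5L)
  x <- make_design(cfg, n = 1e6, seed = 10)
  sv <- make_survival(x, numeric(5), cfg, seed = 11)
  expect_equal(mean(sv$status == 0), closed, tolerance = 0.005)
})

test_that("same seed reproduces datasets bit for bit; train and valid differ", {
  cfg <- scenario_config(4, p = 40, group_sizes = rep(10, 4), q = 4,
                         n_train = 30, n_valid = 30)
  s1 <- simulate_dataset(cfg, seed = 12)
  s2 <- simulate_dataset(cfg, seed = 12)
  expect_identical(s1$train$x, s2$train$x)
  expect_identical(s1$valid$time, s2$valid$time)
  expect_identical(s1$beta, s2$beta)
  expect_false(identical(s1$train$x, s1$valid$x))
  expect_equal(s1$active, s1$train$feature_ids[s1$active_idx])
  # fixed_beta override reuses the supplied effects
  s3 <- simulate_dataset(cfg, seed = 13, fixed_beta = s1$beta)
  expect_identical(s3$beta, s1$beta)
})

test_that("stronger effects shorten event times for high-risk subjects", {
  cfg <- scenario_config(3, p = 10, group_sizes = c(5, 5), q = 2, l = 1,
                         censor_range = c(1e9, 2e9))
  x <- make_design(cfg, n = 20000, seed = 14)
  b_strong <- c(-1.5, -1.5, rep(0, 8))
  sv0 <- make_survival(x, numeric(10), cfg, seed = 15)
  sv1 <- make_survival(x, b_strong, cfg, seed = 15)
  low <- x[, 1] + x[, 2] < -1   # protective effects: negative lp -> high risk
  expect_lt(median(sv1$time[low]), median(sv0$time[low]))
})

test_that("simulation export writes the four CSV files with the truth", {
  cfg <- scenario_config(3, p = 20, group_sizes = rep(5, 4), q = 2, l = 1,
                         n_train = 25, n_valid = 0)
  sim <- simulate_dataset(cfg, seed = 16)
  dir <- file.path(tempdir(), "simout")
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("biomarkers.csv", "survival.csv", "groups.csv", "truth.csv")))))
  truth <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  expect_equal(truth$feature_id[truth$active], sim$active)
  back <- read_survival_dataset(file.path(dir, "biomarkers.csv"),
                                file.path(dir, "survival.csv"),
                                file.path(dir, "groups.csv"))
  expect_identical(back$time, sim$train$time)
})
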