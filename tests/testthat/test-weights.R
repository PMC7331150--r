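# A fixture with two groups where the signal sits in group 1.
weights_fixture <- function() toy_dataset(n = 60, p = 8, n_groups = 2, seed = 51)

test_that("group-mean-coefficient weights follow the reciprocal-mean arithmetic", {
  dat <- weights_fixture()
  uni <- univariable_cox(dat)
  w <- adaptive_weights(dat, "AC", uni = uni)
  for (g in levels(dat$groups)) {
    idx <- dat$groups == g
    expect_equal(unique(w$weight[idx]), 1 / mean(abs(uni$estimate[idx])))
  }
  # hand value: a group with |beta| = (0.2, 0.4) weights both members 1/0.3
  expect_equal(1 / mean(c(0.2, 0.4)), 10 / 3)
})

test_that("Wald-based schemes satisfy the stated arithmetic on a hand group", {
  # group with member walds (1, 4): ASW = 2.5, MSW = 4
  sw <- c(1, 4)
  expect_equal(1 / mean(sw), 0.4)
  expect_equal(1 / max(sw), 0.25)
  expect_equal(1 / (mean(sw) * sw), c(0.4, 0.1))
  expect_equal(1 / (max(sw) * sw), c(0.25, 0.0625))

  dat <- weights_fixture()
  uni <- univariable_cox(dat)
  sw <- uni$wald
  schemes <- list(
    SW = 1 / sw,
    ASW = 1 / ave(sw, dat$groups, FUN = mean),
    MSW = 1 / ave(sw, dat$groups, FUN = max),
    ASWxSW = 1 / (ave(sw, dat$groups, FUN = mean) * sw),
    MSWxSW = 1 / (ave(sw, dat$groups, FUN = max) * sw)
  )
  for (s in names(schemes)) {
    w <- adaptive_weights(dat, s, uni = uni)
    expect_equal(w$weight, unname(schemes[[s]]), tolerance = 1e-12)
    expect_identical(attr(w, "scheme"), s)
  }
})

test_that("group-level summaries order as max >= mean >= reciprocal bounds", {
  dat <- weights_fixture()
  gs <- group_wald_summaries(dat)
  expect_true(all(gs$msw >= gs$asw))
  w_msw_sw <- adaptive_weights(dat, "MSWxSW")
  w_asw_sw <- adaptive_weights(dat, "ASWxSW")
  # since MSW >= ASW, the MSW*SW weight never exceeds the ASW*SW weight
  expect_true(all(w_msw_sw$weight <= w_asw_sw$weight + 1e-12))
  # the member attaining the group max has MSW*SW weight 1/MSW^2
  uni <- univariable_cox(dat)
  for (g in levels(dat$groups)) {
    idx <- which(dat$groups == g)
    top <- idx[which.max(uni$wald[idx])]
    expect_equal(w_msw_sw$weight[top], 1 / max(uni$wald[idx])^2, tolerance = 1e-12)
    # within the group, MSW*SW weights are inversely ordered to SW
    expect_equal(order(w_msw_sw$weight[idx]), order(-uni$wald[idx]))
  }
})

test_that("schemes are invariant to feature reordering", {
  dat <- weights_fixture()
  perm <- sample(ncol(dat$x))
  datp <- survival_dataset(dat$x[, perm], dat$time, dat$status,
                           as.character(dat$groups)[perm])
  for (s in c("AC", "SW", "ASW", "MSW", "ASWxSW", "MSWxSW", "PCA")) {
    w <- adaptive_weights(dat, s)
    wp <- adaptive_weights(datp, s)
    expect_equal(wp$weight, w$weight[perm], tolerance = 1e-9,
                 label = sprintf("scheme %s under permutation", s))
  }
})

test_that("PCA weights: singleton group equals the inverse univariable effect", {
  set.seed(61)
  n <- 30
  x <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  tt <- rexp(n, exp(0.9 * x[, 1]) / 5)
  cc <- runif(n, 1, 8)
  dat <- survival_dataset(x, pmin(tt, cc), as.integer(tt <= cc),
                          groups = c("g1", "g1", "solo"))
  w <- adaptive_weights(dat, "PCA", scale_pc_scores = TRUE)
  # singleton group: PC1 is the centred feature itself; with unit-variance
  # rescaling the score is the standardized feature
  z <- drop(scale(x[, 3], center = TRUE, scale = FALSE))
  z <- z / sqrt(mean(z^2))
  expect_equal(w$weight[3], 1 / abs(fit_univariable(z, dat$time, dat$status)$estimate),
               tolerance = 1e-8)
})

test_that("PCA weights on a duplicated-column group match the column's own effect", {
  set.seed(62)
  n <- 10
  base <- rnorm(n)
  x <- cbind(a = base, b = base, c = rnorm(n))
  tt <- rexp(n, exp(0.6 * base) / 3)
  cc <- runif(n, 0.5, 6)
  dat <- survival_dataset(x, pmin(tt, cc), as.integer(tt <= cc),
                          groups = c("g1", "g1", "g2"))
  w <- adaptive_weights(dat, "PCA", scale_pc_scores = TRUE)
  z <- drop(scale(base, center = TRUE, scale = FALSE))
  z <- z / sqrt(mean(z^2))
  ref <- 1 / abs(fit_univariable(z, dat$time, dat$status)$estimate)
  expect_equal(w$weight[1], ref, tolerance = 1e-6)
  expect_equal(w$weight[2], w$weight[1])
})

test_that("lasso+PCA weights follow the two-step recipe literally", {
  dat <- toy_dataset(n = 80, p = 12, n_groups = 3, seed = 71,
                     beta = c(-1, -0.8, rep(0, 10)))
  w <- adaptive_weights(dat, "lasso_pca", seed = 9)

  # independent re-implementation of the two steps
  step1 <- cox_adaptive_lasso(dat, weights = NULL, seed = 9)
  sel <- step1$beta != 0
  skip_if(!any(sel), "first-step lasso selected nothing on this fixture")
  lev <- levels(dat$groups)
  wg <- setNames(rep(NA_real_, 3), lev)
  for (g in lev[lev %in% unique(as.character(dat$groups[sel]))]) {
    member <- which(dat$groups == g & sel)
    score <- if (length(member) == 1L) dat$x[, member] else {
      xc <- scale(dat$x[, member], center = TRUE, scale = FALSE)
      drop(xc %*% svd(xc)$v[, 1])
    }
    z <- score - mean(score)
    z <- z / sqrt(mean(z^2))
    wg[g] <- 1 / abs(fit_univariable(z, dat$time, dat$status)$estimate)
  }
  wg[is.na(wg)] <- max(wg, na.rm = TRUE)
  expect_equal(w$weight, unname(wg[as.integer(dat$groups)]), tolerance = 1e-6)

  # non-selected groups inherit the maximum selected-group weight
  sel_groups <- unique(as.character(dat$groups[sel]))
  if (length(sel_groups) < 3) {
    inherited <- unique(w$weight[!(as.character(dat$groups) %in% sel_groups)])
    expect_equal(inherited, max(unique(w$weight[as.character(dat$groups) %in% sel_groups])))
  }
})

test_that("degenerate evidence yields infinite weights with a warning, cap caps", {
  dat <- weights_fixture()
  uni <- univariable_cox(dat)
  uni$wald[dat$groups == "g2"] <- 0
  uni$estimate[dat$groups == "g2"] <- 0
  expect_warning(w <- adaptive_weights(dat, "SW", uni = uni), "infinite")
  expect_true(all(is.infinite(w$weight[dat$groups == "g2"])))
  expect_warning(wac <- adaptive_weights(dat, "AC", uni = uni), "infinite")
  expect_true(all(is.infinite(wac$weight[dat$groups == "g2"])))
  wcap <- suppressWarnings(adaptive_weights(dat, "SW", uni = uni, weight_cap = 100))
  expect_true(all(wcap$weight <= 100))
})

test_that("single-biomarker single group under SW recovers classic adaptive lasso", {
  set.seed(81)
  n <- 50
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "a"))
  tt <- rexp(n, exp(0.8 * x[, 1]) / 6)
  cc <- runif(n, 1, 9)
  dat <- survival_dataset(x, pmin(tt, cc), as.integer(tt <= cc), "g")
  w <- adaptive_weights(dat, "SW")
  f <- fit_univariable(x[, 1], dat$time, dat$status)
  expect_equal(w$weight, 1 / f$wald, tolerance = 1e-10)
})
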