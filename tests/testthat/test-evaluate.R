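test_that("selection metrics reproduce hand-counted confusion tables", {
  perfect <- selection_metrics(1:4, 1:4, p = 20)
  expect_equal(c(perfect$fdr, perfect$fnr, perfect$f1), c(0, 0, 1))

  m <- selection_metrics(c(1, 2, 11, 12), active = c(1, 2, 3, 4, 5, 6, 7, 8),
                         p = 30)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(2, 2, 6, 20))
  expect_equal(m$fdr, 0.5)
  expect_equal(m$fnr, 0.75)
  expect_equal(m$f1, 4 / 12)
})

test_that("null-scenario accounting: empty selection scores 0, any selection 1", {
  none <- selection_metrics(integer(0), integer(0), p = 10)
  expect_equal(c(none$fdr, none$fnr, none$f1), c(0, 0, 0))
  some <- selection_metrics(c(3, 7), integer(0), p = 10)
  expect_equal(some$fdr, 1)
  na_mode <- selection_metrics(integer(0), integer(0), p = 10, empty = "na")
  expect_true(is.na(na_mode$fdr))
  expect_error(selection_metrics(c(0, 2), 1:2, p = 10), "out of range")
})

test_that("complements: FDR + precision = 1 and FNR + recall = 1 when defined", {
  set.seed(91)
  for (i in 1:20) {
    sel <- sample(30, sample(0:10, 1))
    act <- sample(30, sample(1:10, 1))
    m <- selection_metrics(sel, act, p = 30)
    if (m$tp + m$fp > 0) expect_equal(m$fdr + m$tp / (m$tp + m$fp), 1)
    expect_equal(m$fnr + m$tp / (m$tp + m$fn), 1)
  }
})

test_that("group lifting follows the any-member rule", {
  groups <- factor(rep(c("a", "b", "c"), each = 4))
  # one false-positive biomarker inside the active group: no group-level FP
  m <- group_metrics(selected = c(1, 2), active = c(1), groups = groups)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  expect_equal(m$level, "group")
  # selection hitting only inactive groups
  m2 <- group_metrics(selected = c(5, 9), active = c(1), groups = groups)
  expect_equal(m2$fdr, 1)
  # two active groups, one biomarker selected in each: no false negatives
  m3 <- group_metrics(selected = c(1, 5), active = c(2, 6), groups = groups)
  expect_equal(m3$fnr, 0)
})

test_that("censoring Kaplan-Meier matches a hand-computed product-limit table", {
  # subjects: time 1(event) 2(censored) 3(event) 4(censored) 5(censored)
  km <- km_censoring(time = 1:5, status = c(1, 0, 1, 0, 0))
  # censoring events at t = 2 (4 at risk), t = 4 (2 at risk), t = 5 (1 at risk)
  expect_equal(km$G(1), 1)
  expect_equal(km$G(2), 3 / 4)
  expect_equal(km$G_minus(2), 1)
  expect_equal(km$G(4), 3 / 4 * 1 / 2)
  expect_equal(km$G_minus(4), 3 / 4)
  expect_equal(km$G(5), 0)

  nocens <- km_censoring(1:4, rep(1, 4))
  expect_equal(nocens$G(3.9), 1)
  allcens <- km_censoring(rep(1, 3), rep(0, 3))
  expect_equal(allcens$G(1), 0)
  expect_equal(allcens$G_minus(1), 1)
})

test_that("uncensored IPCW AUC equals the plain pairwise count", {
  set.seed(101)
  n <- 20
  marker <- rnorm(n)
  tt <- rexp(n, exp(marker) / 3)
  res <- ipcw_auc(marker, tt, rep(1L, n), horizon = median(tt))
  cases <- which(tt <= median(tt))
  controls <- which(tt > median(tt))
  pairs <- outer(marker[cases], marker[controls],
                 function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(res$auc, mean(pairs))
  expect_equal(res$n_cases, length(cases))
})

test_that("AUC edge behaviour: perfect marker, constant marker, degenerate split", {
  tt <- c(1, 2, 3, 7, 8, 9)
  st <- rep(1L, 6)
  expect_equal(ipcw_auc(c(10, 9, 8, 1, 2, 3), tt, st, horizon = 5)$auc, 1)
  expect_equal(ipcw_auc(rep(2, 6), tt, st, horizon = 5)$auc, 0.5)
  und <- ipcw_auc(rnorm(6), tt, st, horizon = 20)
  expect_true(und$undefined)
  expect_true(is.na(und$auc))
})

test_that("AUC is rank-invariant and flips under marker negation", {
  set.seed(111)
  n <- 60
  marker <- rnorm(n)
  tt <- rexp(n, exp(marker) / 4)
  cc <- runif(n, 1, 6)
  time <- pmin(tt, cc)
  st <- as.integer(tt <= cc)
  a0 <- ipcw_auc(marker, time, st, horizon = 3)$auc
  a_mono <- ipcw_auc(exp(2 * marker) + 5, time, st, horizon = 3)$auc
  expect_equal(a_mono, a0)
  a_neg <- ipcw_auc(-marker, time, st, horizon = 3)$auc
  expect_equal(a_neg, 1 - a0, tolerance = 1e-12)
})

test_that("a null marker scores near 0.5 on average over replicates", {
  set.seed(121)
  aucs <- replicate(200, {
    n <- 60
    marker <- rnorm(n)
    tt <- rexp(n, 1 / 6)
    cc <- runif(n, 2, 6)
    ipcw_auc(marker, pmin(tt, cc), as.integer(tt <= cc), horizon = 4)$auc
  })
  expect_gt(mean(aucs, na.rm = TRUE), 0.48)
  expect_lt(mean(aucs, na.rm = TRUE), 0.52)
})
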