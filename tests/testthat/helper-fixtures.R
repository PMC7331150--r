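# Shared fixtures and independent oracles used across the test files.

# Small dataset with a real signal in the first group.
toy_dataset <- function(n = 40, p = 8, n_groups = 2, seed = 1,
                        beta = c(-0.8, -0.6, rep(0, p - 2))) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("bm", seq_len(p))))
  tt <- rexp(n, rate = log(2) / 8 * exp(drop(x %*% beta)))
  cc <- runif(n, 2, 6)
  groups <- paste0("g", sort(rep_len(seq_len(n_groups), p)))
  survival_dataset(x, pmin(tt, cc), as.integer(tt <= cc), groups = groups)
}

# Independent partial log-likelihood oracle: survival::coxph at a fixed
# linear predictor supplied as an offset (Breslow ties).
pll_oracle <- function(eta, time, status) {
  fit <- survival::coxph(survival::Surv(time, status) ~ offset(eta),
                         ties = "breslow")
  fit$loglik[1]
}

# Vectorized Breslow partial log-likelihood over many candidate coefficient
# vectors at once (columns of `betas`), written independently of the package
# internals: cumulative risk sums are accumulated row by row.
pll_grid <- function(x, time, status, betas) {
  o <- order(time, decreasing = TRUE)
  xo <- x[o, , drop = FALSE]
  to <- time[o]
  so <- status[o]
  riskend <- ave(seq_along(to), to, FUN = max)
  ev <- which(so == 1)
  eta <- xo %*% betas
  w <- exp(eta)
  for (i in 2:nrow(w)) w[i, ] <- w[i, ] + w[i - 1, ]
  colSums(eta[ev, , drop = FALSE]) - colSums(log(w[riskend[ev], , drop = FALSE]))
}

# Grid-search maximizer of the 1-D partial likelihood.
uni_grid_oracle <- function(x, time, status, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- pll_grid(matrix(x, ncol = 1), time, status, matrix(grid, nrow = 1))
  grid[which.max(ll)]
}

# Grid-search maximizer of the 2-D weighted-penalized objective.
lasso2d_grid_oracle <- function(x, time, status, w, lam,
                                lo = -2, hi = 2, step = 0.005) {
  g <- seq(lo, hi, by = step)
  grid <- as.matrix(expand.grid(b1 = g, b2 = g))
  ll <- pll_grid(x, time, status, t(grid))
  obj <- ll - lam * (w[1] * abs(grid[, 1]) + w[2] * abs(grid[, 2]))
  grid[which.max(obj), ]
}
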