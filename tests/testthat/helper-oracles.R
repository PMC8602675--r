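# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the implementation it checks.

# Least-squares oracle: solves the normal equations of the log-log model via
# an explicit QR decomposition of the design matrix (no lm()).
ols_oracle <- function(outcome, predictors) {
  X <- cbind(1, log(as.matrix(predictors)))
  y <- log(outcome)
  qr_x <- qr(X)
  beta <- solve.qr(qr_x, y)
  resid <- y - X %*% beta
  n <- length(y)
  p <- ncol(X) - 1
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p - 1)
  xtx_inv <- chol2inv(qr.R(qr_x))
  list(beta = as.numeric(beta),
       se = sqrt(diag(xtx_inv) * sigma2),
       r_squared = 1 - rss / tss,
       f = ((tss - rss) / p) / sigma2)
}

# Kruskal-Wallis H via the variance route: H = (N - 1) * SSB / SST computed
# on mid-ranks (tie correction emerges automatically), algebraically distinct
# from the rank-sum formula.
kw_oracle_h <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(values)
  rbar <- mean(r)
  ssb <- sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - rbar)^2))
  sst <- sum((r - rbar)^2)
  (length(values) - 1) * ssb / sst
}

# Spearman's r by brute force over the definition: Pearson product-moment
# formula expanded termwise on mid-ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Small, fast default panel configuration for tests that only need shape,
# not the full 43 x 30 study dimensions.
small_config <- function(seed = 1, ...) {
  synthetic_config(n_countries = 8, years = 2015:2019, seed = seed, ...)
}

all_pollutant_slice <- function(panel, yr) {
  panel[panel$year == yr & panel$cause == "all_cause" &
          panel$pollutant == "all", ]
}
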