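test_that("the four-point toy design is solved exactly", {
  e <- exp(1)
  apm25 <- c(e, e^2, e, e^2)
  hap <- c(1, 1, e, e)
  yll <- c(e, e^2, e, e^2)
  fit <- suppressWarnings(fit_loglog(yll, data.frame(apm25 = apm25, hap = hap)))
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(unname(fit$coef), c(1, 0), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("noiseless synthetic data returns the structural coefficients", {
  cfg <- synthetic_config(seed = 2, noise_sd = 0)
  slice <- all_pollutant_slice(generate_panel(cfg), 2019)
  fit <- suppressWarnings(fit_loglog(slice$yll_rate,
                                     slice[, c("apm25", "hap")]))
  expect_equal(fit$intercept, 2.476, tolerance = 1e-8)
  expect_equal(unname(fit$coef), c(1.623, 0.15), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("coefficients, errors and fit statistics match the QR oracle", {
  cfg <- synthetic_config(seed = 1)
  slice <- all_pollutant_slice(generate_panel(cfg), 2019)
  fit <- fit_loglog(slice$yll_rate, slice[, c("apm25", "hap")])
  oracle <- ols_oracle(slice$yll_rate, slice[, c("apm25", "hap")])
  expect_equal(c(fit$intercept, unname(fit$coef)), oracle$beta,
               tolerance = 1e-8)
  expect_equal(unname(fit$se), oracle$se, tolerance = 1e-8)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  expect_equal(fit$f_stat$value, oracle$f, tolerance = 1e-8)
  expect_equal(fit$f_stat$df_residual, fit$n - 3)
  # residuals orthogonal to every design column
  X <- cbind(1, log(slice$apm25), log(slice$hap))
  rel <- abs(crossprod(X, fit$residuals)) /
    sqrt(colSums(X^2) * sum(fit$residuals^2))
  expect_true(all(rel < 1e-8))
})

test_that("non-positive values and degenerate designs raise errors", {
  expect_error(fit_loglog(c(1, 2, 0, 4), data.frame(x = 1:4, z = 4:1)),
               class = "airburden_domain_error")
  expect_error(fit_loglog(1:4, data.frame(x = c(1, 2, -3, 4), z = 4:1)),
               class = "airburden_domain_error")
  expect_error(
    suppressWarnings(
      fit_loglog(c(1, 2, 3, 4, 5),
                 data.frame(x = c(1, 2, 4, 8, 16), z = c(1, 4, 16, 64, 256)))),
    class = "airburden_singularity_error")
  expect_error(fit_loglog(1:3, data.frame(x = 1:3, z = 3:1)),
               class = "airburden_argument_error")
})

test_that("elasticity converts log-log slopes to percent outcome changes", {
  expect_equal(round_half_up(elasticity(1.623, 0.10), 1), 16.7)
  expect_equal(round_half_up(elasticity(0.15, 0.10), 1), 1.4)
  for (p in c(0.01, 0.1, 0.5)) {
    expect_equal(elasticity(1, p), 100 * p) # unit elasticity is identity
  }
  expect_error(elasticity(1, -1), class = "airburden_argument_error")
})

test_that("spearman matches hand-ranked values and the brute-force oracle", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3)$statistic, -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$statistic, 0.6)
  set.seed(13)
  for (i in 1:10) {
    x <- stats::rnorm(12)
    y <- stats::rnorm(12) + x
    res <- spearman_cor(x, y)
    expect_equal(res$statistic, spearman_oracle(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(res$statistic, unname(ref$estimate), tolerance = 1e-12)
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "airburden_domain_error")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(17)
  x <- stats::rlnorm(15)
  y <- stats::rlnorm(15) * x
  base <- spearman_cor(x, y)$statistic
  expect_equal(spearman_cor(log(x), y)$statistic, base)
  expect_equal(spearman_cor(x, sqrt(y))$statistic, base)
  expect_equal(spearman_cor(exp(x), y^3)$statistic, base)
})

test_that("kruskal-wallis H matches the variance-route oracle, with ties", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(groups)
  expect_equal(kw$statistic, kw_oracle_h(groups), tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_lt(kw$p_value, 0.05)
  # identical groups carry no signal
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(same)$statistic, 0, tolerance = 1e-12)
  # tied data exercise the tie-corrected denominator
  set.seed(5)
  tied <- list(sample(1:4, 8, TRUE), sample(1:4, 7, TRUE),
               sample(1:4, 9, TRUE))
  expect_equal(kruskal_wallis(tied)$statistic, kw_oracle_h(tied),
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:5)), class = "airburden_argument_error")
  expect_error(kruskal_wallis(list(1:5, numeric(0))),
               class = "airburden_argument_error")
})

test_that("two-group kruskal-wallis equals the squared standardised rank sum", {
  set.seed(31)
  g1 <- stats::rnorm(6)
  g2 <- stats::rnorm(7, 1)
  kw <- kruskal_wallis(list(g1, g2))
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  r1 <- sum(rank(c(g1, g2))[seq_len(n1)])
  z <- (r1 - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kw$statistic, z^2, tolerance = 1e-12)
})

test_that("dunn post-hoc produces pairwise z with bonferroni adjustment", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  out <- dunn_posthoc(same)
  expect_equal(out$z, rep(0, 3))
  expect_equal(out$adjusted_p, rep(1, 3))
  # k = 3 yields exactly choose(3, 2) comparisons, adjusted = min(1, 3p)
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- dunn_posthoc(groups)
  expect_equal(nrow(res), 3)
  expect_equal(res$adjusted_p, pmin(1, res$p_value * 3))
  expect_true(all(res$adjusted_p >= res$p_value))
})

test_that("dunn z reduces to the mann-whitney normal statistic for two groups", {
  set.seed(8)
  g1 <- stats::rnorm(5)
  g2 <- stats::rnorm(5, 0.5)
  res <- dunn_posthoc(list(g1, g2))
  u <- sum(outer(g1, g2, ">")) # no ties with continuous draws
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  z_u <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(res$z, z_u, tolerance = 1e-12)
})

test_that("type-I error of the rank test is calibrated at the 5% level", {
  set.seed(2024)
  n_rep <- 400
  rejections <- 0
  for (i in seq_len(n_rep)) {
    groups <- list(stats::rnorm(10), stats::rnorm(10), stats::rnorm(10))
    if (kruskal_wallis(groups)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / n_rep, 0.02)
  expect_lte(rejections / n_rep, 0.08)
})

test_that("a zero-coefficient predictor barely moves explained variance", {
  cfg <- synthetic_config(seed = 12, b2 = 0, noise_sd = 0)
  slice <- all_pollutant_slice(generate_panel(cfg), 2019)
  fit2 <- suppressWarnings(fit_loglog(slice$yll_rate,
                                      slice[, c("apm25", "hap")]))
  fit1 <- suppressWarnings(fit_loglog(slice$yll_rate, slice[, "apm25",
                                                            drop = FALSE]))
  expect_lt(abs(fit2$r_squared - fit1$r_squared), 0.01)
})
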