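test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synthetic_config(n_countries = 2), "n_countries",
               class = "airburden_config_error")
  expect_error(synthetic_config(years = 1990), "years",
               class = "airburden_config_error")
  expect_error(synthetic_config(noise_sd = -0.1), "noise_sd",
               class = "airburden_config_error")
  expect_error(synthetic_config(hap_range = c(0, 10)), "hap_range",
               class = "airburden_config_error")
  expect_error(synthetic_config(exposure_start_range = c(5, 4)),
               "exposure_start_range", class = "airburden_config_error")
})

test_that("same config and seed regenerate an identical panel; seeds differ", {
  cfg <- small_config(seed = 11)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)
  p3 <- generate_panel(small_config(seed = 12))
  expect_false(isTRUE(all.equal(p1$yll_rate, p3$yll_rate)))
})

test_that("adding countries does not perturb the existing ones", {
  p_small <- generate_panel(synthetic_config(n_countries = 6,
                                             years = 2015:2019, seed = 4))
  p_big <- generate_panel(synthetic_config(n_countries = 9,
                                           years = 2015:2019, seed = 4))
  shared <- unique(p_small$country)
  expect_identical(p_small,
                   p_big[p_big$country %in% shared, ])
})

test_that("noiseless panels satisfy the structural identity exactly", {
  cfg <- small_config(seed = 5, noise_sd = 0)
  slice <- all_pollutant_slice(generate_panel(cfg), 2019)
  expect_equal(log(slice$yll_rate),
               cfg$b0 + cfg$b1 * log(slice$apm25) + cfg$b2 * log(slice$hap),
               tolerance = 1e-12)
})

test_that("generated panels satisfy the record invariants across random configs", {
  for (seed in c(2, 7, 19)) {
    cfg <- synthetic_config(n_countries = 5, years = 2010:2014, seed = seed,
                            noise_sd = stats::runif(1, 0, 0.6),
                            annual_decline_pct = stats::runif(1, 0, 4))
    p <- generate_panel(cfg)
    expect_true(all(p$apm25 > 0) && all(p$ozone > 0) && all(p$hap > 0))
    expect_true(all(p$population > 0))
    expect_true(all(p$death_rate >= 0) && all(p$yll_rate >= 0) &&
                  all(p$daly_rate >= 0))
    expect_true(all(p$sdi >= 0 & p$sdi <= 1))
    # cause-specific totals bounded by all-cause within each pollutant tag
    wide <- tidyr::pivot_wider(p[, c("country", "year", "cause", "pollutant",
                                     "deaths_total")],
                               names_from = "cause",
                               values_from = "deaths_total")
    expect_true(all(wide$ihd + wide$stroke + wide$tbl <=
                      wide$all_cause * (1 + 1e-9)))
    # pollutant-specific totals bounded by the "all" pollutant tag
    pw <- tidyr::pivot_wider(p[, c("country", "year", "cause", "pollutant",
                                   "deaths_total")],
                             names_from = "pollutant",
                             values_from = "deaths_total")
    expect_true(all(pw$apm25 + pw$hap + pw$ozone <= pw$all * (1 + 1e-9)))
  }
})

test_that("exposures decline over years on average at the configured rate", {
  cfg <- synthetic_config(seed = 8, annual_decline_pct = 2)
  slice_start <- all_pollutant_slice(generate_panel(cfg), 1990)
  slice_end <- all_pollutant_slice(generate_panel(cfg), 2019)
  implied_annual <- 1 - (mean(slice_end$apm25) / mean(slice_start$apm25))^(1 / 29)
  expect_gt(implied_annual, 0.005)
  expect_lt(implied_annual, 0.04)
  # SDI couples to exposure and GNI the way development gradients do
  expect_lt(cor(slice_end$sdi, slice_end$apm25, method = "spearman"), -0.3)
  expect_gt(cor(slice_end$sdi, slice_end$gni, method = "spearman"), 0.6)
})

test_that("exposure distribution discretisation behaves at the limits", {
  # point-mass limit: vanishing sd concentrates all mass in the mean's bin
  d <- generate_exposure_distribution(20.8, 1e-9, 10, 0, 60)
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
  expect_equal(d$proportion[findInterval(20.8, seq(0, 60, length.out = 11))],
               1, tolerance = 1e-9)
  # single bin carries everything
  d1 <- generate_exposure_distribution(20.8, 6, 1, 0, 60)
  expect_equal(d1$proportion, 1)
  expect_error(generate_exposure_distribution(20.8, -1, 10, 0, 60),
               class = "airburden_argument_error")
  expect_error(generate_exposure_distribution(20.8, 1e-9, 10, 40, 60),
               class = "airburden_argument_error")
})

test_that("binned truncated normal reproduces its own mean", {
  d <- generate_exposure_distribution(20.8, 6, 50, 0, 60)
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
  # numerical integration oracle for the truncated-normal mean
  mu_oracle <- stats::integrate(function(x) x * stats::dnorm(x, 20.8, 6),
                                0, 60)$value /
    stats::integrate(function(x) stats::dnorm(x, 20.8, 6), 0, 60)$value
  expect_lt(abs(sum(d$bin_mid * d$proportion) - mu_oracle), 0.5)
  expect_lt(abs(sum(d$bin_mid * d$proportion) - 20.8), 0.5)
})
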