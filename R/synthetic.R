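#' Configuration for the synthetic country-year panel generator
#'
#' Bundles and validates the parameters of [generate_panel()]. Defaults
#' emulate a European panel of 43 countries observed annually 1990--2019:
#' ambient PM2.5 declining over time, a household-air-pollution (HAP) index
#' spread log-uniformly across countries, and an age-standardised YLL rate
#' generated from the structural log-log relation
#' \deqn{\ln(YLL) = b_0 + b_1 \ln(aPM_{2.5}) + b_2 \ln(HAP) + \varepsilon,
#'   \quad \varepsilon \sim N(0, \sigma^2).}
#' The default coefficients are (2.476, 1.623, 0.15), so downstream fits have
#' a known ground truth.
#'
#' @param n_countries Number of countries (>= 3; medians and group tests need
#'   at least three units). Default 43.
#' @param years Inclusive integer range of years, at least two distinct
#'   values. Default `1990:2019`.
#' @param seed Integer root seed; every random draw flows from it.
#' @param b0,b1,b2 Structural coefficients of the log-log outcome relation
#'   (intercept, ambient-PM2.5 slope, HAP slope).
#' @param noise_sd Standard deviation of the additive noise on the natural-log
#'   outcome scale, >= 0. Default 0.3.
#' @param exposure_start_range Length-2 positive range (min, max) in ug/m3
#'   for first-year ambient PM2.5 across countries.
#' @param annual_decline_pct Mean yearly percentage decline of ambient PM2.5;
#'   countries vary around it multiplicatively.
#' @param hap_range Length-2 positive range of the HAP exposure index;
#'   countries are drawn log-uniformly within it.
#' @param pop_range Length-2 positive range of country populations.
#' @param sdi_range Length-2 range of the socio-demographic index in (0, 1],
#'   spanning the low/medium/high brackets.
#' @param gni_range Length-2 positive range of GNI per capita (US$), spanning
#'   the income brackets.
#' @param cause_shares Named fractions of the all-cause burden assigned to
#'   ischemic heart disease, stroke and tracheal/bronchus/lung cancer.
#'   Defaults (0.446, 0.252, 0.107) mirror the cause composition of air
#'   pollution mortality in Europe.
#' @param pollutant_shares Named fractions of the all-pollutant burden
#'   assigned to ambient PM2.5, household air pollution and ozone; must sum
#'   to at most 1. Defaults (0.904, 0.053, 0.043).
#' @return A validated object of class `synthetic_config`.
#' @seealso [generate_panel()]
#' @export
synthetic_config <- function(n_countries = 43L,
                             years = 1990:2019,
                             seed = 1L,
                             b0 = 2.476, b1 = 1.623, b2 = 0.15,
                             noise_sd = 0.3,
                             exposure_start_range = c(8, 45),
                             annual_decline_pct = 1.5,
                             hap_range = c(2, 200),
                             pop_range = c(3e5, 8e7),
                             sdi_range = c(0.60, 0.95),
                             gni_range = c(3000, 90000),
                             cause_shares = c(ihd = 0.446, stroke = 0.252,
                                              tbl = 0.107),
                             pollutant_shares = c(apm25 = 0.904, hap = 0.053,
                                                  ozone = 0.043)) {
  bad <- function(field, why) {
    ab_stop(sprintf("Invalid synthetic_config: `%s` %s.", field, why),
            "airburden_config_error", field = field)
  }
  if (!is.numeric(n_countries) || length(n_countries) != 1 || n_countries < 3) {
    bad("n_countries", "must be a single integer >= 3")
  }
  years <- sort(unique(as.integer(years)))
  if (length(years) < 2) bad("years", "must span at least 2 distinct years")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    bad("seed", "must be a single integer")
  }
  for (nm in c("b0", "b1", "b2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      bad(nm, "must be a single finite number")
    }
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    bad("noise_sd", "must be >= 0")
  }
  rngs <- list(exposure_start_range = exposure_start_range,
               hap_range = hap_range, pop_range = pop_range,
               sdi_range = sdi_range, gni_range = gni_range)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (!is.numeric(r) || length(r) != 2 || r[1] <= 0 || r[1] >= r[2]) {
      bad(nm, "must be (min, max) with 0 < min < max")
    }
  }
  if (!is.numeric(annual_decline_pct) || length(annual_decline_pct) != 1 ||
      annual_decline_pct < 0 || annual_decline_pct >= 100) {
    bad("annual_decline_pct", "must be in [0, 100)")
  }
  if (any(cause_shares < 0) || sum(cause_shares) > 1) {
    bad("cause_shares", "must be non-negative and sum to at most 1")
  }
  if (any(pollutant_shares < 0) || sum(pollutant_shares) > 1 + 1e-9) {
    bad("pollutant_shares", "must be non-negative and sum to at most 1")
  }
  structure(list(n_countries = as.integer(n_countries), years = years,
                 seed = as.integer(seed), b0 = b0, b1 = b1, b2 = b2,
                 noise_sd = noise_sd,
                 exposure_start_range = as.numeric(exposure_start_range),
                 annual_decline_pct = annual_decline_pct,
                 hap_range = as.numeric(hap_range),
                 pop_range = as.numeric(pop_range),
                 sdi_range = as.numeric(sdi_range),
                 gni_range = as.numeric(gni_range),
                 cause_shares = cause_shares,
                 pollutant_shares = pollutant_shares),
            class = "synthetic_config")
}

# Minimal save/restore of the global RNG state (base R only).
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic GBD-like country-year panel
#'
#' Simulates a tidy panel of exposures, outcomes and socio-economic covariates
#' with known ground truth, one row per (country, year, cause, pollutant).
#'
#' Per-country attributes (SDI, GNI, baseline exposure, decline rate, HAP,
#' population) and all of that country's year-level noise are drawn from a
#' substream seeded deterministically from `(seed, country index)`, so panels
#' are bit-reproducible and adding countries does not perturb existing ones.
#' SDI is drawn uniformly; GNI increases monotonically with SDI (with
#' log-normal jitter), and baseline ambient PM2.5 decreases with SDI, so
#' lower-development countries carry systematically higher exposure and
#' burden. Exposures decline multiplicatively at `annual_decline_pct` per
#' year on average with log-normal country-level variation. The
#' age-standardised all-cause YLL rate attributable to air pollution follows
#' the structural log-log relation in [synthetic_config()]; DALY and death
#' rates are fixed multiples of it (DALY/YLL = 1.12, YLL per death = 21,
#' in line with the relative magnitudes of published European medians).
#' Cause- and pollutant-specific rows are fixed configurable fractions of the
#' all-cause, all-pollutant row, so shares have known truth.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `country`, `year`, `cause`
#'   (`all_cause`, `ihd`, `stroke`, `tbl`), `pollutant`
#'   (`all`, `apm25`, `hap`, `ozone`), `apm25` (ug/m3), `ozone` (ppb),
#'   `hap` (index), `population`, `sdi`, `gni` (US$),
#'   `deaths_total`, `yll_total`, `daly_total`,
#'   `death_rate`, `yll_rate`, `daly_rate` (per 100,000).
#' @examples
#' cfg <- synthetic_config(n_countries = 5, years = 2015:2019, seed = 42)
#' panel <- generate_panel(cfg)
#' dplyr::filter(panel, cause == "all_cause", pollutant == "all", year == 2019)
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    ab_stop("`config` must be a synthetic_config.", "airburden_config_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  set.seed(config$seed)
  subs <- sample.int(.Machine$integer.max - 1L, config$n_countries,
                     replace = TRUE)

  years <- config$years
  n_years <- length(years)
  t <- years - years[1]
  sdi_lo <- config$sdi_range[1]; sdi_hi <- config$sdi_range[2]
  exp_lo <- config$exposure_start_range[1]
  exp_hi <- config$exposure_start_range[2]

  one_country <- function(i) {
    set.seed(subs[i])
    sdi <- stats::runif(1, sdi_lo, sdi_hi)
    dev <- (sdi - sdi_lo) / (sdi_hi - sdi_lo)   # 0 = least developed
    gni <- exp(log(config$gni_range[1]) +
                 dev * log(config$gni_range[2] / config$gni_range[1]) +
                 stats::rnorm(1, 0, 0.15))
    gni <- min(max(gni, config$gni_range[1]), config$gni_range[2])
    # baseline exposure decreases with development, jittered but kept in range
    u <- min(max((1 - dev) + stats::rnorm(1, 0, 0.12), 0), 1)
    apm25_start <- exp(log(exp_lo) + u * log(exp_hi / exp_lo))
    # country-level multiplicative annual decline with log-normal jitter
    jit <- min(max(exp(stats::rnorm(1, 0, 0.3)), 0.2), 3)
    decline <- config$annual_decline_pct / 100 * jit
    apm25 <- apm25_start * (1 - decline)^t *
      exp(stats::rnorm(n_years, 0, 0.02))
    hap <- exp(stats::runif(1, log(config$hap_range[1]),
                            log(config$hap_range[2])))
    ozone <- stats::runif(1, 38, 50) * (1 - 0.0023)^t *
      exp(stats::rnorm(n_years, 0, 0.01))
    population <- exp(stats::runif(1, log(config$pop_range[1]),
                                   log(config$pop_range[2])))
    eps <- stats::rnorm(n_years, 0, config$noise_sd)
    yll_rate <- exp(config$b0 + config$b1 * log(apm25) +
                      config$b2 * log(hap) + eps)
    tibble::tibble(
      country = sprintf("country_%02d", i),
      year = years,
      apm25 = apm25, ozone = ozone, hap = hap,
      population = population, sdi = sdi, gni = gni,
      yll_rate = yll_rate,
      daly_rate = 1.12 * yll_rate,
      death_rate = yll_rate / 21
    )
  }

  core <- dplyr::bind_rows(lapply(seq_len(config$n_countries), one_country))

  shares <- tidyr::expand_grid(
    cause = c("all_cause", names(config$cause_shares)),
    pollutant = c("all", names(config$pollutant_shares))
  )
  cs <- c(all_cause = 1, config$cause_shares)
  ps <- c(all = 1, config$pollutant_shares)
  shares$share <- unname(cs[shares$cause]) * unname(ps[shares$pollutant])

  panel <- tidyr::crossing(core, shares) |>
    dplyr::mutate(
      death_rate = .data$death_rate * .data$share,
      yll_rate = .data$yll_rate * .data$share,
      daly_rate = .data$daly_rate * .data$share,
      deaths_total = .data$death_rate * .data$population / 1e5,
      yll_total = .data$yll_rate * .data$population / 1e5,
      daly_total = .data$daly_rate * .data$population / 1e5
    ) |>
    dplyr::select("country", "year", "cause", "pollutant", "apm25", "ozone",
                  "hap", "population", "sdi", "gni", "deaths_total",
                  "yll_total", "daly_total", "death_rate", "yll_rate",
                  "daly_rate") |>
    dplyr::arrange(.data$country, .data$year, .data$cause, .data$pollutant)
  panel
}

#' Binned truncated-normal exposure distribution
#'
#' Discretises a normal exposure distribution truncated to `[lower, upper]`
#' into `n_bins` equal-width bins, assigning each bin's truncated-normal
#' probability mass to its midpoint. Useful as the exposure input to
#' [compute_paf()].
#'
#' @param mean,sd Mean and standard deviation of the underlying normal
#'   (exposure units, both > 0).
#' @param n_bins Number of bins, >= 1.
#' @param lower,upper Support bounds, `lower < upper`.
#' @return An [exposure_distribution()] whose proportions sum to 1.
#' @examples
#' d <- generate_exposure_distribution(20.8, 6, 50, 0, 60)
#' sum(d$proportion)  # 1
#' @export
generate_exposure_distribution <- function(mean, sd, n_bins, lower, upper) {
  assert_scalar_number(mean, "mean")
  assert_scalar_number(sd, "sd")
  if (mean <= 0 || sd <= 0) {
    ab_stop("`mean` and `sd` must be > 0.", "airburden_argument_error")
  }
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 1) {
    ab_stop("`n_bins` must be an integer >= 1.", "airburden_argument_error")
  }
  if (lower >= upper) {
    ab_stop("`lower` must be < `upper`.", "airburden_argument_error")
  }
  edges <- seq(lower, upper, length.out = n_bins + 1)
  mass <- diff(stats::pnorm(edges, mean, sd))
  total <- sum(mass)
  if (total <= 0) {
    ab_stop("Support [lower, upper] carries no probability mass.",
            "airburden_argument_error")
  }
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  prop <- mass / total
  # guard against floating-point drift so the distribution invariant holds
  prop <- prop / sum(prop)
  exposure_distribution(mid, prop)
}
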