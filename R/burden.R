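#' Binned exposure distribution
#'
#' Represents the population distribution of exposure to an air pollutant as
#' bin midpoints with the fraction of the population in each bin. This is the
#' discrete form of the continuous exposure distribution that enters the
#' population attributable fraction.
#'
#' @param bin_mid Numeric vector of exposure values (midpoints, e.g. ug/m3),
#'   strictly increasing and non-negative.
#' @param proportion Numeric vector of population fractions per bin,
#'   non-negative and summing to 1 (within 1e-9).
#' @return An object of class `exposure_distribution`.
#' @seealso [compute_paf()], [generate_exposure_distribution()]
#' @export
exposure_distribution <- function(bin_mid, proportion) {
  if (length(bin_mid) == 0L || length(bin_mid) != length(proportion)) {
    ab_stop("`bin_mid` and `proportion` must be non-empty and equal length.",
            "airburden_argument_error")
  }
  if (any(!is.finite(bin_mid)) || any(!is.finite(proportion))) {
    ab_stop("Exposure bins and proportions must be finite.",
            "airburden_argument_error")
  }
  if (any(bin_mid < 0) || is.unsorted(bin_mid, strictly = TRUE)) {
    ab_stop("`bin_mid` must be non-negative and strictly increasing.",
            "airburden_argument_error")
  }
  if (any(proportion < 0) || abs(sum(proportion) - 1) > 1e-9) {
    ab_stop("`proportion` must be non-negative and sum to 1 (within 1e-9).",
            "airburden_argument_error")
  }
  structure(list(bin_mid = as.numeric(bin_mid),
                 proportion = as.numeric(proportion)),
            class = "exposure_distribution")
}

#' Relative-risk curve with a theoretical minimum risk exposure level
#'
#' A piecewise-linear relative-risk function defined by knots, together with
#' the theoretical minimum risk exposure level (TMREL) at which relative risk
#' is normalised to 1. Between knots the curve is linearly interpolated;
#' beyond the end knots it is extended flat; below the TMREL exposure carries
#' no excess risk (RR = 1).
#'
#' @param knot_exposure Numeric vector of exposures at the knots, strictly
#'   increasing.
#' @param knot_rr Positive relative risk at each knot (any positive scaling;
#'   the curve is renormalised so that RR(TMREL) = 1).
#' @param tmrel Theoretical minimum risk exposure level (same units as
#'   `knot_exposure`).
#' @return An object of class `rr_curve`.
#' @seealso [compute_paf()]
#' @export
rr_curve <- function(knot_exposure, knot_rr, tmrel) {
  if (length(knot_exposure) == 0L || length(knot_exposure) != length(knot_rr)) {
    ab_stop("`knot_exposure` and `knot_rr` must be non-empty and equal length.",
            "airburden_argument_error")
  }
  if (any(!is.finite(knot_rr)) || any(knot_rr <= 0)) {
    ab_stop("`knot_rr` must be finite and > 0 everywhere.",
            "airburden_domain_error")
  }
  if (length(knot_exposure) > 1L && is.unsorted(knot_exposure, strictly = TRUE)) {
    ab_stop("`knot_exposure` must be strictly increasing.",
            "airburden_argument_error")
  }
  assert_scalar_number(tmrel, "tmrel")
  structure(list(knot_exposure = as.numeric(knot_exposure),
                 knot_rr = as.numeric(knot_rr),
                 tmrel = as.numeric(tmrel)),
            class = "rr_curve")
}

# Evaluate the normalised RR of a curve at exposures x: linear interpolation
# between knots, flat extrapolation beyond them, RR divided by RR(tmrel),
# and RR = 1 for exposure below the TMREL.
rr_at <- function(rr, x) {
  raw <- if (length(rr$knot_exposure) == 1L) {
    rep(rr$knot_rr, length(x))
  } else {
    stats::approx(rr$knot_exposure, rr$knot_rr, xout = x, rule = 2)$y
  }
  at_tmrel <- if (length(rr$knot_exposure) == 1L) {
    rr$knot_rr
  } else {
    stats::approx(rr$knot_exposure, rr$knot_rr, xout = rr$tmrel, rule = 2)$y
  }
  out <- raw / at_tmrel
  out[x < rr$tmrel] <- 1
  out
}

#' Population attributable fraction from binned exposure and relative risk
#'
#' Computes the PAF for a continuous risk factor from a binned exposure
#' distribution and a relative-risk curve:
#' \deqn{PAF = \frac{\sum_i p_i RR_i - 1}{\sum_i p_i RR_i}}
#' where \eqn{p_i} is the population fraction in bin \eqn{i} and \eqn{RR_i}
#' the relative risk at its midpoint, normalised so that RR equals 1 at the
#' theoretical minimum risk exposure level (TMREL). Exposure below the TMREL
#' contributes RR = 1. When RR >= 1 everywhere the result lies in [0, 1).
#'
#' @param dist An [exposure_distribution()].
#' @param rr An [rr_curve()].
#' @return The PAF as a single numeric fraction.
#' @examples
#' d <- exposure_distribution(c(5, 10), c(0.5, 0.5))
#' curve <- rr_curve(c(0, 5, 10), c(1, 1, 3), tmrel = 0)
#' compute_paf(d, curve) # (0.5*1 + 0.5*3 - 1) / (0.5*1 + 0.5*3) = 0.5
#' @export
compute_paf <- function(dist, rr) {
  if (!inherits(dist, "exposure_distribution")) {
    ab_stop("`dist` must be an exposure_distribution.", "airburden_argument_error")
  }
  if (!inherits(rr, "rr_curve")) {
    ab_stop("`rr` must be an rr_curve.", "airburden_argument_error")
  }
  rri <- rr_at(rr, dist$bin_mid)
  if (any(!is.finite(rri))) {
    ab_stop("Relative risk is non-finite at one or more bin midpoints.",
            "airburden_domain_error")
  }
  s <- sum(dist$proportion * rri)
  (s - 1) / s
}

#' Attributable burden from a PAF and an outcome total
#'
#' Multiplies the population attributable fraction by a total outcome count
#' (deaths, YLL or DALY) to obtain the burden attributable to the exposure.
#' The result is unrounded. A negative PAF (possible when RR < 1 over part of
#' the exposure range) yields a negative, i.e. protective, burden and raises
#' a warning so it is never silent.
#'
#' @param paf Population attributable fraction, < 1.
#' @param total_outcome Total outcome count, >= 0.
#' @return `paf * total_outcome`.
#' @export
attributable_burden <- function(paf, total_outcome) {
  assert_scalar_number(paf, "paf")
  assert_scalar_number(total_outcome, "total_outcome")
  if (paf >= 1) {
    ab_stop("`paf` must be < 1.", "airburden_argument_error")
  }
  if (total_outcome < 0) {
    ab_stop("`total_outcome` must be >= 0.", "airburden_argument_error")
  }
  if (paf < 0) {
    warning("Negative PAF: attributable burden is negative (protective exposure).",
            call. = FALSE)
  }
  paf * total_outcome
}

#' Rate per 100,000 population
#'
#' @param count Outcome count.
#' @param population Population at risk, > 0.
#' @return `100000 * count / population`.
#' @examples
#' rate_per_100k(368006, 742e6) # 49.60 per 100,000
#' @export
rate_per_100k <- function(count, population) {
  if (!is.numeric(count) || !is.numeric(population)) {
    ab_stop("`count` and `population` must be numeric.", "airburden_argument_error")
  }
  if (any(population <= 0)) {
    ab_stop("`population` must be > 0.", "airburden_argument_error")
  }
  100000 * count / population
}

#' Standard population weights for direct age-standardisation
#'
#' @param age_band Character labels of the age bands.
#' @param weight Non-negative weights summing to 1 (within 1e-9).
#' @return An object of class `standard_population`.
#' @export
standard_population <- function(age_band, weight) {
  if (length(age_band) == 0L || length(age_band) != length(weight)) {
    ab_stop("`age_band` and `weight` must be non-empty and equal length.",
            "airburden_argument_error")
  }
  if (anyDuplicated(age_band)) {
    ab_stop("`age_band` labels must be unique.", "airburden_argument_error")
  }
  if (any(weight < 0) || abs(sum(weight) - 1) > 1e-9) {
    ab_stop("`weight` must be non-negative and sum to 1 (within 1e-9).",
            "airburden_argument_error")
  }
  structure(list(age_band = as.character(age_band), weight = as.numeric(weight)),
            class = "standard_population")
}

#' Directly age-standardised rate
#'
#' Weights age-specific rates by a fixed standard population's age
#' distribution, so rates are comparable across countries with different age
#' structures.
#'
#' @param age_rates Named numeric vector of per-100,000 rates; names are age
#'   bands and must match the standard population's bands exactly.
#' @param std A [standard_population()].
#' @return The standardised per-100,000 rate, `sum(weight * rate)`.
#' @export
age_standardise <- function(age_rates, std) {
  if (!inherits(std, "standard_population")) {
    ab_stop("`std` must be a standard_population.", "airburden_argument_error")
  }
  if (is.null(names(age_rates)) || !identical(sort(names(age_rates)),
                                              sort(std$age_band))) {
    ab_stop("Age bands of `age_rates` must match the standard population exactly.",
            "airburden_argument_error")
  }
  sum(std$weight * age_rates[std$age_band])
}

#' Percent change relative to a reference value
#'
#' Returns `100 * (v_ref - v_new) / v_ref`. The sign convention is that a
#' **decrease** from the reference is **positive**, matching the usual
#' epidemiological phrasing "an X% decrease compared to the reference year".
#'
#' @param v_ref Reference (earlier) value, non-zero.
#' @param v_new New (later) value.
#' @return Percent change (positive = decrease).
#' @examples
#' percent_change(20.8, 13.8) # 33.65..., i.e. a 33.7% decrease
#' @export
percent_change <- function(v_ref, v_new) {
  if (!is.numeric(v_ref) || !is.numeric(v_new)) {
    ab_stop("`v_ref` and `v_new` must be numeric.", "airburden_argument_error")
  }
  if (any(v_ref == 0)) {
    ab_stop("`v_ref` must be non-zero.", "airburden_domain_error")
  }
  100 * (v_ref - v_new) / v_ref
}

#' Share of a part in a total, as a percentage
#'
#' @param part Part count, >= 0.
#' @param total Total count, > 0.
#' @return `100 * part / total`.
#' @examples
#' share_of_total(164.3, 368.0) # 44.6% of deaths from ischemic heart disease
#' @export
share_of_total <- function(part, total) {
  if (!is.numeric(part) || !is.numeric(total)) {
    ab_stop("`part` and `total` must be numeric.", "airburden_argument_error")
  }
  if (any(total <= 0)) {
    ab_stop("`total` must be > 0.", "airburden_argument_error")
  }
  if (any(part < 0)) {
    ab_stop("`part` must be >= 0.", "airburden_argument_error")
  }
  100 * part / total
}
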