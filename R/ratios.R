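#' Median of a set of positive reference values
#'
#' The reference value against which each country's metric is compared: the
#' middle order statistic for odd n, the mean of the two middle order
#' statistics for even n (the usual sample median).
#'
#' @param values Non-empty numeric vector.
#' @return The median.
#' @export
reference_median <- function(values) {
  if (length(values) == 0L || !is.numeric(values)) {
    ab_stop("`values` must be a non-empty numeric vector.",
            "airburden_argument_error")
  }
  stats::median(values)
}

#' Ratio of a country's value to the all-country median
#'
#' The building block of the median-relative ratio statistics: a country's
#' DALY rate ratio (DARR), PM2.5 ratio (PMR), YLL rate ratio (YRR) or death
#' rate ratio (DRR) for a year is its metric divided by the median of that
#' metric over **all** countries in the same year (the country is included
#' in its own reference median).
#'
#' @param country_value The country's metric value.
#' @param all_values Metric values of all countries (including this one),
#'   all > 0.
#' @return `country_value / reference_median(all_values)`, unitless.
#' @examples
#' ratio_to_median(8, c(2, 4, 8)) # 2
#' @export
ratio_to_median <- function(country_value, all_values) {
  assert_scalar_number(country_value, "country_value")
  if (any(!is.finite(all_values)) || any(all_values <= 0)) {
    ab_stop("`all_values` must all be finite and > 0.", "airburden_domain_error")
  }
  m <- reference_median(all_values)
  if (m == 0) {
    ab_stop("Reference median is zero.", "airburden_domain_error")
  }
  country_value / m
}

#' Change in a median-relative ratio between two anchor years
#'
#' Returns `(ratio_start - ratio_end) / ratio_start`. A **positive** change
#' means the country reduced its metric at least to the extent of the
#' all-country median reduction between the two years; a negative change
#' means it fell behind the median trend even if its own metric improved.
#'
#' @param ratio_start Ratio at the first anchor year, non-zero.
#' @param ratio_end Ratio at the second anchor year.
#' @return Change as a unitless fraction (multiply by 100 for percent).
#' @examples
#' ratio_change(2, 1)    #  0.5  (+50%, outpaced the median)
#' ratio_change(1, 2.46) # -1.46 (-146%, fell far behind)
#' @export
ratio_change <- function(ratio_start, ratio_end) {
  if (!is.numeric(ratio_start) || !is.numeric(ratio_end)) {
    ab_stop("Ratios must be numeric.", "airburden_argument_error")
  }
  if (any(ratio_start == 0)) {
    ab_stop("`ratio_start` must be non-zero.", "airburden_domain_error")
  }
  (ratio_start - ratio_end) / ratio_start
}

#' Classify a ratio change as positive, neutral or negative
#'
#' @param change Ratio change fraction(s) from [ratio_change()].
#' @param tolerance Half-width of the neutral band: `|change| <= tolerance`
#'   is classified `neutral`. The default 5e-3 treats changes that print as
#'   0.0% (one decimal of percent) as neutral.
#' @return Factor with levels `positive`, `neutral`, `negative`.
#' @export
classify_change <- function(change, tolerance = 5e-3) {
  if (tolerance < 0) {
    ab_stop("`tolerance` must be >= 0.", "airburden_argument_error")
  }
  cls <- ifelse(abs(change) <= tolerance, "neutral",
                ifelse(change > 0, "positive", "negative"))
  factor(cls, levels = c("positive", "neutral", "negative"))
}

#' Median-relative ratios and their change for every country in a panel
#'
#' For each country, computes the ratio of its metric to the all-country
#' median at two anchor years, the relative change of that ratio, and a
#' positive / neutral / negative classification. With `metric = "daly_rate"`
#' this yields the DALY rate ratio (DARR) and DARR change; `"apm25"` the
#' PM2.5 ratio (PMR); `"yll_rate"` the YLL rate ratio (YRR); `"death_rate"`
#' the death rate ratio (DRR).
#'
#' @param panel A tidy panel as produced by [generate_panel()] or
#'   [read_panel()].
#' @param metric One of `"daly_rate"`, `"apm25"`, `"yll_rate"`,
#'   `"death_rate"`.
#' @param year_start,year_end The two anchor years (both present for every
#'   country).
#' @param tolerance Neutral band for [classify_change()].
#' @param cause,pollutant Which panel slice feeds the metric; defaults
#'   `"all_cause"` / `"all"` give the air-pollution-attributable all-cause
#'   rates. Ignored for exposure metrics (`apm25`), which do not vary by
#'   cause or pollutant tag.
#' @return A tibble with one row per country: `country`, `metric`,
#'   `ratio_start`, `ratio_end`, `change` (fraction), `change_pct`, and
#'   `classification`.
#' @examples
#' panel <- generate_panel(synthetic_config(n_countries = 5, seed = 1))
#' classify_panel(panel, "daly_rate", 1990, 2019)
#' @export
classify_panel <- function(panel, metric = c("daly_rate", "apm25", "yll_rate",
                                             "death_rate"),
                           year_start, year_end, tolerance = 5e-3,
                           cause = "all_cause", pollutant = "all") {
  metric <- match.arg(metric)
  assert_scalar_number(year_start, "year_start")
  assert_scalar_number(year_end, "year_end")
  required <- c("country", "year", "cause", "pollutant", metric)
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    ab_stop(paste0("Panel is missing columns: ",
                   paste(missing_cols, collapse = ", ")),
            "airburden_schema_error")
  }
  slice <- panel |>
    dplyr::filter(.data$cause == !!cause, .data$pollutant == !!pollutant,
                  .data$year %in% c(year_start, year_end)) |>
    dplyr::distinct(.data$country, .data$year,
                    value = .data[[metric]])

  have_both <- slice |>
    dplyr::count(.data$country) |>
    dplyr::filter(.data$n < 2)
  if (nrow(have_both) > 0) {
    ab_stop(paste0("Countries missing an anchor year: ",
                   paste(have_both$country, collapse = ", ")),
            "airburden_data_error")
  }
  if (any(slice$value <= 0)) {
    ab_stop("Metric must be positive for all countries in both anchor years.",
            "airburden_domain_error")
  }

  wide <- slice |>
    tidyr::pivot_wider(names_from = "year", values_from = "value",
                       names_prefix = "y")
  v_start <- wide[[paste0("y", year_start)]]
  v_end <- wide[[paste0("y", year_end)]]
  ratio_start <- v_start / reference_median(v_start)
  ratio_end <- v_end / reference_median(v_end)
  change <- ratio_change(ratio_start, ratio_end)
  tibble::tibble(
    country = wide$country,
    metric = metric,
    ratio_start = ratio_start,
    ratio_end = ratio_end,
    change = change,
    change_pct = 100 * change,
    classification = classify_change(change, tolerance)
  )
}
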