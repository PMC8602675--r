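#' Bracket schemes for SDI and GNI grouping
#'
#' A group scheme is an ordered set of labelled, disjoint, half-open numeric
#' brackets `[lower, upper)` (the terminal bracket is closed above) covering
#' the admissible value range.
#'
#' `sdi_scheme()` groups countries by socio-demographic index:
#' low `[0, 0.750)`, medium `[0.750, 0.850)`, high `[0.850, 1]`. The printed
#' convention "low < 0.749, medium 0.750-0.849, high > 0.850" leaves the gaps
#' (0.749, 0.750) and (0.849, 0.850) unassigned; the half-open form closes
#' them so every value in [0, 1] lands in exactly one bracket.
#'
#' `gni_scheme()` groups by GNI per capita (US$, Atlas method). The World
#' Bank lower-middle and upper-middle income groups are merged into one
#' bracket `[1036, 12536)`, and the high-income group (> $12,536) is split
#' into lower high `[12536, 36767)`, moderate high `[36767, 60998)` and very
#' high (>= $60,998, i.e. the printed "> $60,997") for finer resolution where
#' most European countries sit. Values below $1,036 (World Bank low income)
#' are outside coverage.
#'
#' @param labels Character bracket labels, unique, ordered by lower bound.
#' @param lower,upper Numeric bracket bounds; `lower` inclusive, `upper`
#'   exclusive except for the terminal bracket.
#' @param scheme Tag naming the variable the scheme applies to
#'   (`"sdi"`, `"gni"`, or any custom tag).
#' @return An object of class `group_scheme`: a tibble of brackets with a
#'   `scheme` attribute.
#' @examples
#' assign_group(0.8, sdi_scheme())   # "medium"
#' assign_group(40000, gni_scheme()) # "moderate high income"
#' @export
group_scheme <- function(labels, lower, upper, scheme = "custom") {
  if (length(labels) == 0 || anyDuplicated(labels) ||
      length(labels) != length(lower) || length(labels) != length(upper)) {
    ab_stop("`labels`, `lower`, `upper` must be equal-length with unique labels.",
            "airburden_argument_error")
  }
  o <- order(lower)
  labels <- labels[o]; lower <- lower[o]; upper <- upper[o]
  if (any(lower >= upper)) {
    ab_stop("Every bracket needs `lower < upper`.", "airburden_argument_error")
  }
  if (length(lower) > 1 && any(abs(upper[-length(upper)] - lower[-1]) > 1e-12)) {
    ab_stop("Brackets must be contiguous (each upper equals the next lower).",
            "airburden_argument_error")
  }
  structure(tibble::tibble(label = as.character(labels),
                           lower = as.numeric(lower),
                           upper = as.numeric(upper)),
            scheme = scheme,
            class = c("group_scheme", "tbl_df", "tbl", "data.frame"))
}

#' @rdname group_scheme
#' @export
sdi_scheme <- function() {
  group_scheme(c("low", "medium", "high"),
               lower = c(0, 0.750, 0.850),
               upper = c(0.750, 0.850, 1),
               scheme = "sdi")
}

#' @rdname group_scheme
#' @export
gni_scheme <- function() {
  group_scheme(c("middle income", "lower high income",
                 "moderate high income", "very high income"),
               lower = c(1036, 12536, 36767, 60998),
               upper = c(12536, 36767, 60998, Inf),
               scheme = "gni")
}

#' Assign values to a bracket of a group scheme
#'
#' @param value Numeric vector of SDI or GNI values; `NA` values stay `NA`
#'   (callers decide whether to exclude them, see [group_summary()]).
#' @param scheme A [group_scheme()].
#' @return Factor of bracket labels, ordered by bracket lower bound.
#' @export
assign_group <- function(value, scheme) {
  if (!inherits(scheme, "group_scheme")) {
    ab_stop("`scheme` must be a group_scheme.", "airburden_argument_error")
  }
  ok <- !is.na(value)
  out_of_range <- ok & (value < scheme$lower[1] |
                          value > scheme$upper[nrow(scheme)])
  if (any(out_of_range)) {
    ab_stop(sprintf("Value(s) outside scheme coverage [%g, %g]: %s",
                    scheme$lower[1], scheme$upper[nrow(scheme)],
                    paste(utils::head(value[out_of_range], 5), collapse = ", ")),
            "airburden_domain_error")
  }
  idx <- findInterval(value, c(scheme$lower, scheme$upper[nrow(scheme)]),
                      rightmost.closed = TRUE)
  factor(scheme$label[idx], levels = scheme$label)
}

# Tukey median-of-halves quartiles, exclusive of the median for odd n:
# {1,2,3,4,5} -> q1 = median(1,2) = 1.5, q3 = median(4,5) = 4.5.
quartiles_tukey <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 2) return(c(q1 = NA_real_, q3 = NA_real_))
  half <- floor(n / 2)
  c(q1 = stats::median(x[seq_len(half)]),
    q3 = stats::median(x[seq.int(n - half + 1, n)]))
}

#' Per-bracket median and interquartile summaries of a panel measure
#'
#' Assigns each country in one panel year to a bracket of `scheme` and
#' summarises the chosen measure per bracket as n, median and interquartile
#' range. Countries whose grouping variable is missing (e.g. countries with
#' no published GNI) are excluded from the summaries and listed in the
#' `excluded` attribute, never dropped silently. Empty brackets are reported
#' with `n = 0` and `NA` summaries. The ratio of the lowest bracket's median
#' to the highest non-empty bracket's median (a "fold" disparity measure) is
#' attached as attribute `fold_ratio`.
#'
#' @param panel A tidy panel (see [generate_panel()]).
#' @param scheme A [group_scheme()] whose tag (`"sdi"` or `"gni"`) names the
#'   panel column to group on.
#' @param measure Panel column to summarise (default `"daly_rate"`).
#' @param year Panel year to use.
#' @param cause,pollutant Panel slice (defaults `"ihd"`, `"all"`).
#' @param quartile_rule `"tukey"` (median-of-halves, exclusive; default) or
#'   `"quantile7"` (R's default type-7 quantiles).
#' @return A tibble with one row per bracket: `bracket`, `n`, `median`,
#'   `q1`, `q3`; attributes `excluded` (countries with missing grouping
#'   values) and `fold_ratio`.
#' @examples
#' panel <- generate_panel(synthetic_config(seed = 1))
#' group_summary(panel, sdi_scheme(), measure = "daly_rate", year = 2019)
#' @export
group_summary <- function(panel, scheme, measure = "daly_rate", year,
                          cause = "ihd", pollutant = "all",
                          quartile_rule = c("tukey", "quantile7")) {
  quartile_rule <- match.arg(quartile_rule)
  if (!inherits(scheme, "group_scheme")) {
    ab_stop("`scheme` must be a group_scheme.", "airburden_argument_error")
  }
  by_col <- attr(scheme, "scheme")
  required <- c("country", "year", "cause", "pollutant", by_col, measure)
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    ab_stop(paste0("Panel is missing columns: ",
                   paste(missing_cols, collapse = ", ")),
            "airburden_schema_error")
  }
  slice <- panel |>
    dplyr::filter(.data$year == !!year, .data$cause == !!cause,
                  .data$pollutant == !!pollutant) |>
    dplyr::distinct(.data$country, key = .data[[by_col]],
                    value = .data[[measure]])
  excluded <- slice$country[is.na(slice$key)]
  kept <- slice[!is.na(slice$key), ]
  kept$bracket <- assign_group(kept$key, scheme)

  summarise_one <- function(v) {
    if (length(v) == 0) {
      return(tibble::tibble(n = 0L, median = NA_real_,
                            q1 = NA_real_, q3 = NA_real_))
    }
    q <- if (quartile_rule == "tukey") quartiles_tukey(v) else {
      stats::setNames(stats::quantile(v, c(0.25, 0.75), names = FALSE),
                      c("q1", "q3"))
    }
    tibble::tibble(n = length(v), median = stats::median(v),
                   q1 = unname(q["q1"]), q3 = unname(q["q3"]))
  }
  out <- dplyr::bind_rows(lapply(scheme$label, function(lb) {
    dplyr::bind_cols(tibble::tibble(bracket = lb),
                     summarise_one(kept$value[kept$bracket == lb]))
  }))
  out$bracket <- factor(out$bracket, levels = scheme$label)
  non_empty <- out[out$n > 0, ]
  fold <- if (nrow(non_empty) >= 2) {
    non_empty$median[1] / non_empty$median[nrow(non_empty)]
  } else NA_real_
  attr(out, "excluded") <- excluded
  attr(out, "fold_ratio") <- fold
  attr(out, "measure") <- measure
  out
}
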