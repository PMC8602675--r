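panel_columns <- c("country", "year", "cause", "pollutant", "apm25", "ozone",
                   "hap", "population", "sdi", "gni", "deaths_total",
                   "yll_total", "daly_total", "death_rate", "yll_rate",
                   "daly_rate")

#' Write a country-year panel to CSV
#'
#' Tidy layout: one row per (country, year, cause, pollutant); UTF-8, comma
#' separated, "." decimal, header row, full numeric precision.
#'
#' @param panel Panel tibble with the columns of [generate_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  missing_cols <- setdiff(panel_columns, names(panel))
  if (length(missing_cols) > 0) {
    ab_stop(paste0("Panel is missing columns: ",
                   paste(missing_cols, collapse = ", ")),
            "airburden_schema_error")
  }
  readr::write_csv(panel[panel_columns], path)
  invisible(path)
}

# Row-level invariant checks shared by read_panel; returns a character vector
# of violation messages tagged with CSV line numbers (header = line 1).
panel_violations <- function(panel) {
  msgs <- character(0)
  line <- seq_len(nrow(panel)) + 1L
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      msgs <<- c(msgs, sprintf("line %d: %s", line[idx], what))
    }
  }
  bad(!is.finite(panel$population) | panel$population <= 0,
      "population must be > 0")
  for (col in c("apm25", "ozone", "hap")) {
    bad(!is.finite(panel[[col]]) | panel[[col]] <= 0,
        paste(col, "must be > 0"))
  }
  for (col in c("death_rate", "yll_rate", "daly_rate")) {
    bad(!is.finite(panel[[col]]) | panel[[col]] < 0,
        paste(col, "must be >= 0"))
  }
  tol <- 1e-6
  totals <- panel |>
    dplyr::filter(.data$cause == "all_cause") |>
    dplyr::select("country", "year", "pollutant",
                  all_cause_deaths = "deaths_total")
  joined <- panel |>
    dplyr::mutate(.line = line) |>
    dplyr::filter(.data$cause != "all_cause") |>
    dplyr::left_join(totals, by = c("country", "year", "pollutant"))
  over <- !is.na(joined$all_cause_deaths) &
    joined$deaths_total > joined$all_cause_deaths * (1 + tol)
  if (any(over)) {
    msgs <- c(msgs, sprintf("line %d: cause-specific deaths exceed all-cause",
                            joined$.line[over]))
  }
  ptotals <- panel |>
    dplyr::filter(.data$pollutant == "all") |>
    dplyr::select("country", "year", "cause", all_poll_deaths = "deaths_total")
  pjoined <- panel |>
    dplyr::mutate(.line = line) |>
    dplyr::filter(.data$pollutant != "all") |>
    dplyr::left_join(ptotals, by = c("country", "year", "cause"))
  pover <- !is.na(pjoined$all_poll_deaths) &
    pjoined$deaths_total > pjoined$all_poll_deaths * (1 + tol)
  if (any(pover)) {
    msgs <- c(msgs,
              sprintf("line %d: pollutant-specific deaths exceed 'all' total",
                      pjoined$.line[pover]))
  }
  msgs
}

#' Read a country-year panel from CSV with invariant enforcement
#'
#' Reads a tidy panel written by [write_panel()] (or exported by hand in the
#' same layout), checks the schema and row-level invariants (positive
#' exposures and population, non-negative rates, cause- and
#' pollutant-specific totals bounded by their "all" rows) and fails with
#' line-numbered messages on any violation unless `skip_invalid = TRUE`, in
#' which case offending rows are dropped with a warning.
#'
#' @param path CSV file path.
#' @param skip_invalid Drop invalid rows instead of failing.
#' @return A panel tibble.
#' @export
read_panel <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) {
    ab_stop(sprintf("File not found: %s", path), "airburden_argument_error")
  }
  panel <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                             country = readr::col_character(),
                             year = readr::col_integer(),
                             cause = readr::col_character(),
                             pollutant = readr::col_character(),
                             .default = readr::col_double()
                           )))
  missing_cols <- setdiff(panel_columns, names(panel))
  if (length(missing_cols) > 0) {
    ab_stop(paste0("Panel file is missing required columns: ",
                   paste(missing_cols, collapse = ", ")),
            "airburden_schema_error")
  }
  probs <- readr::problems(panel)
  if (nrow(probs) > 0) {
    ab_stop(paste0("Unparseable values at rows: ",
                   paste(utils::head(probs$row, 10), collapse = ", ")),
            "airburden_parse_error")
  }
  panel <- tibble::as_tibble(panel[panel_columns])
  msgs <- panel_violations(panel)
  if (length(msgs) > 0) {
    if (!skip_invalid) {
      ab_stop(paste0("Panel invariant violations:\n",
                     paste(utils::head(msgs, 20), collapse = "\n")),
              "airburden_data_error")
    }
    bad_lines <- unique(as.integer(sub("^line (\\d+):.*$", "\\1", msgs)))
    warning(sprintf("Dropping %d invalid row(s).", length(bad_lines)),
            call. = FALSE)
    panel <- panel[-(bad_lines - 1L), , drop = FALSE]
  }
  panel
}

#' Read a generator or pipeline configuration from JSON or YAML
#'
#' Keys must be arguments of [synthetic_config()]; unknown keys are
#' rejected so typos never pass silently.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A validated [synthetic_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    ab_stop(sprintf("File not found: %s", path), "airburden_argument_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    ab_stop("Config must be .json, .yaml or .yml.", "airburden_argument_error")
  )
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    ab_stop(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")),
            "airburden_config_error")
  }
  for (nm in c("cause_shares", "pollutant_shares")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(synthetic_config, raw)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Orchestrates the pipeline end to end on a panel (read from
#' `panel_path`, or generated synthetically when omitted): median-relative
#' ratios and classification for the DALY rate and ambient PM2.5, the
#' log-log regression of YLL rate on (aPM2.5, HAP) in the final anchor year
#' with elasticities, Kruskal-Wallis/Dunn comparisons of the IHD, stroke and
#' TBL cancer DALY rates across SDI and GNI brackets, and a plain-text
#' summary of the headline quantities. Outputs are deterministic given the
#' inputs and seed; timestamps are confined to the manifest.
#'
#' @param out_dir Output directory (created if needed). Files written:
#'   `ratios_daly_rate.csv`, `ratios_apm25.csv`, `fit.json`,
#'   `group_comparisons.csv`, `summary.txt`, `manifest.json`.
#' @param panel_path Optional panel CSV; when `NULL` a synthetic panel is
#'   generated from `config`.
#' @param config A [synthetic_config()] used when `panel_path` is `NULL`
#'   (default: package defaults with `seed`).
#' @param seed Root seed for synthetic generation.
#' @param year_start,year_end Anchor years.
#' @param verbose Print stage-by-stage log lines.
#' @return Invisibly, a list with the ratios tibbles, fit, group
#'   comparison tibble and summary lines.
#' @export
run_report <- function(out_dir, panel_path = NULL, config = NULL,
                       seed = 1L, year_start = 1990L, year_end = 2019L,
                       verbose = FALSE) {
  if (year_start >= year_end) {
    ab_stop("`year_start` must be < `year_end`.", "airburden_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, msg) {
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }

  if (is.null(panel_path)) {
    if (is.null(config)) config <- synthetic_config(seed = seed)
    say("simulate", sprintf("generating synthetic panel (seed %d)", config$seed))
    panel <- generate_panel(config)
    input_id <- sprintf("synthetic(seed=%d)", config$seed)
  } else {
    say("read", panel_path)
    panel <- read_panel(panel_path)
    input_id <- unname(tools::md5sum(panel_path))
  }

  ratios_daly <- classify_panel(panel, "daly_rate", year_start, year_end)
  ratios_apm <- classify_panel(panel, "apm25", year_start, year_end)
  readr::write_csv(ratios_daly, file.path(out_dir, "ratios_daly_rate.csv"))
  readr::write_csv(ratios_apm, file.path(out_dir, "ratios_apm25.csv"))
  say("ratios", "wrote ratio classifications")

  slice <- panel |>
    dplyr::filter(.data$year == year_end, .data$cause == "all_cause",
                  .data$pollutant == "all")
  fit <- fit_loglog(slice$yll_rate, slice[, c("apm25", "hap")])
  el <- vapply(fit$coef, elasticity, numeric(1), pct_increase = 0.10)
  fit_out <- c(unclass(fit)[c("intercept", "coef", "se", "r_squared",
                              "f_stat", "p_values", "p_overall", "n",
                              "model_string")],
               list(elasticity_10pct = as.list(el)))
  jsonlite::write_json(fit_out, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("regress", fit$model_string)

  comp <- list()
  for (scheme in list(sdi_scheme(), gni_scheme())) {
    tag <- attr(scheme, "scheme")
    for (cs in c("ihd", "stroke", "tbl")) {
      gs <- group_summary(panel, scheme, measure = "daly_rate",
                          year = year_end, cause = cs)
      slice_y <- panel |>
        dplyr::filter(.data$year == year_end, .data$cause == cs,
                      .data$pollutant == "all") |>
        dplyr::distinct(.data$country, key = .data[[tag]],
                        value = .data$daly_rate) |>
        dplyr::filter(!is.na(.data$key))
      groups <- split(slice_y$value, assign_group(slice_y$key, scheme))
      groups <- groups[lengths(groups) > 0]
      if (length(groups) >= 2) {
        kw <- kruskal_wallis(groups)
        comp[[length(comp) + 1]] <- tibble::tibble(
          scheme = tag, cause = cs, measure = "daly_rate",
          k = length(groups), h = kw$statistic, df = kw$df,
          p_value = kw$p_value, fold_ratio = attr(gs, "fold_ratio"),
          n_excluded = length(attr(gs, "excluded"))
        )
      }
    }
  }
  comp <- dplyr::bind_rows(comp)
  readr::write_csv(comp, file.path(out_dir, "group_comparisons.csv"))
  say("compare-groups", sprintf("%d comparisons", nrow(comp)))

  counts <- table(ratios_daly$classification)
  pm_counts <- table(ratios_apm$classification)
  end_tot <- panel |>
    dplyr::filter(.data$year == year_end, .data$pollutant == "all")
  all_deaths <- sum(end_tot$deaths_total[end_tot$cause == "all_cause"])
  cause_share <- vapply(c("ihd", "stroke", "tbl"), function(cs) {
    share_of_total(sum(end_tot$deaths_total[end_tot$cause == cs]), all_deaths)
  }, numeric(1))
  apm_deaths <- panel |>
    dplyr::filter(.data$year == year_end, .data$cause == "all_cause",
                  .data$pollutant == "apm25")
  apm_share <- share_of_total(sum(apm_deaths$deaths_total), all_deaths)

  summary_lines <- c(
    sprintf("Panel: %d countries, %d-%d (%s)",
            dplyr::n_distinct(panel$country), year_start, year_end, input_id),
    sprintf("DALY rate ratio change %d-%d: %d positive, %d neutral, %d negative",
            year_start, year_end, counts[["positive"]], counts[["neutral"]],
            counts[["negative"]]),
    sprintf("PM2.5 ratio change %d-%d: %d positive, %d neutral, %d negative",
            year_start, year_end, pm_counts[["positive"]],
            pm_counts[["neutral"]], pm_counts[["negative"]]),
    sprintf("Cause shares of deaths in %d: IHD %.1f%%, stroke %.1f%%, TBL %.1f%%",
            year_end, cause_share[["ihd"]], cause_share[["stroke"]],
            cause_share[["tbl"]]),
    sprintf("Share of deaths associated with ambient PM2.5: %.1f%%", apm_share),
    sprintf("Fitted model: %s", fit$model_string),
    sprintf("Elasticity: +10%% aPM2.5 -> +%.1f%% YLL; +10%% HAP -> +%.1f%% YLL",
            el[["apm25"]], el[["hap"]])
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  manifest <- list(
    package = "airburden",
    version = as.character(utils::packageVersion("airburden")),
    seed = seed,
    input = input_id,
    anchor_years = c(year_start, year_end),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("report", out_dir)
  invisible(list(ratios_daly = ratios_daly, ratios_apm25 = ratios_apm,
                 fit = fit, elasticity_10pct = el, comparisons = comp,
                 summary = summary_lines))
}
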