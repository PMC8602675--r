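#' Log-log multiple regression with elasticity-type coefficients
#'
#' Fits ordinary least squares on natural-log-transformed outcome and
#' predictors,
#' \deqn{\ln(y) = b_0 + b_1 \ln(x_1) + \dots + b_p \ln(x_p) + \varepsilon,}
#' the form used to relate an age-standardised YLL rate to ambient PM2.5 and
#' household air pollution. Slopes are elasticity-type coefficients: a
#' fraction `p` increase in a predictor multiplies the outcome by
#' `(1 + p)^b` (see [elasticity()]).
#'
#' All values must be strictly positive; zeros or negatives raise an error
#' rather than being silently offset -- filter or correct such records
#' explicitly before fitting.
#'
#' @param outcome Positive numeric outcome vector (e.g. YLL rate per
#'   100,000).
#' @param predictors Data frame (or named list) of positive numeric predictor
#'   vectors, e.g. `data.frame(apm25 = ..., hap = ...)`.
#' @return An object of class `loglog_fit`: a list with `intercept`, `coef`
#'   (named slopes), `se` (standard errors, intercept first), `r_squared`,
#'   `f_stat` (list: `value`, `df_model`, `df_residual`), `p_values` (named,
#'   per coefficient), `p_overall` (F-test), `n`, and `model_string`.
#' @examples
#' cfg <- synthetic_config(noise_sd = 0, seed = 7)
#' panel <- generate_panel(cfg)
#' slice <- dplyr::filter(panel, year == 2019, cause == "all_cause",
#'                        pollutant == "all")
#' fit <- fit_loglog(slice$yll_rate, slice[, c("apm25", "hap")])
#' fit$coef  # recovers (1.623, 0.150) exactly on noiseless data
#' @export
fit_loglog <- function(outcome, predictors) {
  predictors <- as.data.frame(predictors)
  if (ncol(predictors) < 1) {
    ab_stop("`predictors` must contain at least one variable.",
            "airburden_argument_error")
  }
  if (any(!vapply(predictors, is.numeric, logical(1))) || !is.numeric(outcome)) {
    ab_stop("Outcome and predictors must be numeric.",
            "airburden_argument_error")
  }
  if (nrow(predictors) != length(outcome)) {
    ab_stop("Outcome and predictors must have the same length.",
            "airburden_argument_error")
  }
  if (any(outcome <= 0) || any(as.matrix(predictors) <= 0)) {
    ab_stop(paste("All outcome and predictor values must be > 0 for the",
                  "log-log model; remove or correct non-positive records",
                  "before fitting."),
            "airburden_domain_error")
  }
  p <- ncol(predictors)
  n <- length(outcome)
  if (n <= p + 1) {
    ab_stop("Need more observations than predictors + 1.",
            "airburden_argument_error")
  }
  dat <- as.data.frame(lapply(predictors, log))
  dat$.y <- log(outcome)
  fit <- stats::lm(.y ~ ., data = dat)
  if (fit$rank < p + 1) {
    ab_stop("Design matrix is rank-deficient (collinear predictors).",
            "airburden_singularity_error")
  }
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  fstat <- sm$fstatistic
  p_overall <- if (is.null(fstat)) NA_real_ else {
    stats::pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
              lower.tail = FALSE)
  }
  slopes <- coefs[-1]
  names(slopes) <- names(predictors)
  model_string <- paste0(
    "log(y) = ", format(coefs[[1]], digits = 4), " + ",
    paste(sprintf("%s x log(%s)", format(slopes, digits = 4), names(slopes)),
          collapse = " + "))
  structure(list(
    intercept = unname(coefs[1]),
    coef = slopes,
    se = stats::setNames(sm$coefficients[, "Std. Error"],
                         c("(Intercept)", names(slopes))),
    r_squared = sm$r.squared,
    f_stat = list(value = unname(fstat[["value"]]),
                  df_model = unname(fstat[["numdf"]]),
                  df_residual = unname(fstat[["dendf"]])),
    p_values = stats::setNames(sm$coefficients[, "Pr(>|t|)"],
                               c("(Intercept)", names(slopes))),
    p_overall = unname(p_overall),
    n = n,
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    model_string = model_string
  ), class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat("Log-log regression fit\n")
  cat("  ", x$model_string, "\n", sep = "")
  cat(sprintf("  n = %d, R-squared = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
              x$n, x$r_squared, x$f_stat$df_model, x$f_stat$df_residual,
              x$f_stat$value, x$p_overall))
  invisible(x)
}

#' Elasticity interpretation of a log-log slope
#'
#' In a log-log model with slope `coef`, a relative increase `pct_increase`
#' in the predictor multiplies the outcome by `(1 + pct_increase)^coef`.
#' This helper returns the implied percent change in the outcome,
#' `100 * ((1 + pct_increase)^coef - 1)`.
#'
#' @param coef Slope from the log-log model.
#' @param pct_increase Relative increase in the predictor as a fraction
#'   (`0.10` = +10%), > -1.
#' @return Percent change in the outcome.
#' @examples
#' elasticity(1.623, 0.10) # 16.7: +10% PM2.5 -> +16.7% YLL
#' elasticity(0.150, 0.10) #  1.4: +10% HAP   ->  +1.4% YLL
#' @export
elasticity <- function(coef, pct_increase) {
  if (!is.numeric(coef) || !is.numeric(pct_increase)) {
    ab_stop("`coef` and `pct_increase` must be numeric.",
            "airburden_argument_error")
  }
  if (any(pct_increase <= -1)) {
    ab_stop("`pct_increase` must be > -1.", "airburden_argument_error")
  }
  100 * ((1 + pct_increase)^coef - 1)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), with a
#' two-sided p-value from the t-approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `test_result` list: `statistic` (r), `n`, `p_value`, `method`.
#' @examples
#' spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$statistic # 0.6
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    ab_stop("`x` and `y` must have equal length >= 3.",
            "airburden_argument_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    ab_stop("Correlation is undefined for a constant vector.",
            "airburden_domain_error")
  }
  r <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(statistic = r, n = n, p_value = p,
                 method = "spearman"),
            class = "test_result")
}

# Tie-corrected Kruskal-Wallis H for pooled values and group labels.
# Classic rank-sum form: H = [12/(N(N+1)) * sum R_j^2/n_j - 3(N+1)] / C
# with tie correction C = 1 - sum(t^3 - t)/(N^3 - N).
kw_statistic <- function(values, g) {
  r <- rank(values)
  n <- tabulate(g)
  N <- length(values)
  rs <- tapply(r, g, sum)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / n) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) return(NaN)
  h / corr
}

#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric comparison of two or more groups by ranks, with the
#' standard tie correction; the p-value uses the chi-square approximation on
#' k - 1 degrees of freedom (the large-sample reference). For total n <= 10
#' an exact permutation p-value is available via `exact = TRUE`, computed by
#' full enumeration of the group assignments.
#'
#' @param groups List of >= 2 non-empty numeric vectors (total n >= 5 for the
#'   chi-square approximation; smaller totals are allowed with
#'   `exact = TRUE`).
#' @param exact If `TRUE`, also compute the exact permutation p-value
#'   (only for total n <= 10; enumeration grows factorially).
#' @return A `test_result` list: `statistic` (H), `df`, `group_sizes`,
#'   `p_value` (chi-square), `p_exact` (permutation, or `NA`), `method`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2) {
    ab_stop("`groups` must be a list of at least 2 groups.",
            "airburden_argument_error")
  }
  if (any(lengths(groups) == 0)) {
    ab_stop("Every group must be non-empty.", "airburden_argument_error")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  N <- length(values)
  if (N < 5 && !exact) {
    ab_stop("Total n must be >= 5 for the chi-square approximation.",
            "airburden_argument_error")
  }
  kt <- stats::kruskal.test(values, g)
  h <- unname(kt$statistic)
  p_exact <- NA_real_
  if (exact) {
    if (N > 10) {
      ab_stop("Exact permutation p-value is only supported for total n <= 10.",
              "airburden_argument_error")
    }
    perm_h <- permutation_statistics(values, lengths(groups),
                                     function(v, gg) kw_statistic(v, gg))
    p_exact <- mean(perm_h >= h - 1e-12)
  }
  structure(list(statistic = h, df = unname(kt$parameter),
                 group_sizes = lengths(groups),
                 p_value = unname(kt$p.value), p_exact = p_exact,
                 method = "kruskal_wallis"),
            class = "test_result")
}

# Enumerate all distinct assignments of pooled values to groups of the given
# sizes and evaluate `stat(values, group_factor)` for each. Used as the
# exact small-sample reference for the rank tests.
permutation_statistics <- function(values, sizes, stat) {
  N <- length(values)
  k <- length(sizes)
  out <- list()
  recurse <- function(remaining_idx, gi, assignment) {
    if (gi > k) {
      g <- factor(assignment, levels = seq_len(k))
      out[[length(out) + 1]] <<- stat(values, g)
      return(invisible(NULL))
    }
    if (gi == k) {
      assignment[remaining_idx] <- k
      recurse(integer(0), k + 1L, assignment)
      return(invisible(NULL))
    }
    combos <- utils::combn(remaining_idx, sizes[gi], simplify = FALSE)
    for (idx in combos) {
      a <- assignment
      a[idx] <- gi
      recurse(setdiff(remaining_idx, idx), gi + 1L, a)
    }
    invisible(NULL)
  }
  recurse(seq_len(N), 1L, integer(N))
  unlist(out)
}

#' Dunn's post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie-corrected pooled
#' variance,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_s (t_s^3 - t_s)}{12(N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' with two-sided normal p-values. Bonferroni adjustment multiplies each
#' p-value by the number of pairwise comparisons actually performed,
#' k(k-1)/2, capped at 1.
#'
#' @inheritParams kruskal_wallis
#' @param exact If `TRUE` (total n <= 10), adds an exact permutation
#'   p-value per pair based on the permutation distribution of |z|.
#' @return A tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `adjusted_p`, and `p_exact` (NA unless `exact`).
#' @export
dunn_posthoc <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2) {
    ab_stop("`groups` must be a list of at least 2 groups.",
            "airburden_argument_error")
  }
  if (any(lengths(groups) == 0)) {
    ab_stop("Every group must be non-empty.", "airburden_argument_error")
  }
  values <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  k <- length(groups)
  N <- length(values)
  m <- k * (k - 1) / 2

  dunn_z <- function(v, g) {
    r <- rank(v)
    mean_ranks <- tapply(r, g, mean)
    n <- tabulate(g)
    ties <- table(v)
    sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
    pairs <- utils::combn(seq_len(k), 2)
    z <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      se <- sqrt(sigma2 * (1 / n[i1] + 1 / n[i2]))
      z[j] <- (mean_ranks[i1] - mean_ranks[i2]) / se
    }
    z
  }

  g <- factor(rep(seq_len(k), sizes))
  z <- dunn_z(values, g)
  pairs <- utils::combn(seq_len(k), 2)
  p <- 2 * stats::pnorm(-abs(z))
  p_exact <- rep(NA_real_, length(z))
  if (exact) {
    if (N > 10) {
      ab_stop("Exact permutation p-values are only supported for total n <= 10.",
              "airburden_argument_error")
    }
    perm_z <- permutation_statistics(values, sizes, dunn_z)
    perm_z <- matrix(perm_z, ncol = m, byrow = TRUE)
    for (j in seq_along(z)) {
      p_exact[j] <- mean(abs(perm_z[, j]) >= abs(z[j]) - 1e-12)
    }
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  tibble::tibble(
    group1 = nm[pairs[1, ]],
    group2 = nm[pairs[2, ]],
    z = z,
    p_value = p,
    adjusted_p = pmin(1, p * m),
    p_exact = p_exact
  )
}
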