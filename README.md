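# airburden

Tools for quantifying the health burden attributable to air pollution across
country-year panels, aimed at environmental epidemiologists and burden-of-disease
analysts working with GBD-style extracts (exposures, deaths, YLL, DALYs, SDI,
GNI per country and year).

## What it computes

**Attributable burden.** For a binned exposure distribution with population
fractions *pᵢ* and a relative-risk curve normalised to 1 at the theoretical
minimum risk exposure level (TMREL),

    PAF = (Σᵢ pᵢ·RRᵢ − 1) / (Σᵢ pᵢ·RRᵢ)

and the attributable count is PAF × total outcome. Helpers convert counts to
per-100,000 rates, directly age-standardise rates, and compute percent changes
(decrease-positive convention) and shares of a total.

**Median-relative ratio statistics.** For a metric *m* (DALY rate, ambient
PM2.5, YLL rate or death rate), a country's ratio in year *t* is

    R_t = m_t(country) / median[m_t(all countries)]

and its change between two anchor years is (R_start − R_end) / R_start. A
positive change means the country reduced its metric at least to the extent of
the all-country median reduction; countries are classified
positive / neutral / negative with a configurable neutral band. These are the
DALY rate ratio (DARR), PM2.5 ratio (PMR), YLL rate ratio (YRR) and death rate
ratio (DRR).

**Association and group comparison.** OLS on natural logs,
ln(YLL) = b₀ + b₁·ln(aPM2.5) + b₂·ln(HAP) + ε, with elasticity
interpretation 100·((1+p)^b − 1); Spearman rank correlation
(t-approximation); Kruskal–Wallis by ranks with tie correction; Dunn's
post-hoc pairwise z tests with Bonferroni adjustment; SDI and GNI bracket
assignment with per-bracket median/IQR summaries and fold ratios.

**Synthetic panels.** `generate_panel()` simulates a GBD-like panel (default
43 countries × 1990–2019) whose YLL rate follows the log-log relation above
with known coefficients (default b = 2.476, 1.623, 0.15), declining exposures,
and development gradients (SDI coupled to GNI and inversely to exposure), so
every downstream stage can be tested against known ground truth.

## Worked example

```r
library(airburden)

panel <- generate_panel(synthetic_config(seed = 1))

# each country's DALY-rate progress relative to the all-country median
ratios <- classify_panel(panel, "daly_rate", 1990, 2019)
table(ratios$classification)
#> positive  neutral negative
#>       19        0       24

# log-log regression of YLL rate on exposures in the final year
slice <- subset(panel, year == 2019 & cause == "all_cause" & pollutant == "all")
fit <- fit_loglog(slice$yll_rate, slice[, c("apm25", "hap")])
fit
#> Log-log regression fit
#>   log(y) = 2.195 + 1.7313 x log(apm25) + 0.1704 x log(hap)
#>   n = 43, R-squared = 0.906, F(2, 40) = 191.921, p = 3.14e-21
elasticity(fit$coef[["apm25"]], 0.10)  # % YLL increase for +10% PM2.5
#> [1] 17.94

# burden arithmetic
compute_paf(exposure_distribution(c(5, 10), c(0.5, 0.5)),
            rr_curve(c(0, 5, 10), c(1, 1, 3), tmrel = 0))
#> [1] 0.5

# disparity by development bracket
gs <- group_summary(panel, sdi_scheme(), measure = "daly_rate",
                    year = 2019, cause = "ihd")
attr(gs, "fold_ratio")   # low-SDI median / high-SDI median
#> [1] 6.34
```

The fitted slopes (1.73, 0.17) sit within sampling error of the generating
coefficients (1.623, 0.15) at the default noise level; with `noise_sd = 0`
they are recovered to machine precision and the +10% PM2.5 elasticity prints
as 16.7%.

A command-line wrapper with `simulate`, `ratios`, `regress`,
`compare-groups` and `report` subcommands is installed under
`inst/cli/airburden.R`; `run_report()` drives the same pipeline from R and
writes a report bundle (ratio CSVs, fit JSON, group comparisons, summary,
manifest).

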