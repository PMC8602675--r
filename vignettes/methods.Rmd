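---
title: "Methods: attributable burden, median-relative ratios and the log-log exposure model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributable burden, median-relative ratios and the log-log exposure model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airburden)
```

## The problem

Ambient fine particulate matter (aPM2.5), household air pollution from solid
fuels (HAP) and ozone drive a large share of cardiovascular and respiratory
mortality. Comparative risk assessment expresses this as burden *attributable*
to exposure: the fraction of deaths, years of life lost (YLL) or
disability-adjusted life years (DALY) that would not occur if everyone were
exposed at the theoretical minimum risk exposure level (TMREL). Beyond levels
and trends, policy questions are often *relative*: did a country reduce its
burden at least as fast as its region? This package implements the full chain
— PAF, attributable counts and rates, median-relative ratio statistics,
an exposure–outcome regression with elasticity interpretation, and
nonparametric comparisons across development brackets — on tidy country-year
panels.

## Attributable burden

For a binned exposure distribution with population fractions $p_i$ at
exposures $x_i$ and a relative-risk curve $RR(\cdot)$,

$$\mathrm{PAF} = \frac{\sum_i p_i RR(x_i) - 1}{\sum_i p_i RR(x_i)},$$

with $RR$ normalised so that $RR(\mathrm{TMREL}) = 1$. This is the standard
discrete form of the continuous-risk PAF. Choices a user should know about:

* **Curve evaluation.** Linear interpolation between knots, flat extrapolation
  beyond the end knots, and $RR = 1$ below the TMREL (exposure below the
  minimum-risk level carries no excess risk). Normalisation divides the whole
  curve by $RR(\mathrm{TMREL})$, which makes the PAF invariant to any positive
  rescaling of the curve — a property the tests exercise directly.
* **TMREL as a point.** Published comparative-risk pipelines often draw the
  TMREL from a distribution; here it is a point value, keeping the PAF a
  closed-form, exactly testable function. Averaging over several TMREL values
  can be emulated by averaging PAFs.
* **No uncertainty intervals.** Draw-level uncertainty propagation is a
  feature of the upstream estimation machinery, not of this package; outputs
  are point estimates.

Attributable counts are `PAF × total outcome` (unrounded; a negative PAF from
a protective exposure warns rather than failing), rates are
`1e5 × count / population`, and age-standardisation is the direct method:
$\sum_a w_a r_a$ with fixed standard-population weights $w_a$.

`percent_change(v_ref, v_new)` returns `100 × (v_ref − v_new)/v_ref`,
**positive for decreases**. Burden reporting overwhelmingly phrases temporal
results as "an X% decrease"; making that the positive direction keeps printed
tables and computed values aligned. For comparisons against numbers printed to
fixed precision, `round_half_up()` provides round-half-away-from-zero, since
base R's banker's rounding disagrees on exact halves.

## Median-relative ratio statistics

For metric $m$ and year $t$, a country's ratio is
$R_t = m_t(\text{country}) / \mathrm{median}_t(\text{all countries})$, and its
change between anchor years is $(R_{start} - R_{end})/R_{start}$. Applied to
the DALY rate this is the DALY rate ratio (DARR); to aPM2.5 the PM2.5 ratio
(PMR); to YLL and death rates the YRR and DRR. A positive change means the
country's own relative reduction exceeded the median's relative reduction —
an algebraic identity the property tests verify — so the statistic measures
progress *relative to the field*, not absolute improvement: a country can
improve its own rate and still classify negative.

Decisions:

* **The country counts in its own median.** The reference is the median of
  *all* countries, giving every country the identical reference and a
  well-defined median at any panel size.
* **Neutral band.** Changes are classified neutral when
  $|\mathrm{change}| \le$ 5×10⁻³ (default, configurable). Ratio changes are
  conventionally reported to one decimal of percent; the band makes "prints
  as 0.0%" the operational meaning of neutral, so equal ratios at both
  anchors classify neutral under floating-point arithmetic.
* **Fractions internally, percent at the surface.** `change` is a fraction;
  `change_pct` and reports render percent.
* **Metric choice.** The DARR uses the age-standardised all-cause DALY rate
  attributable to air pollution (cause `all_cause`, pollutant `all` in the
  panel layout); the selector is configurable.

## The log-log exposure model and elasticities

`fit_loglog()` fits $\ln y = b_0 + \sum_j b_j \ln x_j + \varepsilon$ by OLS
(natural logs throughout). Slopes are elasticity-type coefficients: a
fraction $p$ increase in $x_j$ multiplies the outcome by $(1+p)^{b_j}$, so
the implied outcome change is $100((1+p)^{b_j}-1)$ percent. With the default
generator coefficients $b_1 = 1.623$ and $b_2 = 0.15$, a 10% exposure
increase implies +16.7% YLL for aPM2.5 and +1.4% for HAP — closed forms the
acceptance tests check analytically.

Non-positive outcomes or predictors are an error, never silently offset:
log-scale fits on shifted data estimate a different model, so the caller must
filter explicitly. The fit reports coefficients, standard errors, $R^2$, the
overall F statistic with its degrees of freedom and p-values; tests verify it
against an independent QR solution of the normal equations, residual
orthogonality to the design, and exact recovery on noiseless synthetic data.

A related design property: a predictor whose true coefficient is zero
changes $R^2$ negligibly when dropped. This motivates fitting the
two-predictor model (aPM2.5, HAP) and treating a non-informative third
exposure as excluded — the package asserts the property on synthetic data
rather than hard-coding any exclusion.

## Rank-based tests

* **Spearman** is the Pearson correlation of mid-ranks (average ranks on
  ties) with a two-sided p-value from the t-approximation on $n-2$ degrees
  of freedom.
* **Kruskal–Wallis** uses the classic tie-corrected H with a chi-square
  reference on $k-1$ degrees of freedom. The implementation delegates to
  `stats::kruskal.test`; the test suite validates it against an
  algebraically distinct variance-route formula, and against the identity
  $H = z^2$ with the normalised rank-sum statistic in the two-group case.
* **Dunn's post-hoc** pairwise z statistics use mean ranks with the
  tie-corrected pooled variance and two-sided normal p-values; Bonferroni
  multiplies by the $k(k-1)/2$ comparisons actually performed, capped at 1.
  No installed package provides this test, so it is implemented here.
* **Exact small-sample references.** For total $n \le 10$ both tests can
  compute exact permutation p-values by full enumeration of group
  assignments (`exact = TRUE`). These serve as oracles: the statistic must
  match exactly; the chi-square/normal approximations are expected to track
  the exact p only to small-sample accuracy (the suite uses a 0.1 absolute
  band, the typical size of the discreteness gap at these n).

## Development brackets

SDI brackets are low $[0, 0.750)$, medium $[0.750, 0.850)$, high
$[0.850, 1]$. Printed conventions of the form "low < 0.749, medium
0.750–0.849, high > 0.850" leave the gaps $(0.749, 0.750)$ and
$(0.849, 0.850)$ unassigned; half-open intervals close them so brackets
partition the range — a deliberate, documented divergence. GNI brackets
merge the World Bank lower-middle and upper-middle groups into one
($[1036, 12536)$, reflecting how few European countries fall there) and
split high income into lower $[12536, 36767)$, moderate $[36767, 60998)$
and very high ($\ge 60998$). Values below \$1,036 are outside coverage and
error. Records with missing GNI are excluded from GNI analyses and reported
in an exclusion list, never dropped silently.

Quartiles default to Tukey's median-of-halves, *exclusive* of the median for
odd n (so $\{1,2,3,4,5\}$ gives IQR $(1.5, 4.5)$); type-7 quantiles are
available since published tables rarely state their IQR convention. Each
summary carries a fold ratio (lowest bracket median / highest bracket
median), a scale-invariant disparity measure.

## The synthetic generator

`generate_panel()` emulates the statistical structure of a GBD-style
European extract, with defaults chosen once as the study conditions:

* 43 countries × 1990–2019, structural coefficients (2.476, 1.623, 0.15),
  log-normal outcome noise `noise_sd = 0.3` — a noise level at which the
  cross-sectional fit attains $R^2 \approx 0.9$, matching the strength of
  association typical of national exposure–burden data.
* First-year aPM2.5 spread log-uniformly over 8–45 µg/m³ and declining
  multiplicatively at 1.5%/year on average with log-normal country jitter
  (a ~35% median decline over 29 years, the magnitude seen in Europe);
  multiplicative decline keeps exposures positive by construction.
* HAP treated as a positive continuous index drawn log-uniformly over
  2–200 per country: published sources report HAP as a population exposure
  measure without common units, and the regression needs only positivity
  and spread. HAP is constant within country, so its slope is identified
  cross-sectionally.
* SDI uniform on 0.60–0.95 (spanning all three brackets); GNI increases
  monotonically with SDI with log-normal jitter (rank correlation ≈ 0.9),
  and baseline exposure decreases with SDI — so low-development brackets
  carry higher burden by construction, giving the group comparisons a known
  direction.
* Ozone near 44 ppb declining ~6% over the period; it does not enter the
  outcome relation.
* DALY and death rates are fixed multiples of the YLL rate (DALY/YLL = 1.12,
  YLL per death = 21, consistent with the relative magnitudes of published
  European medians); cause shares (IHD 0.446, stroke 0.252, TBL 0.107) and
  pollutant shares (aPM2.5 0.904, HAP 0.053, ozone 0.043) are fixed
  configurable fractions, so shares computed downstream have known truth.

**Randomness contract.** One root seed; per-country substreams are derived
from it by a sequential draw, so the same seed is bit-reproducible and
adding countries never perturbs existing ones. All generator state is local
(the caller's RNG state is saved and restored).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no gridded exposure modelling or
population-weighting within countries, no age structure (age-standardised
rates are generated directly), no draw-level uncertainty, no spatial or
temporal correlation of shocks beyond the smooth trends, and cause/pollutant
splits that are exactly proportional rather than cause-specific. Tests on
synthetic panels validate the *computational chain*, and directional
properties (exposure–burden correlation, development gradients), not
real-world effect sizes.

## Problem sizes and numerical choices

The test suite fixes seeds everywhere; stochastic checks use 200 replicate
panels for slope recovery (bias of each slope, defined as mean estimate
minus truth, bounded by 0.05; ±2 SE coverage for the aPM2.5 slope within
[0.90, 0.99]) and 2,000 null replicates of three groups of 14 for the
type-I error of the rank test (empirical rate within [0.03, 0.07] at
α = 0.05). Exposure-distribution discretisation guards against
floating-point drift by renormalising bin masses; proportions must sum to 1
within 10⁻⁹. Degenerate inputs error early with typed conditions
(`airburden_config_error`, `airburden_schema_error`, ...) naming the
offending field, row or country.

## Limitations

Real relative-risk curves and TMRELs are user inputs — the package ships
only synthetic test curves and makes no claim about which curve applies to
which cause. Quantities that depend on real downloaded data (observed
correlations, regression fits, country classification counts, fold ratios)
are reproduced only qualitatively on synthetic panels. The ratio-change
statistic can understate progress for countries that start from very low
levels; it is a relative measure and should be read alongside absolute
levels and changes.
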