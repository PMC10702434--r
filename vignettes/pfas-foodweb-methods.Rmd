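---
title: "Methods: censored PFAS concentrations, balanced-bootstrap transfer factors, and diet-tracer ordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored PFAS concentrations, balanced-bootstrap transfer factors, and diet-tracer ordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasweb)
```

## The problem

Insectivorous birds feeding at the boundary of aquatic and terrestrial
habitats integrate contaminant exposure from several environmental
compartments at once: air, surface water, sediment, and the aquatic and
terrestrial invertebrates they eat. `pfasweb` implements the statistical
pipeline for tracing per- and polyfluoroalkyl substances (PFAS) through
such a food web from compartment-level concentration monitoring data:

1. handling of left-censored concentrations (detection-frequency
   screening, regression-on-order-statistics imputation),
2. congener proportion profiles per compartment,
3. bioaccumulation factors (BAF, organism over abiotic medium) and
   non-trophic-adjusted biomagnification factors (BMF, predator tissue
   over prey) estimated with a sample-size-balancing bootstrap,
4. a diet-tracer multivariate suite over fatty-acid (FA) signatures:
   arcsine-square-root transform, PCA with 95% group ellipses,
   Pillai-trace MANOVA, Tukey–Kramer post hoc tests, and multiple factor
   analysis (MFA) of the PFAS congener tables.

The package embeds the published study fixtures — the compartment
summary table (`table1_summaries()`: mean ± SE, range, n, and the
ND/"not determined" flags for 31 congeners × 7 compartments) and the
published transfer-factor table (`table2_cells()`, 11 compartment pairs
× 17 congeners) — and synthetic generators that emulate the study's
statistical structure so that every stage can be validated end to end
without unpublished raw data.

## Units and eligibility

Concentrations stay in compartment-native units (air ng/m³, surface
water ng/mL, sediment and biota ng/g wet weight); no cross-media
normalization is performed, so each BAF/BMF ratio carries mixed units,
recorded per pair in `table2_pairs()$units`. A transfer factor is
attempted whenever both compartments carry a measurable ("exact")
concentration for the congener; detection-frequency screening gates the
hypothesis tests and ordinations, **not** the transfer factors. Whole-
panel totals (Σ-PFAS rows) are stored as summaries but excluded from all
per-congener computation.

## Censored concentrations

*Screening.* A congener is statistically analyzable in a compartment
when it was detected in at least 60% of determined samples
(`screen_congeners()`, boundary inclusive). Samples in which a congener
was not determined at all are excluded from the denominator.

*Imputation.* Nondetects in analyzable series (censored fraction ≤ 40%)
are replaced by robust regression on order statistics (`ros_impute()`):
Hirsch–Stedinger exceedance probabilities assign plotting positions that
respect every censoring threshold, `log(concentration)` of the detects
is regressed on the standard-normal quantiles of their positions by
ordinary least squares, and each censored entry is replaced by the
back-transformed prediction at its own position. Detected values are
never altered, and imputed values are **not** clipped at their detection
limit — the fitted line carries no such guarantee and clipping would
bias means; a prediction above its limit raises a warning instead.
Within each censored interval, both detects and censored observations
receive Weibull-type positions `r/(m+1)`, which reduces to the classical
`i/(n+1)` rule on uncensored data, making ROS the identity there. The
natural logarithm is used throughout; every downstream ratio and
proportion is invariant to the base.

Alternatives not implemented (out of scope): maximum-likelihood and
Kaplan–Meier censored estimators.

## Profiles

`sample_profile()` divides each congener's value by the sample's summed
PFAS concentration. Nondetects contribute zero; congeners not determined
in the sample's matrix leave the denominator entirely, and the congener
panel actually summed is recorded, because the air panel (21 analytes)
differs from the other compartments (46). Compartment profiles are
arithmetic means of per-sample proportions — every sample's composition
counts equally, regardless of its total burden — which differs from the
ratio of mean concentrations on heterogeneous samples.
`profile_from_summaries()` provides the ratio-of-means approximation
available from published means and labels it as such: on the embedded
fixture it recovers the terrestrial-invertebrate PFOS dominance (~84%)
exactly, while for the nestling GI tract the sum of printed congener
means (25.6 ng/g) overshoots the printed whole-panel total (23.1 ng/g),
so the published 41% PFOS share is only recovered against the printed
total. Per-sample shares printed in the study text (e.g. 48% in liver)
require the unpublished raw data and are not reproduction targets.

## Balanced-bootstrap transfer factors

Compartment sample sizes differ (5–15). Following the study's balancing
device, each side of a ratio is resampled with replacement to a common
size (`n_draws = 1000`) before its mean is taken. The point estimate is

> mean of all numerator draws / mean of all denominator draws,

pooled over `n_boot` paired replicates, which converges on the ratio of
compartment sample means; a single 1000-draw resample would leave 2–4%
Monte-Carlo noise per cell. The attached spread and percentile 95%
interval instead come from paired classical bootstrap replicates at the
*original* sample sizes: re-drawing 1000 values from 15 can only measure
resampling noise, not the compartments' sampling variability, and would
give intervals with essentially zero coverage. With this separation the
intervals cover a known true ratio at roughly the nominal rate in
simulation (percentile intervals at n = 15 undercover mildly, as they
generally do). Whether the study drew with or without replacement is not
stated; with replacement is the default (required to draw 1000 from 15)
and the alternative is a flag.

Randomness is derived per pair × congener from the master seed and the
cell's labels, so matrix entries are individually reproducible and
independent of evaluation order. Classification uses the strict rule:
bioaccumulative/biomagnifying iff the estimate exceeds 1.

### Known source-table inconsistencies

Checked cell by cell against the published compartment means, the
published transfer table contains six cells the pipeline cannot
reproduce as printed, all documented in the acceptance tests rather than
silently absorbed:

* five cells are printed as "-" (not calculable) although both
  compartments have measurable means — PFDA aquatic-invertebrates/
  sediment, PFOA GI/air, PFOA GI/surface-water, PFDA liver/surface-water
  and PFOA GI/aquatic-invertebrates (implied ratios 0.23, 17.1, 20.0,
  2700 and 1.20). The pipeline computes them; the acceptance test
  asserts both that fact and the not-computable status of the remaining
  130 dashed cells.
* one printed value (N-MeFOSAA GI/surface-water, 5.11) sits 2.15% from
  the ratio of published means (0.30/0.06 = 5.00) because the
  surface-water mean is printed to one significant figure; it is
  asserted against 5.00 at 2% and against 5.11 at 3%.

A few fixture cells also print a mean outside their own printed range or
with a dropped exponent sign; these carry an explicit `note` and are
stored as printed (exponent typos corrected).

## Ordination suite

FA proportions are arcsine-square-root transformed, then analyzed with a
centered, unit-variance-scaled SVD PCA (transform first, then scale; a
`scale` flag covers the other order). Axis signs follow a fixed
convention — largest-magnitude loading positive — and group ellipses use
the normal-theory 95% radius `sqrt(qchisq(.95, 2)) = 2.4477` on the
per-group score covariance (a plotting convention). Pillai's trace is
computed from the between/within cross-product matrices as
`tr(H(H+E)^-1)` with the standard F approximation; the study's printed
MANOVA degrees of freedom do not match any standard convention for its
stated design, so standard df are reported and the printed statistic is
not a numeric target (it needs the unpublished raw data, as do the
printed PC variance shares of 47%/31%). Univariate follow-ups use
Tukey–Kramer studentized-range comparisons with the harmonic-mean
adjustment for unequal n (exactly Tukey's HSD at equal n); no correction
is applied across FA variables, matching the study. MFA standardizes
each variable group, divides it by the square root of its first PCA
eigenvalue (group weight = reciprocal first eigenvalue), and runs a
global centered PCA on the concatenation; PFAS inputs are log-
transformed then standardized. Variable-dimension associations are
correlation tests at α = 0.05 (a declared display threshold).

## Synthetic worlds

*Concentrations* (`gen_concentrations()`): lognormal per compartment ×
congener — the study log-transforms concentrations to reach normality —
with `meanlog` chosen so the arithmetic population mean equals the
configured truth (defaults: the published measurable means), a common
geometric SD of 1.6 (moderate environmental spread; a single declared
constant), detection limits that emit nondetects below the limit, and
the study's sample sizes 5, 6, 6, 5, 5, 15, 15. True means, true
pair ratios and censoring probabilities travel in a ground-truth sidecar.
What this world omits: between-congener correlation within a sample,
spatial/temporal structure, and measurement error distinct from
biological variance — so a green recovery test establishes estimator
correctness under the stated model, not robustness to those features.

*Fatty acids* (`gen_fa_signatures()`): Dirichlet draws (concentration
150, tight replicate-level compositions) around group mean signatures
over the seven major dietary FAs, planting the study's qualitative
structure: 18:2n6 (terrestrial marker) peaks in terrestrial
invertebrates, 20:1n9/20:5n3 (aquatic markers) in aquatic invertebrates,
swallow tissues in between with carcass nearer the terrestrial source.
Group sizes default to 5, 5, 15, 15.

*Pinned dataset* (`gen_table1_like()`): deterministic expansion of the
published summary table into per-sample values with the sample mean
pinned exactly to the published mean, values inside the published range,
and spread targeting the published SE where the range allows; cells
flagged mean-outside-range collapse to constants. Running the transfer
pipeline on this dataset reproduces the published BAF/BMF table, which
is the package's primary acceptance surface
(`scripts/acceptance.R`).

## Numerical choices and limitations

* All randomness flows through integer seeds below 2³¹; derived
  substreams use a small string hash, not R's default sequential streams.
* Percentile intervals and bootstrap SDs are Monte-Carlo quantities;
  `n_boot = 200` keeps the full 11 × 17 matrix in seconds on one CPU.
* `ros_impute()` requires ≥ 3 detects and warns above 40% censoring;
  series failing the screen keep detects-only means for transfer-factor
  use, as the published summary table does.
* Ties among detects take first-occurrence ranks within their censoring
  interval; two nondetects at one limit receive ordered Weibull
  positions, so their imputations are monotone.
* Zero-variance ANOVA input returns F = 0 (no spread, no signal) rather
  than NaN.
* The package does not model trophic-level-adjusted magnification,
  fugacity/partitioning, or isotope mixing; isotopes are descriptive in
  the source study.
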