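---
title: "Methods: design-based wetland soil carbon accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design-based wetland soil carbon accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetcarbon)
```

## The estimation problem

A national wetland soil-carbon stock is a population quantity: the sum,
over every hectare of wetland in a survey frame, of the carbon held in
the top 120 cm of soil. It is estimated from a probability sample of
wetland points with unequal inclusion probabilities $\pi_i$ (wetland
types are deliberately over- or under-sampled), each visited once and
described by soil horizon. `wetcarbon` implements the full estimation
chain and a synthetic generator that plays the role of the field
campaign, so that every stage can be validated against a known truth.

## Horizon carbon density and depth slicing

For a horizon of thickness $d_l$ (cm), bulk density $\rho_d$
(g cm$^{-3}$) and soil organic carbon concentration $C$ (% of fine-earth
mass, total minus inorganic carbon),

$$\rho_c = A \, d_l \, \rho_d \, \frac{C}{100}, \qquad A = 10{,}000\ \mathrm{cm^2\,m^{-2}},$$

gives the stored carbon in g m$^{-2}$. Horizon boundaries differ between
profiles, so profiles are divided into 1-cm increments ([`slice_profile()`]):
each centimetre takes the thickness-weighted mixture of the horizons
overlapping it, under the assumption that soil is homogeneous within a
horizon. This choice makes slicing exactly conservative — summing
increments reproduces the direct horizon values to floating-point
accuracy — which the test suite asserts at $10^{-9}$ relative tolerance
on 1,000 random profiles.

Aggregation over a depth range ([`depth_range_density()`]) requires the
range to be *fully* covered by described, data-complete horizons;
otherwise the site is excluded from that range's estimate. We chose
complete coverage over prorating partial coverage because prorating
silently biases deep-range densities downward at sites with shallow
impenetrable layers; the cost is a contributing sample size that shrinks
with depth, which is also how the real survey behaves. Reporting stops
at 120 cm.

## Quality control

Thin horizons (< 8 cm) are not lab-sampled, and field bulk density is
unreliable, so before accounting each profile passes two rule sets:

* **Carbon imputation** ([`impute_missing_carbon()`]): a missing surface
  SOC is equated to the next lower horizon with data (conservative when
  an organic cap overlies mineral soil); an interior gap takes the
  arithmetic mean of the nearest horizons above and below, with
  consecutive gaps sharing the same neighbour average; a missing bottom
  horizon copies from above (our own mirror of the surface rule — it can
  be disabled). Sites with no SOC anywhere are excluded and logged.
  Imputation never alters observed values and is idempotent.
* **Bulk density screening** ([`screen_bulk_density()`]): measured values
  above 2.0 g cm$^{-3}$ (the physical ceiling of measurable bulk
  density) are replaced by the modelled value, as are values differing
  from the modelled value by more than 40%; missing values are filled.
  The 40% rule's denominator is the modelled value — the natural reading
  of "differed from the modelled bulk density by 40%" — and is
  configurable.

## The bulk density model

About 30% of sampled horizons lack usable bulk density, so a
pedotransfer model supplies it: stagewise gradient-boosted shallow
regression trees under squared-error loss with shrinkage and row
subsampling, predicting $\rho_d$ from ten covariates (SOC, reporting
group, EC, CEC, horizon mid-depth, clay, silt, HGM class, sand, horizon
order). Defaults — 3,000 trees, shrinkage 0.01, depth 5, bag fraction
0.5, a seeded simple random 70/30 train/holdout split — follow standard
boosted-regression-tree practice for soil property prediction; all are
exposed in [`bd_model_spec()`]. Fit quality is the holdout $R^2 = 1 -
\mathrm{SSE}/\mathrm{SST}$; variable importance is the share of total
squared-error reduction attributable to splits on each predictor,
normalised to 100% with one-hot indicator columns pooled back to their
parent predictor. The xgboost backend honours this contract
deterministically (single thread, seeded subsampling); its native
handling of missing predictor values — routing them down each tree's
learned default branch — replaces median/mode filling, and unseen
categorical levels at prediction time map to an all-zero "other"
encoding with a warning. Predictions are truncated to (0.05, 2.0]
g cm$^{-3}$.

On generator-default synthetic data the model reaches holdout
$R^2 \approx 0.95$ with SOC carrying ~90% of the importance — the same
qualitative structure (strong fit, SOC-dominated) as published NWCA
bulk-density modelling, though the synthetic relation is cleaner than
field data, so the numbers are not comparable beyond that.

## Soil classification and carbon type

Histosol-derived field rules label a profile an organic-soil wetland if
(a) every horizon down to at least 40 cm is organic (peat, muck, mucky
peat), or (b) at least 40 cm of the top 80 cm is organic, or (c) with an
impenetrable layer above 40 cm, two-thirds or more of the described
thickness is organic and mineral material totals under 10 cm; otherwise
mineral. Boundary readings: "a minimum of 40 cm" and "at least 40 cm"
are inclusive ($\ge 40$), "< 10 cm" is strict, and rule (a) is read as
"no mineral horizon above 40 cm" (a thin mineral surface cap
disqualifies). The decision depends only on cumulative organic/mineral
thicknesses, so it is invariant to horizon subdivision — a property the
tests exercise. Carbon type is a total two-way split: tidal saline sites
hold blue carbon, freshwater inland sites teal carbon.

## Disturbance screening and threshold calibration

Ten stressor measures (buffer agriculture, residential/urban,
hydrologic, industrial and habitat-modification scores, a buffer
summary, high- and moderate-impact hydrologic alteration counts, a soil
heavy-metal exceedance index, relative alien plant cover) are screened
against per-reporting-group thresholds: *least* disturbed means at or
below every least threshold, *most* means strictly above any single most
threshold, the rest are *intermediate*. Screening is monotone — raising
an index can never move a site toward a less-disturbed class.

"Most disturbed" is a relative designation, so most thresholds are
calibrated ([`calibrate_thresholds()`]): per group, all ten thresholds sit
at a common upper quantile of the group's index distributions, and the
quantile is chosen on a deterministic grid as the highest one whose
exceedance fraction still reaches the target (default 0.25). The
realised fraction is therefore the smallest achievable value at or above
the target — with $\ge 20$ sites per group this lands within target
$+ 1/20$, i.e. inside the intended 20–30% band — and is monotone in the
target, which the tests sweep. Degenerate (tied) indices fall back to
the nearest achievable fraction with a warning. Both probability and
non-probability sites enter calibration; only probability sites enter
estimates. Real surveys publish their threshold values separately; here
they are data-calibrated inputs, not claims about any particular
landscape.

## Design-based estimation

With weights $w_i = 1/\pi_i$ expressed as hectares represented, a
subpopulation's represented area, total stock and mean density are
$\hat A = \sum w_i$, $\hat T = \sum w_i y_i$ and $\hat T / \hat A$, over
the contributing sites (in the subpopulation, depth range available).
Variances use the with-replacement (Hansen–Hurwitz) approximation

$$\widehat{\mathrm{var}}(\hat T) = \frac{m}{m-1} \sum_{i=1}^{m} (z_i - \bar z)^2,$$

computed over the *full* sample of size $m$ with $z_i = w_i y_i$ for
contributing sites and $z_i = 0$ otherwise; the mean uses the
ratio-linearised residuals $w_i (y_i - \hat{\bar Y})$. Including the
zeros matters: subpopulation membership and depth availability are
random under the design, and dropping non-contributing sites understates
the variance of totals — in our replicate experiments 95% CI coverage
fell to ~0.84 under the contributing-only variance and sits at ~0.95–0.97
with the domain form. The estimator deliberately ignores the spatial
structure of the original sample selection (the survey's local
neighbourhood variance estimator needs site coordinates, which are out
of scope) and applies no finite-population correction; both affect SEs,
not point estimates, and leave the intervals mildly conservative at the
~10% sampling fractions we simulate.

Scaling to a target population ([`scale_to_target()`]) multiplies totals
by the target/inference area ratio, leaves mean densities unchanged, and
reports no SEs — extrapolation assumes the unsampled area follows the
sampled trends, and its uncertainty cannot be estimated from the sample.
Published target-population tables of this kind are not exactly
recoverable by any single area ratio (their regional cells imply
different ratios per row), so the package documents and implements
proportional scaling and does not attempt to match those cells.

## The synthetic generator

[`generate_population()`] emulates the features of NWCA-like data that the
pipeline must survive, with every constant exposed in
[`simulation_config()`]:

* **Profiles**: contiguous horizons to 120 cm, or to a shallower
  impenetrable layer (probability 0.15, depth uniform on 30–110 cm),
  lognormal thicknesses, ~25% of horizons thin (< 8 cm, unsampled:
  chemistry and bulk density missing).
* **SOC**: $s_0 e^{-kd}$ with lognormal noise (log-sd 0.3); organic
  archetype $s_0 = 35\%$, $k = 0.004$ cm$^{-1}$; mineral $s_0 = 8\%$,
  $k = 0.025$ cm$^{-1}$ — surface concentrations and decay scales
  bracketing typical peat and wet mineral soils. Organic-archetype
  fractions vary by reporting group (highest in the
  Eastern-Mountains/Upper-Midwest groups).
* **Bulk density**: $\rho_d = 1.6\,e^{-0.08\,\mathrm{SOC}} +
  \varepsilon$, $\varepsilon \sim N(0, 0.1)$, truncated to (0.05, 2.0] —
  a decaying-exponential pedotransfer shape that spans mineral (~1.5)
  to peat (~0.1) densities and makes SOC the dominant predictor, as in
  field pedotransfer models. 30% of sampled horizons lose their value;
  2% receive a gross error above 2.0 g cm$^{-3}$ to exercise the QC
  screen.
* **Disturbance**: latent least/intermediate/most classes (25/45/30%)
  drive a site severity scalar (lognormal medians 0.3/1.2/3.5) that
  scales all ten indices (gamma jitter), so classes are recoverable by
  thresholding; most-disturbed sites get a multiplicative SOC reduction
  ramping from none at the surface to 0.6 at 90 cm (intermediate sites
  half of it) — a device to create a least-vs-most density gap, not a
  mechanistic claim.
* **Design**: ten reporting groups in realistic proportions (tidal
  groups smallest), relative inclusion probabilities by wetland type
  (estuarine types over-sampled ~2×), a 25.2 Mha frame split equally
  among population sites. [`sample_survey()`] draws fixed-size samples by
  randomised-order systematic PPS, giving exact inclusion probabilities
  $\pi_i = n p_i$ (capped at 1) and Horvitz–Thompson-unbiased totals —
  the generic unequal-probability stand-in for a spatially balanced
  design, which needs coordinates we do not simulate.

Ground truth is computed from the complete pre-missingness horizon data
by census aggregation, per site and per subpopulation. A single master
seed derives per-stage child seeds, so output is deterministic.

What passing tests do *not* show: the generator has no spatial
autocorrelation, no correlation between inclusion probability and
carbon beyond wetland-type composition, clean exponential depth decay,
and missingness that is random rather than driven by field conditions.
Results on it validate the machinery — estimator unbiasedness, rule
correctness, conservation, calibration — not the field realism of any
particular number.

## Numerical choices and degenerate inputs

Depths are cm below the surface on half-open intervals $[{\rm top},
{\rm bottom})$; missing values are empty CSV fields, never sentinels;
SOC differences that come out negative (carbonate-rich soils) clip to 0
with a warning. Contiguity and boundary comparisons use $10^{-6}$ cm
slack; classification thresholds use $10^{-9}$ slack on the inclusive
side. A constant bulk-density response fits with $R^2$ reported as 0 and
a warning; an empty subpopulation yields an `n = 0` row with `NA`
estimates rather than an error; degenerate disturbance indices warn and
return the nearest achievable fraction. Threshold ties: least compliance
is non-strict ($\le$), most exceedance strict ($>$).

## Problem sizes

The test suite runs on a shared 600-site population plus a
2,000-site population (200-site samples, 500 replicates) for the
estimator checks; the acceptance script uses the same 2,000/200/500
configuration. These sizes give Monte-Carlo standard errors a few times
smaller than the effects being checked while keeping a full run in the
low minutes on one core.

## Known limitations

SEs are approximations (no spatial variance estimator, no
finite-population correction); the bulk-density importance
decomposition is gain-based and, like all impurity importances, can
favour high-cardinality predictors; the histosol rules implement only
the three stated criteria, not full soil taxonomy keying; carbon
accretion rates are out of scope — stocks are a snapshot, and nothing
here estimates fluxes.
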