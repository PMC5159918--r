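# wetcarbon

Design-based accounting of wetland soil organic carbon stocks from
probability-survey soil profile data, in the style of the US EPA's
National Wetland Condition Assessment (NWCA).

National and regional wetland carbon stocks cannot be read off a map:
they are estimated from a probability sample of wetland sites, each
carrying a survey weight (the hectares it represents, the inverse of its
inclusion probability), with soil described by horizon to ~120 cm and
analysed for carbon and bulk density. `wetcarbon` implements the full
chain from field-style tables to population estimates, for ecologists
and survey statisticians who need a tested, reproducible version of that
workflow — and a synthetic data generator with known ground truth to
validate every step without access to survey microdata.

## The model

Carbon density of a soil horizon (g m⁻²) is

```
ρ_c = A · d_l · ρ_d · C/100
```

with `A = 10,000` cm² m⁻², `d_l` the layer thickness (cm), `ρ_d` the
bulk density (g cm⁻³) and `C` the soil organic carbon concentration (%,
total minus inorganic carbon). Because horizon depths differ between
profiles, each profile is divided into 1-cm increments, so stocks can be
aggregated over any depth range (0–30, 30–60, 60–90, 90–120 cm by
default); a site contributes to a range only when its profile fully
covers it. Per-site densities `y_i` (tC ha⁻¹) and weights `w_i` (ha)
give design-based estimates for any subpopulation:

```
area      Â = Σ w_i            (ha)
total     T̂ = Σ w_i y_i        (reported in PgC)
mean      T̂ / Â                (tC ha⁻¹)
```

with with-replacement (Hansen–Hurwitz) standard errors computed over the
full sample, zeros included for non-contributing sites. Around this core
sit the survey's supporting rules, all implemented and unit-tested:

* **QC / imputation** — missing surface-horizon carbon is equated to the
  next horizon below; interior gaps take the mean of the horizons above
  and below; measured bulk density above 2.0 g cm⁻³ or differing from
  the modelled value by more than 40% is replaced by the modelled value.
* **Bulk density model** — gradient-boosted regression trees (squared
  error, shrinkage, bagging; xgboost backend) predicting ρ_d from SOC,
  reporting group, EC, CEC, depth, texture, HGM class and horizon order,
  with a 70/30 train/holdout split and gain-based importance normalised
  to 100%.
* **Soil classification** — histosol-derived rules labelling each
  profile organic or mineral (organic throughout the top 40 cm, or ≥40
  organic cm in the top 80, or the impenetrable-layer rule), and
  blue/teal carbon typing by the tidal-saline flag.
* **Disturbance screening** — least / intermediate / most disturbed from
  ten stressor measures screened against per-reporting-group thresholds,
  with quantile calibration of the "most" thresholds to a target
  exceedance fraction (~20–30%).
* **Scaling** — inference-population totals scaled proportionally to a
  larger target frame (means unchanged, no SEs for the unsampled area).

## Worked example

```r
library(wetcarbon)

# a synthetic NWCA-like population with known ground truth
sim <- generate_population(simulation_config(seed = 7,
                                             n_population_sites = 1000,
                                             n_sampled_sites = 150))
svy <- sample_survey(sim, seed = 8)        # unequal-probability sample

# fit the bulk density model on measured horizons, QC the sampled profiles
fit <- fit_bd_model(sim$horizons, sim$sites,
                    bd_model_spec(n_trees = 600, shrinkage = 0.05, seed = 7))
fit
#> Bulk density boosted-tree model: 600 trees, holdout R2 = 0.951
#>   train n = 2642, holdout n = 1132
#>   relative importance (%):
#>     soc_pct                 91.35
#>     cec                      1.42
#>     horizon_mid_depth_cm     1.34
#>     ...

qc <- qc_profiles(sim$horizons[sim$horizons$site_id %in% svy$site_id, ],
                  svy, fit)

# slice to 1-cm increments, aggregate, and estimate
per_site <- site_depth_densities(qc$horizons) |>
  dplyr::left_join(svy[, c("site_id", "weight_ha", "tidal_saline")],
                   by = "site_id") |>
  dplyr::mutate(carbon_type = carbon_type(tidal_saline))
est <- estimate_all(per_site, groupings = "carbon_type")
subset(est, depth_lo_cm == 0 & depth_hi_cm == 120)
#>      grouping subpopulation ... n_sites area_Mha mean_tC_ha se_mean total_PgC se_total
#>      national      National         125   21.350      354.8   6.366    7.5738   0.3616
#>   carbon_type          blue          18    1.555      350.6   8.063    0.5452   0.1216
#>   carbon_type          teal         107   19.795      355.1   6.836    7.0287   0.4092
```

Reading the output: the 125 sampled sites whose profiles reach 120 cm
represent 21.3 Mha storing an estimated 7.57 ± 0.36 PgC (mean density
355 tC ha⁻¹); freshwater inland (teal) wetlands hold ~13× the stock of
tidal saline (blue) sites, almost entirely through their larger area.
`scale_to_target(est, inference_area_Mha, target_area_Mha)` extrapolates
totals to a wider survey frame, and `run_pipeline()` performs the whole
sequence (simulate → QC → model → account → classify → screen →
estimate) into an inspectable run directory with a manifest.

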