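# climspace

Coupled projections of **climate-space shifts** and **body-size / growth-rate
shifts** for temperate river fishes, for ecologists and fisheries scientists
who want both halves of the climate-change story in one reproducible
pipeline: where a species' suitable climate moves, *and* how its populations'
growth restructures inside it.

## What it computes

**Climate space.** Presence/absence on a grid is modelled against six
bioclimatic variables (pre-filtered at pairwise Pearson |r| > 0.70) with a
configurable roster of classifiers — GLM, GAM (4-knot smooths), MARS,
classification trees, boosted trees, random forest, neural network. Each is
scored by the mean held-out AUC over 50 stratified 80:20 splits; those with
AUC ≥ 0.7 form a weighted-mean ensemble (weights ∝ mean AUC). Cells with
ensemble probability ≥ 0.6 are the species' climate space, summarised per
scenario by cell counts, percent change, centroid displacement (haversine
distance, bearing with 0° = north) and Welch t-tests on occupied-cell
coordinates.

**Growth.** Per fish, length at the last scale annulus is back-calculated by
the scale-proportional method, `L_a = -(u/v) + (L_c + u/v)(S_a/S_c)`, from
the species-wide regression `S = u + vL`. Per population, nonlinear least
squares fits the two-parameter von Bertalanffy model

```
L_t = L∞ (1 − exp(−K t))
```

Then `L∞` and `K` are regressed on climate with GLM, GAM and MARS, combined
with weights ∝ 1/GCV (GCV = leave-one-out mean squared prediction error) and
projected under each scenario.

**Coupling.** Scenario-mean `L∞` and `K` are regressed on the percent change
in climate space (with 8 scenarios: F df = (1, 6)), and per-scenario mean
length-at-age curves carry empirical 95% bands across populations.

A synthetic-data module generates the full stated world — spatially
structured bioclim surfaces, logistic niche occupancy, temperature-size-rule
growth data with scale radii — so everything runs and is tested without
external data.

## Worked example

```r
library(climspace)
res <- run_pipeline(demo_config(seed = 1))
res$species$virtual_roach$ensemble
#> <sdm_ensemble> virtual_roach: 7 member(s), cutoff 0.70
#>   GLM  weight 0.145 (mean AUC 0.855)
#>   GAM  weight 0.146 (mean AUC 0.865)
#>   ...
#>   AUC: 0.895 (resubstitution), 0.846 (weighted member eval)

res$species$virtual_roach$range_shifts[1:2, c("scenario", "n_cells", "pct_change", "distance_km")]
#>           scenario n_cells pct_change distance_km
#> 1 gcm_a_rcp26_2050     508      59.75    85.10496
#> 2 gcm_a_rcp26_2070     530      66.67    98.13397

res$species$virtual_roach$coupling[, c("target", "slope", "r2", "F", "df1", "df2")]
#>   target         slope        r2        F df1 df2
#> 1   Linf -0.0952180157 0.9766272 250.7091   1   6
#> 2      K  0.0004068046 0.9920517 748.8803   1   6
```

Read: all seven algorithms clear the AUC cutoff; under the mildest scenario
the virtual species' climate space grows 59.75% (508 vs 318 cells) and its
centroid moves 85 km; across the eight scenarios the mean asymptotic length
falls ~0.10 mm per percent of climate-space expansion (R² = 0.98) while the
growth coefficient rises — the expanding-range, shrinking-fish,
faster-growth pattern the temperature-size rule predicts.

The same analysis, stage by stage with narrative output, lives in
`analysis/01_simulate.R` … `analysis/06_integration.R` (run from the
repository root; tables land in `results/analysis/`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete demo pipeline from the installed package — synthetic
world, variable reduction, growth fits, the seven-member ensemble with
per-scenario presence grids, growth-climate projections, range statistics
and coupling regressions — printing the ensemble report, per-scenario range
shifts and coupling statistics, and writes the JSON target report to
`--out`. Pipeline artifacts land next to it under `results/pipeline/`.

## Further reading

The methods vignette (`vignettes/climate-space-and-growth.Rmd`) documents
the model assumptions, every tunable with units and defaults, what the
synthetic world does and does not emulate, numerical choices (clamped MARS
extrapolation, LOO-GCV identities, degenerate-input handling) and known
limitations.
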