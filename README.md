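# pondpredict

Environmental predictability of ponds and shallow lakes, estimated from long
multispectral satellite image time series.

Ecologists studying temporary waters need to know whether a habitat
fluctuates on a repeatable seasonal schedule or erratically: the answer
shapes the life histories of everything from resting-egg zooplankton to
migratory waterfowl. Satellite archives (Landsat-class: 30 m pixels,
revisits of a few weeks, decades of depth) make the focal variable — the
water-surface area *A* of each pond — observable at scale, but saline ponds
complicate the extraction (salt crusts mimic water in band-ratio indices)
and clouds riddle the series with gaps.

`pondpredict` implements the full chain:

1. **Water detection (2cA)** — per pixel, a two-condition assessment:
   MNDWI = (Green − MIR)/(Green + MIR) > 0 marks water candidates, then
   NIR reflectance ≥ 0.4 reclassifies bright candidates as salt crust.
2. **Time series** — per pond and scene, water area with a cloud-uncertainty
   interval `[area, area_max]`; monthly-balanced mean area and hydroperiod.
3. **Discrete predictability** — Colwell's constancy *C*, contingency *M*
   and predictability *P = C + M* on month x state contingency tables,
   under five state definitions (`COL_wd`, `COL_ANa`, `COL_ANw`,
   `COL_MAXlin`, `COL_MAXg`):

   *P* = 1 − (H(XY) − H(X)) / log *s*,

   with H(X), H(Y), H(XY) the entropies of the month, state and joint
   distributions and *s* the number of states.
4. **Continuous predictability** — a penalized cubic-spline (GAM) fit of
   normalized area A′ = A/Ā on day of year; P_GAM = 1/SD of the residuals
   (`GAM_a`, `GAM_w`).
5. **Model comparison** — Pearson correlations between model estimates,
   chord distance √(2 − 2r), UPGMA clustering, bootstrap clade support,
   threshold cut.
6. **Synthetic truth** — generators for scenes and series that emulate the
   archive (27 years, ~23-day usable cadence, 50% cloud loss, seasonal
   Mediterranean hydrology), so every stage is testable without external
   data.

Rasters are read and written as ESRI ASCII grids (plain-text, GIS-standard);
see the methods vignette (`vignettes/predictability-methods.Rmd`) for every
modeling choice and its rationale.

## Worked example

Three synthetic ponds with known regimes — near-permanent, seasonal, and
erratic:

```r
library(pondpredict)

permanent <- generate_pond_series(series_truth(
  seasonal = function(d) 1 + 0.3 * cos(2 * pi * (d - 46) / 365.25),
  noise_sd = 0.15, dry_threshold = 0, seed = 1), pond_id = 1)
seasonal <- generate_pond_series(series_truth(noise_sd = 0.2,
  dry_threshold = 0.15, seed = 2), pond_id = 2)
erratic <- generate_pond_series(series_truth(
  seasonal = function(d) rep(1, length(d)),
  noise_sd = 0.7, dry_threshold = 0.15, inter_annual_sd = 0.3, seed = 3),
  pond_id = 3)

seasonal
#> <pond_series> pond 2  429 obs (222 cloud-free)  1984-2011
sapply(list(permanent, seasonal, erratic), hydroperiod)
#> [1] 1.0000000 0.8926297 0.8665457

run_discrete_model(permanent, "COL_wd")
#> pond 1  COL_wd     P = 1.000 (C 1.000, M 0.000, n = 181)
run_discrete_model(seasonal, "COL_ANa")
#> pond 2  COL_ANa    P = 0.565 (C 0.166, M 0.399, n = 186)
run_continuous_model(erratic, "GAM_a")
#> pond 3  GAM_a  P_GAM = 1.403 (sd_res 0.7128, mean 38561.3 m2)
```

Reading the numbers: the never-dry pond is perfectly predictable under the
water/dry model (*P* = 1, all constancy). The seasonal pond's predictability
under `COL_ANa` is mostly *contingency* (M = 0.40 of P = 0.57): its state is
a repeatable function of the month. The erratic pond's GAM residual SD
(0.71) is large, so its continuous predictability is low (P_GAM = 1.4);
compare P_GAM = 5.1 for the near-permanent pond.

The whole pipeline (areas CSV → 7-model estimates → correlation/UPGMA
comparison) runs via `run_pipeline()`, or from the shell:

```sh
Rscript -e 'pondpredict::pond_cli()' predict --areas areas.csv --out estimates.csv
Rscript -e 'pondpredict::pond_cli()' compare --estimates estimates.csv \
    --n-boot 10000 --seed 42 --cut 0.90 --out comparison/
```

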