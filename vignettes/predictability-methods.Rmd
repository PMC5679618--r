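---
title: "Quantifying pond predictability from multispectral time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pond predictability from multispectral time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondpredict)
```

## The problem

Many organisms of temporary ponds — zooplankton with resting eggs, amphibians,
waterfowl — live or die by whether the flooding regime of their habitat is
*predictable*: does the pond fill and dry on a repeatable seasonal schedule,
or erratically? Long ecological time series are rare, but satellite archives
are not. Three decades of multispectral imagery at 30 m resolution give, for
every pond, hundreds of dated estimates of its water-surface area $A$ — enough
to quantify the predictable (seasonal) and unpredictable (stochastic)
components of its fluctuation.

`pondpredict` implements that pipeline end to end: pixel classification of
water against soil and salt crust, construction of per-pond $A$ time series
with explicit cloud bookkeeping, seven predictability models (five discrete,
Colwell-style; two continuous, spline-regression-based), and a model
comparison stage.

## Water detection: the two-condition assessment

Saline ponds are the hard case: evaporation leaves a bright salt crust that
fools band-ratio water indices. Classification is therefore sequential:

1. **Water candidacy.** The Modified Normalized Difference Water Index,
   $\mathrm{MNDWI} = (\rho_{green} - \rho_{MIR}) / (\rho_{green} + \rho_{MIR})$,
   must be strictly positive. $\mathrm{MNDWI} = 0$ (including the no-signal
   0/0 case) is classified soil — the conservative reading of "positive
   values".
2. **Salt filter.** Among candidates only, near-infrared reflectance
   $\geq 0.4$ reclassifies the pixel as salt crust ("lower than 0.4" is
   non-salt, so 0.4 itself is salt). Water is what survives both conditions.

Cloudy and nodata pixels are merged into a single *unusable* class before
classification; nothing downstream distinguishes them, and no operation ever
un-flags one. Disabling the salt filter can only move salt pixels to water,
so the unfiltered area estimate is an upper bound of the filtered one — a
directional invariant the test suite checks on noisy synthetic scenes.

Rasters are handled as ESRI ASCII grids (a plain-text, GIS-standard,
single-band raster format) because the target environment provides no
GeoTIFF reader; the format carries the same header metadata (grid size, cell
size, corner coordinates, nodata sentinel) and round-trips exactly.

## From pixels to series: the cloud interval

For each pond and scene the package records an *interval*:
`area` counts water pixels only (clouds counted as non-water) and `area_max`
additionally counts clouded pixels inside the pond. The truth lies in
`[area, area_max]` whatever the clouds hide. Cloud-free means
`cloud_fraction == 0` exactly.

Summaries are *monthly balanced* so an archive with more summer than winter
scenes does not bias them:

* **Mean area** $\bar A$: per calendar month the mean of cloud-free areas,
  then the mean over observed months.
* **Hydroperiod**: per calendar month the fraction of cloud-free
  observations with $A > 0$, averaged over observed months.
* **Monthly aggregation** (discrete models): within each (year, month), only
  the observations with that month's minimum cloud cover are kept (all of
  them when tied) and averaged. Months never observed are skipped, not
  imputed — imputation would invent data.

## Discrete models: Colwell's predictability

The continuous variable $A$ is discretized into states; time is discretized
into the 12 calendar months; years act as replicates. With counts $N_{ij}$
(state $i$, month $j$), column sums $X_j$, row sums $Y_i$, total $Z$ and $s$
states:

$$C = 1 - \frac{H(Y)}{\log s}, \qquad
  M = \frac{H(X) + H(Y) - H(XY)}{\log s}, \qquad
  P = C + M = 1 - \frac{H(XY) - H(X)}{\log s},$$

where $H(\cdot)$ are Shannon entropies with $0\log 0 = 0$. Constancy $C$
rewards staying in one state; contingency $M$ rewards a state that is a
repeatable function of the month. The $\log s$ normalization makes the index
independent of the logarithm base (tested against a base-2 oracle).

Five state definitions are supported:

| model | states | breaks |
|---|---|---|
| `COL_wd` | 2 | dry ($A = 0$) vs wet ($A > 0$) |
| `COL_ANa` | 3 | $\bar A \pm 70\%\,\bar A$; middle state closed on both ends |
| `COL_ANw` | 3 | as `COL_ANa`, dry monthly values excluded, wet-only mean |
| `COL_MAXlin` | 3 | thirds of $\max A$ |
| `COL_MAXg` | 3 | quarters of $\max A$: breaks at 1/4 and 2/4 |

State assignment is *interval-safe*: a monthly value contributes only if
`area` and `area_max` fall in the same state; otherwise the clouded part of
the pond could change the state and the month is excluded. Aggregation to
monthly values happens first, then state assignment — the order in which the
procedure presents itself; the alternative (assign first, then aggregate) is
not provided. For `COL_ANw` the reference mean uses wet observations only
(the model's "with water presence" reading); the all-data mean is available
via `anw_mean_all = TRUE` since the original definition leaves this open.
$\max A$ is taken over cloud-free raw observations rather than monthly
aggregates, because averaging can only shrink a maximum.

All five models are invariant to permuting years and to rescaling all areas
by a positive constant (thresholds scale with $\bar A$ and $\max A$) — both
are property tests.

## Continuous models: seasonal-curve residuals

The normalized area $A' = A/\bar A$ is regressed on day of year with a
penalized cubic-spline smoother; predictability is the reciprocal residual
dispersion:

$$P_{GAM} = \frac{1}{SD_{res}},$$

with $SD_{res}$ the $n-1$ sample standard deviation of the residuals.
Because $\operatorname{mean}(A') \approx 1$ when zeros enter the mean,
$P_{GAM}$ is approximately the inverse coefficient of variation about the
seasonal curve. `GAM_a` normalizes by the all-data mean; `GAM_w` by the
wet-only mean, which compresses $A'$ (and inflates $P_{GAM}$) for ponds that
are usually dry. Both fit *all* cloud-free observations; for `GAM_w` the dry
observations can additionally be dropped from the regression itself
(`gam_w_drop_zeros = TRUE`), but the default follows the literal definition
— dry states excluded *for mean computation* only.

Numerical choices, each deliberately fixed:

* **Basis**: cubic B-splines (`bs = "bs"`, dimension $k = 8$). Natural cubic
  regression splines were rejected because their boundary constraints cannot
  reproduce a cubic polynomial exactly, which breaks an otherwise clean
  correctness check (a spline smoother should fit a cubic with ~machine-zero
  residuals; the B-spline basis does, at $10^{-15}$). A cyclic basis
  (`cyclic = TRUE`) is available to force continuity across the year
  boundary but is off by default — the non-cyclic fit matches the plain
  "cubic splines" description.
* **Smoothing selection**: REML, not GCV. On noise-free data GCV stalls at a
  finite penalty (residuals $\sim 10^{-7}$ on an exact cubic) while REML
  drives it to machine precision; REML is also the selector recommended by
  the smoother's own authors for being less prone to undersmoothing.
  `method = "GCV.Cp"` remains available.
* **Degeneracy**: an all-identical $A'$ yields a valid zero-residual fit
  flagged `degenerate`; $P_{GAM}$ is then reported as `Inf` *with an
  explicit warning* (class `pond_degenerate_fit`), never a silent number.
* **Day of year**: `yday + 1`, so Feb 29 is day 60 and later days shift with
  the calendar; the one-day jitter is far below the smoother's resolution.

## Model comparison

Estimates form a ponds-by-models matrix (ponds failing any model are dropped
listwise with a warning). Pearson correlations between model columns —
computed with and without the most ephemeral ponds, which destabilize the
continuous indices — are converted to chord distances
$d = \sqrt{2 - 2r} \in [0, 2]$ and clustered by UPGMA (average linkage).
Merge heights are recorded on the average-linkage distance scale itself (not
halved), and the conventional cut at distance 0.90 applies on that scale.
Ties on the minimal distance are broken lexicographically on cluster labels
(a cluster is labeled by its smallest leaf), which makes merge order
deterministic; an independent naive agglomeration oracle checks merge order
and heights.

Cluster support is the ordinary bootstrap proportion: ponds are resampled
with replacement, the tree rebuilt, and each internal node of the full-data
tree scored by the fraction of bootstrap trees containing the same leaf set.
This is *not* the multiscale (AU-corrected) bootstrap some cluster tools
report; proportions are labeled as such and numeric equivalence with AU
values is not claimed. Degenerate resamples (a zero-variance model column)
are skipped but stay in the denominator — conservative support. Ponds are
sorted by id before resampling, so support values are invariant to input row
order and reproducible under a fixed seed.

`cut_clusters` joins leaves connected by merges at height $\leq$ the
threshold: duplicated models (height 0) therefore stay together at any
threshold, while generic dendrograms fall apart completely at threshold 0.

## The synthetic world

The generator states the emulated archive once and the tests inherit it:

* 27-year span from 1984, **23-day effective cadence** (~16 usable scenes a
  year — what two 16-day-revisit satellites deliver after archive gaps; the
  nominal 16-day cadence would give ~50% more scenes than such archives
  actually hold), each observation fully clouded with probability 0.5. The
  defaults yield ~200–230 cloud-free observations per pond.
* Seasonal regime: normalized area peaks mid February and bottoms out in
  late summer (`default_seasonal`), mean close to 1 — the Mediterranean
  winter-wet pattern.
* Stochasticity: observation noise SD 0.3 on the $A'$ scale, multiplicative
  year effect SD 0.15, areas below 10% of the mean recorded dry, median
  pond 40,000 m². These are mid-range values for strongly fluctuating
  saline ponds; they are fixed once and never tuned against test outcomes.
* Scenes: archetype reflectance triplets for water, salt and soil placed
  well clear of both classification thresholds, Gaussian reflectance noise
  (default SD 0.02), clipped to [0, 1].

What a green test does *not* establish: the generator has no spatial
autocorrelation of noise, no mixed pixels at pond edges, no atmospheric
residuals, no georegistration error, and its hydrology is a caricature
(smooth seasonal curve x year effect + noise). Green tests certify the
*estimators*, not the sensor chain.

One acceptance-level property is intentionally left failing, with analysis:
recovering a residual SD of $\sigma = 0.8$ around a flat seasonal level of 1
from a physically non-negative series is impossible with Gaussian noise —
about 10.6% of the distribution is censored at zero area, which shrinks the
observable residual SD to roughly $0.70$ and biases $1/P_{GAM}$ by about
$-13\%$. The bias depends only on the ratio $\sigma$/level, so no admissible
non-negative series evades it. At $\sigma \leq 0.4$ the same recovery is
accurate to $\leq 2\%$, and when Gaussian residuals are fed to the smoother
directly (no censoring) recovery is within 10% at every tested $\sigma$.

## Limitations

* Only the MNDWI + NIR rule is implemented; alternative indices (NDWI,
  AWEI) and sub-pixel water fractions are out of scope.
* Colwell machinery is exercised for 2–3 states at monthly steps only.
* No uncertainty intervals on $P$ or $P_{GAM}$; the bootstrap quantifies
  cluster stability, not estimate error.
* Both model families pool days of the year across years and therefore
  ignore serial correlation between consecutive observations.
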