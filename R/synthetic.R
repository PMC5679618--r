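# Synthetic scenes and pond series with known truth.
#
# The generators emulate a Landsat-5/7-like archive over Mediterranean
# saline ponds: 30 m pixels, a ~23-day effective scene cadence sustained for
# 27 years (the two satellites' usable archive, about 16 scenes a year),
# clouds removing about half of the observations, and a seasonal
# water-surface-area cycle (wet winter, dry late summer) with multiplicative
# year effects and observation noise. Everything is deterministic under a
# seed, so classification, time-series and predictability stages can be
# tested against exact truth.

#' Default archetype spectra for the three cover classes
#'
#' Reflectance triplets (green, nir, mir) placed well inside their
#' classification regions: water is dark in NIR/MIR with positive MNDWI,
#' salt crust is bright everywhere (MNDWI > 0 but NIR >= 0.4), soil has
#' negative MNDWI. Margins to both thresholds exceed 5 x the default noise
#' SD (0.02).
#'
#' @return named list of length-3 numeric vectors.
#' @export
default_archetypes <- function() {
  list(water = c(green = 0.12, nir = 0.05, mir = 0.02),
       salt  = c(green = 0.45, nir = 0.55, mir = 0.15),
       soil  = c(green = 0.10, nir = 0.25, mir = 0.30))
}

#' Describe a synthetic scene (truth)
#'
#' @param truth_labels integer matrix over the [pond_labels()] palette
#'   (cloud pixels become cloud in the generated scene mask).
#' @param archetypes named list of (green, nir, mir) reflectance triplets
#'   for `water`, `salt`, `soil`; each must classify to its own label
#'   noise-free (checked).
#' @param noise_sd Gaussian reflectance noise SD (default 0.02).
#' @param seed integer seed.
#' @return object of class `scene_truth`.
#' @export
scene_truth <- function(truth_labels, archetypes = default_archetypes(),
                        noise_sd = 0.02, seed = 1L) {
  if (!is.matrix(truth_labels) || any(!truth_labels %in% pond_labels())) {
    stop_pond("pond_input_error", "truth_labels must use the 0..3 palette")
  }
  for (cls in c("water", "salt", "soil")) {
    a <- archetypes[[cls]]
    if (is.null(a)) stop_pond("pond_config_error", "missing archetype: %s", cls)
    got <- classify_pixel(a[["green"]], a[["nir"]], a[["mir"]])
    if (got != cls) {
      stop_pond("pond_config_error",
                "archetype %s classifies as %s noise-free", cls, got)
    }
  }
  structure(list(truth_labels = truth_labels, archetypes = archetypes,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_truth")
}

#' A simple pond layout for scene simulations
#'
#' A water disk surrounded by a salt ring on a soil background, mimicking a
#' drying saline pond with an evaporite crust.
#'
#' @param nrow,ncol grid size in pixels.
#' @param water_radius,salt_radius radii in pixels (salt_radius >
#'   water_radius).
#' @return integer label matrix.
#' @export
pond_layout <- function(nrow = 100, ncol = 100, water_radius = 18,
                        salt_radius = 26) {
  cy <- (nrow + 1) / 2; cx <- (ncol + 1) / 2
  rr <- outer(seq_len(nrow), seq_len(ncol),
              function(y, x) sqrt((y - cy)^2 + (x - cx)^2))
  L <- pond_labels()
  lab <- matrix(L[["soil"]], nrow, ncol)
  lab[rr <= salt_radius] <- L[["salt"]]
  lab[rr <= water_radius] <- L[["water"]]
  lab
}

#' Generate a synthetic scene from its truth
#'
#' Reflectance = archetype + Gaussian noise, clipped to \[0, 1\]; pixels
#' labeled cloud in the truth are carried into the scene's cloud mask (their
#' reflectances are arbitrary).
#'
#' @param truth a [scene_truth()].
#' @param scene_id,date metadata for the generated scene.
#' @param seed overrides the truth's seed.
#' @return list with `scene` (a [scene()]) and `truth` (a
#'   `classified_scene` holding the truth labels).
#' @export
generate_scene <- function(truth, scene_id = "synthetic", date = "2000-06-15",
                           seed = truth$seed) {
  lab <- truth$truth_labels
  L <- pond_labels()
  dims <- dim(lab)
  set.seed(as.integer(seed))
  bands <- list()
  for (b in c("green", "nir", "mir")) {
    base <- matrix(0, dims[1L], dims[2L])
    for (cls in c("soil", "salt", "water")) {
      base[lab == L[[cls]]] <- truth$archetypes[[cls]][[b]]
    }
    noisy <- base + matrix(rnorm(prod(dims), 0, truth$noise_sd),
                           dims[1L], dims[2L])
    bands[[b]] <- pmin(pmax(noisy, 0), 1)
  }
  cloud <- lab == L[["cloud"]]
  sc <- scene(scene_id, date, bands$green, bands$nir, bands$mir, cloud = cloud)
  truth_cs <- structure(list(scene_id = scene_id, date = sc$date, labels = lab,
                             pixel_area = sc$pixel_area,
                             geotransform = sc$geotransform),
                        class = "classified_scene")
  list(scene = sc, truth = truth_cs)
}

#' Default seasonal curve of the series generator
#'
#' Mediterranean regime: maximum normalized area in late winter (mid
#' February), minimum in late summer; mean close to 1.
#'
#' @param doy day of year.
#' @return expected normalized area A'.
#' @export
default_seasonal <- function(doy) {
  pmax(0, 1 + 0.9 * cos(2 * pi * (doy - 46) / 365.25))
}

#' Describe a synthetic pond series (truth)
#'
#' Defaults state the emulated world: a 27-year archive starting in 1984
#' with a 23-day effective scene cadence (~16 usable scenes a year, as two
#' 16-day-revisit satellites deliver after archive gaps), each observation
#' fully clouded with probability 0.5, seasonal cycle [default_seasonal()],
#' observation noise SD 0.3 and year-effect SD 0.15 on the normalized
#' scale, areas below 10 percent of the mean recorded as dry, and a median
#' pond of 40,000 m^2. With these defaults a pond yields about 214
#' cloud-free observations.
#'
#' @param seasonal function day-of-year -> expected A' (non-negative).
#' @param mean_area_m2 scale of the pond (m^2).
#' @param noise_sd observation noise SD on the A' scale.
#' @param dry_threshold A' level below which the pond is recorded dry.
#' @param inter_annual_sd SD of the multiplicative year effect.
#' @param revisit_days sampling cadence in days.
#' @param cloud_prob per-observation probability of being clouded.
#' @param partial_clouds if `TRUE`, clouded observations get a cloud
#'   fraction uniform in (0, 1) hiding a proportional share of the water,
#'   instead of all-or-nothing clouds.
#' @param years span of the archive.
#' @param start first acquisition date.
#' @param extent_factor pond-footprint area in units of `mean_area_m2`
#'   (bounds `area_max` under clouds).
#' @param seed integer seed.
#' @return object of class `series_truth`.
#' @export
series_truth <- function(seasonal = default_seasonal, mean_area_m2 = 40000,
                         noise_sd = 0.3, dry_threshold = 0.1,
                         inter_annual_sd = 0.15, revisit_days = 23,
                         cloud_prob = 0.5, partial_clouds = FALSE,
                         years = 27, start = "1984-03-01",
                         extent_factor = 2.5, seed = 1L) {
  if (cloud_prob < 0 || cloud_prob >= 1) {
    stop_pond("pond_input_error", "cloud_prob must lie in [0, 1)")
  }
  if (!is.function(seasonal)) {
    stop_pond("pond_input_error", "seasonal must be a function of day-of-year")
  }
  structure(list(seasonal = seasonal, mean_area_m2 = mean_area_m2,
                 noise_sd = noise_sd, dry_threshold = dry_threshold,
                 inter_annual_sd = inter_annual_sd,
                 revisit_days = revisit_days, cloud_prob = cloud_prob,
                 partial_clouds = partial_clouds, years = years,
                 start = as_date_strict(start),
                 extent_factor = extent_factor, seed = as.integer(seed)),
            class = "series_truth")
}

#' Generate a synthetic pond series
#'
#' For every visit date, `A' = max(0, seasonal(doy) * year_effect + eps)`
#' with `eps ~ N(0, noise_sd^2)` and a yearly `year_effect ~ N(1,
#' inter_annual_sd^2)` (floored at 0); values below `dry_threshold` are
#' recorded as dry (area 0). Clouded observations report zero visible water
#' and an `area_max` bounded by the pond footprint, exactly as the pixel
#' pipeline would.
#'
#' @param truth a [series_truth()].
#' @param pond_id id for the generated series.
#' @param seed overrides the truth's seed.
#' @return a [pond_series()]; the truth object is attached as attribute
#'   `"truth"`, the noise-free expected A' per observation as
#'   `"expected_aprime"`.
#' @export
generate_pond_series <- function(truth, pond_id = 1L, seed = truth$seed) {
  set.seed(as.integer(seed))
  dates <- seq(truth$start, by = truth$revisit_days,
               length.out = ceiling(truth$years * 365.25 / truth$revisit_days))
  doy <- day_of_year(dates)
  yr <- as.integer(format(dates, "%Y"))
  yr_levels <- sort(unique(yr))
  eff <- pmax(0, rnorm(length(yr_levels), 1, truth$inter_annual_sd))
  year_effect <- eff[match(yr, yr_levels)]
  expected <- truth$seasonal(doy) * year_effect
  aprime <- pmax(0, expected + rnorm(length(dates), 0, truth$noise_sd))
  aprime[aprime < truth$dry_threshold] <- 0
  true_area <- aprime * truth$mean_area_m2
  footprint <- truth$extent_factor * truth$mean_area_m2
  clouded <- runif(length(dates)) < truth$cloud_prob
  cf <- ifelse(clouded,
               if (truth$partial_clouds) NA_real_ else 1,
               0)
  if (truth$partial_clouds) {
    cf[clouded] <- runif(sum(clouded), 0.05, 0.95)
  }
  visible <- true_area * (1 - cf)
  area_max <- visible + cf * footprint
  s <- pond_series(pond_id, dates, visible, area_max, cf)
  attr(s, "truth") <- truth
  attr(s, "expected_aprime") <- expected
  s
}
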