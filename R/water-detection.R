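# Two-condition assessment (2cA): MNDWI water candidacy + NIR salt filter.
#
# Saline ponds leave high-albedo salt crusts when they dry; a crust is bright
# in the green band and dark in the middle infrared, so it passes a band-ratio
# water index. The 2cA therefore screens in two steps: (1) MNDWI > 0 selects
# potentially water-covered pixels; (2) among those, NIR reflectance >= 0.4
# reclassifies the pixel as salt, the rest is water. The salt filter is only
# ever applied to pixels that passed the first condition.

#' Modified Normalized Difference Water Index
#'
#' `MNDWI = (green - mir) / (green + mir)`, in \[-1, 1\]. When both bands are
#' zero there is no signal and the index is defined as 0, which downstream
#' classification treats as non-water (conservative).
#'
#' @param green,mir reflectance values (scalars, vectors or matrices), >= 0.
#' @return numeric index, same shape as the inputs.
#' @export
mndwi <- function(green, mir) {
  if (any(green < 0, na.rm = TRUE) || any(mir < 0, na.rm = TRUE)) {
    stop_pond("pond_input_error", "reflectance must be non-negative")
  }
  den <- green + mir
  out <- ifelse(den == 0, 0, (green - mir) / den)
  if (is.matrix(green)) out <- matrix(out, nrow(green), ncol(green))
  out
}

#' Classify a pixel with the two-condition assessment
#'
#' Decision order: cloud flag wins; then `MNDWI <= mndwi_cut` is soil;
#' among water candidates, `NIR >= nir_salt_cut` is salt; the rest is water.
#' Water candidacy is strict (`MNDWI > 0`), and reflectance exactly at the
#' salt cut is salt ("lower than 0.4" is non-salt).
#'
#' @param green,nir,mir reflectances, >= 0; vectors are classified elementwise.
#' @param cloud logical, `TRUE` for unusable pixels.
#' @param mndwi_cut water-candidacy threshold on MNDWI (default 0).
#' @param nir_salt_cut NIR reflectance at and above which a water candidate is
#'   salt crust (default 0.4).
#' @return character vector of labels among `"soil"`, `"salt"`, `"water"`,
#'   `"cloud"`.
#' @export
classify_pixel <- function(green, nir, mir, cloud = FALSE,
                           mndwi_cut = 0, nir_salt_cut = 0.4) {
  if (any(nir < 0, na.rm = TRUE)) {
    stop_pond("pond_input_error", "reflectance must be non-negative")
  }
  idx <- mndwi(green, mir)
  n <- length(idx)
  cloud <- rep_len(as.logical(cloud), n)
  lab <- rep("soil", n)
  cand <- idx > mndwi_cut
  lab[cand & rep_len(nir, n) >= nir_salt_cut] <- "salt"
  lab[cand & rep_len(nir, n) < nir_salt_cut] <- "water"
  lab[cloud] <- "cloud"
  lab
}

#' Classify a whole scene
#'
#' Applies [classify_pixel()] elementwise to a scene; the grid result is, by
#' construction and by test, identical to the per-pixel rule.
#'
#' @param x a [scene()].
#' @param mndwi_cut,nir_salt_cut thresholds, see [classify_pixel()].
#' @param salt_filter set `FALSE` to disable the second condition (all water
#'   candidates become water); used to study the effect of the salt filter.
#' @return a `classified_scene`: integer label grid using [pond_labels()],
#'   plus scene metadata.
#' @export
classify_scene <- function(x, mndwi_cut = 0, nir_salt_cut = 0.4,
                           salt_filter = TRUE) {
  if (!inherits(x, "pond_scene")) stop_pond("pond_input_error", "not a pond_scene")
  idx <- mndwi(x$green, x$mir)
  L <- pond_labels()
  lab <- matrix(L[["soil"]], nrow(idx), ncol(idx))
  cand <- idx > mndwi_cut
  if (salt_filter) {
    lab[cand & x$nir >= nir_salt_cut] <- L[["salt"]]
    lab[cand & x$nir < nir_salt_cut] <- L[["water"]]
  } else {
    lab[cand] <- L[["water"]]
  }
  lab[x$cloud] <- L[["cloud"]]
  structure(list(scene_id = x$scene_id, date = x$date, labels = lab,
                 pixel_area = x$pixel_area, geotransform = x$geotransform),
            class = "classified_scene")
}

#' @export
print.classified_scene <- function(x, ...) {
  tab <- table(factor(x$labels, levels = pond_labels(),
                      labels = names(pond_labels())))
  cat(sprintf("<classified_scene> %s  %s\n", x$scene_id,
              if (inherits(x$date, "Date")) format(x$date) else "<no date>"))
  print(tab)
  invisible(x)
}

#' Water-surface area of one pond in one classified scene
#'
#' `area` counts only water-labeled pixels (clouded pixels count as
#' non-water); `area_max` additionally counts the clouded pixels inside the
#' pond, so `[area, area_max]` brackets the true area whatever the clouds
#' hide. Downstream state assignment uses the interval to decide whether an
#' observation is usable.
#'
#' @param classified a `classified_scene`.
#' @param mask a [pond_mask()] aligned with the scene.
#' @param pond_id pond to measure (must be present in the mask).
#' @param pixel_area m^2 per pixel; defaults to the scene's.
#' @return one-row data.frame: `pond_id`, `date`, `area_m2`, `area_max_m2`,
#'   `cloud_fraction`.
#' @export
pond_area <- function(classified, mask, pond_id, pixel_area = NULL) {
  if (!pond_id %in% mask$pond_ids) {
    stop_pond("pond_input_error", "unknown pond_id: %s", pond_id)
  }
  if (!identical(dim(mask$labels), dim(classified$labels))) {
    stop_pond("pond_alignment_error", "mask and scene shapes differ")
  }
  pixel_area <- pixel_area %||% classified$pixel_area
  L <- pond_labels()
  inside <- mask$labels == pond_id
  lab <- classified$labels[inside]
  n_water <- sum(lab == L[["water"]])
  n_cloud <- sum(lab == L[["cloud"]])
  data.frame(pond_id = pond_id, date = classified$date,
             area_m2 = n_water * pixel_area,
             area_max_m2 = (n_water + n_cloud) * pixel_area,
             cloud_fraction = n_cloud / length(lab))
}

#' Extract all pond areas from a stack of classified scenes
#'
#' @param classified_list list of `classified_scene` objects.
#' @param mask a [pond_mask()]; must contain at least one pond.
#' @return data.frame of per-pond, per-date observations (long format).
#' @export
pond_areas <- function(classified_list, mask) {
  if (length(mask$pond_ids) == 0L) {
    stop_pond("pond_input_error", "pond mask contains no ponds")
  }
  if (length(classified_list) == 0L) {
    stop_pond("pond_input_error", "empty scene stack")
  }
  rows <- lapply(classified_list, function(cs) {
    do.call(rbind, lapply(mask$pond_ids, function(id) pond_area(cs, mask, id)))
  })
  out <- do.call(rbind, rows)
  out[order(out$pond_id, out$date), , drop = FALSE]
}

#' Per-pixel water frequency across a scene stack
#'
#' For each pixel, the proportion of scenes in which it was labeled water
#' among the scenes in which it was usable (not cloud). Pixels clouded in
#' every scene get `NA` (undefined).
#'
#' @param stack list of `classified_scene` objects with identical shapes.
#' @param mask optional [pond_mask()]; only used to check alignment.
#' @return numeric matrix of fractions in \[0, 1\] (or `NA`).
#' @export
water_frequency_map <- function(stack, mask = NULL) {
  if (length(stack) == 0L) stop_pond("pond_input_error", "empty scene stack")
  dims <- dim(stack[[1L]]$labels)
  L <- pond_labels()
  water <- matrix(0L, dims[1L], dims[2L])
  seen <- matrix(0L, dims[1L], dims[2L])
  for (cs in stack) {
    if (!identical(dim(cs$labels), dims)) {
      stop_pond("pond_alignment_error", "scene shapes differ within stack")
    }
    water <- water + (cs$labels == L[["water"]])
    seen <- seen + (cs$labels != L[["cloud"]])
  }
  if (!is.null(mask) && !identical(dim(mask$labels), dims)) {
    stop_pond("pond_alignment_error", "mask shape differs from stack")
  }
  out <- water / seen
  out[seen == 0L] <- NA_real_
  out
}
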