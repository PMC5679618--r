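# Scenes, pond masks and classified-label rasters.

#' Label palette for classified scenes
#'
#' Classified rasters use a fixed integer palette: 0 soil, 1 salt, 2 water,
#' 3 cloud (cloud also covers nodata: the two are merged into a single
#' "unusable" channel, since nothing downstream distinguishes them).
#'
#' @return named integer vector `c(soil = 0, salt = 1, water = 2, cloud = 3)`.
#' @export
pond_labels <- function() {
  c(soil = 0L, salt = 1L, water = 2L, cloud = 3L)
}

#' Construct a Scene
#'
#' A scene is one dated multiband surface-reflectance raster: green
#' (0.52-0.60 um), NIR (0.76-0.90 um) and MIR (1.55-1.75 um) grids in
#' reflectance units (expected range 0-1), plus a logical cloud grid marking
#' unusable pixels.
#'
#' @param scene_id character identifier.
#' @param date acquisition date (`Date` or ISO-8601 string).
#' @param green,nir,mir numeric reflectance matrices of identical shape.
#' @param cloud logical matrix (`TRUE` = unusable); defaults to all clear.
#' @param pixel_area area of one pixel in m^2 (default 900 = 30 m x 30 m).
#' @param geotransform list with `xll`, `yll`, `cellsize`; when supplied,
#'   `pixel_area` is derived from `cellsize^2`.
#' @return an object of class `pond_scene`.
#' @export
scene <- function(scene_id, date, green, nir, mir, cloud = NULL,
                  pixel_area = 900, geotransform = NULL) {
  date <- as_date_strict(date)
  if (length(date) != 1L) stop_pond("pond_input_error", "scene needs exactly one date")
  dims <- dim(green)
  for (b in list(nir, mir)) {
    if (!identical(dim(b), dims)) {
      stop_pond("pond_alignment_error", "scene bands have mismatched shapes")
    }
  }
  if (is.null(cloud)) cloud <- matrix(FALSE, dims[1L], dims[2L])
  if (!identical(dim(cloud), dims)) {
    stop_pond("pond_alignment_error", "cloud mask shape differs from bands")
  }
  if (!is.null(geotransform)) pixel_area <- geotransform$cellsize^2
  if (!is.numeric(pixel_area) || pixel_area <= 0) {
    stop_pond("pond_input_error", "pixel_area must be > 0")
  }
  structure(list(scene_id = as.character(scene_id), date = date,
                 green = green, nir = nir, mir = mir,
                 cloud = cloud > 0, pixel_area = pixel_area,
                 geotransform = geotransform %||%
                   list(xll = 0, yll = 0, cellsize = sqrt(pixel_area))),
            class = "pond_scene")
}

#' @export
print.pond_scene <- function(x, ...) {
  cat(sprintf("<pond_scene> %s  %s  %dx%d px  %.0f m2/px  %.1f%% unusable\n",
              x$scene_id, format(x$date), nrow(x$green), ncol(x$green),
              x$pixel_area, 100 * mean(x$cloud)))
  invisible(x)
}

#' Read a dated multiband scene from ASCII grids
#'
#' Band files are located from `band_map`: integer entries `k` resolve to
#' `<path>_band<k>.asc` (with `path` acting as a prefix), character entries
#' are taken as file paths. Pixels that are nodata in any band, or outside
#' the valid reflectance range \[0, 1\] after scaling, are flagged as cloud
#' (unusable) and never reach the classifier.
#'
#' @param path scene prefix (see above).
#' @param band_map named vector mapping the semantic band names `green`,
#'   `nir`, `mir` to band indices or file paths.
#' @param date acquisition date (`Date` or ISO string).
#' @param cloud optional path to a cloud-mask ASCII grid (non-zero = cloud);
#'   absent means all-clear.
#' @param scale factor applied to stored values to reach reflectance units;
#'   use `1e-4` for products stored as reflectance x 10,000.
#' @return a [scene()] object.
#' @export
read_scene <- function(path, band_map, date, cloud = NULL, scale = 1) {
  need <- c("green", "nir", "mir")
  if (is.null(names(band_map)) || !all(need %in% names(band_map))) {
    stop_pond("pond_config_error",
              "band_map must name all of: %s", paste(need, collapse = ", "))
  }
  band_file <- function(b) {
    v <- band_map[[b]]
    if (is.character(v)) v else sprintf("%s_band%d.asc", path, as.integer(v))
  }
  grids <- lapply(need, function(b) read_ascii_grid(band_file(b)))
  names(grids) <- need
  dims <- dim(grids$green$values)
  for (b in need[-1L]) {
    if (!identical(dim(grids[[b]]$values), dims)) {
      stop_pond("pond_alignment_error", "band %s shape differs", b)
    }
  }
  bands <- lapply(grids, function(g) g$values * scale)
  unusable <- Reduce(`|`, lapply(bands, function(v) is.na(v) | v < 0 | v > 1))
  if (!is.null(cloud)) {
    cm <- read_ascii_grid(cloud)$values
    if (!identical(dim(cm), dims)) {
      stop_pond("pond_alignment_error", "cloud mask shape differs from bands")
    }
    unusable <- unusable | (!is.na(cm) & cm != 0) | is.na(cm)
  }
  # unusable pixels keep finite placeholders; the cloud flag shields them
  bands <- lapply(bands, function(v) { v[is.na(v)] <- 0; pmin(pmax(v, 0), 1) })
  g <- grids$green
  scene(scene_id = basename(path), date = date,
        green = bands$green, nir = bands$nir, mir = bands$mir,
        cloud = unusable,
        geotransform = list(xll = g$xll, yll = g$yll, cellsize = g$cellsize))
}

#' Construct a pond mask
#'
#' @param labels integer matrix; 0 = background, k > 0 = pixels of pond k.
#' @return an object of class `pond_mask` with `labels` and the sorted
#'   `pond_ids` present.
#' @export
pond_mask <- function(labels) {
  if (!is.matrix(labels)) stop_pond("pond_input_error", "labels must be a matrix")
  if (any(is.na(labels)) || any(labels != round(labels)) || any(labels < 0)) {
    stop_pond("pond_input_error", "pond mask must contain non-negative integers")
  }
  mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  structure(list(labels = labels, pond_ids = as.integer(ids)),
            class = "pond_mask")
}

#' Read a pond mask raster
#'
#' @param path ASCII grid of integer pond labels (0 = background).
#' @return a [pond_mask()].
#' @export
read_pond_mask <- function(path) {
  g <- read_ascii_grid(path)
  v <- g$values
  if (any(is.na(v))) v[is.na(v)] <- 0
  if (any(abs(v - round(v)) > 1e-9)) {
    stop_pond("pond_input_error", "pond mask raster is not integer-valued")
  }
  pond_mask(matrix(as.integer(round(v)), nrow(v), ncol(v)))
}

#' Write a classified-label raster
#'
#' Writes the label grid of a classified scene as a single-band integer
#' ASCII grid using the palette of [pond_labels()].
#'
#' @param labels a `classified_scene` (from [classify_scene()]) or an
#'   integer matrix with values in 0-3.
#' @param path output `.asc` path.
#' @export
write_labels <- function(labels, path) {
  gt <- NULL
  if (inherits(labels, "classified_scene")) {
    gt <- labels$geotransform
    labels <- labels$labels
  }
  if (!is.matrix(labels) || any(is.na(labels)) ||
      any(labels != round(labels)) || any(labels < 0) || any(labels > 3)) {
    stop_pond("pond_input_error", "labels must be integers in 0..3")
  }
  gt <- gt %||% list(xll = 0, yll = 0, cellsize = 30)
  write_ascii_grid(matrix(as.integer(labels), nrow(labels), ncol(labels)),
                   path, xll = gt$xll, yll = gt$yll, cellsize = gt$cellsize)
}

#' Read back a classified-label raster
#'
#' @param path `.asc` file written by [write_labels()].
#' @param scene_id,date metadata to attach (defaults parsed from filename
#'   are not attempted).
#' @return a `classified_scene`.
#' @export
read_labels <- function(path, scene_id = basename(path), date = NA) {
  g <- read_ascii_grid(path)
  v <- g$values
  if (any(is.na(v)) || any(v != round(v)) || any(v < 0) || any(v > 3)) {
    stop_pond("pond_input_error", "label raster has values outside 0..3")
  }
  structure(list(scene_id = scene_id,
                 date = if (all(is.na(date))) NA else as_date_strict(date),
                 labels = matrix(as.integer(v), nrow(v), ncol(v)),
                 pixel_area = g$cellsize^2,
                 geotransform = list(xll = g$xll, yll = g$yll,
                                     cellsize = g$cellsize)),
            class = "classified_scene")
}

#' Read a scene manifest
#'
#' A manifest is a CSV with columns `scene_id`, `path`, `date` listing the
#' scenes of an archive; dates are ISO-8601.
#'
#' @param path CSV file.
#' @return data.frame with parsed dates, sorted by date.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_pond("pond_io_error", "manifest not found: %s", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("scene_id", "path", "date")
  if (!all(need %in% names(m))) {
    stop_pond("pond_config_error", "manifest needs columns: %s",
              paste(need, collapse = ", "))
  }
  m$date <- as_date_strict(m$date)
  m[order(m$date), , drop = FALSE]
}
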