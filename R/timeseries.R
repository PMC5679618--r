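# Per-pond observation series and the monthly-balanced summaries.
#
# All long-run summaries are balanced over the 12 calendar months first, so
# that an archive with more summer than winter scenes does not bias the mean
# area or the hydroperiod. "Cloud-free" always means cloud_fraction == 0.

#' Construct a pond observation series
#'
#' @param pond_id integer pond identifier.
#' @param date observation dates (`Date` or ISO strings); must be strictly
#'   increasing after sorting (no duplicate dates).
#' @param area water-surface areas in m^2 (clouds counted as non-water).
#' @param area_max upper bound: area if every clouded pixel were water;
#'   defaults to `area` (no clouds).
#' @param cloud_fraction fraction of pond pixels clouded, in \[0, 1\].
#' @return object of class `pond_series`.
#' @export
pond_series <- function(pond_id, date, area, area_max = area,
                        cloud_fraction = 0) {
  date <- as_date_strict(date)
  n <- length(date)
  area <- rep_len(area, n)
  area_max <- rep_len(area_max, n)
  cloud_fraction <- rep_len(cloud_fraction, n)
  o <- order(date)
  date <- date[o]; area <- area[o]; area_max <- area_max[o]
  cloud_fraction <- cloud_fraction[o]
  if (n > 1L && any(diff(as.numeric(date)) <= 0)) {
    stop_pond("pond_input_error", "dates must be strictly increasing")
  }
  if (any(area < 0) || any(area_max < area - 1e-9)) {
    stop_pond("pond_input_error", "need 0 <= area <= area_max")
  }
  if (any(cloud_fraction < 0) || any(cloud_fraction > 1)) {
    stop_pond("pond_input_error", "cloud_fraction must lie in [0, 1]")
  }
  if (any(cloud_fraction == 0 & abs(area_max - area) > 1e-9)) {
    stop_pond("pond_input_error",
              "cloud_fraction 0 observations must have area == area_max")
  }
  obs <- data.frame(pond_id = as.integer(pond_id), date = date,
                    area_m2 = area, area_max_m2 = area_max,
                    cloud_fraction = cloud_fraction)
  structure(list(pond_id = as.integer(pond_id), observations = obs,
                 span = range(as.integer(format(date, "%Y")))),
            class = "pond_series")
}

#' @export
print.pond_series <- function(x, ...) {
  o <- x$observations
  cat(sprintf("<pond_series> pond %d  %d obs (%d cloud-free)  %d-%d\n",
              x$pond_id, nrow(o), sum(o$cloud_fraction == 0),
              x$span[1L], x$span[2L]))
  invisible(x)
}

#' Read pond series from an areas CSV
#'
#' Expects columns `pond_id`, `date`, `area_m2` and optionally
#' `area_max_m2`, `cloud_fraction` (both default to the cloud-free case).
#'
#' @param path CSV file as written by [pond_areas()] / the `areas` CLI step.
#' @return named list of [pond_series()], one per pond.
#' @export
series_from_csv <- function(path) {
  if (!file.exists(path)) stop_pond("pond_io_error", "areas file not found: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pond_id", "date", "area_m2")
  if (!all(need %in% names(d))) {
    stop_pond("pond_config_error", "areas CSV needs columns: %s",
              paste(need, collapse = ", "))
  }
  if (is.null(d$area_max_m2)) d$area_max_m2 <- d$area_m2
  if (is.null(d$cloud_fraction)) d$cloud_fraction <- 0
  out <- lapply(split(d, d$pond_id), function(p) {
    pond_series(p$pond_id[1L], p$date, p$area_m2, p$area_max_m2,
                p$cloud_fraction)
  })
  names(out) <- vapply(out, function(s) as.character(s$pond_id), "")
  out
}

cloudfree_obs <- function(series) {
  o <- series$observations
  o[o$cloud_fraction == 0, , drop = FALSE]
}

#' Monthly-balanced mean water-surface area
#'
#' For each calendar month, the mean area over that month's cloud-free
#' observations is taken; the returned value is the mean over months having
#' data. With `exclude_zeros = TRUE`, dry observations (area = 0) are left
#' out before averaging (water-only mean).
#'
#' @param series a [pond_series()].
#' @param exclude_zeros drop area = 0 observations first.
#' @return mean area in m^2.
#' @export
mean_area <- function(series, exclude_zeros = FALSE) {
  o <- cloudfree_obs(series)
  if (exclude_zeros) o <- o[o$area_m2 > 0, , drop = FALSE]
  if (nrow(o) == 0L) {
    stop_pond("pond_estimation_error", "no qualifying observations for mean area")
  }
  month <- as.integer(format(o$date, "%m"))
  mean(tapply(o$area_m2, month, mean))
}

#' Annual hydroperiod
#'
#' For each calendar month, the fraction of its cloud-free observations with
#' area > 0; the hydroperiod is the average of those fractions over months
#' having data. 1 means the pond was wet in every usable observation, 0 that
#' it never was.
#'
#' @param series a [pond_series()].
#' @return fraction in \[0, 1\].
#' @export
hydroperiod <- function(series) {
  o <- cloudfree_obs(series)
  if (nrow(o) == 0L) {
    stop_pond("pond_estimation_error", "no cloud-free observations")
  }
  month <- as.integer(format(o$date, "%m"))
  mean(tapply(o$area_m2 > 0, month, mean))
}

#' Aggregate a series to one value per (year, month)
#'
#' Within each observed (year, month), only the observations with the lowest
#' cloud cover of that month are retained (all of them when tied) and their
#' areas averaged. Months never observed are absent from the output, not
#' imputed.
#'
#' @param series a [pond_series()].
#' @return data.frame with `year`, `month`, `area_m2`, `area_max_m2`,
#'   `cloud_fraction` (the month's minimum) and `basis` (number of
#'   observations averaged), sorted by year then month.
#' @export
monthly_series <- function(series) {
  o <- series$observations
  if (nrow(o) == 0L) {
    return(data.frame(year = integer(), month = integer(), area_m2 = numeric(),
                      area_max_m2 = numeric(), cloud_fraction = numeric(),
                      basis = integer()))
  }
  key <- format(o$date, "%Y-%m")
  parts <- split(o, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    cf <- min(p$cloud_fraction)
    sel <- p[p$cloud_fraction == cf, , drop = FALSE]
    data.frame(year = as.integer(format(sel$date[1L], "%Y")),
               month = as.integer(format(sel$date[1L], "%m")),
               area_m2 = mean(sel$area_m2),
               area_max_m2 = mean(sel$area_max_m2),
               cloud_fraction = cf, basis = nrow(sel))
  }))
  rownames(out) <- NULL
  out[order(out$year, out$month), , drop = FALSE]
}

#' Normalize a series to relative area vs day of year
#'
#' Keeps cloud-free observations only and returns `A' = area / mean` against
#' the observation's day of year. With the all-data mean, the mean of A'
#' approaches 1.
#'
#' @param series a [pond_series()].
#' @param mean_area_m2 normalizing mean (> 0), typically from [mean_area()].
#' @return data.frame with `doy` (1-366) and `aprime`.
#' @export
normalize_series <- function(series, mean_area_m2) {
  if (!is.numeric(mean_area_m2) || mean_area_m2 <= 0) {
    stop_pond("pond_input_error", "normalizing mean must be > 0")
  }
  o <- cloudfree_obs(series)
  data.frame(doy = day_of_year(o$date), aprime = o$area_m2 / mean_area_m2)
}
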