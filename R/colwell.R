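# Colwell's predictability on month-by-state contingency tables, and the
# five discrete state-definition models.
#
# The index decomposes predictability P into constancy C (the pond stays in
# one state year-round) and contingency M (the state is a repeatable function
# of the month). With counts N[i, j] for state i in calendar month j, column
# sums X_j, row sums Y_i, grand total Z and s states:
#   H(X)  = -sum_j (X_j/Z) log(X_j/Z)
#   H(Y)  = -sum_i (Y_i/Z) log(Y_i/Z)
#   H(XY) = -sum_ij (N_ij/Z) log(N_ij/Z)
#   C = 1 - H(Y)/log s,  M = (H(X) + H(Y) - H(XY))/log s,
#   P = 1 - (H(XY) - H(X))/log s = C + M,
# with 0 log 0 = 0. The normalization by log s makes the metrics independent
# of the logarithm base.

DISCRETE_MODELS <- c("COL_wd", "COL_ANa", "COL_ANw", "COL_MAXlin", "COL_MAXg")
CONTINUOUS_MODELS <- c("GAM_a", "GAM_w")
ALL_MODELS <- c("COL_wd", "GAM_a", "COL_ANa", "GAM_w", "COL_ANw",
                "COL_MAXg", "COL_MAXlin")

#' Discrete state-model specifications
#'
#' The five supported state definitions:
#' \describe{
#'   \item{COL_wd}{water/dry, 2 states: s1 if A = 0, s2 if A > 0.}
#'   \item{COL_ANa}{average neighborhood, all data: s1 if A < 0.3 Abar,
#'     s2 if 0.3 Abar <= A <= 1.7 Abar, s3 above (Abar +/- 70 percent).}
#'   \item{COL_ANw}{as COL_ANa but dry monthly values are excluded and the
#'     mean is computed over wet observations only.}
#'   \item{COL_MAXlin}{thirds of the maximum: breaks at 1/3 and 2/3 MAX(A).}
#'   \item{COL_MAXg}{geometric partition of the maximum: breaks at 1/4 and
#'     2/4 MAX(A).}
#' }
#' The middle state is closed on both ends; the reference value (mean or
#' maximum) scales with the data, which makes every model invariant to a
#' multiplicative rescaling of areas.
#'
#' @param name one of `COL_wd`, `COL_ANa`, `COL_ANw`, `COL_MAXlin`,
#'   `COL_MAXg`.
#' @param neighborhood half-width of the COL_AN* tolerance band as a
#'   fraction of the mean (default 0.7).
#' @return a `state_model_spec` list: `name`, `n_states`, `reference`
#'   (`"none"`, `"mean"` or `"max"`), `thresholds` (break fractions of the
#'   reference), `exclude_dry`.
#' @export
state_model_spec <- function(name, neighborhood = 0.7) {
  name <- match.arg(name, DISCRETE_MODELS)
  spec <- switch(name,
    COL_wd     = list(n_states = 2L, reference = "none",
                      thresholds = numeric(), exclude_dry = FALSE),
    # breaks computed in tenths so that e.g. 1 - 0.7 is exactly 0.3
    COL_ANa    = list(n_states = 3L, reference = "mean",
                      thresholds = c(10 - 10 * neighborhood,
                                     10 + 10 * neighborhood) / 10,
                      exclude_dry = FALSE),
    COL_ANw    = list(n_states = 3L, reference = "mean",
                      thresholds = c(10 - 10 * neighborhood,
                                     10 + 10 * neighborhood) / 10,
                      exclude_dry = TRUE),
    COL_MAXlin = list(n_states = 3L, reference = "max",
                      thresholds = c(1 / 3, 2 / 3), exclude_dry = FALSE),
    COL_MAXg   = list(n_states = 3L, reference = "max",
                      thresholds = c(1 / 4, 2 / 4), exclude_dry = FALSE))
  if (is.unsorted(spec$thresholds, strictly = TRUE)) {
    stop_pond("pond_config_error", "thresholds must be strictly increasing")
  }
  structure(c(list(name = name), spec), class = "state_model_spec")
}

# state of a single area value under a spec (no interval logic)
state_of <- function(area, spec, reference_value) {
  if (spec$name == "COL_wd") return(ifelse(area == 0, 1L, 2L))
  b <- spec$thresholds * reference_value
  ifelse(area < b[1L], 1L, ifelse(area <= b[2L], 2L, 3L))
}

#' Cloud-safe state assignment
#'
#' Assigns the state of an observation from its area interval: the state is
#' accepted only if the lower bound (`area`) and the upper bound
#' (`area_max`, clouds counted as water) fall in the same state; otherwise
#' the observation is excluded (`NA`), because the clouded part of the pond
#' could change the state.
#'
#' @param area,area_max area interval in m^2 (vectors allowed).
#' @param spec a [state_model_spec()].
#' @param reference_value mean or maximum area (m^2) for the threshold-based
#'   models; must be > 0 for those; ignored for COL_wd.
#' @return integer state (1-based) or `NA` for excluded observations.
#' @export
assign_state <- function(area, area_max, spec, reference_value = NULL) {
  if (spec$reference != "none") {
    if (is.null(reference_value) || !is.numeric(reference_value) ||
        reference_value <= 0) {
      stop_pond("pond_input_error",
                "%s needs a positive reference value", spec$name)
    }
  }
  if (any(area_max < area - 1e-9)) {
    stop_pond("pond_input_error", "need area <= area_max")
  }
  lo <- state_of(area, spec, reference_value)
  hi <- state_of(area_max, spec, reference_value)
  ifelse(lo == hi, lo, NA_integer_)
}

#' Build the month-by-state contingency table of a series
#'
#' The series is aggregated to one value per (year, month) with
#' [monthly_series()]; each monthly value is assigned a state with the
#' cloud-interval safety rule; years are treated as replicates, so counts
#' accumulate over years into an `n_states` x 12 table. For COL_ANw, dry
#' monthly values (area = 0) are dropped before tabulation.
#'
#' @param series a [pond_series()].
#' @param spec a [state_model_spec()].
#' @param reference_value reference area (m^2), see [assign_state()].
#' @return object of class `contingency_table`: integer matrix (states x
#'   months) with attributes `pond_id` and `model`.
#' @export
build_table <- function(series, spec, reference_value = NULL) {
  ms <- monthly_series(series)
  if (nrow(ms) == 0L) {
    stop_pond("pond_estimation_error", "series has no observations")
  }
  if (spec$exclude_dry) ms <- ms[ms$area_m2 > 0, , drop = FALSE]
  st <- if (nrow(ms)) {
    assign_state(ms$area_m2, ms$area_max_m2, spec, reference_value)
  } else integer()
  keep <- !is.na(st)
  if (!any(keep)) {
    stop_pond("pond_estimation_error",
              "all monthly observations excluded under %s", spec$name)
  }
  counts <- matrix(0L, spec$n_states, 12L,
                   dimnames = list(state = paste0("s", seq_len(spec$n_states)),
                                   month = month.abb))
  for (i in which(keep)) {
    counts[st[i], ms$month[i]] <- counts[st[i], ms$month[i]] + 1L
  }
  structure(counts, class = c("contingency_table", class(counts)),
            pond_id = series$pond_id, model = spec$name)
}

#' Colwell's constancy, contingency and predictability
#'
#' @param counts a states x months count matrix (rows = states); the number
#'   of states is taken from `nrow(counts)`.
#' @return object of class `colwell_result`: list with `constancy`,
#'   `contingency`, `predictability` (each in \[0, 1\], predictability =
#'   constancy + contingency) and the input `table`.
#' @export
colwell_metrics <- function(counts) {
  counts <- unclass(counts)
  if (!is.matrix(counts) || any(counts < 0)) {
    stop_pond("pond_input_error", "counts must be a non-negative matrix")
  }
  Z <- sum(counts)
  if (Z < 1) stop_pond("pond_input_error", "contingency table has zero total")
  s <- nrow(counts)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  HX <- ent(colSums(counts) / Z)
  HY <- ent(rowSums(counts) / Z)
  HXY <- ent(counts / Z)
  C <- 1 - HY / log(s)
  M <- (HX + HY - HXY) / log(s)
  clamp <- function(v) min(max(v, 0), 1)
  C <- clamp(C); M <- clamp(M)
  structure(list(constancy = C, contingency = M,
                 predictability = clamp(C + M), table = counts),
            class = "colwell_result")
}

#' @export
print.colwell_result <- function(x, ...) {
  cat(sprintf("Colwell P = %.3f  (constancy %.3f + contingency %.3f)\n",
              x$predictability, x$constancy, x$contingency))
  invisible(x)
}

#' Run one discrete predictability model on a series
#'
#' Resolves the model's reference value (the monthly-balanced mean area for
#' COL_ANa; the wet-only mean for COL_ANw; the maximum cloud-free observed
#' area for the COL_MAX models), builds the contingency table and computes
#' the Colwell metrics.
#'
#' @param series a [pond_series()].
#' @param name model name, see [state_model_spec()].
#' @param neighborhood COL_AN* band half-width (default 0.7).
#' @param anw_mean_all use the all-data mean instead of the wet-only mean
#'   for COL_ANw (default `FALSE`).
#' @return object of class `predictability_estimate`: `pond_id`, `model`,
#'   `predictability`, `constancy`, `contingency`, `n_months_used` (number
#'   of tabulated year-months) and the table.
#' @export
run_discrete_model <- function(series, name, neighborhood = 0.7,
                               anw_mean_all = FALSE) {
  spec <- state_model_spec(name, neighborhood = neighborhood)
  ref <- switch(spec$reference,
    none = NULL,
    mean = mean_area(series,
                     exclude_zeros = spec$exclude_dry && !anw_mean_all),
    max  = {
      o <- cloudfree_obs(series)
      if (nrow(o) == 0L) {
        stop_pond("pond_estimation_error", "no cloud-free observations")
      }
      mx <- max(o$area_m2)
      if (mx <= 0) stop_pond("pond_estimation_error",
                             "maximum observed area is zero; %s undefined", name)
      mx
    })
  tab <- build_table(series, spec, ref)
  met <- colwell_metrics(tab)
  structure(list(pond_id = series$pond_id, model = name,
                 predictability = met$predictability,
                 constancy = met$constancy, contingency = met$contingency,
                 n_months_used = sum(tab), reference_value = ref,
                 table = tab),
            class = "predictability_estimate")
}

#' @export
print.predictability_estimate <- function(x, ...) {
  cat(sprintf("pond %d  %-10s P = %.3f (C %.3f, M %.3f, n = %d)\n",
              x$pond_id, x$model, x$predictability, x$constancy,
              x$contingency, x$n_months_used))
  invisible(x)
}
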