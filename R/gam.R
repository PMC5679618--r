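# Continuous predictability: seasonal spline fit and P_GAM = 1 / SD_res.
#
# The typical intra-annual curve is a penalized cubic-spline regression of
# the normalized area A' on day of year; predictability is the reciprocal of
# the standard deviation of the residuals around that curve. Because A' has
# mean ~1 (when zeros enter the mean), P_GAM is approximately the inverse
# coefficient of variation about the seasonal curve.

#' Fit the seasonal curve to normalized area
#'
#' Penalized least-squares cubic-spline fit of A' on day of year, smoothing
#' parameter selected by REML (default; GCV available). The default basis is
#' the cubic B-spline (`"bs"`), which spans cubic polynomials exactly; a
#' cyclic basis (`"cc"`) can be requested to force curve continuity across
#' the year boundary.
#'
#' @param doy day of year, 1-366.
#' @param aprime normalized areas A'.
#' @param k spline basis dimension (default 8).
#' @param cyclic use a cyclic cubic basis (default `FALSE`).
#' @param method smoothing selection, `"REML"` (default) or `"GCV.Cp"`.
#' @return object of class `seasonal_fit`: `fitted`, `residuals`, `n_obs`,
#'   `degenerate` flag, the mgcv model (`NULL` for degenerate input), plus
#'   the inputs and settings.
#' @export
fit_seasonal_curve <- function(doy, aprime, k = 8, cyclic = FALSE,
                               method = c("REML", "GCV.Cp")) {
  method <- match.arg(method)
  if (length(doy) != length(aprime)) {
    stop_pond("pond_input_error", "doy and aprime lengths differ")
  }
  if (any(doy < 1 | doy > 366)) {
    stop_pond("pond_input_error", "day of year must lie in [1, 366]")
  }
  n <- length(aprime)
  n_distinct <- length(unique(doy))
  if (n < 3L || n_distinct < 2L * k) {
    stop_pond("pond_estimation_error",
              "too few points for a k = %d seasonal fit (%d distinct days)",
              k, n_distinct)
  }
  degenerate <- sd(aprime) == 0
  if (degenerate) {
    # all-identical response: the curve is that constant, residuals are zero
    fit <- list(model = NULL, fitted = rep(aprime[1L], n),
                residuals = rep(0, n))
  } else {
    bs <- if (cyclic) "cc" else "bs"
    d <- data.frame(doy = doy, aprime = aprime)
    m <- mgcv::gam(aprime ~ s(doy, k = k, bs = bs), data = d, method = method)
    fit <- list(model = m, fitted = as.numeric(fitted(m)),
                residuals = as.numeric(residuals(m)))
  }
  structure(c(fit, list(n_obs = n, k = k, cyclic = cyclic, method = method,
                        doy = doy, aprime = aprime, degenerate = degenerate)),
            class = "seasonal_fit")
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat(sprintf("<seasonal_fit> n = %d, k = %d, %s%s  sd(res) = %.4g\n",
              x$n_obs, x$k, x$method,
              if (x$degenerate) " [degenerate]" else "",
              sd(x$residuals)))
  invisible(x)
}

#' Continuous predictability index from a seasonal fit
#'
#' `P_GAM = 1 / SD_res`, where `SD_res` is the sample standard deviation
#' (n - 1 divisor) of the fit residuals. A degenerate zero-residual fit has
#' no finite predictability: the function warns explicitly and returns
#' `Inf`.
#'
#' @param fit a [fit_seasonal_curve()] result.
#' @return positive number (or `Inf` with a warning for degenerate fits).
#' @export
p_gam <- function(fit) {
  if (!inherits(fit, "seasonal_fit")) {
    stop_pond("pond_input_error", "fit must be a seasonal_fit")
  }
  if (fit$n_obs < 3L) stop_pond("pond_input_error", "need at least 3 residuals")
  sd_res <- sd(fit$residuals)
  if (sd_res == 0) {
    warning(structure(
      class = c("pond_degenerate_fit", "warning", "condition"),
      list(message = "zero residual SD: infinite predictability", call = NULL)))
    return(Inf)
  }
  1 / sd_res
}

#' Run a continuous (GAM) predictability model on a series
#'
#' Both variants fit all cloud-free observations; they differ in the
#' normalizing mean. `GAM_a` uses the monthly-balanced mean over all
#' cloud-free data; `GAM_w` computes the mean over wet (area > 0)
#' observations only, which compresses A' for ponds that are usually dry.
#' Optionally (`gam_w_drop_zeros = TRUE`) the dry observations can also be
#' dropped from the regression itself; by default they are excluded from the
#' mean computation only.
#'
#' @param series a [pond_series()].
#' @param variant `"GAM_a"` or `"GAM_w"`.
#' @param k,cyclic,method passed to [fit_seasonal_curve()].
#' @param gam_w_drop_zeros for GAM_w, also drop area = 0 observations from
#'   the fit (default `FALSE`).
#' @return object of class `gam_result`: `pond_id`, `variant`, `p_gam`,
#'   `sd_res`, `mean_used` (m^2), `degenerate`, and the `fit`.
#' @export
run_continuous_model <- function(series, variant = c("GAM_a", "GAM_w"),
                                 k = 8, cyclic = FALSE, method = "REML",
                                 gam_w_drop_zeros = FALSE) {
  variant <- match.arg(variant)
  mean_used <- mean_area(series, exclude_zeros = variant == "GAM_w")
  pts <- normalize_series(series, mean_used)
  if (variant == "GAM_w" && gam_w_drop_zeros) {
    pts <- pts[pts$aprime > 0, , drop = FALSE]
  }
  fit <- fit_seasonal_curve(pts$doy, pts$aprime, k = k, cyclic = cyclic,
                            method = method)
  sd_res <- sd(fit$residuals)
  p <- if (sd_res == 0) Inf else 1 / sd_res
  if (sd_res == 0) {
    warning(structure(
      class = c("pond_degenerate_fit", "warning", "condition"),
      list(message = sprintf("pond %d %s: zero residual SD, infinite predictability",
                             series$pond_id, variant), call = NULL)))
  }
  structure(list(pond_id = series$pond_id, model = variant, variant = variant,
                 predictability = p, p_gam = p, sd_res = sd_res,
                 mean_used = mean_used, degenerate = sd_res == 0, fit = fit),
            class = c("gam_result", "predictability_estimate"))
}

#' @export
print.gam_result <- function(x, ...) {
  cat(sprintf("pond %d  %-6s P_GAM = %.3f (sd_res %.4f, mean %.1f m2)%s\n",
              x$pond_id, x$variant, x$p_gam, x$sd_res, x$mean_used,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
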