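# End-to-end pipeline: scenes -> classification -> areas -> 7 predictability
# models -> model comparison. All method constants live in the run config,
# never inside the operations, so sensitivity analyses are one-flag changes.

#' Default run configuration
#'
#' Collects every tunable of the pipeline with its standard value: the
#' MNDWI water-candidacy cut (0), the NIR salt-crust cut (0.4 reflectance),
#' the average-neighborhood half-width (0.7), the COL_MAX break fractions,
#' the GAM settings (basis dimension 8, non-cyclic, REML) and the
#' comparison settings (10,000 bootstrap resamples, cut at 0.90).
#'
#' @param ... named overrides of any default.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    band_map = c(green = 2L, nir = 4L, mir = 5L),
    scale = 1,
    mndwi_cut = 0,
    nir_salt_cut = 0.4,
    neighborhood = 0.7,
    maxlin_breaks = c(1 / 3, 2 / 3),
    maxg_breaks = c(1 / 4, 2 / 4),
    gam_k = 8L,
    gam_cyclic = FALSE,
    gam_method = "REML",
    gam_w_drop_zeros = FALSE,
    anw_mean_all = FALSE,
    n_boot = 10000L,
    seed = 42L,
    cut = 0.90,
    exclude_ponds = NULL,
    models = ALL_MODELS
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_pond("pond_config_error", "unknown config entries: %s",
              paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys override [run_config()] defaults.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_pond("pond_io_error", "config not found: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals %||% list())
}

config_hash <- function(cfg) {
  # stable content hash without extra dependencies
  txt <- paste(deparse(cfg[order(names(unclass(cfg)))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251 + 1)) %% .Machine$integer.max)
}

#' Run every requested predictability model on one series
#'
#' @param series a [pond_series()].
#' @param config a [run_config()].
#' @return data.frame with one row per model: `pond_id`, `model`,
#'   `constancy`, `contingency` (NA for continuous models),
#'   `predictability`, `n_months_used`.
#' @export
run_models <- function(series, config = run_config()) {
  rows <- lapply(config$models, function(m) {
    if (m %in% DISCRETE_MODELS) {
      r <- run_discrete_model(series, m, neighborhood = config$neighborhood,
                              anw_mean_all = config$anw_mean_all)
      data.frame(pond_id = r$pond_id, model = m, constancy = r$constancy,
                 contingency = r$contingency,
                 predictability = r$predictability,
                 n_months_used = r$n_months_used)
    } else {
      r <- run_continuous_model(series, m, k = config$gam_k,
                                cyclic = config$gam_cyclic,
                                method = config$gam_method,
                                gam_w_drop_zeros = config$gam_w_drop_zeros)
      data.frame(pond_id = r$pond_id, model = m, constancy = NA_real_,
                 contingency = NA_real_, predictability = r$p_gam,
                 n_months_used = r$fit$n_obs)
    }
  })
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' Stages: (1) if a scene manifest is configured, classify every scene with
#' the two-condition assessment and extract per-pond areas; otherwise read a
#' prepared areas CSV; (2) run the seven predictability models per pond;
#' (3) compare models (correlations with and without excluded ponds, chord
#' distance, UPGMA with bootstrap support, threshold cut). Outputs are
#' written under `out_dir` (`areas.csv`, `estimates.csv`, `comparison/`,
#' `config.yaml`, `run.log`); every stage failure aborts with a
#' stage-named message.
#'
#' @param config a [run_config()].
#' @param areas_csv path to a prepared areas CSV (pond_id, date, area_m2,
#'   ...), used when no manifest is given.
#' @param manifest optional scene manifest CSV (scene_id, path, date).
#' @param pond_mask_path pond-mask raster, required with `manifest`.
#' @param out_dir output directory.
#' @return (invisibly) list with `estimates` (wide ponds x models
#'   data.frame), `correlations`, `dendrogram`, `clusters`.
#' @export
run_pipeline <- function(config = run_config(), areas_csv = NULL,
                         manifest = NULL, pond_mask_path = NULL,
                         out_dir = "pondpredict-run") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = logf, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_pond("pond_pipeline_error", "stage '%s' failed: %s",
                name, conditionMessage(e))
    })
  }
  log_line("pipeline start; config hash %s; RNG seed %d",
           config_hash(config), config$seed)
  yaml::write_yaml(lapply(unclass(config), function(v) if (is.function(v)) NULL else v),
                   file.path(out_dir, "config.yaml"))

  areas <- stage("areas", {
    if (!is.null(manifest)) {
      if (is.null(pond_mask_path)) {
        stop_pond("pond_config_error", "manifest runs need a pond mask")
      }
      man <- read_manifest(manifest)
      mask <- read_pond_mask(pond_mask_path)
      labdir <- file.path(out_dir, "labels")
      dir.create(labdir, showWarnings = FALSE)
      classified <- lapply(seq_len(nrow(man)), function(i) {
        sc <- read_scene(man$path[i], config$band_map, man$date[i],
                         scale = config$scale)
        cs <- classify_scene(sc, config$mndwi_cut, config$nir_salt_cut)
        write_labels(cs, file.path(labdir, paste0(man$scene_id[i], ".asc")))
        cs
      })
      a <- pond_areas(classified, mask)
      write.csv(a, file.path(out_dir, "areas.csv"), row.names = FALSE)
      a
    } else {
      if (is.null(areas_csv)) {
        stop_pond("pond_config_error", "need either a manifest or an areas CSV")
      }
      read.csv(areas_csv, stringsAsFactors = FALSE)
    }
  })

  est_long <- stage("predict", {
    tmp <- tempfile(fileext = ".csv"); on.exit(unlink(tmp), add = TRUE)
    write.csv(areas, tmp, row.names = FALSE)
    series <- series_from_csv(tmp)
    out <- do.call(rbind, lapply(series, run_models, config = config))
    rownames(out) <- NULL
    out
  })
  est_wide <- stats::reshape(
    est_long[, c("pond_id", "model", "predictability")],
    idvar = "pond_id", timevar = "model", direction = "wide")
  names(est_wide) <- sub("^predictability\\.", "", names(est_wide))
  est_wide <- est_wide[, c("pond_id", intersect(ALL_MODELS, names(est_wide))),
                       drop = FALSE]
  write.csv(format(est_wide, digits = 15, trim = TRUE),
            file.path(out_dir, "estimates.csv"), row.names = FALSE, quote = FALSE)
  log_line("predict: %d ponds x %d models", nrow(est_wide), ncol(est_wide) - 1L)

  cmp <- stage("compare", {
    em <- estimate_matrix(est_long)
    cordir <- file.path(out_dir, "comparison")
    dir.create(cordir, showWarnings = FALSE)
    r_all <- correlation_matrix(em)
    r_sub <- if (!is.null(config$exclude_ponds)) {
      correlation_matrix(em, exclude_ponds = config$exclude_ponds)
    } else NULL
    write.csv(r_all, file.path(cordir, "correlations_all.csv"))
    if (!is.null(r_sub)) {
      write.csv(r_sub, file.path(cordir, "correlations_excluded.csv"))
    }
    dend <- bootstrap_support(em, n_boot = config$n_boot, seed = config$seed)
    dendrogram_newick(dend, file.path(cordir, "dendrogram.nwk"))
    cl <- cut_clusters(dend, config$cut)
    memb <- data.frame(
      model = unlist(cl),
      cluster = rep(seq_along(cl), lengths(cl)))
    write.csv(memb, file.path(cordir, "clusters.csv"), row.names = FALSE)
    list(correlations = r_all, correlations_excluded = r_sub,
         dendrogram = dend, clusters = cl)
  })
  log_line("compare: %d clusters at cut %.2f", length(cmp$clusters), config$cut)
  log_line("pipeline done")
  invisible(list(estimates = est_wide, correlations = cmp$correlations,
                 correlations_excluded = cmp$correlations_excluded,
                 dendrogram = cmp$dendrogram, clusters = cmp$clusters))
}
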