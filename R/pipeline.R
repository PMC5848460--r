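#' Run the full synthesis-and-measurement pipeline in memory
#'
#' For every specimen of the cohort: render, deconvolve, place ROIs, measure
#' FWHM widths and band intensities, aggregate to cells and specimens, and
#' assign scores. Images are discarded after measurement unless `out_dir` is
#' given, keeping memory flat for full-size cohorts.
#'
#' @param cfg A [cohort_config()].
#' @param thresholds [score_thresholds()] used for specimen scoring.
#' @param stains [stain_matrix()] shared by rendering and deconvolution.
#' @param k ROIs per cell.
#' @param min_peak_od Validity threshold for a profile.
#' @param out_dir Optional directory; when given, images (`.ppm`) and
#'   `manifest.csv` are materialized there.
#' @return List with `plan`, `truth`, `cells` (one row per cell: truth +
#'   measurements) and `specimens` (one row per specimen, incl.
#'   `assigned_score`).
#' @export
run_cohort <- function(cfg, thresholds = default_thresholds(),
                       stains = default_stain_matrix(), k = 4,
                       min_peak_od = 0.05, out_dir = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  cells_acc <- list()
  spec_acc <- list()
  cb <- function(specimen_id, image, truth) {
    cells <- measure_specimen(image, truth, stains = stains, k = k,
                              min_peak_od = min_peak_od,
                              seed = truth$seed[1])
    summ <- summarize_specimen(cells, thresholds)
    cells_acc[[specimen_id]] <<- cells
    spec_acc[[specimen_id]] <<- cbind(
      data.frame(specimen_id = specimen_id,
                 score_preset = truth$score_preset[1],
                 ish_label = truth$ish_label[1], seed = truth$seed[1]),
      summ)
  }
  gen <- generate_cohort(cfg, out_dir = out_dir, callback = cb)
  cells <- do.call(rbind, cells_acc)
  specimens <- do.call(rbind, spec_acc)
  rownames(cells) <- rownames(specimens) <- NULL
  list(plan = gen$plan, truth = gen$truth, cells = cells,
       specimens = specimens)
}

#' Run configuration
#'
#' Serializable description of a complete run: cohort design, optics,
#' stains, morphometry settings and the master seed. Round-trips through
#' JSON unchanged (see [write_run_config()] / [read_run_config()]).
#'
#' @param master_seed Integer master seed.
#' @param n_per_category Specimens per category.
#' @param categories Scoring categories to simulate.
#' @param lambda_nm Illumination wavelength for the optics defaults.
#' @param thresholds_um Length-3 increasing score thresholds (um).
#' @param stains Named list with `hematoxylin` and `dab` OD-RGB vectors.
#' @param k_rois ROIs per cell.
#' @param min_peak_od Profile validity threshold.
#' @param specimen Named list of overrides forwarded to [specimen_config()]
#'   (e.g. `n_cells`, `psf_sigma_um`, `canvas_um`, `rgb_noise_sd`).
#' @param write_images Materialize rendered images in the run directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(master_seed = 1, n_per_category = 40,
                       categories = c("1+", "2+", "3+"),
                       lambda_nm = 600, thresholds_um = c(0.4, 1.0, 2.0),
                       stains = list(hematoxylin = c(0.650, 0.704, 0.286),
                                     dab = c(0.269, 0.568, 0.778)),
                       k_rois = 4, min_peak_od = 0.05,
                       specimen = list(), write_images = FALSE) {
  if (is.null(stains$hematoxylin) || is.null(stains$dab)) {
    stop("config key 'stains' must provide 'hematoxylin' and 'dab' vectors")
  }
  structure(
    list(master_seed = as.integer(master_seed),
         n_per_category = as.integer(n_per_category),
         categories = categories, lambda_nm = lambda_nm,
         thresholds_um = thresholds_um, stains = stains,
         k_rois = k_rois, min_peak_od = min_peak_od,
         specimen = specimen, write_images = isTRUE(write_images)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$specimen <- as.list(raw$specimen)
  raw$stains <- lapply(raw$stains, as.numeric)
  do.call(run_config, raw)
}

#' Execute a full run into a directory
#'
#' Orchestrates synth -> measure -> classify -> stats under one master seed
#' and writes all artifacts: `cells.csv`, `specimens.csv`, `summary.csv`,
#' `comparisons.csv`, `correlation.csv`, `ish_comparison.csv`,
#' `manifest.csv`, `config_used.json` (and images when configured).
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the [run_cohort()] result plus `stats`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  thresholds <- do.call(score_thresholds, as.list(cfg$thresholds_um))
  stains <- stain_matrix(list(
    stain_vector("hematoxylin", cfg$stains$hematoxylin),
    stain_vector("dab", cfg$stains$dab)))
  ccfg <- do.call(cohort_config, c(
    list(n_per_category = cfg$n_per_category, categories = cfg$categories,
         master_seed = cfg$master_seed),
    cfg$specimen))
  res <- run_cohort(ccfg, thresholds = thresholds, stains = stains,
                    k = cfg$k_rois, min_peak_od = cfg$min_peak_od,
                    out_dir = if (cfg$write_images) out_dir else NULL)
  res$stats <- cohort_statistics(res$cells, res$specimens)
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(res$cells, "cells.csv")
  wcsv(res$specimens, "specimens.csv")
  wcsv(res$truth, "manifest.csv")
  wcsv(res$stats$category$summary, "summary.csv")
  wcsv(res$stats$category$pairwise, "comparisons.csv")
  wcsv(res$stats$correlation, "correlation.csv")
  if (!is.null(res$stats$ish)) wcsv(res$stats$ish, "ish_comparison.csv")
  ver <- as.character(utils::packageVersion("magrule"))
  cfg_out <- c(unclass(cfg), list(package_version = ver))
  jsonlite::write_json(cfg_out, file.path(out_dir, "config_used.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Cohort statistics bundle
#'
#' Computes the statistical report of a measured cohort: per-category
#' summaries with pairwise Welch tests, the pooled 1+/2+ per-cell
#' width-intensity Pearson correlation, and (when 2+ specimens carry ISH
#' labels) the ISH subgroup comparison.
#'
#' @param cells,specimens Measurement tables from [run_cohort()].
#' @return List with `category` (see [category_summary()]), `correlation`
#'   (data.frame) and `ish` (data.frame or NULL).
#' @export
cohort_statistics <- function(cells, specimens) {
  cat_res <- category_summary(cells, specimens)
  pooled <- cells$score_preset %in% c("1+", "2+") & cells$n_valid_rois > 0
  corr <- if (sum(pooled) >= 3) {
    r <- pearson_r(cells$mean_width_um[pooled],
                   cells$mean_intensity_pct[pooled],
                   label = "1+ and 2+ pooled, per-cell means")
    data.frame(label = r$label, n = r$n, pearson_r = r$pearson_r)
  } else data.frame(label = character(0), n = integer(0),
                    pearson_r = numeric(0))
  two <- specimens[specimens$score_preset == "2+", , drop = FALSE]
  ish <- NULL
  if (sum(two$ish_label == "positive") >= 2 &&
      sum(two$ish_label == "negative") >= 2) {
    cmp <- ish_subgroup_comparison(two)
    ish <- do.call(rbind, lapply(names(cmp), function(v) {
      x <- cmp[[v]]
      data.frame(variable = v, n_pos = x$n[1], n_neg = x$n[2],
                 mean_pos = x$means[1], mean_neg = x$means[2],
                 sd_pos = x$sds[1], sd_neg = x$sds[2],
                 t_statistic = x$t_statistic, df = x$df,
                 p_value = x$p_value, significant = x$significant)
    }))
  }
  list(category = cat_res, correlation = corr, ish = ish)
}

#' Protocol bookkeeping
#'
#' Number of planned measurement slots of a cohort design:
#' specimens x cells x ROIs. The study protocol (3 categories x 40
#' specimens, 10 cells, 4 ROIs) yields 4800.
#'
#' @param n_specimens Total specimens.
#' @param n_cells Cells per specimen.
#' @param k ROIs per cell.
#' @return Integer slot count.
#' @export
roi_slots <- function(n_specimens, n_cells = 10, k = 4) {
  stopifnot(n_specimens >= 0, n_cells >= 0, k >= 0)
  as.integer(n_specimens) * as.integer(n_cells) * as.integer(k)
}
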