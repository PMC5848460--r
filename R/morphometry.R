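#' Place perpendicular line-profile ROIs on a cell membrane
#'
#' Reproduces the measurement protocol: `k` short segments perpendicular to
#' the membranous precipitate (radial for a circular cell), centered on the
#' membrane circle, at angles evenly spaced over the stained arc with a
#' seeded jitter. With partial staining, all ROIs stay inside the stained
#' arc; a cell with no stained arc gets zero ROIs.
#'
#' @param cell One-row data.frame with `cx_um`, `cy_um`, `radius_um`,
#'   `true_width_um` (or `width_hint_um`), `completeness`, `arc_center_rad`
#'   (synthetic mode: a row of the ground-truth manifest).
#' @param k Number of ROIs (protocol: 4).
#' @param length_um Segment length in um; default 3x the expected width,
#'   clamped to `[1.5, 6.5]` um.
#' @param jitter Fraction of the even spacing used as uniform angular jitter
#'   (0 disables it).
#' @return `data.frame(roi_id, angle_rad, x1_um, y1_um, x2_um, y2_um,
#'   length_um)`.
#' @export
place_rois <- function(cell, k = 4, length_um = NULL, jitter = 0.25) {
  stopifnot(k >= 1, nrow(cell) == 1)
  comp <- if (!is.null(cell$completeness)) cell$completeness else 1
  if (comp <= 0) {
    return(data.frame(roi_id = integer(0), angle_rad = numeric(0),
                      x1_um = numeric(0), y1_um = numeric(0),
                      x2_um = numeric(0), y2_um = numeric(0),
                      length_um = numeric(0)))
  }
  w_hint <- if (!is.null(cell$true_width_um)) cell$true_width_um
            else if (!is.null(cell$width_hint_um)) cell$width_hint_um
            else 1
  if (is.null(length_um)) length_um <- min(max(3 * w_hint, 1.5), 6.5)
  th0 <- if (!is.null(cell$arc_center_rad)) cell$arc_center_rad else 0
  span <- 2 * pi * comp
  base <- th0 + span * ((seq_len(k) - 0.5) / k - 0.5)
  jit <- if (jitter > 0) stats::runif(k, -1, 1) * jitter * span / k else 0
  ang <- base + jit
  ux <- cos(ang); uy <- sin(ang)
  px <- cell$cx_um + cell$radius_um * ux
  py <- cell$cy_um + cell$radius_um * uy
  data.frame(
    roi_id = seq_len(k), angle_rad = ang,
    x1_um = px - ux * length_um / 2, y1_um = py - uy * length_um / 2,
    x2_um = px + ux * length_um / 2, y2_um = py + uy * length_um / 2,
    length_um = length_um
  )
}

# Bilinear interpolation of matrix `m` (rows = y, cols = x, pixel centers at
# (i - 0.5) / s um) at micrometre coordinates (x, y). Errors when any point
# leaves the outer pixel-center hull by more than half a pixel.
bilinear_at <- function(m, x_um, y_um, pixel_scale, what = "ROI") {
  u <- x_um * pixel_scale + 0.5   # continuous column coordinate
  v <- y_um * pixel_scale + 0.5   # continuous row coordinate
  nr <- nrow(m); nc <- ncol(m)
  if (any(u < 0.5 | u > nc + 0.5 | v < 0.5 | v > nr + 0.5)) {
    stop(what, " extends outside the image bounds")
  }
  j0 <- pmin(pmax(floor(u), 1), nc - 1); fi <- pmin(pmax(u - j0, 0), 1)
  i0 <- pmin(pmax(floor(v), 1), nr - 1); fj <- pmin(pmax(v - i0, 0), 1)
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    m[cbind(i0, j0 + 1)] * fi * (1 - fj) +
    m[cbind(i0 + 1, j0)] * (1 - fi) * fj +
    m[cbind(i0 + 1, j0 + 1)] * fi * fj
}

#' Extract a 1-D optical-density profile along a ROI
#'
#' Samples a concentration map along the ROI segment at sub-pixel steps
#' (default 0.25 px) by bilinear interpolation. Sub-pixel sampling matters:
#' at 5.11 px/um a 1+ band is only ~3.3 px wide.
#'
#' @param conc `H x W` concentration matrix (one stain channel, OD units).
#' @param roi One-row ROI data.frame from [place_rois()] (fields `x1_um`,
#'   `y1_um`, `x2_um`, `y2_um`).
#' @param pixel_scale Pixels per micrometer of the image.
#' @param step_px Sampling step in pixels.
#' @return `data.frame(x_um, od)`; `x_um` runs along the segment from 0.
#' @export
extract_profile <- function(conc, roi, pixel_scale, step_px = 0.25) {
  stopifnot(is.matrix(conc), nrow(roi) == 1, step_px > 0)
  dx <- roi$x2_um - roi$x1_um; dy <- roi$y2_um - roi$y1_um
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("degenerate ROI: identical endpoints")
  t <- seq(0, len, by = step_px / pixel_scale)
  xs <- roi$x1_um + dx / len * t
  ys <- roi$y1_um + dy / len * t
  label <- if (!is.null(roi$roi_id)) paste("ROI", roi$roi_id) else "ROI"
  data.frame(x_um = t,
             od = bilinear_at(conc, xs, ys, pixel_scale, what = label))
}

#' Full width at half maximum of a line profile
#'
#' The operational definition of precipitate width: the FWHM of the largest
#' peak of the DAB OD profile, with the half-maximum crossings located by
#' linear interpolation between samples. A profile whose peak OD falls below
#' `min_peak_od` is "insufficient for quantification" and returns an invalid
#' measurement (not an error). Optionally removes the Gaussian PSF
#' contribution in quadrature (`w = sqrt(FWHM^2 - (2.3548 sigma)^2)`); off by
#' default so that measurements stay on the raw scale.
#'
#' @param profile `data.frame(x_um, od)` from [extract_profile()].
#' @param min_peak_od Minimal peak OD for a valid measurement.
#' @param psf_sigma_um If > 0, apply the quadrature PSF correction.
#' @return List: `valid`, `width_um`, `peak_od`, `x_left_um`, `x_right_um`.
#' @export
measure_width <- function(profile, min_peak_od = 0.05, psf_sigma_um = 0) {
  stopifnot(all(c("x_um", "od") %in% names(profile)))
  if (nrow(profile) < 5) stop("profile too short (need >= 5 samples)")
  od <- profile$od; x <- profile$x_um
  ipk <- which.max(od)
  pk <- od[ipk]
  invalid <- list(valid = FALSE, width_um = NA_real_, peak_od = pk,
                  x_left_um = NA_real_, x_right_um = NA_real_)
  if (!is.finite(pk) || pk < min_peak_od) return(invalid)
  half <- pk / 2
  # walk out from the peak to the first sample below half-max on each side
  il <- ipk
  while (il > 1 && od[il - 1] >= half) il <- il - 1
  ir <- ipk
  while (ir < length(od) && od[ir + 1] >= half) ir <- ir + 1
  if (il == 1 || ir == length(od)) return(invalid)  # band clipped by ROI
  xl <- x[il - 1] + (half - od[il - 1]) / (od[il] - od[il - 1]) *
    (x[il] - x[il - 1])
  xr <- x[ir] + (half - od[ir]) / (od[ir + 1] - od[ir]) *
    (x[ir + 1] - x[ir])
  w <- xr - xl
  if (psf_sigma_um > 0) {
    fwhm_psf <- 2.3548200450309493 * psf_sigma_um
    w <- if (w > fwhm_psf) sqrt(w^2 - fwhm_psf^2) else w
  }
  list(valid = TRUE, width_um = w, peak_od = pk, x_left_um = xl,
       x_right_um = xr)
}

#' Relative intensity over the measured band
#'
#' Mean OD over the band support (between the FWHM crossings), converted to
#' the inverted relative grey scale by [dab_intensity_pct()].
#'
#' @param profile `data.frame(x_um, od)`.
#' @param width_measurement Result of [measure_width()] on the same profile.
#' @return Intensity in percent, or `NA` for an invalid width.
#' @export
measure_intensity <- function(profile, width_measurement) {
  if (!isTRUE(width_measurement$valid)) return(NA_real_)
  sel <- profile$x_um >= width_measurement$x_left_um &
    profile$x_um <= width_measurement$x_right_um
  dab_intensity_pct(profile$od[sel])
}

#' Measure one cell: profiles, widths, intensities
#'
#' Places ROIs on the cell, extracts DAB profiles and measures width and
#' intensity for each.
#'
#' @param dab `H x W` DAB concentration matrix.
#' @param cell One-row ground-truth (or annotation) record.
#' @param pixel_scale Pixels per micrometer.
#' @param k ROIs per cell.
#' @param min_peak_od Validity threshold, see [measure_width()].
#' @param ... Passed to [place_rois()].
#' @return `data.frame` with one row per ROI: `roi_id`, `width_um`,
#'   `intensity_pct`, `peak_od`, `valid`.
#' @export
measure_cell <- function(dab, cell, pixel_scale, k = 4, min_peak_od = 0.05,
                         ...) {
  rois <- place_rois(cell, k = k, ...)
  if (nrow(rois) == 0) {
    return(data.frame(roi_id = integer(0), width_um = numeric(0),
                      intensity_pct = numeric(0), peak_od = numeric(0),
                      valid = logical(0)))
  }
  out <- lapply(seq_len(nrow(rois)), function(i) {
    prof <- extract_profile(dab, rois[i, ], pixel_scale)
    wm <- measure_width(prof, min_peak_od = min_peak_od)
    data.frame(roi_id = rois$roi_id[i], width_um = wm$width_um,
               intensity_pct = measure_intensity(prof, wm),
               peak_od = wm$peak_od, valid = wm$valid)
  })
  do.call(rbind, out)
}

#' Aggregate ROI measurements to a cell
#'
#' Arithmetic mean of the valid profile widths and intensities. A cell with
#' zero valid profiles is flagged absent (`n_valid_rois = 0`, `NA` means);
#' such cells feed the score-0 logic at the specimen level.
#'
#' @param profiles Data.frame from [measure_cell()].
#' @return One-row data.frame: `mean_width_um`, `mean_intensity_pct`,
#'   `n_valid_rois`.
#' @export
aggregate_cell <- function(profiles) {
  ok <- which(profiles$valid)
  if (length(ok) == 0) {
    return(data.frame(mean_width_um = NA_real_,
                      mean_intensity_pct = NA_real_, n_valid_rois = 0L))
  }
  data.frame(mean_width_um = mean(profiles$width_um[ok]),
             mean_intensity_pct = mean(profiles$intensity_pct[ok]),
             n_valid_rois = length(ok))
}

#' Summarize a specimen and assign its IHC score
#'
#' Mean and SD of the per-cell mean widths (protocol: 10 cells), mean
#' intensity, and the score assigned by [classify_width()] on the specimen
#' mean width. When every cell is flagged absent the precipitate is deemed
#' absent or insufficient for quantification and the specimen scores 0.
#'
#' @param cells Data.frame with one row per cell (`mean_width_um`,
#'   `mean_intensity_pct`, `n_valid_rois`), e.g. stacked [aggregate_cell()]
#'   rows.
#' @param thresholds A [score_thresholds()].
#' @return One-row data.frame: `mean_width_um`, `sd_width_um`,
#'   `mean_intensity_pct`, `n_cells`, `n_measured`, `assigned_score`.
#' @export
summarize_specimen <- function(cells, thresholds = default_thresholds()) {
  if (nrow(cells) == 0) stop("no cells to summarize")
  ok <- which(cells$n_valid_rois > 0)
  if (length(ok) == 0) {
    return(data.frame(mean_width_um = NA_real_, sd_width_um = NA_real_,
                      mean_intensity_pct = NA_real_,
                      n_cells = nrow(cells), n_measured = 0L,
                      assigned_score = score_factor("0")))
  }
  mw <- mean(cells$mean_width_um[ok])
  data.frame(
    mean_width_um = mw,
    sd_width_um = if (length(ok) > 1) stats::sd(cells$mean_width_um[ok])
                  else NA_real_,
    mean_intensity_pct = mean(cells$mean_intensity_pct[ok]),
    n_cells = nrow(cells), n_measured = length(ok),
    assigned_score = classify_width(mw, thresholds)
  )
}

#' Fraction of the cell perimeter that is stained
#'
#' Samples the perimeter at `n_angles` angular steps; at each angle the
#' radial maximum of the DAB OD near the membrane circle is compared against
#' `od_threshold`. Complete ring-shaped staining gives 1.0.
#'
#' @param dab `H x W` DAB concentration matrix.
#' @param cell One-row record with `cx_um`, `cy_um`, `radius_um` (and
#'   optionally `true_width_um` to size the radial search window).
#' @param pixel_scale Pixels per micrometer.
#' @param od_threshold OD above which a perimeter point counts as stained.
#' @param n_angles Angular sampling density.
#' @return Fraction in `[0, 1]`.
#' @export
ring_completeness <- function(dab, cell, pixel_scale, od_threshold = 0.05,
                              n_angles = 360) {
  w <- if (!is.null(cell$true_width_um)) cell$true_width_um else 2
  half <- w / 2 + 0.6
  th <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  rr <- seq(cell$radius_um - half, cell$radius_um + half,
            by = 0.25 / pixel_scale)
  stained <- vapply(th, function(a) {
    od <- bilinear_at(dab, cell$cx_um + rr * cos(a),
                      cell$cy_um + rr * sin(a), pixel_scale,
                      what = "perimeter ray")
    max(od) >= od_threshold
  }, logical(1))
  mean(stained)
}

#' Measure every cell of a rendered specimen
#'
#' Deconvolves the RGB image and runs the full per-cell protocol (`k` ROIs,
#' FWHM width, band intensity, cell aggregation).
#'
#' @param image An [rgb_image()].
#' @param truth Ground-truth manifest rows for this specimen (one per cell).
#' @param stains [stain_matrix()] used for deconvolution.
#' @param k ROIs per cell.
#' @param min_peak_od Validity threshold.
#' @param seed Seed for the ROI-placement jitter.
#' @return `data.frame`, one row per cell: truth columns joined with
#'   `mean_width_um`, `mean_intensity_pct`, `n_valid_rois`.
#' @export
measure_specimen <- function(image, truth, stains = default_stain_matrix(),
                             k = 4, min_peak_od = 0.05, seed = NULL) {
  stopifnot(inherits(image, "rgb_image"))
  if (!is.null(seed)) set.seed(seed)
  conc <- deconvolve(rgb_to_od(image), stains)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    prof <- measure_cell(conc$dab, truth[i, ], image$pixel_scale, k = k,
                         min_peak_od = min_peak_od)
    cbind(truth[i, , drop = FALSE], aggregate_cell(prof))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
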