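cell_row <- function(cx = 10, cy = 10, r = 6, w = 1, comp = 1, th0 = 0) {
  data.frame(cx_um = cx, cy_um = cy, radius_um = r, true_width_um = w,
             completeness = comp, arc_center_rad = th0)
}

test_that("place_rois puts radial segments on the stained arc", {
  set.seed(1)
  rois <- place_rois(cell_row(), k = 4)
  expect_equal(nrow(rois), 4)
  # ~90 degree spacing up to the jitter bound (0.25 of the even spacing)
  gaps <- diff(sort(rois$angle_rad %% (2 * pi)))
  expect_true(all(abs(gaps - pi / 2) <= pi / 4 + 1e-9))
  # segments are radial and centered on the membrane circle
  mid <- cbind((rois$x1_um + rois$x2_um) / 2, (rois$y1_um + rois$y2_um) / 2)
  expect_equal(sqrt((mid[, 1] - 10)^2 + (mid[, 2] - 10)^2), rep(6, 4),
               tolerance = 1e-9)
  # half staining: all ROIs inside the stained semicircle
  rois2 <- place_rois(cell_row(comp = 0.5, th0 = pi / 2), k = 4)
  ad <- abs(((rois2$angle_rad - pi / 2 + pi) %% (2 * pi)) - pi)
  expect_true(all(ad <= pi / 2))
  # k = 1 without jitter: segment through (cx + r, cy) along the radius
  r1 <- place_rois(cell_row(), k = 1, jitter = 0)
  expect_equal(c(r1$x1_um, r1$x2_um), c(10 + 6 - r1$length_um / 2,
                                        10 + 6 + r1$length_um / 2))
  expect_equal(c(r1$y1_um, r1$y2_um), c(10, 10))
  # no stained arc -> zero ROIs
  expect_equal(nrow(place_rois(cell_row(comp = 0))), 0)
})

test_that("extract_profile samples at sub-pixel steps and validates bounds", {
  conc <- matrix(0, 100, 100)
  roi <- data.frame(x1_um = 3, y1_um = 5, x2_um = 8, y2_um = 5)
  prof <- extract_profile(conc, roi, pixel_scale = 5.11)
  expect_equal(prof$od, rep(0, nrow(prof)))        # pure background
  expect_equal(diff(prof$x_um)[1], 0.25 / 5.11)
  expect_error(extract_profile(conc, data.frame(x1_um = 1, y1_um = 1,
                                                x2_um = 1, y2_um = 1),
                               5.11), "degenerate")
  expect_error(extract_profile(conc, data.frame(x1_um = -5, y1_um = 5,
                                                x2_um = 8, y2_um = 5),
                               5.11), "outside")
})

test_that("an unblurred rendered band reads back as a box of the true width", {
  cfg <- specimen_config(category_preset("3+", 1.5, 0, amp_max = 0.8),
                         n_cells = 1, seed = 13, canvas_um = 36,
                         cell_radius_range = c(7, 7), psf_sigma_um = 0,
                         rgb_noise_sd = 0, background_h_od = 0)
  out <- render_specimen(cfg)
  conc <- deconvolve(rgb_to_od(out$image))
  roi <- place_rois(out$truth, k = 1, jitter = 0)
  prof <- extract_profile(conc$dab, roi, out$image$pixel_scale)
  wm <- measure_width(prof)
  step <- 1 / out$image$pixel_scale  # rasterized edges land within a pixel
  expect_lt(abs(wm$width_um - 1.5), step)
})

test_that("measure_width finds the FWHM by crossing interpolation", {
  step <- 0.25 / 5.11
  x <- (0:60) * step
  box <- data.frame(x_um = x, od = as.numeric(x >= 20 * step & x < 30 * step))
  wm <- measure_width(box)
  expect_true(wm$valid)
  expect_equal(wm$width_um, 10 * step, tolerance = 1e-9)  # 0.489 um
  # Gaussian profile: FWHM = 2.3548 sigma within 1%
  sig <- 0.3
  g <- data.frame(x_um = x, od = 0.8 * exp(-(x - mean(x))^2 / (2 * sig^2)))
  expect_equal(measure_width(g)$width_um, 2.3548 * sig, tolerance = 0.01)
  # flat profile is invalid, not an error
  expect_false(measure_width(data.frame(x_um = x, od = 0 * x))$valid)
  expect_error(measure_width(data.frame(x_um = 1:3, od = 1:3)), "short")
})

test_that("FWHM is invariant to profile reversal and OD scaling", {
  set.seed(8)
  step <- 0.25 / 5.11
  x <- (0:80) * step
  for (rep in 1:20) {
    w <- runif(1, 0.4, 2.5); s <- runif(1, 0.05, 0.2); a <- runif(1, 0.1, 2)
    od <- a * (pnorm((w / 2 - (x - 2)) / s) - pnorm((-w / 2 - (x - 2)) / s))
    p <- data.frame(x_um = x, od = od)
    p_rev <- data.frame(x_um = x, od = rev(od))
    p_scaled <- data.frame(x_um = x, od = 10 * od)
    w0 <- measure_width(p)$width_um
    expect_equal(measure_width(p_rev)$width_um, w0, tolerance = 1e-9)
    expect_equal(measure_width(p_scaled)$width_um, w0, tolerance = 1e-9)
  }
})

test_that("PSF quadrature correction undoes Gaussian broadening when enabled", {
  # exact for a Gaussian band: the PSF adds in quadrature
  step <- 0.02
  x <- seq(0, 6, by = step)
  s_band <- 0.4; s_psf <- 0.15
  od <- exp(-(x - 3)^2 / (2 * (s_band^2 + s_psf^2)))
  raw <- measure_width(data.frame(x_um = x, od = od))$width_um
  corr <- measure_width(data.frame(x_um = x, od = od),
                        psf_sigma_um = s_psf)$width_um
  true_fwhm <- 2.3548 * s_band
  expect_gt(raw, true_fwhm)
  expect_equal(corr, true_fwhm, tolerance = 0.01)
  # narrower than the PSF itself: correction is skipped, not imaginary
  narrow <- exp(-(x - 3)^2 / (2 * 0.01^2))
  wn <- measure_width(data.frame(x_um = x, od = narrow), psf_sigma_um = 0.15)
  expect_true(is.finite(wn$width_um))
})

test_that("measure_intensity averages OD over the band support", {
  step <- 0.25 / 5.11
  x <- (0:60) * step
  prof <- data.frame(x_um = x, od = as.numeric(x >= 20 * step & x < 40 * step))
  wm <- measure_width(prof)
  expect_equal(measure_intensity(prof, wm), 100 * (255 - 26) / 255,
               tolerance = 1.5)  # band OD ~1 -> ~89.8%
  # doubling the OD never decreases the intensity
  prof2 <- transform(prof, od = 2 * od)
  expect_gte(measure_intensity(prof2, measure_width(prof2)),
             measure_intensity(prof, wm))
  expect_true(is.na(measure_intensity(prof, list(valid = FALSE))))
})

test_that("cell and specimen aggregation follow the protocol", {
  p <- data.frame(roi_id = 1:4, width_um = c(0.8, 1.0, 1.2, NA),
                  intensity_pct = c(50, 60, 70, NA), peak_od = 1,
                  valid = c(TRUE, TRUE, TRUE, FALSE))
  agg <- aggregate_cell(p)
  expect_equal(agg$mean_width_um, 1.0)
  expect_equal(agg$n_valid_rois, 3)
  none <- aggregate_cell(transform(p, valid = FALSE))
  expect_equal(none$n_valid_rois, 0)
  expect_true(is.na(none$mean_width_um))

  cells <- data.frame(mean_width_um = rep(2.14, 10),
                      mean_intensity_pct = 90, n_valid_rois = 4)
  s <- summarize_specimen(cells)
  expect_equal(as.character(s$assigned_score), "3+")
  expect_equal(s$n_measured, 10)
  # all cells absent -> insufficient for quantification -> score 0
  absent <- data.frame(mean_width_um = NA_real_,
                       mean_intensity_pct = NA_real_,
                       n_valid_rois = 0L)[rep(1, 10), ]
  expect_equal(as.character(summarize_specimen(absent)$assigned_score), "0")
  # degenerate single cell: SD undefined
  one <- summarize_specimen(cells[1, ])
  expect_true(is.na(one$sd_width_um))
  expect_error(summarize_specimen(cells[0, ]), "no cells")
})

test_that("end-to-end width recovery tracks the numerical oracle over [0.4, 3]", {
  for (w in c(0.4, 0.8, 1.6, 3.0)) {
    cfg <- specimen_config(category_preset("3+", w, 0, amp_max = 0.8),
                           n_cells = 1, seed = round(100 * w),
                           canvas_um = 40, cell_radius_range = c(8, 8),
                           rgb_noise_sd = 0, background_h_od = 0)
    out <- render_specimen(cfg)
    cells <- measure_specimen(out$image, out$truth, seed = 1)
    oracle <- box_gauss_fwhm_oracle(w, cfg$psf_sigma_um)
    expect_lt(abs(cells$mean_width_um - oracle), 0.1)
  }
})

test_that("ring completeness recovers the stained fraction", {
  base <- list(n_cells = 1, canvas_um = 40, cell_radius_range = c(9, 9),
               rgb_noise_sd = 0, background_h_od = 0)
  full <- render_specimen(do.call(specimen_config, c(
    list(preset = category_preset("3+", 2.0, 0, amp_max = 0.8), seed = 4),
    base)))
  conc <- deconvolve(rgb_to_od(full$image))
  expect_equal(ring_completeness(conc$dab, full$truth, 5.11), 1.0)
  half <- render_specimen(do.call(specimen_config, c(
    list(preset = category_preset("3+", 2.0, 0, amp_max = 0.8), seed = 4,
         completeness = 0.5), base)))
  conch <- deconvolve(rgb_to_od(half$image))
  expect_lt(abs(ring_completeness(conch$dab, half$truth, 5.11) - 0.5), 0.02)
  blank <- matrix(0, nrow(conch$dab), ncol(conch$dab))
  expect_equal(ring_completeness(blank, half$truth, 5.11), 0.0)
})
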