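#' Per-score generator preset
#'
#' Describes how cells of one IHC scoring category are generated: the
#' distribution of membranous DAB band widths (truncated normal, in measured
#' width space) and the width-to-amplitude coupling that produces DAB optical
#' density. For 1+/2+ the amplitude is `slope * width + intercept` plus
#' Gaussian per-cell noise; for 3+ the amplitude is capped at `amp_max`
#' (chromogen saturation) with no additive noise.
#'
#' @param score One of `"1+"`, `"2+"`, `"3+"`.
#' @param width_mean,width_sd Mean and SD of the band width (um).
#' @param width_trunc Length-2 positive, ordered truncation bounds (um).
#' @param amp_slope,amp_intercept Width-amplitude coupling (OD per um, OD).
#' @param amp_noise_sd Per-cell amplitude noise SD (OD); ignored when
#'   `amp_max` is finite.
#' @param amp_max Saturation cap (OD); `Inf` disables saturation.
#' @return Object of class `category_preset`.
#' @export
category_preset <- function(score, width_mean, width_sd,
                            width_trunc = c(0.1, 4.0),
                            amp_slope = 0.55, amp_intercept = 0.05,
                            amp_noise_sd = 0.132, amp_max = Inf) {
  score <- match.arg(score, c("1+", "2+", "3+"))
  stopifnot(width_mean > 0, width_sd >= 0,
            length(width_trunc) == 2, all(width_trunc > 0))
  if (width_trunc[1] >= width_trunc[2]) {
    stop("degenerate truncation interval")
  }
  structure(
    list(score = score, width_mean = width_mean, width_sd = width_sd,
         width_trunc = width_trunc, amp_slope = amp_slope,
         amp_intercept = amp_intercept, amp_noise_sd = amp_noise_sd,
         amp_max = amp_max),
    class = "category_preset"
  )
}

#' Shipped per-score presets
#'
#' Width distributions follow the measured per-score statistics
#' (1+: 0.64 +/- 0.1 um; 2+: 1.0 +/- 0.23 um; 3+: 2.14 +/- 0.4 um). The
#' width-amplitude coupling is shared by 1+ and 2+ and calibrated (see
#' `scripts/calibrate_coupling.R`) so that the pooled 1+/2+ per-cell
#' width-intensity Pearson correlation lands near 0.73; the 3+ amplitude is
#' saturated at 1.0 OD.
#'
#' @param score Optional single score to return one preset.
#' @return A named list of [category_preset()]s, or one preset.
#' @export
default_presets <- function(score = NULL) {
  p <- list(
    "1+" = category_preset("1+", 0.64, 0.10),
    "2+" = category_preset("2+", 1.00, 0.23),
    "3+" = category_preset("3+", 2.14, 0.40, amp_max = 1.0)
  )
  if (is.null(score)) p else p[[match.arg(score, names(p))]]
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate draw outside bounds")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Draw per-cell width and amplitude from a preset
#'
#' Widths come from the preset's truncated normal; amplitudes from the linear
#' width-amplitude coupling (with per-cell Gaussian noise for unsaturated
#' presets, a hard cap for saturated ones). Amplitudes are floored at 0.02 OD
#' so every stained cell remains detectable.
#'
#' @param preset A [category_preset()].
#' @param n Number of cells.
#' @return `data.frame(true_width_um, true_amplitude)`.
#' @export
sample_cell_params <- function(preset, n) {
  stopifnot(inherits(preset, "category_preset"), n >= 0)
  w <- rtruncnorm(n, preset$width_mean, preset$width_sd,
                  preset$width_trunc[1], preset$width_trunc[2])
  a <- preset$amp_slope * w + preset$amp_intercept
  if (is.finite(preset$amp_max)) {
    a <- pmin(a, preset$amp_max)
  } else if (preset$amp_noise_sd > 0 && n > 0) {
    a <- a + stats::rnorm(n, sd = preset$amp_noise_sd)
  }
  data.frame(true_width_um = w, true_amplitude = pmax(a, 0.02))
}

#' Specimen rendering configuration
#'
#' Everything needed to render one synthetic specimen: which score preset,
#' how many tumor cells, cell geometry, counterstain, optics (Gaussian PSF)
#' and sensor model (pixel scale, read noise, 8-bit quantization).
#'
#' @param preset A [category_preset()] (or a score string, resolved through
#'   [default_presets()]).
#' @param n_cells Cells per specimen (protocol: 10). 0 is allowed and yields
#'   a background-only image.
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @param cell_radius_range Cell radius range (um).
#' @param nucleus_fraction Nucleus radius as a fraction of the cell radius.
#' @param nucleus_od Hematoxylin OD of the nucleus.
#' @param completeness Fraction of the circumference that is stained, (0, 1].
#' @param psf_sigma_um Gaussian PSF sigma (um).
#' @param pixel_scale Pixels per micrometer (scanner resolution).
#' @param rgb_noise_sd Gaussian RGB noise SD in grey levels.
#' @param canvas_um Square canvas side (um).
#' @param background_h_od Mean OD of the faint hematoxylin background wash.
#' @param clearance_um Minimal gap kept between membrane circles and to the
#'   canvas edge (keeps line profiles from crossing neighboring cells).
#' @param ish_label `"positive"`, `"negative"` or `"none"`; annotation only,
#'   never feeds back into the generative model.
#' @return Object of class `specimen_config`.
#' @export
specimen_config <- function(preset, n_cells = 10, seed = 1,
                            cell_radius_range = c(6, 12),
                            nucleus_fraction = 0.5, nucleus_od = 0.6,
                            completeness = 1.0,
                            psf_sigma_um = 0.10, pixel_scale = 5.11,
                            rgb_noise_sd = 2, canvas_um = 140,
                            background_h_od = 0.02, clearance_um = 4,
                            ish_label = "none") {
  if (is.character(preset)) preset <- default_presets(preset)
  stopifnot(inherits(preset, "category_preset"),
            n_cells >= 0, psf_sigma_um >= 0, pixel_scale > 0,
            completeness > 0, completeness <= 1,
            length(cell_radius_range) == 2,
            cell_radius_range[1] > 0,
            cell_radius_range[1] <= cell_radius_range[2])
  ish_label <- match.arg(ish_label, c("none", "positive", "negative"))
  structure(
    list(preset = preset, n_cells = as.integer(n_cells),
         seed = as.integer(seed),
         cell_radius_range = cell_radius_range,
         nucleus_fraction = nucleus_fraction, nucleus_od = nucleus_od,
         completeness = completeness, psf_sigma_um = psf_sigma_um,
         pixel_scale = pixel_scale, rgb_noise_sd = rgb_noise_sd,
         canvas_um = canvas_um, background_h_od = background_h_od,
         clearance_um = clearance_um, ish_label = ish_label),
    class = "specimen_config"
  )
}

# Non-overlapping circle placement by random sequential rejection sampling.
place_cells <- function(cfg) {
  n <- cfg$n_cells
  if (n == 0) {
    return(data.frame(cx_um = numeric(0), cy_um = numeric(0),
                      radius_um = numeric(0)))
  }
  rmax <- cfg$cell_radius_range[2]
  margin <- rmax + cfg$clearance_um
  lo <- margin
  hi <- cfg$canvas_um - margin
  if (hi <= lo) stop("canvas too small for the requested cell radii")
  # crude feasibility: random sequential packing jams near ~50% coverage
  eff_r <- mean(cfg$cell_radius_range) + cfg$clearance_um / 2
  if (n * pi * eff_r^2 > 0.45 * (hi - lo + 2 * eff_r)^2) {
    stop("canvas too small for n_cells: expected packing density too high")
  }
  r <- stats::runif(n, cfg$cell_radius_range[1], cfg$cell_radius_range[2])
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:5000) {
      x <- stats::runif(1, lo, hi)
      y <- stats::runif(1, lo, hi)
      if (i == 1) { ok <- TRUE } else {
        j <- seq_len(i - 1)
        ok <- all(sqrt((cx[j] - x)^2 + (cy[j] - y)^2) >=
                    r[j] + r[i] + cfg$clearance_um)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; break }
    }
    if (!ok) stop("could not place ", n, " non-overlapping cells; ",
                  "increase canvas_um or reduce n_cells")
  }
  data.frame(cx_um = cx, cy_um = cy, radius_um = r)
}

# Smoothed indicator: box of half-width h centered at 0, convolved with a
# Gaussian of sd sigma, evaluated at (signed or absolute) distance x.
blurred_box <- function(x, h, sigma) {
  if (sigma <= 0) return(as.numeric(abs(x) <= h))
  stats::pnorm((h - x) / sigma) - stats::pnorm((-h - x) / sigma)
}

#' Render one synthetic IHC specimen
#'
#' Builds continuous-space optical-density fields -- a DAB annulus of the
#' cell's true width centered on each cell perimeter (over its stained arc)
#' and a hematoxylin nucleus disk -- convolved analytically with the Gaussian
#' PSF, samples them at pixel centers, remixes to RGB through the
#' Beer-Lambert stain model, adds Gaussian read noise and quantizes to 8 bits.
#'
#' @param cfg A [specimen_config()].
#' @param stains A [stain_matrix()] used for remixing.
#' @return List with `image` (an [rgb_image()]) and `truth` (per-cell
#'   data.frame: `cell_id`, `cx_um`, `cy_um`, `radius_um`, `true_width_um`,
#'   `true_amplitude`, `completeness`, `arc_center_rad`).
#' @export
render_specimen <- function(cfg, stains = default_stain_matrix()) {
  stopifnot(inherits(cfg, "specimen_config"))
  set.seed(cfg$seed)
  s <- cfg$pixel_scale
  npx <- as.integer(round(cfg$canvas_um * s))
  cells <- place_cells(cfg)
  pars <- sample_cell_params(cfg$preset, nrow(cells))
  arc_center <- stats::runif(nrow(cells), 0, 2 * pi)
  truth <- cbind(
    data.frame(cell_id = seq_len(nrow(cells))), cells, pars,
    data.frame(completeness = rep(cfg$completeness, nrow(cells)),
               arc_center_rad = arc_center)
  )

  dab <- matrix(0, npx, npx)
  hem <- matrix(0, npx, npx)
  sig <- cfg$psf_sigma_um
  # pixel centers in um: column j -> x=(j-0.5)/s, row i -> y=(i-0.5)/s
  ax <- (seq_len(npx) - 0.5) / s
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    reach <- tr$radius_um + tr$true_width_um / 2 + 4 * sig + 2 / s
    jj <- which(ax >= tr$cx_um - reach & ax <= tr$cx_um + reach)
    ii <- which(ax >= tr$cy_um - reach & ax <= tr$cy_um + reach)
    dx <- ax[jj] - tr$cx_um
    dy <- ax[ii] - tr$cy_um
    d <- sqrt(outer(dy^2, dx^2, "+"))       # rows = y, cols = x
    band <- blurred_box(d - tr$radius_um, tr$true_width_um / 2, sig)
    if (tr$completeness < 1) {
      th <- atan2(outer(dy, rep(1, length(dx))), outer(rep(1, length(dy)), dx))
      adiff <- abs(((th - tr$arc_center_rad + pi) %% (2 * pi)) - pi)
      arc_half_um <- pi * tr$completeness * tr$radius_um
      band <- band * blurred_box(adiff * tr$radius_um, arc_half_um, sig)
    }
    dab[ii, jj] <- dab[ii, jj] + tr$true_amplitude * band
    rnuc <- cfg$nucleus_fraction * tr$radius_um
    hem[ii, jj] <- hem[ii, jj] +
      cfg$nucleus_od * blurred_box(d, rnuc, sig)
  }
  if (cfg$background_h_od > 0) {
    hem <- hem + pmax(0, stats::rnorm(npx * npx, cfg$background_h_od,
                                      cfg$background_h_od / 2))
  }
  img <- remix(list(hematoxylin = hem, dab = dab), stains,
               pixel_scale = s, noise_sd = cfg$rgb_noise_sd)
  list(image = img, truth = truth)
}

#' Cohort configuration
#'
#' A cohort is a set of specimens per scoring category, mirroring the study
#' design: 40 specimens per category, 10 cells each, with the equivocal 2+
#' category split 20/20 into ISH-positive and ISH-negative labels drawn from
#' the same generative model (the labels carry no signal by construction).
#'
#' @param n_per_category Specimens per category.
#' @param categories Character vector of categories to generate.
#' @param master_seed Integer master seed; per-specimen seeds are derived
#'   from it (see Details).
#' @param presets Named list of [category_preset()]s.
#' @param ... Further arguments forwarded to [specimen_config()] for every
#'   specimen (e.g. `n_cells`, `psf_sigma_um`, `canvas_um`).
#'
#' @details Per-specimen seeds are derived from the master seed by a single
#' `sample.int(2^31 - 2, n)` draw under `set.seed(master_seed)`, so a cohort
#' is reproducible across platforms from the master seed alone.
#'
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_category = 40,
                          categories = c("1+", "2+", "3+"),
                          master_seed = 1,
                          presets = default_presets(), ...) {
  stopifnot(n_per_category >= 1, all(categories %in% names(presets)))
  structure(
    list(n_per_category = as.integer(n_per_category),
         categories = categories, master_seed = as.integer(master_seed),
         presets = presets, specimen_args = list(...)),
    class = "cohort_config"
  )
}

#' Build the specimen plan of a cohort
#'
#' Expands a [cohort_config()] into one row per specimen with its derived
#' seed and ISH label (2+ specimens only: first half positive, second half
#' negative).
#'
#' @param cfg A [cohort_config()].
#' @return `data.frame(specimen_id, score_preset, ish_label, seed)`.
#' @export
cohort_plan <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_per_category
  plan <- do.call(rbind, lapply(cfg$categories, function(sc) {
    ish <- rep("none", n)
    if (sc == "2+") {
      ish <- rep(c("positive", "negative"), c(ceiling(n / 2), floor(n / 2)))
    }
    data.frame(
      specimen_id = sprintf("%s_%03d", sub("\\+", "plus", sc), seq_len(n)),
      score_preset = sc, ish_label = ish
    )
  }))
  set.seed(cfg$master_seed)
  plan$seed <- sample.int(.Machine$integer.max - 1L, nrow(plan))
  plan
}

#' Generate a synthetic cohort
#'
#' Renders every specimen of the plan and collects the ground-truth manifest.
#' Images can be kept in memory, written to disk as PPM, or handed to a
#' callback and discarded (the memory-friendly path used by the measurement
#' pipeline).
#'
#' @param cfg A [cohort_config()].
#' @param out_dir If non-NULL, images are written here as
#'   `<specimen_id>.ppm` together with `manifest.csv`.
#' @param keep_images Keep rendered images in the returned list.
#' @param callback Optional `function(specimen_id, image, truth)` invoked per
#'   specimen right after rendering.
#' @return List with `plan`, `truth` (manifest: one row per cell, including
#'   specimen columns) and, if `keep_images`, `images` (named list).
#' @export
generate_cohort <- function(cfg, out_dir = NULL, keep_images = FALSE,
                            callback = NULL) {
  plan <- cohort_plan(cfg)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- file.path(out_dir, paste0(plan$specimen_id, ".ppm"))
    if (anyDuplicated(paths)) stop("duplicate output paths in plan")
  }
  images <- if (keep_images) stats::setNames(vector("list", nrow(plan)),
                                             plan$specimen_id)
  truth_all <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    scfg <- do.call(specimen_config, c(
      list(preset = cfg$presets[[plan$score_preset[i]]],
           seed = plan$seed[i], ish_label = plan$ish_label[i]),
      cfg$specimen_args
    ))
    spec <- render_specimen(scfg)
    tr <- spec$truth
    tr <- cbind(data.frame(specimen_id = plan$specimen_id[i],
                           score_preset = plan$score_preset[i],
                           ish_label = plan$ish_label[i],
                           seed = plan$seed[i]), tr)
    truth_all[[i]] <- tr
    if (!is.null(out_dir)) write_ppm(spec$image, paths[i])
    if (keep_images) images[[i]] <- spec$image
    if (!is.null(callback)) callback(plan$specimen_id[i], spec$image, tr)
  }
  truth <- do.call(rbind, truth_all)
  if (!is.null(out_dir)) {
    utils::write.csv(truth, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  out <- list(plan = plan, truth = truth)
  if (keep_images) out$images <- images
  out
}
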