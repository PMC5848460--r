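#' Unit stain vector
#'
#' A stain's absorbance signature: its relative optical density in the R, G
#' and B channels, normalized to unit Euclidean length. Optical density is
#' base-10 throughout (Ruifrok-Johnston convention).
#'
#' @param name Stain label, e.g. `"dab"` or `"hematoxylin"`.
#' @param od_rgb Numeric length-3 vector of non-negative OD components, at
#'   least one positive; normalized internally.
#' @return An object of class `stain_vector`.
#' @export
stain_vector <- function(name, od_rgb) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(od_rgb), length(od_rgb) == 3)
  if (any(od_rgb < 0) || all(od_rgb == 0)) {
    stop("od_rgb must be non-negative with at least one positive component")
  }
  v <- od_rgb / sqrt(sum(od_rgb^2))
  structure(list(name = name, od_rgb = v), class = "stain_vector")
}

#' Stain matrix for mixing and unmixing
#'
#' Assembles two or three [stain_vector()]s into the 3x3 matrix used both to
#' render images (forward Beer-Lambert mixing) and to separate them (color
#' deconvolution). When only two stains are given, the third row is the
#' normalized cross product of the first two (the residual channel), which
#' guarantees invertibility for non-collinear stains.
#'
#' @param stains List of 2 or 3 [stain_vector()] objects.
#' @return Object of class `stain_matrix`: a list with `m` (3x3 matrix, rows =
#'   stains, columns = RGB) and `names` (stain labels).
#' @export
stain_matrix <- function(stains) {
  stopifnot(is.list(stains), length(stains) %in% c(2L, 3L),
            all(vapply(stains, inherits, logical(1), "stain_vector")))
  m <- t(vapply(stains, function(s) s$od_rgb, numeric(3)))
  nm <- vapply(stains, function(s) s$name, character(1))
  if (nrow(m) == 2L) {
    res <- c(m[1, 2] * m[2, 3] - m[1, 3] * m[2, 2],
             m[1, 3] * m[2, 1] - m[1, 1] * m[2, 3],
             m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
    if (sqrt(sum(res^2)) < 1e-9) stop("stain vectors are collinear")
    m <- rbind(m, res / sqrt(sum(res^2)))
    nm <- c(nm, "residual")
  }
  if (abs(det(m)) < 1e-9) stop("stain matrix is singular")
  rownames(m) <- nm
  colnames(m) <- c("r", "g", "b")
  structure(list(m = m, names = nm), class = "stain_matrix")
}

#' Default hematoxylin-DAB stain matrix
#'
#' The published Ruifrok-Johnston absorbance vectors for hematoxylin
#' (0.650, 0.704, 0.286) and DAB (0.269, 0.568, 0.778), unit-normalized, with
#' a residual third channel.
#'
#' @return A [stain_matrix()].
#' @export
default_stain_matrix <- function() {
  stain_matrix(list(
    stain_vector("hematoxylin", c(0.650, 0.704, 0.286)),
    stain_vector("dab", c(0.269, 0.568, 0.778))
  ))
}

#' RGB image container
#'
#' An 8-bit RGB raster with a physical pixel scale. Pixels are stored as an
#' `H x W x 3` integer array in `[0, 255]`.
#'
#' @param pixels `H x W x 3` numeric array of values in `[0, 255]`.
#' @param pixel_scale Pixels per micrometer (> 0).
#' @return Object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, pixel_scale) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (pixel_scale <= 0) stop("pixel_scale must be positive")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, pixel_scale = pixel_scale),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %d x %d px, %.2f px/um (%.1f x %.1f um)>\n",
              d[1], d[2], x$pixel_scale,
              d[1] / x$pixel_scale, d[2] / x$pixel_scale))
  invisible(x)
}

#' Convert RGB transmission to optical density
#'
#' Per-channel Beer-Lambert transform `OD_c = -log10(max(I_c, eps) / I0)`.
#' The one-grey-level floor `eps` keeps black pixels finite.
#'
#' @param img An [rgb_image()], or a bare `H x W x 3` array.
#' @param i0 Incident (white) level, default 255.
#' @param eps Grey-level floor before the log, default 1.
#' @return `H x W x 3` numeric array of non-negative optical densities.
#' @export
rgb_to_od <- function(img, i0 = 255, eps = 1) {
  if (inherits(img, "rgb_image")) img <- img$pixels
  stopifnot(is.array(img), length(dim(img)) == 3, dim(img)[3] == 3)
  if (i0 <= 0) stop("i0 must be positive")
  -log10(pmax(img, eps) / i0)
}

#' Color deconvolution
#'
#' Per-pixel linear unmixing of channel optical densities into per-stain
#' concentration maps: solves `od = t(M) %*% conc` for each pixel and clips
#' negative solutions to zero.
#'
#' @param od `H x W x 3` array of channel optical densities (see
#'   [rgb_to_od()]).
#' @param stains A [stain_matrix()].
#' @return Named list of `H x W` concentration matrices (base-10 OD units),
#'   one per stain, class `od_image`.
#' @export
deconvolve <- function(od, stains = default_stain_matrix()) {
  stopifnot(inherits(stains, "stain_matrix"),
            is.array(od), length(dim(od)) == 3, dim(od)[3] == 3)
  d <- dim(od)
  flat <- matrix(od, ncol = 3)             # pixels x channels
  conc <- flat %*% solve(stains$m)          # solve conc %*% M = od
  conc[conc < 0] <- 0
  out <- lapply(seq_along(stains$names), function(i) {
    matrix(conc[, i], nrow = d[1], ncol = d[2])
  })
  names(out) <- stains$names
  structure(out, class = "od_image")
}

#' Remix stain concentrations into an RGB image
#'
#' Forward Beer-Lambert rendering: `I_c = round(I0 * 10^(-sum_s conc_s *
#' M[s, c]))`, clamped to `[0, 255]`.
#'
#' @param conc Named list of `H x W` concentration matrices (subset of the
#'   stains in `stains`).
#' @param stains A [stain_matrix()].
#' @param pixel_scale Pixels per micrometer recorded on the output image.
#' @param i0 White level, default 255.
#' @param noise_sd Gaussian read-noise SD in grey levels added per channel
#'   before quantization (default 0).
#' @return An [rgb_image()].
#' @export
remix <- function(conc, stains = default_stain_matrix(), pixel_scale = 5.11,
                  i0 = 255, noise_sd = 0) {
  stopifnot(inherits(stains, "stain_matrix"), is.list(conc), length(conc) >= 1)
  if (any(vapply(conc, min, numeric(1)) < 0)) {
    stop("concentrations must be non-negative")
  }
  d <- dim(conc[[1]])
  od <- array(0, dim = c(d[1], d[2], 3))
  for (nm in names(conc)) {
    row <- match(nm, stains$names)
    if (is.na(row)) stop("unknown stain in concentration list: ", nm)
    for (ch in 1:3) od[, , ch] <- od[, , ch] + conc[[nm]] * stains$m[row, ch]
  }
  px <- i0 * 10^(-od)
  if (noise_sd > 0) px <- px + stats::rnorm(length(px), sd = noise_sd)
  px <- round(px)
  px[px < 0] <- 0
  px[px > 255] <- 255
  rgb_image(px, pixel_scale)
}

#' Relative DAB intensity on the paper's inverted scale
#'
#' Reconstructs the DAB-only grey value from the mean optical density of a
#' region, `G = round(255 * 10^(-mean OD))`, and returns the inverted relative
#' intensity `100 * (255 - G) / 255`, so that 0% is white (unstained) and
#' 100% is black (fully saturated staining).
#'
#' @param dab_conc Numeric vector or matrix of DAB concentrations (OD) over a
#'   non-empty region.
#' @return Relative intensity in percent, in `[0, 100]`.
#' @examples
#' dab_intensity_pct(1.0)  # 89.8
#' @export
dab_intensity_pct <- function(dab_conc) {
  v <- as.numeric(dab_conc)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("region is empty")
  g <- round(255 * 10^(-mean(v)))
  100 * (255 - g) / 255
}
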