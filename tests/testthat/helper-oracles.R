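# Independent numeric oracles used across the suite.

# FWHM of a unit box of width w convolved with a Gaussian PSF (sd sigma),
# by brute-force discrete 1-D convolution on a fine grid. Independent of the
# package's analytic renderer and of its crossing-interpolation code path.
box_gauss_fwhm_oracle <- function(w, sigma, dx = 5e-4) {
  half_span <- w / 2 + max(6 * sigma, 0.5)
  x <- seq(-half_span, half_span, by = dx)
  box <- as.numeric(abs(x) <= w / 2)
  if (sigma <= 0) return(w)
  xk <- seq(-5 * sigma, 5 * sigma, by = dx)
  kern <- exp(-xk^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  y <- stats::convolve(box, rev(kern), type = "open")
  xo <- seq(min(x) - (length(kern) - 1) / 2 * dx, by = dx,
            length.out = length(y))
  half <- max(y) / 2
  above <- which(y >= half)
  i1 <- above[1]; i2 <- above[length(above)]
  xl <- xo[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * dx
  xr <- xo[i2] + (half - y[i2]) / (y[i2 + 1] - y[i2]) * dx
  xr - xl
}

# Textbook Welch re-implementation, structured differently from the package
# (works from summary statistics).
welch_oracle <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  va <- sum((a - ma)^2) / (length(a) - 1)
  vb <- sum((b - mb)^2) / (length(b) - 1)
  qa <- va / length(a); qb <- vb / length(b)
  t <- (ma - mb) / sqrt(qa + qb)
  df <- (qa + qb)^2 / (qa^2 / (length(a) - 1) + qb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Small, fast specimen configuration for rendering tests.
tiny_specimen <- function(..., seed = 11) {
  specimen_config(
    preset = category_preset("2+", 1.0, 0.0),
    n_cells = 2, seed = seed, cell_radius_range = c(6, 8),
    canvas_um = 50, rgb_noise_sd = 0, background_h_od = 0, ...
  )
}
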