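#' Numerical aperture of a microscope objective
#'
#' Computes `NA = n * sin(alpha)` from the refractive index of the immersion
#' medium and the half-angle of the maximum cone of light accepted by the
#' objective.
#'
#' @param n Refractive index of the immersion medium (>= 1; 1.0 for air,
#'   about 1.515 for immersion oil).
#' @param alpha_deg Half-angle of the acceptance cone, in degrees, in (0, 90].
#' @return The numerical aperture, a dimensionless value in (0, n].
#' @examples
#' numerical_aperture(1.0, 30)   # 0.5
#' numerical_aperture(1.515, 41.3)
#' @export
numerical_aperture <- function(n, alpha_deg) {
  stopifnot(is.numeric(n), is.numeric(alpha_deg))
  if (any(n < 1)) stop("refractive index n must be >= 1")
  if (any(alpha_deg <= 0 | alpha_deg > 90)) {
    stop("half-angle must be in (0, 90] degrees")
  }
  n * sin(alpha_deg * pi / 180)
}

#' Diffraction-limited resolution by Abbe's law
#'
#' The minimum resolvable distance of a light-microscope objective,
#' `d = lambda / (2 * NA)`, returned in micrometers.
#'
#' @param lambda_nm Wavelength of the illumination in nanometers (> 0).
#' @param na Numerical aperture of the objective (> 0).
#' @return Resolution `d` in micrometers.
#' @examples
#' abbe_resolution(600, 0.3)   # 1.0 um (a typical 10x objective)
#' abbe_resolution(600, 0.14)  # ~2.14 um (5x)
#' @export
abbe_resolution <- function(lambda_nm, na) {
  stopifnot(is.numeric(lambda_nm), is.numeric(na))
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  if (any(na <= 0)) stop("numerical aperture must be positive")
  lambda_nm / (2000 * na)
}

#' Objective specification
#'
#' A labelled microscope objective with nominal magnification and numerical
#' aperture. If `half_angle_deg` is supplied it must be consistent with
#' `na = n * sin(alpha)`.
#'
#' @param name Label, e.g. `"10x"`.
#' @param magnification Nominal magnification (> 0).
#' @param na Numerical aperture, in (0, n].
#' @param n Refractive index of the medium (default 1.0, air).
#' @param half_angle_deg Optional half-angle in degrees; checked against `na`.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(name, magnification, na, n = 1.0,
                           half_angle_deg = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (magnification <= 0) stop("magnification must be positive")
  if (n < 1) stop("refractive index n must be >= 1")
  if (na <= 0 || na > n) stop("numerical aperture must lie in (0, n]")
  if (!is.null(half_angle_deg)) {
    if (abs(numerical_aperture(n, half_angle_deg) - na) > 1e-9) {
      stop("half_angle_deg inconsistent with na: expected na = n*sin(alpha)")
    }
  }
  structure(
    list(name = name, magnification = magnification, na = na, n = n,
         half_angle_deg = half_angle_deg),
    class = "objective_spec"
  )
}

#' Standard diagnostic objectives
#'
#' The set of objectives considered by the magnification rule, with their
#' conventional numerical apertures (5x NA 0.14, 10x NA 0.3, 20x NA 0.5,
#' 100x NA 0.75).
#'
#' @return A list of [objective_spec()] objects.
#' @export
default_objectives <- function() {
  list(
    objective_spec("5x", 5, 0.14),
    objective_spec("10x", 10, 0.30),
    objective_spec("20x", 20, 0.50),
    objective_spec("100x", 100, 0.75)
  )
}

#' IHC score levels
#'
#' Ordered factor levels for the four-tier membranous staining score.
#' @return Character vector `c("0", "1+", "2+", "3+")`.
#' @export
score_levels <- function() c("0", "1+", "2+", "3+")

score_factor <- function(x) {
  factor(x, levels = score_levels(), ordered = TRUE)
}

#' Width thresholds for score classification
#'
#' The optical-resolution windows of the magnification rule: a precipitate is
#' recognizable with a given objective only when its width reaches that
#' objective's resolution limit. The lower window edges are, by default, the
#' rounded resolutions 0.4 um (40x), 1.0 um (10x) and 2.0 um (5x). The 5x
#' formula value `abbe_resolution(600, 0.14) = 2.143` um is also legitimate
#' and can be passed explicitly.
#'
#' @param w_min_1plus,w_min_2plus,w_min_3plus Strictly increasing positive
#'   widths (um): minimal band width for scores 1+, 2+ and 3+.
#' @return An object of class `score_thresholds`.
#' @examples
#' default_thresholds()
#' score_thresholds(0.4, 1.0, abbe_resolution(600, 0.14))
#' @export
score_thresholds <- function(w_min_1plus = 0.4, w_min_2plus = 1.0,
                             w_min_3plus = 2.0) {
  w <- c(w_min_1plus, w_min_2plus, w_min_3plus)
  stopifnot(is.numeric(w), length(w) == 3, all(is.finite(w)))
  if (!(w[1] > 0 && w[1] < w[2] && w[2] < w[3])) {
    stop("thresholds must be strictly increasing and positive")
  }
  structure(
    list(w_min_1plus = w[1], w_min_2plus = w[2], w_min_3plus = w[3]),
    class = "score_thresholds"
  )
}

#' @rdname score_thresholds
#' @export
default_thresholds <- function() score_thresholds()

#' Classify a membrane width into an IHC score
#'
#' Maps measured precipitate widths to scores through the resolution windows:
#' score 0 below `w_min_1plus` (or no measurable precipitate, `NA`), 1+ in
#' `[w_min_1plus, w_min_2plus)`, 2+ in `[w_min_2plus, w_min_3plus)`, 3+ at or
#' above `w_min_3plus`. Lower bounds are inclusive, so a width exactly at a
#' window edge takes the higher score.
#'
#' @param w Width(s) in micrometers; `NA` encodes "no measurable precipitate"
#'   and maps to score 0.
#' @param thresholds A [score_thresholds()] object.
#' @return Ordered factor with levels `0 < 1+ < 2+ < 3+`.
#' @examples
#' classify_width(c(0.2, 0.64, 1.0, 2.14), default_thresholds())
#' @export
classify_width <- function(w, thresholds = default_thresholds()) {
  stopifnot(inherits(thresholds, "score_thresholds"))
  if (any(!is.na(w) & w < 0)) stop("width must be non-negative")
  cuts <- c(thresholds$w_min_1plus, thresholds$w_min_2plus,
            thresholds$w_min_3plus)
  idx <- findInterval(w, cuts) + 1L  # NA stays NA
  idx[is.na(w)] <- 1L
  score_factor(score_levels()[idx])
}
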