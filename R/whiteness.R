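#' CIE 1964 10-degree observer on a wavelength grid
#'
#' Color-matching functions of the CIE 1964 supplementary standard
#' observer, evaluated from the published multi-lobe Gaussian (log-normal)
#' analytic approximations rather than from the official tabulated data,
#' which keeps the package free of bundled tables at the cost of a few
#' percent of local accuracy. All downstream quantities (normalization
#' constant, whiteboard white point) are computed from the same functions,
#' so whiteness values are internally consistent. Supply your own table to
#' [tristimulus()] for strict CIE-table fidelity.
#'
#' @param grid Wavelength grid (nm).
#' @return Matrix with columns `xbar`, `ybar`, `zbar` (one row per band,
#'   all nonnegative).
#' @export
cie_observer_1964 <- function(grid = wavelength_grid()) {
  wl <- as.numeric(grid)
  xbar <- 0.398 * exp(-1250 * log((wl + 570.1) / 1014)^2) +
    1.132 * exp(-234 * log((1338 - wl) / 743.5)^2)
  ybar <- 1.011 * exp(-0.5 * ((wl - 556.1) / 46.14)^2)
  zbar <- 2.060 * exp(-32 * log((wl - 265.8) / 180.4)^2)
  cbind(xbar = pmax(xbar, 0), ybar = pmax(ybar, 0), zbar = pmax(zbar, 0))
}

#' Daylight (D65-like) illuminant on a wavelength grid
#'
#' Relative spectral power of a smooth daylight approximation: a Planckian
#' radiator at 6504 K (the correlated color temperature of standard
#' illuminant D65), normalized to 100 at 560 nm. This reproduces the broad
#' shape of D65 over the visible range without its fine structure; as with
#' the observer functions, any externally tabulated spectral power
#' distribution on the same grid can be passed instead.
#'
#' @param grid Wavelength grid (nm).
#' @return Numeric vector of relative power, one value per band.
#' @export
illuminant_d65 <- function(grid = wavelength_grid()) {
  wl <- as.numeric(grid)
  c2 <- 1.4388e7  # nm K
  planck <- function(l) l^-5 / (exp(c2 / (l * 6504)) - 1)
  100 * planck(wl) / planck(560)
}

#' Tristimulus values by the equal-interval wavelength method
#'
#' Computes X10, Y10, Z10 as weighted sums of reflectance, illuminant
#' power and the 10-degree color-matching functions over the grid, with
#' the grid step as the quadrature interval:
#' `X10 = K * sum(delta * R * xbar * step)` and likewise for Y10, Z10.
#'
#' Under the standard convention (`k_convention = "illuminant"`) the
#' normalization constant `K = 100 / sum(R * ybar * step)` depends only on
#' the illuminant, so a perfect reflector scores Y10 = 100 and real
#' samples score below it. The alternative `"sample"` convention folds the
#' sample reflectance into K as well, which forces Y10 = 100 for every
#' sample and is retained only to reproduce that literal reading of the
#' normalization; it is not useful for comparing samples.
#'
#' @param set A `spectrum_set` (or a single numeric reflectance vector on
#'   `grid`).
#' @param illuminant Per-band relative spectral power (default
#'   [illuminant_d65()] on the set's grid).
#' @param observer Observer matrix as from [cie_observer_1964()].
#' @param k_convention `"illuminant"` (standard) or `"sample"`.
#' @param grid Grid used when `set` is a bare numeric vector.
#' @return Data frame with one row per sample: `X10`, `Y10`, `Z10`, `K`.
#' @export
tristimulus <- function(set, illuminant = NULL, observer = NULL,
                        k_convention = c("illuminant", "sample"),
                        grid = wavelength_grid()) {
  k_convention <- match.arg(k_convention)
  if (!inherits(set, "spectrum_set")) {
    set <- spectrum_set(matrix(set, nrow = 1), grid)
  }
  g <- set$grid
  step <- as.numeric(g)[2] - as.numeric(g)[1]
  if (is.null(illuminant)) illuminant <- illuminant_d65(g)
  if (is.null(observer)) observer <- cie_observer_1964(g)
  if (length(illuminant) != length(g) || nrow(observer) != length(g)) {
    stop("illuminant/observer are not on the set's wavelength grid")
  }
  if (all(illuminant == 0)) stop("all-zero illuminant")
  # equal-interval summation with trapezoidal end weights: the integration
  # range truncates at 450 nm where some matching functions are still far
  # from zero, and the half-weight endpoints keep the sums consistent with
  # a trapezoid quadrature of the same integrand
  wq <- rep(step, length(g))
  wq[c(1, length(wq))] <- step / 2
  Wm <- observer * illuminant * wq
  raw <- set$values %*% Wm   # n x 3, un-normalized sums
  if (k_convention == "illuminant") {
    K <- rep(100 / sum(illuminant * observer[, "ybar"] * wq), nrow(raw))
  } else {
    K <- ifelse(raw[, "ybar"] > 0, 100 / raw[, "ybar"], NA_real_)
  }
  data.frame(X10 = K * raw[, "xbar"], Y10 = K * raw[, "ybar"],
             Z10 = K * raw[, "zbar"], K = K, row.names = NULL)
}

#' Chromaticity coordinates from tristimulus values
#'
#' `x10 = X10 / (X10 + Y10 + Z10)`, `y10 = Y10 / (X10 + Y10 + Z10)`.
#' Invariant under scaling of all three tristimulus values.
#'
#' @param X10,Y10,Z10 Tristimulus values (vectors; the sum must be > 0).
#' @return Data frame with columns `x10`, `y10`.
#' @export
chromaticity <- function(X10, Y10, Z10) {
  s <- X10 + Y10 + Z10
  if (any(s <= 0)) stop("zero or negative tristimulus sum")
  data.frame(x10 = X10 / s, y10 = Y10 / s)
}

#' Whiteboard reference chromaticity
#'
#' Chromaticity coordinates `(xn, yn)` of the standard whiteboard, taken
#' by default as a perfect diffuse reflector under the given illuminant
#' and observer (i.e. the illuminant white point). Override with measured
#' whiteboard coordinates when available.
#'
#' @param illuminant,observer,grid As in [tristimulus()].
#' @return List with `xn` and `yn`.
#' @export
whiteboard_reference <- function(illuminant = NULL, observer = NULL,
                                 grid = wavelength_grid()) {
  ts <- tristimulus(rep(1, length(grid)), illuminant, observer, grid = grid)
  ch <- chromaticity(ts$X10, ts$Y10, ts$Z10)
  list(xn = ch$x10, yn = ch$y10)
}

#' Ganz whiteness index
#'
#' `W10 = Y10 + 800 * (xn - x10) + 1700 * (yn - y10)`: luminance plus
#' fixed-coefficient penalties for chromaticity shifts away from the
#' whiteboard reference. No clamping is applied.
#'
#' @param Y10 Luminance factor.
#' @param x10,y10 Sample chromaticity.
#' @param ref Whiteboard reference, a list with `xn`, `yn`
#'   (default [whiteboard_reference()]).
#' @return Numeric whiteness values.
#' @export
ganz_whiteness <- function(Y10, x10, y10, ref = whiteboard_reference()) {
  Y10 + 800 * (ref$xn - x10) + 1700 * (ref$yn - y10)
}

# Printed whiteness bands of the four browning grades and the midpoint
# thresholds between adjacent bands.
grade_bands <- data.frame(
  grade = 1:4,
  lower = c(61.05, 34.23, 25.08, 13.15),
  upper = c(81.84, 49.70, 34.66, 22.81)
)
grade_thresholds <- c(55.375, 34.445, 23.945)  # midpoints between bands

#' Grade whiteness into four browning levels
#'
#' Level 1 is pure white, Level 4 heavily browned. Grade boundaries are
#' the midpoints between the adjacent calibrated whiteness bands
#' ([61.05, 81.84], [34.23, 49.7], [25.08, 34.66], [13.15, 22.81]), i.e.
#' thresholds at 55.375, 34.445 and 23.945, so any value inside a band's
#' non-overlapping interior maps to that band's level. (Bands 2 and 3
#' overlap on [34.23, 34.66]; there the midpoint threshold decides.)
#' Values falling between bands are graded by
#' the same thresholds but flagged `"gap"`; values beyond the calibrated
#' extremes (below 13.15 or above 81.84) map to the nearest level and are
#' flagged `"out_of_calibration"`.
#'
#' @param W10 Numeric whiteness values.
#' @return Data frame with columns `W10`, `grade` (integer 1--4) and
#'   `flag` (`"ok"`, `"gap"`, or `"out_of_calibration"`).
#' @export
grade_whiteness <- function(W10) {
  stopifnot(is.numeric(W10), all(is.finite(W10)))
  grade <- 4L - findInterval(W10, rev(grade_thresholds))
  in_band <- vapply(W10, function(w) {
    any(w >= grade_bands$lower & w <= grade_bands$upper)
  }, logical(1))
  flag <- ifelse(in_band, "ok",
                 ifelse(W10 < min(grade_bands$lower) |
                          W10 > max(grade_bands$upper),
                        "out_of_calibration", "gap"))
  data.frame(W10 = W10, grade = as.integer(grade), flag = flag)
}

#' Whiteness results for a batch of spectra
#'
#' Composes tristimulus computation, chromaticity, the Ganz whiteness
#' index and four-level grading for every spectrum in a set, preserving
#' sample order.
#'
#' @param set A `spectrum_set`.
#' @param ref Whiteboard reference (default: illuminant white point
#'   computed from the same tables).
#' @param illuminant,observer,k_convention As in [tristimulus()].
#' @return Data frame with one row per sample: `sample_id`, `X10`, `Y10`,
#'   `Z10`, `x10`, `y10`, `K`, `W10`, `grade`, `flag`.
#' @export
whiteness_pipeline <- function(set, ref = NULL, illuminant = NULL,
                               observer = NULL,
                               k_convention = c("illuminant", "sample")) {
  stopifnot(inherits(set, "spectrum_set"))
  k_convention <- match.arg(k_convention)
  g <- set$grid
  if (is.null(illuminant)) illuminant <- illuminant_d65(g)
  if (is.null(observer)) observer <- cie_observer_1964(g)
  if (is.null(ref)) ref <- whiteboard_reference(illuminant, observer, g)
  ts <- tristimulus(set, illuminant, observer, k_convention)
  ch <- chromaticity(ts$X10, ts$Y10, ts$Z10)
  w <- ganz_whiteness(ts$Y10, ch$x10, ch$y10, ref)
  gr <- grade_whiteness(w)
  data.frame(sample_id = set$sample_id, ts[c("X10", "Y10", "Z10")], ch,
             K = ts$K, W10 = w, grade = gr$grade, flag = gr$flag,
             row.names = NULL)
}
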