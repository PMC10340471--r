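#' Configuration for the synthetic spectra generator
#'
#' Collects the knobs of the generative model used to emulate visible-range
#' diffuse reflectance of white button mushrooms: sample count, the
#' moisture range of fresh mushrooms, the browning-grade mixture, the
#' per-sample multiplicative/additive scatter dispersions, and the
#' per-band measurement noise.
#'
#' @param n_samples Number of spectra to generate (>= 1).
#' @param moisture_range Two-element percent interval from which per-sample
#'   moisture is drawn uniformly. Default `c(80, 95)`, a typical wet-basis
#'   range for fresh A. bisporus tissue.
#' @param grade_mix Proportions of browning grades 1--4 (sums to 1).
#' @param scatter_slope_sd Log-scale SD of the per-sample multiplicative
#'   scatter factor `b_i ~ LogNormal(0, scatter_slope_sd)`.
#' @param scatter_offset_sd SD of the per-sample additive baseline
#'   `a_i ~ Normal(0, scatter_offset_sd)` (reflectance units).
#' @param noise_sd SD of independent per-band Gaussian measurement noise
#'   (reflectance units).
#' @param quadratic_moisture If `TRUE`, adds a small quadratic term to the
#'   moisture-to-absorption map so the signal is no longer exactly affine.
#' @param seed Integer seed.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_samples = 200,
                             moisture_range = c(80, 95),
                             grade_mix = c(0.25, 0.25, 0.25, 0.25),
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             noise_sd = 0.005,
                             quadratic_moisture = FALSE,
                             seed = 1L) {
  stopifnot(n_samples >= 1, length(moisture_range) == 2,
            moisture_range[1] < moisture_range[2],
            length(grade_mix) == 4, all(grade_mix >= 0),
            scatter_slope_sd >= 0, scatter_offset_sd >= 0, noise_sd >= 0)
  if (abs(sum(grade_mix) - 1) > 1e-8) stop("grade_mix proportions must sum to 1")
  structure(list(n_samples = as.integer(n_samples),
                 moisture_range = moisture_range,
                 grade_mix = grade_mix,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 noise_sd = noise_sd,
                 quadratic_moisture = isTRUE(quadratic_moisture),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Structural constants of the synthetic reflectance model
#'
#' Returns the deterministic ingredients of the clean synthetic spectrum
#' so that tests and diagnostics can reconstruct it by linear algebra:
#' the smooth base reflectance curve, the browning dip shape and per-grade
#' dip depths, the Gaussian absorption-band basis (centers at 475, 490,
#' 650, 690, 730 and 740 nm), and the affine map from moisture percent to
#' band depths.
#'
#' @param grid Wavelength grid.
#' @return List with `base` (numeric per band), `brown_shape` (per band),
#'   `grade_depth` (length 4), `bump_basis` (band-by-6 matrix),
#'   `depth_intercept` and `depth_slope` (length 6), and `bump_centers_nm`.
#' @export
synthetic_truth_model <- function(grid = wavelength_grid()) {
  wl <- as.numeric(grid)
  base <- 0.82 + 0.10 / (1 + exp(-(wl - 520) / 40))
  brown_shape <- exp(-(wl - 450) / 110)
  # Dip depths per grade, calibrated once by bisection so clean whiteness
  # medians of each grade fall at the centers of the four grading bands.
  grade_depth <- c(0.02216804, 0.22374117, 0.29086212, 0.35861890)
  centers <- c(475, 490, 650, 690, 730, 740)
  widths <- c(8, 8, 10, 10, 9, 6)
  slope <- c(0.0018, 0.0022, 0.0030, 0.0034, 0.0038, 0.0040)
  intercept <- -60 * slope  # zero absorption at 60% moisture
  basis <- sapply(seq_along(centers), function(k) {
    exp(-0.5 * ((wl - centers[k]) / widths[k])^2)
  })
  list(base = base, brown_shape = brown_shape, grade_depth = grade_depth,
       bump_basis = basis, depth_intercept = intercept, depth_slope = slope,
       bump_centers_nm = centers)
}

clean_spectrum_matrix <- function(moisture, grade, model, quadratic = FALSE) {
  depths <- outer(moisture, model$depth_slope) +
    matrix(model$depth_intercept, length(moisture), 6, byrow = TRUE)
  if (quadratic) {
    depths <- depths + 2e-5 * outer((moisture - 87.5)^2, model$depth_slope / mean(model$depth_slope))
  }
  brown <- 1 - outer(model$grade_depth[grade], model$brown_shape)
  sweep(brown, 2, model$base, `*`) - depths %*% t(model$bump_basis)
}

#' Generate synthetic mushroom reflectance spectra with ground truth
#'
#' Draws per-sample moisture and browning grade, builds the clean
#' reflectance `base * brown(grade) - sum_k c_k(moisture) g_k`, then applies
#' per-sample multiplicative/additive scatter and per-band Gaussian noise:
#' `observed = a_i + b_i * clean + eps`. Scatter parameters are recorded in
#' the ground truth so that scatter-correction methods can be validated
#' against them exactly.
#'
#' @param config A [generator_config()].
#' @param grid Wavelength grid.
#' @return List with `set` (a `spectrum_set` whose labels carry moisture
#'   percent, grade and clean whiteness) and `truth` (data frame with
#'   moisture, grade, whiteness, scatter `a`, `b`, plus attribute
#'   `"clean"` holding the noise- and scatter-free spectra).
#' @export
generate_spectra <- function(config = generator_config(),
                             grid = wavelength_grid()) {
  stopifnot(inherits(config, "generator_config"))
  model <- synthetic_truth_model(grid)
  n <- config$n_samples
  out <- with_seed(config$seed, {
    moisture <- stats::runif(n, config$moisture_range[1], config$moisture_range[2])
    grade <- sample.int(4, n, replace = TRUE, prob = config$grade_mix)
    a <- stats::rnorm(n, 0, config$scatter_offset_sd)
    b <- stats::rlnorm(n, 0, config$scatter_slope_sd)
    eps <- matrix(stats::rnorm(n * length(grid), 0, config$noise_sd),
                  n, length(grid))
    list(moisture = moisture, grade = grade, a = a, b = b, eps = eps)
  })
  clean <- clean_spectrum_matrix(out$moisture, out$grade, model,
                                 config$quadratic_moisture)
  observed <- out$a + clean * out$b + out$eps
  w <- whiteness_pipeline(spectrum_set(pmax(clean, 0), grid))$W10
  labels <- data.frame(moisture_pct = out$moisture, grade = out$grade,
                       whiteness = w)
  set <- spectrum_set(observed, grid, labels = labels)
  truth <- data.frame(sample_id = set$sample_id,
                      moisture_pct = out$moisture, grade = out$grade,
                      whiteness = w, scatter_a = out$a, scatter_b = out$b)
  attr(truth, "clean") <- clean
  list(set = set, truth = truth)
}

#' Recover moisture from clean synthetic spectra by linear algebra
#'
#' For noise- and scatter-free spectra of known grade, subtracting the
#' base-times-browning profile leaves exactly the weighted Gaussian band
#' basis; least squares on that basis recovers the band depths and the
#' affine depth-to-moisture map inverts them. Used to certify that the
#' generated signal carries exactly recoverable moisture information.
#'
#' @param clean Matrix of clean spectra (samples by bands).
#' @param grade Integer vector of browning grades.
#' @param grid Wavelength grid.
#' @return Numeric vector of recovered moisture percentages.
#' @export
moisture_from_clean <- function(clean, grade, grid = wavelength_grid()) {
  model <- synthetic_truth_model(grid)
  brown <- 1 - outer(model$grade_depth[grade], model$brown_shape)
  resid <- sweep(brown, 2, model$base, `*`) - clean
  depths <- t(qr.solve(model$bump_basis, t(resid)))
  m_est <- sweep(depths, 2, model$depth_intercept) %*%
    (1 / model$depth_slope) / 6
  as.numeric(m_est)
}

#' Generate a paired reference/device spectrum set for calibration
#'
#' Emulates the side-by-side acquisition used to calibrate a device
#' against a reference spectrometer: the device spectrum equals the
#' reference minus a fixed per-band offset profile, plus zero-mean
#' Gaussian jitter.
#'
#' @param set Reference `spectrum_set`.
#' @param offset_profile Per-band offset vector (reference minus device).
#' @param jitter_sd SD of per-band Gaussian jitter.
#' @param seed Integer seed.
#' @return A `spectrum_set` of device spectra aligned with `set`.
#' @export
generate_calibration_pair <- function(set, offset_profile, jitter_sd = 0,
                                      seed = 1L) {
  stopifnot(inherits(set, "spectrum_set"))
  if (length(offset_profile) != length(set$grid)) {
    stop("offset profile is not on the set's wavelength grid")
  }
  n <- length(set)
  jitter <- with_seed(seed, matrix(stats::rnorm(n * length(set$grid), 0, jitter_sd),
                                   n, length(set$grid)))
  device <- sweep(set$values, 2, offset_profile) + jitter
  spectrum_set(device, set$grid, sample_id = set$sample_id,
               labels = set$labels)
}
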