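#' Savitzky-Golay smoothing
#'
#' Replaces each band by the center value of a local least-squares
#' polynomial fit over a sliding window. Interior bands use the symmetric
#' window; the first and last half-windows are filled by evaluating the
#' polynomial fitted to the terminal window at the edge positions, so the
#' band count is preserved.
#'
#' @param set A `spectrum_set` (each spectrum smoothed independently).
#' @param window Odd window length in bands (default 7).
#' @param polyorder Polynomial degree (default 2, must be < `window`).
#' @return Smoothed `spectrum_set`.
#' @export
savitzky_golay <- function(set, window = 7, polyorder = 2) {
  stopifnot(inherits(set, "spectrum_set"))
  if (window %% 2 != 1) stop("Savitzky-Golay window must be odd")
  if (window < polyorder + 1) stop("window must exceed the polynomial order")
  if (window > length(set$grid)) stop("window longer than the spectrum")
  smoothed <- t(apply(set$values, 1, signal::sgolayfilt, p = polyorder,
                      n = window))
  spectrum_set(smoothed, set$grid, sample_id = set$sample_id,
               labels = set$labels)
}

#' Min-max normalization per spectrum
#'
#' Rescales each spectrum linearly to span [0, 1]. A unit-vector variant
#' (division by the Euclidean norm) is available for comparison.
#'
#' @param set A `spectrum_set` with non-constant spectra.
#' @param method `"minmax"` (default) or `"unit_norm"`.
#' @return Normalized `spectrum_set`.
#' @export
normalize_spectra <- function(set, method = c("minmax", "unit_norm")) {
  method <- match.arg(method)
  stopifnot(inherits(set, "spectrum_set"))
  out <- t(apply(set$values, 1, function(v) {
    if (method == "minmax") {
      rng <- range(v)
      if (rng[1] == rng[2]) stop("cannot min-max normalize a constant spectrum")
      (v - rng[1]) / (rng[2] - rng[1])
    } else {
      nrm <- sqrt(sum(v^2))
      if (nrm == 0) stop("cannot normalize an all-zero spectrum")
      v / nrm
    }
  }))
  spectrum_set(out, set$grid, sample_id = set$sample_id, labels = set$labels)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum to zero mean and unit standard
#' deviation using the population (1/N) standard deviation, removing
#' per-spectrum additive and multiplicative scatter.
#'
#' @param set A `spectrum_set`; every spectrum must have positive spread.
#' @return Transformed `spectrum_set`.
#' @export
snv <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  out <- t(apply(set$values, 1, function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) stop("SNV undefined for a constant spectrum")
    (v - mean(v)) / s
  }))
  spectrum_set(out, set$grid, sample_id = set$sample_id, labels = set$labels)
}

#' Multiplicative scatter correction
#'
#' Fits each spectrum against a reference by ordinary least squares,
#' `s ~ a + b * reference`, and returns `(s - a) / b`, undoing per-sample
#' additive offset and multiplicative scaling. The reference defaults to
#' the mean spectrum of the set being corrected; to avoid information
#' leaking from test data, fit the reference on training spectra and pass
#' it explicitly when correcting new spectra.
#'
#' @param set A `spectrum_set`.
#' @param reference Per-band reference spectrum; `NULL` (default) uses the
#'   mean spectrum of `set` (which then needs >= 2 spectra).
#' @return Corrected `spectrum_set`, with attributes `msc_reference`
#'   (the reference used) and `msc_coefficients` (data frame of per-sample
#'   `a` and `b`).
#' @export
msc <- function(set, reference = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  if (is.null(reference)) {
    if (length(set) < 2) stop("mean-reference MSC needs at least 2 spectra")
    reference <- colMeans(set$values)
  }
  if (length(reference) != length(set$grid)) {
    stop("MSC reference is not on the set's wavelength grid")
  }
  X <- cbind(1, reference)
  coefs <- t(apply(set$values, 1, function(v) qr.solve(X, v)))
  if (any(abs(coefs[, 2]) < 1e-12)) {
    stop("MSC slope estimate is numerically zero for at least one spectrum")
  }
  corrected <- (set$values - coefs[, 1]) / coefs[, 2]
  out <- spectrum_set(corrected, set$grid, sample_id = set$sample_id,
                      labels = set$labels)
  attr(out, "msc_reference") <- as.numeric(reference)
  attr(out, "msc_coefficients") <- data.frame(a = coefs[, 1], b = coefs[, 2])
  out
}

#' Apply one of the four preprocessing methods by name
#'
#' Dispatch helper used by the pipeline: `"sg"`, `"normalization"`,
#' `"snv"` or `"msc"`.
#'
#' @param set A `spectrum_set`.
#' @param method Method name.
#' @param ... Passed to the underlying transform (e.g. `window`,
#'   `polyorder` for SG; `reference` for MSC).
#' @return Transformed `spectrum_set`.
#' @export
preprocess <- function(set, method = c("msc", "sg", "normalization", "snv"),
                       ...) {
  method <- match.arg(method)
  switch(method,
         sg = savitzky_golay(set, ...),
         normalization = normalize_spectra(set, ...),
         snv = snv(set),
         msc = msc(set, ...))
}
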