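#' Fit a per-band inter-instrument offset
#'
#' Estimates the per-wavelength additive offset between a reference
#' spectrometer and a portable device from paired acquisitions of the same
#' samples: the per-sample differences are averaged band by band.
#'
#' Two sign conventions are available. `"reference_minus_device"` (the
#' default) averages `reference - device`, so that adding the offset to
#' device spectra moves them onto the reference. `"device_minus_reference"`
#' averages `device - reference`, the literal difference sometimes quoted
#' with offset-calibration formulas; applying that offset moves device
#' spectra *away* from the reference, so it is kept only for fidelity
#' comparisons.
#'
#' @param reference `spectrum_set` from the reference instrument.
#' @param device `spectrum_set` from the device, same samples in the same
#'   order on the same grid.
#' @param sign_convention `"reference_minus_device"` or
#'   `"device_minus_reference"`.
#' @return An object of class `"calibration_offset"` with fields `grid`,
#'   `mean_delta`, `n_pairs`, `sign_convention`.
#' @export
fit_offset <- function(reference, device,
                       sign_convention = c("reference_minus_device",
                                           "device_minus_reference")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(inherits(reference, "spectrum_set"), inherits(device, "spectrum_set"))
  stop_grid_mismatch(reference, device)
  if (length(reference) != length(device)) {
    stop("reference and device sets have different sample counts")
  }
  if (length(reference) < 1) stop("need at least one sample pair")
  delta <- if (sign_convention == "reference_minus_device") {
    reference$values - device$values
  } else {
    device$values - reference$values
  }
  structure(list(grid = reference$grid,
                 mean_delta = colMeans(delta),
                 n_pairs = length(reference),
                 sign_convention = sign_convention),
            class = "calibration_offset")
}

#' @export
print.calibration_offset <- function(x, ...) {
  cat(sprintf("<calibration_offset> %d bands, %d pairs, convention %s\n",
              length(x$mean_delta), x$n_pairs, x$sign_convention))
  cat(sprintf("mean |offset| = %.5g\n", mean(abs(x$mean_delta))))
  invisible(x)
}

#' Apply a fitted offset to device spectra
#'
#' Adds the fitted per-band mean offset to every spectrum:
#' `calibrated = device + mean_delta`. This is a pure per-band shift (no
#' gain term) and is therefore not idempotent: applying a nonzero offset
#' twice shifts by twice the offset.
#'
#' @param device `spectrum_set` to calibrate.
#' @param offset A `calibration_offset` from [fit_offset()].
#' @return Calibrated `spectrum_set`.
#' @export
apply_offset <- function(device, offset) {
  stopifnot(inherits(device, "spectrum_set"), inherits(offset, "calibration_offset"))
  if (length(device$grid) != length(offset$grid) ||
      any(abs(as.numeric(device$grid) - as.numeric(offset$grid)) > 1e-9)) {
    stop("offset is not on the device set's wavelength grid")
  }
  spectrum_set(sweep(device$values, 2, offset$mean_delta, `+`), device$grid,
               sample_id = device$sample_id, labels = device$labels)
}

#' Pearson agreement between two aligned spectrum sets
#'
#' Pearson correlation over all paired reflectance values, the summary
#' used to certify that a device tracks a reference spectrometer. With
#' `per_sample = TRUE` also returns one correlation per sample pair.
#'
#' @param a,b Aligned `spectrum_set`s (same grid, same sample order,
#'   at least 3 paired values in total).
#' @param per_sample Also compute per-sample correlations.
#' @return Overall Pearson r; with `per_sample = TRUE`, a list with
#'   `overall` and `per_sample`.
#' @export
agreement_pearson <- function(a, b, per_sample = FALSE) {
  stopifnot(inherits(a, "spectrum_set"), inherits(b, "spectrum_set"))
  stop_grid_mismatch(a, b)
  if (length(a) != length(b)) stop("sets have different sample counts")
  x <- as.numeric(a$values)
  y <- as.numeric(b$values)
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  if (!per_sample) return(r)
  list(overall = r,
       per_sample = vapply(seq_len(length(a)), function(i) {
         stats::cor(a$values[i, ], b$values[i, ])
       }, numeric(1)))
}
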