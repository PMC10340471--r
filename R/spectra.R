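#' Construct a wavelength grid
#'
#' A regular wavelength grid in nanometres. The package default covers the
#' visible acquisition range 450--760 nm sampled every 1 nm (311 bands).
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm).
#' @param step_nm Sampling interval (nm).
#' @return Numeric vector of wavelengths with class `"wavelength_grid"`.
#' @export
wavelength_grid <- function(start_nm = 450, end_nm = 760, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm))
  if (start_nm >= end_nm) stop("wavelength grid requires start < end")
  if (step_nm <= 0) stop("wavelength grid requires step > 0")
  n <- (end_nm - start_nm) / step_nm
  if (abs(n - round(n)) > 1e-8) {
    stop("grid span must be an integer multiple of the step")
  }
  g <- seq(start_nm, end_nm, by = step_nm)
  class(g) <- c("wavelength_grid", "numeric")
  g
}

#' Bundle spectra into a spectrum set
#'
#' A `spectrum_set` holds a sample-by-band reflectance matrix on one shared
#' wavelength grid, together with sample identifiers and optional per-sample
#' labels (moisture percentage, whiteness grade or whiteness value).
#'
#' @param values Numeric matrix, one row per sample, one column per band.
#'   Reflectance is a dimensionless fraction; values modestly above 1 are
#'   tolerated to accommodate measurement noise.
#' @param grid Wavelength grid (see [wavelength_grid()]); length must equal
#'   `ncol(values)`.
#' @param sample_id Character vector of sample identifiers (default
#'   `"s1"`, `"s2"`, ...).
#' @param labels Optional data frame of per-sample labels with columns among
#'   `moisture_pct`, `grade`, `whiteness`; row count must match.
#' @return Object of class `"spectrum_set"`.
#' @export
spectrum_set <- function(values, grid = wavelength_grid(),
                         sample_id = NULL, labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("reflectance values must be numeric")
  if (ncol(values) != length(grid)) {
    stop(sprintf("values have %d bands but the grid has %d", ncol(values),
                 length(grid)))
  }
  if (any(!is.finite(values))) stop("reflectance values must all be finite")
  if (is.null(sample_id)) {
    sample_id <- if (nrow(values) > 0) paste0("s", seq_len(nrow(values))) else character(0)
  }
  if (length(sample_id) != nrow(values)) {
    stop("sample_id length must equal the number of spectra")
  }
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (nrow(labels) != nrow(values)) {
      stop("label rows must match the number of spectra")
    }
  }
  rownames(values) <- sample_id
  colnames(values) <- format_wavelength(grid)
  structure(list(values = values, grid = grid, sample_id = sample_id,
                 labels = labels),
            class = "spectrum_set")
}

format_wavelength <- function(grid) {
  formatC(as.numeric(grid), format = "g", digits = 10)
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d bands (%g-%g nm, step %g nm)\n",
              nrow(x$values), length(x$grid), min(x$grid), max(x$grid),
              if (length(x$grid) > 1) x$grid[2] - x$grid[1] else NA_real_))
  if (!is.null(x$labels)) {
    cat("labels:", paste(names(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) nrow(x$values)

#' Subset a spectrum set by sample
#'
#' @param x A `spectrum_set`.
#' @param i Sample index vector.
#' @param ... Ignored.
#' @return A `spectrum_set` with the selected samples.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  spectrum_set(x$values[i, , drop = FALSE], x$grid,
               sample_id = x$sample_id[i],
               labels = if (!is.null(x$labels)) x$labels[i, , drop = FALSE])
}

stop_grid_mismatch <- function(a, b) {
  if (length(a$grid) != length(b$grid) ||
      any(abs(as.numeric(a$grid) - as.numeric(b$grid)) > 1e-9)) {
    stop("spectrum sets are on different wavelength grids")
  }
  invisible(NULL)
}

label_columns <- c("moisture_pct", "grade", "whiteness")

#' Read spectra from CSV
#'
#' The on-disk format is UTF-8 comma-separated text: a `sample_id` column
#' first, then one column per wavelength (numeric header, strictly
#' increasing, evenly spaced), then optional label columns `moisture_pct`,
#' `grade`, `whiteness`.
#'
#' @param path Path to a CSV file written by [write_spectra()] or following
#'   the same layout.
#' @return A `spectrum_set`.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!"sample_id" %in% names(raw)) stop("missing 'sample_id' column")
  lbl_cols <- intersect(label_columns, names(raw))
  wl_names <- setdiff(names(raw), c("sample_id", lbl_cols))
  wl <- suppressWarnings(as.numeric(wl_names))
  if (any(is.na(wl))) {
    stop(sprintf("non-numeric wavelength header: %s",
                 paste(wl_names[is.na(wl)][1], collapse = ", ")))
  }
  if (length(wl) < 2 || any(diff(wl) <= 0)) stop("non-monotone grid")
  steps <- diff(wl)
  if (max(steps) - min(steps) > 1e-6) stop("wavelength grid is not evenly spaced")
  grid <- wavelength_grid(wl[1], wl[length(wl)], steps[1])

  vals <- matrix(NA_real_, nrow(raw), length(wl))
  for (j in seq_along(wl_names)) {
    v <- suppressWarnings(as.numeric(raw[[wl_names[j]]]))
    bad <- which(is.na(v) | raw[[wl_names[j]]] == "")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or missing value at row %d, wavelength %s",
                   bad[1], wl_names[j]))
    }
    vals[, j] <- v
  }
  labels <- NULL
  if (length(lbl_cols) > 0) {
    labels <- as.data.frame(lapply(raw[lbl_cols], function(x) {
      suppressWarnings(as.numeric(x))
    }))
    names(labels) <- lbl_cols
  }
  spectrum_set(vals, grid, sample_id = raw$sample_id, labels = labels)
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra()]; values are written with 12 significant
#' digits so a round trip preserves reflectances to well below 1e-9
#' relative error, and output is byte-stable for identical input.
#'
#' @param set A `spectrum_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  df <- data.frame(sample_id = set$sample_id, stringsAsFactors = FALSE)
  vals <- set$values
  for (j in seq_along(set$grid)) {
    df[[format_wavelength(set$grid)[j]]] <- formatC(vals[, j], format = "g",
                                                    digits = 12)
  }
  if (!is.null(set$labels)) {
    for (nm in names(set$labels)) {
      df[[nm]] <- formatC(set$labels[[nm]], format = "g", digits = 12)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Wet-basis moisture content from drying masses
#'
#' Moisture content by the oven-drying (direct drying) method on a wet
#' basis: `100 * (m1 - m2) / m1`, where `m1` is the fresh mass and `m2` the
#' mass after drying to constant weight.
#'
#' @param m1 Fresh mass in grams (> 0). Samples are expected in the 4--7 g
#'   range used with 0.001 g balances; values outside it raise a warning,
#'   not an error.
#' @param m2 Dry mass in grams (`0 <= m2 <= m1`).
#' @return Moisture content in percent. Vectorized over both masses.
#' @export
moisture_content <- function(m1, m2) {
  if (any(m1 <= 0)) stop("fresh mass m1 must be positive")
  if (any(m2 < 0)) stop("dry mass m2 must be nonnegative")
  if (any(m2 > m1)) stop("negative moisture: dry mass exceeds fresh mass")
  if (any(m1 < 4 | m1 > 7)) {
    warning("fresh mass outside the expected 4-7 g sampling range")
  }
  100 * (m1 - m2) / m1
}

#' Coefficient of determination
#'
#' `r2_score()` is the coefficient of determination
#' `1 - SS_res / SS_tot` (not squared Pearson correlation); [rmse()] is the
#' root mean squared error in the units of the target variable. These are
#' the RC2/Rp2 and RMSEC/RMSEP figures used to report model quality on
#' training and test sets respectively.
#'
#' @param y_true Observed values (length >= 2, non-constant for R2).
#' @param y_pred Predicted values, same length.
#' @return A single number.
#' @export
r2_score <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("undefined R^2: y_true is constant")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' @rdname r2_score
#' @export
rmse <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  sqrt(mean((y_true - y_pred)^2))
}

check_paired <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  if (length(y_true) < 2) stop("need at least 2 paired values")
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred))) {
    stop("non-finite values in metric inputs")
  }
  invisible(NULL)
}

#' Random 4:1 train/test split
#'
#' Partitions a spectrum set into training and test subsets at the 4:1
#' ratio used throughout the modeling workflow. The test set holds
#' `round(n / 5)` samples so that, e.g., 200 samples split 160/40 and 160
#' samples split 128/32. The split is uniformly random and reproducible for
#' a fixed seed.
#'
#' @param set A `spectrum_set` with at least 5 samples.
#' @param seed Integer seed controlling the permutation.
#' @return List with elements `train` and `test` (both `spectrum_set`) and
#'   `test_idx` (the sampled test indices).
#' @export
split_train_test <- function(set, seed = 1L) {
  n <- length(set)
  if (n < 5) stop("need at least 5 samples for a 4:1 split")
  n_test <- round(n / 5)
  test_idx <- sort(with_seed(seed, sample.int(n, n_test)))
  list(train = set[setdiff(seq_len(n), test_idx)],
       test = set[test_idx],
       test_idx = test_idx)
}

# Evaluate expr under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
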