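#' Successive projections algorithm for wavelength selection
#'
#' Forward selection of minimally collinear wavelengths. Starting from a
#' candidate band, the algorithm repeatedly projects the remaining columns
#' of the (mean-centered) spectral matrix onto the orthogonal complement of
#' the already-selected columns and admits the column with the largest
#' projection norm. Every chain prefix is then scored by the
#' cross-validated RMSE of a multiple linear regression of the response on
#' the selected bands, and the chain and size with the smallest RMSE win.
#'
#' Ties in projection norm are broken toward the lowest band index, and
#' ties in RMSE toward the earliest (smallest) start and size, so the
#' result is deterministic. Columns that are exact linear combinations of
#' the selected set have zero projection norm and can never be selected.
#'
#' @param X Sample-by-band numeric matrix (>= 2 rows).
#' @param y Response vector (moisture percent, whiteness, ...).
#' @param max_size Largest subset size to scan (<= number of bands).
#' @param first_band `"scan_all"` (default) to try every starting band, or
#'   a single band index to fix the chain start.
#' @param n_folds Folds for the cross-validated scoring (default 5; folds
#'   are assigned round-robin in sample order, so scoring is deterministic).
#' @param wavelengths Optional wavelengths (nm) for reporting.
#' @return Object of class `"spa_result"`: `selected_indices` (sorted),
#'   `selected_wavelengths`, `chain` (in selection order), `rmse_curve`
#'   (RMSE per prefix size for the winning start), `chosen_size`,
#'   `start_band`, `rmse_min`.
#' @export
spa_select <- function(X, y, max_size, first_band = "scan_all",
                       n_folds = 5, wavelengths = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("SPA needs at least 2 samples")
  if (max_size < 1 || max_size > ncol(X)) {
    stop("max_size must be between 1 and the number of bands")
  }
  if (length(y) != nrow(X)) stop("response length must match sample count")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  col_norm2 <- colSums(Xc^2)
  if (any(col_norm2 < 1e-24)) stop("degenerate X: zero-variance column")

  starts <- if (identical(first_band, "scan_all")) seq_len(ncol(X)) else {
    stopifnot(is.numeric(first_band), first_band >= 1, first_band <= ncol(X))
    as.integer(first_band)
  }

  best <- list(rmse = Inf)
  for (s in starts) {
    chain <- spa_chain(Xc, s, max_size)
    curve <- vapply(seq_along(chain), function(m) {
      cv_rmse_mlr(X[, chain[seq_len(m)], drop = FALSE], y, n_folds)
    }, numeric(1))
    m_star <- which.min(curve)
    if (curve[m_star] < best$rmse) {
      best <- list(rmse = curve[m_star], chain = chain, curve = curve,
                   size = m_star, start = s)
    }
  }

  sel <- sort(best$chain[seq_len(best$size)])
  structure(list(selected_indices = sel,
                 selected_wavelengths = if (!is.null(wavelengths)) wavelengths[sel],
                 chain = best$chain,
                 rmse_curve = best$curve,
                 chosen_size = best$size,
                 start_band = best$start,
                 rmse_min = best$rmse),
            class = "spa_result")
}

# Build one projection chain: repeatedly take the column with the largest
# norm after projecting out the span of the selected columns.
spa_chain <- function(Xc, start, max_size) {
  R <- Xc                      # residual columns
  chain <- integer(0)
  pick <- start
  for (m in seq_len(max_size)) {
    chain <- c(chain, pick)
    v <- R[, pick]
    nv2 <- sum(v^2)
    if (nv2 < 1e-24) break
    R <- R - outer(v, colSums(R * v) / nv2)  # project out v
    norms <- colSums(R^2)
    norms[chain] <- -Inf
    norms[norms < 1e-20] <- -Inf             # collinear: never selectable
    if (m == max_size || all(!is.finite(norms))) break
    pick <- which.max(norms)                 # which.max takes first on ties
  }
  chain
}

# Deterministic k-fold CV RMSE of an intercept MLR, robust to rank
# deficiency within a fold (NA coefficients contribute zero).
cv_rmse_mlr <- function(X, y, n_folds) {
  n <- length(y)
  k <- max(2L, min(n_folds, n))
  fold <- rep_len(seq_len(k), n)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- stats::lm.fit(cbind(1, X[tr, , drop = FALSE]), y[tr])
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred[!tr] <- cbind(1, X[!tr, , drop = FALSE]) %*% beta
  }
  sqrt(mean((y - pred)^2))
}

#' @export
print.spa_result <- function(x, ...) {
  cat(sprintf("<spa_result> %d bands selected (start %d, CV RMSE %.5g)\n",
              x$chosen_size, x$start_band, x$rmse_min))
  if (!is.null(x$selected_wavelengths)) {
    cat("wavelengths:", paste(x$selected_wavelengths, collapse = ", "), "nm\n")
  } else {
    cat("indices:", paste(x$selected_indices, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Principal component analysis of a spectral matrix
#'
#' PCA on mean-centered (unscaled) reflectances, the chemometric
#' convention for spectra on a common physical scale. Components are
#' ordered by decreasing contribution rate (share of total variance).
#'
#' @param X Sample-by-band matrix (>= 2 rows).
#' @return Object of class `"pca_result"`: `center`, `loadings`
#'   (band-by-component, orthonormal), `scores`, `contribution`,
#'   `cumulative_contribution`, and `n_selected` (all components until
#'   [pca_select()] is applied).
#' @export
pca_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 samples")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  contrib <- p$sdev^2 / sum(p$sdev^2)
  structure(list(center = p$center,
                 loadings = p$rotation,
                 scores = p$x,
                 contribution = contrib,
                 cumulative_contribution = cumsum(contrib),
                 n_selected = length(contrib)),
            class = "pca_result")
}

#' Retain the leading components reaching a cumulative contribution
#'
#' Sets `n_selected` to the smallest number of leading components whose
#' cumulative contribution rate reaches the threshold (default 95%).
#'
#' @param result A `pca_result`.
#' @param threshold Cumulative contribution share in (0, 1].
#' @return The updated `pca_result`.
#' @export
pca_select <- function(result, threshold = 0.95) {
  stopifnot(inherits(result, "pca_result"), threshold > 0, threshold <= 1)
  result$n_selected <- which(result$cumulative_contribution >= threshold - 1e-12)[1]
  if (is.na(result$n_selected)) result$n_selected <- length(result$contribution)
  result
}

#' Project new spectra onto stored principal components
#'
#' @param result A `pca_result`.
#' @param X New sample-by-band matrix on the same bands.
#' @param n_components Number of components (default `result$n_selected`).
#' @return Score matrix (samples by components).
#' @export
pca_transform <- function(result, X, n_components = result$n_selected) {
  stopifnot(inherits(result, "pca_result"))
  X <- as.matrix(X)
  if (ncol(X) != length(result$center)) stop("band count mismatch")
  sweep(X, 2, result$center) %*% result$loadings[, seq_len(n_components), drop = FALSE]
}
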