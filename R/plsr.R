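#' Partial least squares regression (PLS1)
#'
#' Fits a univariate-response PLS regression by the standard iterative
#' PLS1 deflation: each factor's weight vector is the covariance direction
#' between the deflated spectra and the deflated response, scores are the
#' projections, and both blocks are deflated before the next factor.
#' Predictors and response are mean-centered (no variance scaling, the
#' usual convention for reflectance spectra).
#'
#' @param X Sample-by-band matrix.
#' @param y Response vector.
#' @param k Number of latent factors, `1 <= k <= min(n - 1, bands)`.
#' @return Object of class `"plsr_model"` with weights `W`, loadings `P`,
#'   response loadings `q`, centers, and the collapsed per-band coefficient
#'   vector plus intercept.
#' @export
plsr_fit <- function(X, y, k) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("response length must match sample count")
  k_max <- min(nrow(X) - 1, ncol(X))
  if (k < 1 || k > k_max) {
    stop(sprintf("k must be between 1 and min(n - 1, bands) = %d", k_max))
  }
  if (stats::var(y) == 0) stop("zero-variance response")
  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2, x_center)
  f <- y - y_center
  W <- matrix(0, ncol(X), k)
  P <- matrix(0, ncol(X), k)
  q <- numeric(k)
  for (a in seq_len(k)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {        # response fully explained; keep earlier factors
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      k <- a - 1
      break
    }
    w <- w / nw
    t_scores <- as.numeric(E %*% w)
    tt <- sum(t_scores^2)
    p <- as.numeric(crossprod(E, t_scores)) / tt
    qa <- sum(f * t_scores) / tt
    E <- E - outer(t_scores, p)
    f <- f - qa * t_scores
    W[, a] <- w
    P[, a] <- p
    q[a] <- qa
  }
  coef <- W %*% solve(crossprod(P, W), q)
  structure(list(n_factors = k, x_center = x_center, y_center = y_center,
                 W = W, P = P, q = q,
                 coefficients = as.numeric(coef),
                 intercept = y_center - sum(x_center * coef)),
            class = "plsr_model")
}

#' Predict from a fitted PLS regression
#'
#' `via = "coefficients"` uses the collapsed per-band regression vector;
#' `via = "factors"` recomputes scores factor by factor with the stored
#' weights and loadings. The two paths agree to numerical precision.
#'
#' @param model A `plsr_model`.
#' @param X New sample-by-band matrix.
#' @param via Prediction path.
#' @return Numeric vector of predictions.
#' @export
plsr_predict <- function(model, X, via = c("coefficients", "factors")) {
  via <- match.arg(via)
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_center)) stop("band count mismatch")
  if (via == "coefficients") {
    return(as.numeric(X %*% model$coefficients + model$intercept))
  }
  E <- sweep(X, 2, model$x_center)
  yhat <- rep(model$y_center, nrow(X))
  for (a in seq_len(model$n_factors)) {
    t_scores <- as.numeric(E %*% model$W[, a])
    yhat <- yhat + model$q[a] * t_scores
    E <- E - outer(t_scores, model$P[, a])
  }
  yhat
}

#' Choose the PLS factor count by cross-validated RMSE
#'
#' Scans `k = 1..k_max` and returns the factor count with the smallest
#' k-fold cross-validated RMSE (first minimum on ties). Folds are assigned
#' round-robin in sample order, so the choice is deterministic.
#'
#' @param X Sample-by-band matrix.
#' @param y Response vector.
#' @param k_max Largest factor count to scan (capped at `min(n - 2, bands)`
#'   so every training fold supports the fit).
#' @param n_folds CV folds (default 5).
#' @return List with `k` (the chosen count) and `rmse_curve`.
#' @export
plsr_select_k <- function(X, y, k_max = 15, n_folds = 5) {
  X <- as.matrix(X)
  n <- length(y)
  k <- max(2L, min(n_folds, n))
  fold <- rep_len(seq_len(k), n)
  k_cap <- min(k_max, ncol(X), n - ceiling(n / k) - 1)
  if (k_cap < 1) stop("too few samples to cross-validate any factor count")
  curve <- vapply(seq_len(k_cap), function(kk) {
    pred <- numeric(n)
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- plsr_fit(X[tr, , drop = FALSE], y[tr], kk)
      pred[!tr] <- plsr_predict(m, X[!tr, , drop = FALSE])
    }
    sqrt(mean((y - pred)^2))
  }, numeric(1))
  list(k = which.min(curve), rmse_curve = curve)
}
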