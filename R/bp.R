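#' Configuration for the feedforward (BP) network
#'
#' A three-layer perceptron: linear input, a hyperbolic-tangent ("tansig")
#' hidden layer of 5--10 units, and a single linear ("purelin") output.
#' Training is damped Gauss-Newton (Levenberg-Marquardt) on mean squared
#' error; a plain gradient-descent fallback using `lr` is available.
#'
#' @param n_hidden Hidden units (default 8; the scan in
#'   [bp_scan_hidden()] covers 5--10).
#' @param lr Learning rate for the gradient-descent fallback (default 0.1;
#'   unused by Levenberg-Marquardt, which adapts its own damping).
#' @param max_epochs Training epochs (default 100; 1000 when refining a
#'   metaheuristic-chosen initialization, see [ssa_bp_train()]).
#' @param goal_mse Early-stop target for the training MSE on the
#'   standardized response scale (default 0.001).
#' @param algorithm `"lm"` (Levenberg-Marquardt, default) or `"gd"`.
#' @param seed Integer seed for weight initialization.
#' @return A list of class `"bp_config"`.
#' @export
bp_config <- function(n_hidden = 8, lr = 0.1, max_epochs = 100,
                      goal_mse = 0.001, algorithm = c("lm", "gd"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_hidden >= 1, lr > 0, max_epochs >= 0, goal_mse >= 0)
  structure(list(n_hidden = as.integer(n_hidden), lr = lr,
                 max_epochs = as.integer(max_epochs), goal_mse = goal_mse,
                 algorithm = algorithm, seed = as.integer(seed)),
            class = "bp_config")
}

bp_n_params <- function(n_input, n_hidden) {
  n_hidden * n_input + n_hidden + n_hidden + 1
}

bp_unpack <- function(theta, d, h) {
  list(W1 = matrix(theta[seq_len(h * d)], h, d),
       b1 = theta[h * d + seq_len(h)],
       w2 = theta[h * d + h + seq_len(h)],
       b2 = theta[h * d + 2 * h + 1])
}

bp_forward <- function(theta, Xs, d, h) {
  p <- bp_unpack(theta, d, h)
  H <- tanh(sweep(Xs %*% t(p$W1), 2, p$b1, `+`))
  list(H = H, yhat = as.numeric(H %*% p$w2 + p$b2))
}

# Jacobian of predictions w.r.t. the packed parameter vector.
bp_jacobian <- function(theta, Xs, H, d, h) {
  p <- bp_unpack(theta, d, h)
  Dw <- (1 - H^2) * rep(p$w2, each = nrow(H))
  J1 <- Dw[, rep(seq_len(h), times = d), drop = FALSE] *
    Xs[, rep(seq_len(d), each = h), drop = FALSE]
  cbind(J1, Dw, H, 1)
}

#' Train the BP network
#'
#' Inputs are rescaled feature-wise to [-1, 1] and the response is
#' standardized; both mappings are stored in the model and inverted at
#' prediction time. Training minimizes mean squared error by
#' Levenberg-Marquardt: a damped Gauss-Newton step on the full Jacobian,
#' with the damping factor decreased tenfold after an accepted step and
#' increased tenfold after a rejected one. When the parameter count
#' exceeds the sample count the step is computed through the n-by-n dual
#' system, so full-spectrum inputs remain cheap. Training stops at the MSE
#' goal, the epoch limit, a vanishing gradient, or damping overflow.
#'
#' @param X Sample-by-feature matrix.
#' @param y Response vector.
#' @param config A [bp_config()].
#' @param init Optional packed parameter vector (see internals) overriding
#'   the seeded uniform(-0.5, 0.5) initialization; used by the sparrow
#'   search wrapper.
#' @return Object of class `"bp_model"` with weights, scaling constants,
#'   and a `history` data frame of per-epoch MSE (standardized scale).
#' @export
bp_train <- function(X, y, config = bp_config(), init = NULL) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("response length must match sample count")
  d <- ncol(X)
  h <- config$n_hidden
  n <- nrow(X)

  x_min <- apply(X, 2, min)
  x_max <- apply(X, 2, max)
  rng <- ifelse(x_max > x_min, x_max - x_min, 1)
  Xs <- sweep(sweep(X, 2, x_min), 2, rng, `/`) * 2 - 1
  Xs[, x_max == x_min] <- 0
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (is.na(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd

  np <- bp_n_params(d, h)
  theta <- if (!is.null(init)) {
    if (length(init) != np) stop("init has the wrong parameter count")
    as.numeric(init)
  } else {
    with_seed(config$seed, stats::runif(np, -0.5, 0.5))
  }

  fwd <- bp_forward(theta, Xs, d, h)
  r <- fwd$yhat - ys
  sse <- sum(r^2)
  history <- data.frame(epoch = 0L, mse = sse / n)
  mu <- 1e-3
  epoch <- 0L
  while (epoch < config$max_epochs && sse / n > config$goal_mse) {
    epoch <- epoch + 1L
    if (config$algorithm == "gd") {
      J <- bp_jacobian(theta, Xs, fwd$H, d, h)
      theta <- theta - config$lr * as.numeric(crossprod(J, r)) * 2 / n
      fwd <- bp_forward(theta, Xs, d, h)
      r <- fwd$yhat - ys
      sse <- sum(r^2)
    } else {
      J <- bp_jacobian(theta, Xs, fwd$H, d, h)
      g <- as.numeric(crossprod(J, r))
      if (max(abs(g)) < 1e-12) break
      accepted <- FALSE
      while (!accepted && mu <= 1e10) {
        delta <- if (np <= n) {
          A <- crossprod(J)
          diag(A) <- diag(A) + mu
          tryCatch(as.numeric(solve(A, g)), error = function(e) NULL)
        } else {
          B <- tcrossprod(J)
          diag(B) <- diag(B) + mu
          tryCatch(as.numeric(crossprod(J, solve(B, r))),
                   error = function(e) NULL)
        }
        if (is.null(delta) || any(!is.finite(delta))) {
          mu <- mu * 10
          next
        }
        cand <- theta - delta
        fwd_new <- bp_forward(cand, Xs, d, h)
        r_new <- fwd_new$yhat - ys
        sse_new <- sum(r_new^2)
        if (!is.finite(sse_new)) {
          stop(sprintf("NaN loss at epoch %d", epoch))
        }
        if (sse_new < sse) {
          theta <- cand
          fwd <- fwd_new
          r <- r_new
          sse <- sse_new
          mu <- max(mu * 0.1, 1e-20)
          accepted <- TRUE
        } else {
          mu <- mu * 10
        }
      }
      if (!accepted) {
        history <- rbind(history, data.frame(epoch = epoch, mse = sse / n))
        break  # damping overflow: converged as far as LM can go
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, mse = sse / n))
  }

  p <- bp_unpack(theta, d, h)
  structure(list(W1 = p$W1, b1 = p$b1, w2 = p$w2, b2 = p$b2,
                 theta = theta,
                 x_min = x_min, x_range = rng, x_const = x_max == x_min,
                 y_mean = y_mean, y_sd = y_sd,
                 n_input = d, n_hidden = h,
                 config = config, history = history),
            class = "bp_model")
}

#' Predict from a trained BP network
#'
#' A pure function of the model and inputs: applies the stored input
#' scaling, the tansig/purelin forward pass, and the inverse response
#' standardization.
#'
#' @param model A `bp_model`.
#' @param X New sample-by-feature matrix.
#' @return Numeric vector of predictions in response units.
#' @export
bp_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_input) stop("feature count mismatch")
  Xs <- sweep(sweep(X, 2, model$x_min), 2, model$x_range, `/`) * 2 - 1
  Xs[, model$x_const] <- 0
  H <- tanh(sweep(Xs %*% t(model$W1), 2, model$b1, `+`))
  as.numeric(H %*% model$w2 + model$b2) * model$y_sd + model$y_mean
}

#' Scan hidden-layer sizes and keep the most accurate network
#'
#' Trains one network per hidden size (default 5--10) on an internal 4:1
#' train/validation split, selects the size with the highest validation
#' R-squared (ties go to the smaller size), and refits that size on all
#' supplied samples.
#'
#' @param X Sample-by-feature matrix.
#' @param y Response vector.
#' @param hidden Candidate hidden sizes.
#' @param config Base [bp_config()]; its `n_hidden` is overridden.
#' @param seed Seed for the internal validation split.
#' @return The refitted `bp_model`, with attribute `"scan"` (data frame of
#'   size and validation R-squared).
#' @export
bp_scan_hidden <- function(X, y, hidden = 5:10, config = bp_config(),
                           seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 samples to scan hidden sizes")
  val_idx <- with_seed(seed, sample.int(n, round(n / 5)))
  tr <- setdiff(seq_len(n), val_idx)
  scores <- vapply(hidden, function(h) {
    cfg <- config
    cfg$n_hidden <- as.integer(h)
    m <- bp_train(X[tr, , drop = FALSE], y[tr], cfg)
    r2_score(y[val_idx], bp_predict(m, X[val_idx, , drop = FALSE]))
  }, numeric(1))
  ord <- order(hidden)  # ascending sizes so ties resolve to the smallest
  best <- ord[which.max(scores[ord])]
  cfg <- config
  cfg$n_hidden <- as.integer(hidden[best])
  model <- bp_train(X, y, cfg)
  attr(model, "scan") <- data.frame(n_hidden = hidden, val_r2 = scores)
  model
}
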