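#' Configuration for the sparrow search algorithm
#'
#' Population metaheuristic with three roles: producers (discoverers) lead
#' the search, scroungers follow the best producer, and a scout fraction
#' is re-dispersed each iteration when danger is sensed. Defaults follow
#' the settings used for network-weight optimization in this pipeline:
#' population 10, 20 iterations, 70% producers, 20% scouts, alert
#' threshold 0.6.
#'
#' @param pop_size Population size (>= 2).
#' @param n_iter Iterations (0 allowed: no search beyond initialization).
#' @param discoverer_frac Producer share of the population, in (0, 1].
#' @param scout_frac Share re-dispersed as scouts each iteration, in (0, 1].
#' @param alert_value Safety threshold in (0, 1] governing producer moves.
#' @param seed Integer seed.
#' @return A list of class `"ssa_config"`.
#' @export
ssa_config <- function(pop_size = 10, n_iter = 20, discoverer_frac = 0.7,
                       scout_frac = 0.2, alert_value = 0.6, seed = 1L) {
  stopifnot(pop_size >= 2, n_iter >= 0,
            discoverer_frac > 0, discoverer_frac <= 1,
            scout_frac > 0, scout_frac <= 1,
            alert_value > 0, alert_value <= 1)
  structure(list(pop_size = as.integer(pop_size), n_iter = as.integer(n_iter),
                 discoverer_frac = discoverer_frac, scout_frac = scout_frac,
                 alert_value = alert_value, seed = as.integer(seed)),
            class = "ssa_config")
}

#' Minimize a function with the sparrow search algorithm
#'
#' Canonical producer/scrounger/scout update rules. Producers shrink
#' toward the origin of their own position while the alert is low and take
#' Gaussian steps otherwise; scroungers either jump near the worst
#' position (the hungrier half) or follow the best producer; a random
#' scout fraction moves toward the global best if sitting on the edge of
#' the group, or jitters if already at the best. Positions are clamped to
#' the bounds after every move, and the best position ever evaluated is
#' retained (elitism), so the reported fitness history is monotone
#' nonincreasing.
#'
#' @param fitness Function mapping a numeric vector of length `dim` to a
#'   finite scalar to minimize.
#' @param dim Dimension of the search space.
#' @param lower,upper Bounds, scalars or length-`dim` vectors (finite).
#' @param config An [ssa_config()].
#' @return List with `best_position`, `best_fitness`, and `history`
#'   (best-so-far fitness; length `n_iter + 1` including initialization).
#' @export
ssa_optimize <- function(fitness, dim, lower, upper, config = ssa_config()) {
  stopifnot(dim >= 1)
  lower <- rep_len(lower, dim)
  upper <- rep_len(upper, dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop("bounds must be finite with lower < upper")
  }
  np <- config$pop_size
  eval_fit <- function(x) {
    f <- fitness(x)
    if (!is.finite(f)) {
      stop(sprintf("non-finite fitness at position (%s)",
                   paste(signif(x, 4), collapse = ", ")))
    }
    f
  }
  clamp <- function(X) {
    X <- pmax(X, matrix(lower, np, dim, byrow = TRUE))
    pmin(X, matrix(upper, np, dim, byrow = TRUE))
  }

  with_seed(config$seed, {
    X <- matrix(stats::runif(np * dim), np, dim)
    X <- sweep(sweep(X, 2, upper - lower, `*`), 2, lower, `+`)
    f <- apply(X, 1, eval_fit)
    best_i <- which.min(f)
    best_x <- X[best_i, ]
    best_f <- f[best_i]
    history <- best_f

    n_prod <- max(1L, round(np * config$discoverer_frac))
    n_scout <- max(1L, round(np * config$scout_frac))

    for (t in seq_len(config$n_iter)) {
      ord <- order(f)
      X <- X[ord, , drop = FALSE]
      f <- f[ord]
      x_best_iter <- X[1, ]
      x_worst <- X[np, ]

      # producers
      r2 <- stats::runif(1)
      alpha <- stats::runif(1)
      for (i in seq_len(n_prod)) {
        if (r2 < config$alert_value) {
          X[i, ] <- X[i, ] * exp(-i / (alpha * config$n_iter + 1e-12))
        } else {
          X[i, ] <- X[i, ] + stats::rnorm(dim)
        }
      }
      x_prod_best <- X[1, ]

      # scroungers
      if (n_prod < np) {
        for (i in (n_prod + 1):np) {
          if (i > np / 2) {
            X[i, ] <- stats::rnorm(dim) * exp((x_worst - X[i, ]) / i^2)
          } else {
            A <- sample(c(-1, 1), dim, replace = TRUE)
            X[i, ] <- x_prod_best + abs(X[i, ] - x_prod_best) * A / dim
          }
        }
      }

      # scouts: a random subset senses danger
      scouts <- sample.int(np, n_scout)
      for (i in scouts) {
        if (f[i] > f[1]) {
          X[i, ] <- x_best_iter + stats::rnorm(1) * abs(X[i, ] - x_best_iter)
        } else {
          K <- stats::runif(1, -1, 1)
          X[i, ] <- X[i, ] + K * abs(X[i, ] - x_worst) / (f[i] - f[np] + 1e-50)
        }
      }

      X <- clamp(X)
      f <- apply(X, 1, eval_fit)
      if (min(f) < best_f) {
        best_f <- min(f)
        best_x <- X[which.min(f), ]
      }
      history <- c(history, best_f)
    }
    list(best_position = best_x, best_fitness = best_f, history = history)
  })
}

#' Train a BP network from a sparrow-search-optimized initialization
#'
#' Searches the packed initial weight/bias vector of the network: each
#' candidate is refined with a short Levenberg-Marquardt run (20 epochs)
#' on an internal 4:1 split of the supplied samples and scored by
#' validation MSE; the best initialization then seeds a full training run
#' with `max_epochs = 1000`. With `n_iter = 0` the search is skipped
#' entirely and this reduces to plain [bp_train()] from the seeded random
#' initialization (with the longer epoch budget).
#'
#' @param X Sample-by-feature matrix.
#' @param y Response vector.
#' @param config A [bp_config()]; `max_epochs` is overridden to 1000 for
#'   the final run.
#' @param ssa A [ssa_config()].
#' @param weight_bound Symmetric search bound on each initial parameter
#'   (default 1).
#' @return A `bp_model`, with attributes `"ssa_history"` (best validation
#'   MSE per iteration) and `"ssa_val_mse"`.
#' @export
ssa_bp_train <- function(X, y, config = bp_config(), ssa = ssa_config(),
                         weight_bound = 1) {
  X <- as.matrix(X)
  final_cfg <- config
  final_cfg$max_epochs <- 1000L
  if (ssa$n_iter == 0) {
    return(bp_train(X, y, final_cfg))
  }
  n <- nrow(X)
  if (n < 5) stop("need at least 5 samples for the internal validation split")
  val_idx <- with_seed(ssa$seed, sample.int(n, round(n / 5)))
  tr <- setdiff(seq_len(n), val_idx)
  short_cfg <- config
  short_cfg$max_epochs <- 20L
  np <- bp_n_params(ncol(X), config$n_hidden)
  fitness <- function(theta) {
    m <- bp_train(X[tr, , drop = FALSE], y[tr], short_cfg, init = theta)
    mean((y[val_idx] - bp_predict(m, X[val_idx, , drop = FALSE]))^2)
  }
  opt <- ssa_optimize(fitness, np, -weight_bound, weight_bound, ssa)
  model <- bp_train(X, y, final_cfg, init = opt$best_position)
  attr(model, "ssa_history") <- opt$history
  attr(model, "ssa_val_mse") <- opt$best_fitness
  model
}
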