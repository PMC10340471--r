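test_that("SPA finds the generating bands when columns are orthogonal", {
  # centered orthogonal design: scaled contrast columns, column 5 largest
  # among the non-start columns so the chain started at 2 picks it next
  H <- stats::contr.helmert(30)[, 1:6]   # orthogonal, zero-sum columns
  Q <- sweep(H, 2, sqrt(colSums(H^2)), `/`)
  X <- Q %*% diag(c(3, 6, 2.5, 2, 5, 1.5))
  y <- X[, 2] + 0.5 * X[, 5]
  res <- spa_select(X, y, max_size = 2, first_band = 2)
  expect_setequal(res$selected_indices, c(2, 5))
  expect_lt(res$rmse_min, 1e-8)
})

test_that("an exactly duplicated column is never selected twice", {
  set.seed(21)
  X <- matrix(rnorm(40 * 5), 40, 5)
  X <- cbind(X, X[, 2])                  # column 6 duplicates column 2
  y <- rowSums(X[, 1:3])
  res <- spa_select(X, y, max_size = 5)
  expect_false(all(c(2, 6) %in% res$chain))
  # direct check: after selecting column 2 its duplicate has zero projection
  chain <- spa_select(X, y, max_size = 5, first_band = 2)$chain
  expect_false(6 %in% chain)
})

test_that("projection chains equal the exhaustive recursion oracle", {
  set.seed(22)
  for (trial in 1:5) {
    X <- matrix(rnorm(25 * 6), 25, 6)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    y <- rnorm(25)
    for (start in 1:6) {
      got <- spa_select(X, y, max_size = 6, first_band = start)$chain
      expect_identical(got, as.integer(spa_oracle_chain(Xc, start, 6)))
    }
  }
})

test_that("SPA selection is invariant to positive scaling of the response", {
  set.seed(23)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- X[, 3] - 2 * X[, 7] + rnorm(30, 0, 0.05)
  a <- spa_select(X, y, max_size = 4)
  b <- spa_select(X, 100 * y, max_size = 4)
  expect_identical(a$selected_indices, b$selected_indices)
  expect_identical(a$chosen_size, b$chosen_size)
  expect_equal(b$rmse_min, 100 * a$rmse_min)
})

test_that("with orthogonal X and full max_size SPA returns all bands", {
  set.seed(24)
  Q <- qr.Q(qr(scale(matrix(rnorm(20 * 5), 20, 5), scale = FALSE)))
  y <- Q %*% c(1, 2, 3, 4, 5)
  res <- spa_select(Q, y, max_size = 5, first_band = 1)
  expect_setequal(res$chain, 1:5)
  expect_length(res$rmse_curve, 5)
})

test_that("spa result invariants hold on a realistic problem", {
  g <- generate_spectra(generator_config(n_samples = 60,
                                         grade_mix = c(1, 0, 0, 0), seed = 30))
  X <- g$set$values
  res <- spa_select(X, g$truth$moisture_pct, max_size = 5,
                    wavelengths = as.numeric(g$set$grid))
  expect_false(is.unsorted(res$selected_indices))
  expect_identical(anyDuplicated(res$selected_indices), 0L)
  expect_identical(res$chosen_size, which.min(res$rmse_curve))
  expect_length(res$selected_indices, res$chosen_size)
  expect_identical(res$selected_wavelengths,
                   as.numeric(g$set$grid)[res$selected_indices])
  expect_error(spa_select(X, g$truth$moisture_pct, max_size = 400), "max_size")
})

test_that("PCA contributions match an independent eigendecomposition", {
  set.seed(25)
  X <- matrix(rnorm(40 * 8), 40, 8) %*% diag(c(4, 3, 2, rep(0.5, 5)))
  res <- pca_fit(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(res$contribution, ev / sum(ev), tolerance = 1e-8)
  # loadings orthonormal, scores centered
  expect_equal(crossprod(res$loadings), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(res$scores))), 1e-10)
  # reconstruction from all components
  rec <- sweep(res$scores %*% t(res$loadings), 2, res$center, `+`)
  expect_lt(max(abs(rec - X)), 1e-8)
})

test_that("rank-1 data concentrate on a single component", {
  set.seed(26)
  v <- rnorm(7)
  X <- outer(rnorm(12), v) + matrix(2, 12, 7)
  res <- pca_select(pca_fit(X), 0.95)
  expect_equal(res$contribution[1], 1, tolerance = 1e-12)
  expect_identical(res$n_selected, 1L)
})

test_that("component retention is minimal and monotone in the threshold", {
  set.seed(27)
  X <- matrix(rnorm(30 * 10), 30, 10) %*% diag(10:1 / 3)
  res <- pca_fit(X)
  prev <- 0L
  for (th in c(0.5, 0.8, 0.9, 0.95, 0.99, 1)) {
    k <- pca_select(res, th)$n_selected
    expect_gte(k, prev)
    expect_gte(res$cumulative_contribution[k], th - 1e-12)
    if (k > 1) expect_lt(res$cumulative_contribution[k - 1], th)
    prev <- k
  }
  # transform of the training data reproduces the stored scores
  sc <- pca_transform(res, X, n_components = 3)
  expect_equal(sc, res$scores[, 1:3], tolerance = 1e-10, ignore_attr = TRUE)
})
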