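test_that("Savitzky-Golay reproduces polynomials and matches the local-fit oracle", {
  g31 <- small_grid(31)
  const <- spectrum_set(matrix(0.7, 1, 31), g31)
  expect_equal(savitzky_golay(const, 7, 2)$values, const$values)

  # a cubic sampled exactly is reproduced everywhere by a cubic fit
  x <- seq_len(31)
  cub <- spectrum_set(rbind(0.5 + 0.01 * x - 2e-4 * x^2 + 3e-6 * x^3), g31)
  out <- savitzky_golay(cub, 7, 3)
  expect_lt(max(abs(out$values - cub$values)), 1e-10)

  # random spectra against the brute-force per-window refit, edges included
  s <- random_set(10, 31, seed = 14)
  S <- sg_oracle_matrix(31, 7, 2)
  expect_lt(max(abs(savitzky_golay(s, 7, 2)$values - s$values %*% t(S))), 1e-10)

  expect_error(savitzky_golay(s, 6, 2), "odd")
  expect_error(savitzky_golay(s, 33, 2), "longer")
})

test_that("smoothing commutes with adding a low-degree polynomial", {
  s <- random_set(3, 31, seed = 15)
  x <- seq_len(31)
  poly <- 0.2 - 0.01 * x + 4e-4 * x^2
  shifted <- spectrum_set(sweep(s$values, 2, poly, `+`), s$grid)
  expect_equal(savitzky_golay(shifted, 9, 2)$values,
               sweep(savitzky_golay(s, 9, 2)$values, 2, poly, `+`),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("min-max normalization spans [0,1] and is idempotent", {
  g3 <- small_grid(3)
  s <- spectrum_set(rbind(c(0.2, 0.6, 1.0)), g3)
  expect_equal(unname(normalize_spectra(s)$values), rbind(c(0, 0.5, 1)))
  once <- normalize_spectra(random_set(4, 11, seed = 16))
  expect_equal(normalize_spectra(once)$values, once$values)
  flat <- spectrum_set(matrix(0.4, 1, 3), g3)
  expect_error(normalize_spectra(flat), "constant")
})

test_that("SNV yields zero mean and unit population sd and is affine-invariant", {
  s <- random_set(6, 21, seed = 17)
  out <- snv(s)$values
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_lt(max(abs(sqrt(rowMeans((out - rowMeans(out))^2)) - 1)), 1e-12)

  shifted <- spectrum_set(0.3 + 1.7 * s$values, s$grid)
  expect_equal(snv(shifted)$values, out, tolerance = 1e-12, ignore_attr = TRUE)

  g3 <- small_grid(3)
  expect_equal(unname(snv(spectrum_set(rbind(c(1, 2, 3)), g3))$values),
               rbind(c(-sqrt(3 / 2), 0, sqrt(3 / 2))))
  expect_error(snv(spectrum_set(matrix(1, 1, 3), g3)), "constant")
})

test_that("MSC undoes known additive/multiplicative scatter", {
  s <- random_set(3, 21, seed = 18)
  ref <- colMeans(s$values)

  # correcting the reference itself leaves it unchanged with (a, b) = (0, 1)
  ref_set <- spectrum_set(rbind(ref), s$grid)
  self <- msc(ref_set, reference = ref)
  expect_equal(as.numeric(self$values), unname(ref), tolerance = 1e-12)
  expect_equal(attr(self, "msc_coefficients")$a, 0, tolerance = 1e-10)
  expect_equal(attr(self, "msc_coefficients")$b, 1, tolerance = 1e-10)

  # s = 0.3 + 1.7 * ref is mapped back onto ref
  scat <- spectrum_set(rbind(0.3 + 1.7 * ref), s$grid)
  expect_lt(max(abs(msc(scat, reference = ref)$values - ref)), 1e-10)

  expect_error(msc(s, reference = rep(0.5, 21)))  # zero-variance reference
})

test_that("MSC recovers the generator's scatter parameters at zero noise", {
  g <- generate_spectra(generator_config(n_samples = 10, noise_sd = 0,
                                         scatter_slope_sd = 0.1,
                                         scatter_offset_sd = 0.03, seed = 9))
  clean <- attr(g$truth, "clean")
  for (i in 1:10) {
    one <- msc(g$set[i], reference = clean[i, ])
    cf <- attr(one, "msc_coefficients")
    expect_equal(cf$a, g$truth$scatter_a[i], tolerance = 1e-8)
    expect_equal(cf$b, g$truth$scatter_b[i], tolerance = 1e-8)
    expect_lt(max(abs(one$values - clean[i, ])), 1e-8)
  }
})

test_that("all transforms preserve band count and grid", {
  s <- random_set(4, 21, seed = 19)
  for (m in c("sg", "normalization", "snv", "msc")) {
    out <- preprocess(s, m)
    expect_identical(dim(out$values), dim(s$values))
    expect_identical(as.numeric(out$grid), as.numeric(s$grid))
  }
})
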