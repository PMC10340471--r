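test_that("tristimulus normalization gives the perfect reflector Y10 = 100", {
  grid <- wavelength_grid()
  white <- spectrum_set(matrix(1, 1, length(grid)), grid)
  ts <- tristimulus(white)
  expect_equal(ts$Y10, 100)

  black <- spectrum_set(matrix(0, 1, length(grid)), grid)
  expect_equal(unlist(tristimulus(black)[c("X10", "Y10", "Z10")]),
               c(X10 = 0, Y10 = 0, Z10 = 0))

  # linearity in reflectance
  half <- spectrum_set(matrix(0.5, 1, length(grid)), grid)
  expect_equal(unlist(tristimulus(half)[1:3]), unlist(ts[1:3]) / 2)

  # the sample-dependent normalization forces Y10 = 100 for any sample
  grey <- spectrum_set(matrix(runif(length(grid), 0.3, 0.8), 1), grid)
  expect_equal(tristimulus(grey, k_convention = "sample")$Y10, 100)
  expect_lt(tristimulus(grey)$Y10, 100)
})

test_that("tristimulus sums agree with a trapezoid quadrature oracle", {
  grid <- wavelength_grid()
  wl <- as.numeric(grid)
  refl <- 0.5 + 0.3 * sin(wl / 40) * exp(-(wl - 600)^2 / 2e4)
  ts <- tristimulus(refl, grid = grid)
  R <- illuminant_d65(grid)
  obs <- cie_observer_1964(grid)
  K_o <- 100 / trapz(wl, R * obs[, "ybar"])
  oracle <- c(K_o * trapz(wl, refl * R * obs[, "xbar"]),
              K_o * trapz(wl, refl * R * obs[, "ybar"]),
              K_o * trapz(wl, refl * R * obs[, "zbar"]))
  got <- unlist(ts[c("X10", "Y10", "Z10")])
  expect_true(all(abs(got - oracle) < 0.001 * ts$Y10))
})

test_that("chromaticity projects tristimulus values correctly", {
  expect_equal(chromaticity(100, 100, 100), data.frame(x10 = 1/3, y10 = 1/3))
  expect_equal(chromaticity(50, 25, 25), data.frame(x10 = 0.5, y10 = 0.25))
  a <- chromaticity(12, 34, 56)
  b <- chromaticity(12 * 7, 34 * 7, 56 * 7)
  expect_equal(a, b)
  expect_error(chromaticity(0, 0, 0), "zero")
})

test_that("the Ganz whiteness formula matches hand arithmetic", {
  ref <- list(xn = 0.31, yn = 0.33)
  expect_equal(ganz_whiteness(100, 0.31, 0.33, ref), 100)
  expect_equal(ganz_whiteness(80, 0.31 - 0.01, 0.33 - 0.02, ref), 122)
  # strictly decreasing in x10 with everything else fixed
  w <- ganz_whiteness(80, seq(0.30, 0.35, by = 0.01), 0.33, ref)
  expect_true(all(diff(w) < 0))
})

test_that("grading maps the calibrated medians and band interiors correctly", {
  med <- grade_whiteness(c(69.32, 40.91, 30.38, 19.1))
  expect_identical(med$grade, 1:4)
  expect_true(all(med$flag == "ok"))

  # every value inside a band's non-overlapping interior maps to its level
  # (bands 2 and 3 overlap on [34.23, 34.66], where the midpoint decides)
  interiors <- list(`1` = c(61.05, 81.84), `2` = c(34.67, 49.7),
                    `3` = c(25.08, 34.22), `4` = c(13.15, 22.81))
  for (lev in names(interiors)) {
    w <- seq(interiors[[lev]][1], interiors[[lev]][2], length.out = 25)
    g <- grade_whiteness(w)
    expect_true(all(g$grade == as.integer(lev)))
    expect_true(all(g$flag == "ok"))
  }
  # inside the overlap the midpoint threshold 34.445 decides, flags stay ok
  ov <- grade_whiteness(c(34.3, 34.445, 34.6))
  expect_identical(ov$grade, c(3L, 2L, 2L))
  expect_true(all(ov$flag == "ok"))

  # gap between bands is graded by the midpoint threshold and flagged
  gap <- grade_whiteness(c(55.0, 55.375, 50.9))
  expect_identical(gap$grade, c(2L, 1L, 2L))
  expect_true(all(gap$flag == "gap"))

  out <- grade_whiteness(c(5, 95))
  expect_identical(out$grade, c(4L, 1L))
  expect_true(all(out$flag == "out_of_calibration"))
})

test_that("the whiteness pipeline composes per sample and preserves order", {
  grid <- wavelength_grid()
  white <- spectrum_set(matrix(1, 1, length(grid)), grid)
  res <- whiteness_pipeline(white)
  expect_equal(res$W10, 100)           # whiteboard = its own chromaticity
  expect_identical(res$grade, 1L)

  g <- generate_spectra(generator_config(n_samples = 8, seed = 60))
  res8 <- whiteness_pipeline(g$set)
  expect_identical(nrow(res8), 8L)
  expect_identical(res8$sample_id, g$set$sample_id)

  # heavier browning scores below pure white within one batch
  model <- synthetic_truth_model()
  clean <- mushspec:::clean_spectrum_matrix(rep(90, 2), c(1L, 4L), model)
  w2 <- whiteness_pipeline(spectrum_set(clean))$W10
  expect_gt(w2[1], w2[2])
})

test_that("observer and illuminant tables are valid on the default grid", {
  obs <- cie_observer_1964()
  expect_identical(nrow(obs), 311L)
  expect_true(all(obs >= 0))
  expect_true(all(illuminant_d65() > 0))
  # ybar peaks near 557 nm
  expect_equal(as.numeric(wavelength_grid())[which.max(obs[, "ybar"])], 556,
               tolerance = 0.01)
  expect_error(tristimulus(spectrum_set(matrix(1, 1, 311)),
                           illuminant = rep(0, 311)), "all-zero")
})
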