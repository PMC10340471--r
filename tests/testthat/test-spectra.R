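test_that("CSV round trip preserves reflectances, labels and ids", {
  labels <- data.frame(moisture_pct = runif(5, 80, 95), grade = rep(1L, 5))
  s <- random_set(5, 11, seed = 3, labels = labels)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path)
  s2 <- read_spectra(path)
  expect_equal(s2$values, s$values, tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(s2$values - s$values)), 1e-9)
  expect_equal(s2$sample_id, s$sample_id)
  expect_equal(s2$labels$moisture_pct, labels$moisture_pct, tolerance = 1e-9)
  expect_identical(as.numeric(s2$grid), as.numeric(s$grid))
})

test_that("writing is byte-stable and an empty set gives a header-only file", {
  s <- random_set(3, 6, seed = 9)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, p1)
  write_spectra(s, p2)
  expect_identical(readLines(p1), readLines(p2))

  empty <- spectrum_set(matrix(numeric(0), 0, 6), small_grid(6))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(empty, p3)
  expect_length(readLines(p3), 1)
  expect_equal(length(read_spectra(p3)), 0)
})

test_that("malformed CSV inputs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,500,499,501", "a,1,2,3"), path)
  expect_error(read_spectra(path), "non-monotone")

  writeLines(c("sample_id,450,451,452", "a,1,2"), path)
  expect_error(read_spectra(path))

  writeLines(c("sample_id,450,451,452", "a,1,x,3"), path)
  expect_error(read_spectra(path), "row 1.*451")

  expect_error(spectrum_set(matrix(1, 2, 5), small_grid(6)), "bands")
  expect_error(spectrum_set(matrix(c(1, NA), 1, 2), small_grid(2)), "finite")
  expect_error(wavelength_grid(500, 499), "start < end")
})

test_that("wet-basis moisture formula and its guards", {
  expect_equal(moisture_content(5.000, 0.500), 90.0)
  expect_equal(moisture_content(4.000, 4.000), 0.0)
  expect_equal(moisture_content(6.123, 0.551), 100 * (6.123 - 0.551) / 6.123)
  expect_equal(moisture_content(6.123, 0.551), 91.0011432, tolerance = 1e-7)
  # scale invariance in mass units
  m1 <- runif(20, 4, 7); m2 <- runif(20, 0, 3)
  for (c_scale in c(0.5, 2, 13.7)) {
    expect_equal(suppressWarnings(moisture_content(c_scale * m1, c_scale * m2)),
                 moisture_content(m1, m2))
  }
  expect_warning(moisture_content(3.5, 0.5), "4-7 g")
  expect_warning(moisture_content(8.0, 0.5), "4-7 g")
  expect_error(moisture_content(5, 6), "negative moisture")
  expect_error(moisture_content(0, 0), "positive")
})

test_that("r2 and rmse match brute-force summation on random vectors", {
  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  y <- c(1, 5, 2, 8)
  expect_equal(r2_score(y, rep(mean(y), 4)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  set.seed(11)
  for (i in 1:20) {
    yt <- rnorm(30); yp <- rnorm(30)
    sr <- 0; st <- 0
    for (j in 1:30) {
      sr <- sr + (yt[j] - yp[j])^2
      st <- st + (yt[j] - mean(yt))^2
    }
    expect_equal(r2_score(yt, yp), 1 - sr / st, tolerance = 1e-12)
    expect_equal(rmse(yt, yp), sqrt(sr / 30), tolerance = 1e-12)
  }
  expect_error(r2_score(rep(1, 4), 1:4), "undefined")
  expect_error(rmse(1:3, 1:4), "differ")
})

test_that("4:1 split is an exhaustive disjoint partition with the printed sizes", {
  s200 <- random_set(200, 6, seed = 5)
  sp <- split_train_test(s200, seed = 7)
  expect_length(sp$train, 160)
  expect_length(sp$test, 40)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), s200$sample_id)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)

  s160 <- random_set(160, 6, seed = 5)
  sp2 <- split_train_test(s160, seed = 7)
  expect_length(sp2$train, 128)
  expect_length(sp2$test, 32)

  sp3 <- split_train_test(s200, seed = 7)
  expect_identical(sp$test_idx, sp3$test_idx)
  expect_error(split_train_test(random_set(4, 6)), "at least 5")
})
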