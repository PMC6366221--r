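test_that("rubberband baseline: a line is its own lower hull", {
  x <- seq(2000, 1000, by = -10)
  s <- ftir_spectrum(x, 0.2 + 0.001 * x)
  out <- rubberband_baseline(s)
  expect_lt(max(abs(out$corrected$intensities)), 1e-12)
  expect_equal(out$baseline$intensities, s$intensities, tolerance = 1e-12)
})

test_that("rubberband baseline: three-point hand case", {
  s <- ftir_spectrum(c(3, 2, 1), c(0, 5, 0))
  out <- rubberband_baseline(s)
  expect_equal(out$baseline$intensities, c(0, 0, 0))
  expect_equal(out$corrected$intensities, c(0, 5, 0))
  expect_error(rubberband_baseline(ftir_spectrum(c(2, 1), c(0, 1))),
               "at least 3")
})

test_that("rubberband baseline matches the brute-force hull oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 400
    x <- seq(1000, 3000, length.out = n)
    convex <- 0.3 + 2e-8 * (x - 1800)^2                 # convex background
    peaks <- 0.6 * exp(-(x - 1400)^2 / 1800) +
      0.9 * exp(-(x - 2300)^2 / 5000) + abs(rnorm(n, 0, 0.02))
    s <- ftir_spectrum(rev(x), rev(convex + peaks))
    got <- rubberband_baseline(s)$corrected$intensities
    want <- rev(convex + peaks) - rev(oracle_lower_hull(x, convex + peaks))
    expect_lt(max(abs(got - want)), 1e-10)
    # contract: non-negative, touches zero at least twice
    expect_gte(min(got), -1e-12)
    expect_gte(sum(abs(got) < 1e-10), 2L)
  }
})

test_that("rubberband baseline is idempotent", {
  s <- random_spectrum(300, seed = 9)
  once <- rubberband_baseline(s)$corrected
  twice <- rubberband_baseline(once)$corrected
  expect_lt(max(abs(twice$intensities - once$intensities)), 1e-10)
})

test_that("hull support points are capped at n_points", {
  # strictly convex curve: every point is a hull vertex
  x <- seq(1000, 1200, by = 2)
  s <- ftir_spectrum(rev(x), rev(1e-4 * (x - 1100)^2))
  out <- rubberband_baseline(s, n_points = 10L)
  bl <- rev(out$baseline$intensities)
  # baseline is piecewise linear with at most 10 vertices = 9 segments
  slopes <- round(diff(bl) / diff(x), 10)
  expect_lte(length(unique(slopes)), 9L)
})

test_that("vector normalization centres and scales to unit norm", {
  s <- ftir_spectrum(c(1000, 998), c(0, 2))
  v <- vector_normalize(s)
  expect_equal(v$intensities, c(-1, 1) / sqrt(2))

  r <- random_spectrum(150, seed = 3)
  v1 <- vector_normalize(r)
  expect_equal(sum(v1$intensities), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(v1$intensities^2)), 1, tolerance = 1e-12)
  # idempotence
  v2 <- vector_normalize(v1)
  expect_lt(max(abs(v2$intensities - v1$intensities)), 1e-12)
  # plain L2 variant keeps the mean
  l2 <- vector_normalize(r, method = "l2")
  expect_equal(sqrt(sum(l2$intensities^2)), 1, tolerance = 1e-12)
  expect_gt(mean(l2$intensities), 0)

  expect_error(vector_normalize(ftir_spectrum(c(1, 2), c(3, 3))),
               "zero variance")
})

test_that("baseline correction then normalization gives mean-0 norm-1", {
  for (seed in 1:3) {
    s <- random_spectrum(250, seed = seed)
    out <- vector_normalize(rubberband_baseline(s)$corrected)
    expect_equal(sum(out$intensities), 0, tolerance = 1e-10)
    expect_equal(sum(out$intensities^2), 1, tolerance = 1e-10)
  }
})

test_that("SNR quality test behaves across noise levels", {
  x <- seq(4000, 400, by = -2)
  smooth <- exp(-(x - 1650)^2 / (2 * 28^2))       # ptp 1, flat near 2000
  expect_gt(quality_snr(ftir_spectrum(x, smooth)), 4000)

  # Monte-Carlo: sd 1e-4 noise in the window -> SNR ~ 1e4 (factor 1.5);
  # sd 1e-3 -> ~1e3, failing the 4000 cut-off
  snr_at <- function(sigma, seed) {
    set.seed(seed)
    y <- smooth
    inw <- x >= 1900 & x <= 2100
    y[inw] <- y[inw] + rnorm(sum(inw), 0, sigma)
    quality_snr(ftir_spectrum(x, y))
  }
  s4 <- vapply(1:100, function(i) snr_at(1e-4, i), numeric(1))
  expect_gt(mean(s4), 1e4 / 1.5)
  expect_lt(mean(s4), 1e4 * 1.5)
  s3 <- vapply(1:100, function(i) snr_at(1e-3, i), numeric(1))
  expect_gt(mean(s3), 1e3 / 1.5)
  expect_lt(mean(s3), 1e3 * 1.5)
  expect_true(all(s3 < 4000))

  expect_error(quality_snr(ftir_spectrum(c(1000, 998, 996), c(1, 2, 3))),
               "noise window")
})

test_that("preprocess_set excludes failing spectra with a warning", {
  x <- seq(4000, 400, by = -2)
  good <- ftir_spectrum(x, exp(-(x - 1650)^2 / 1568), strain = "A",
                        condition = "c", replicate = 1L)
  set.seed(1)
  bad_y <- good$intensities
  inw <- x >= 1900 & x <= 2100
  bad_y[inw] <- bad_y[inw] + rnorm(sum(inw), 0, 1e-3)
  bad <- ftir_spectrum(x, bad_y, strain = "A", condition = "c",
                       replicate = 2L)
  expect_warning(out <- preprocess_set(ftir_set(list(good, bad))),
                 "excluded")
  expect_length(out$set$spectra, 1L)
  expect_equal(out$excluded$replicate, 2L)
})
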