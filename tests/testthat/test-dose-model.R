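test_that("primary fit recovers an exact quadratic and saturates on 3 points", {
  m <- fit_primary(0:3, c(0, 3, 10, 21))     # RC = 2 SI^2 + SI
  expect_equal(m$a, 2, tolerance = 1e-10)
  expect_equal(m$b, 1, tolerance = 1e-10)
  expect_equal(m$c, 0, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-12)

  m3 <- fit_primary(c(0.3, 1.1, 2.9), c(4, 17, 80))
  expect_equal(m3$r2, 1, tolerance = 1e-12)
  expect_error(fit_primary(c(1, 1, 2), c(1, 2, 3)), "distinct")
})

test_that("primary fit agrees with the normal-equations oracle", {
  set.seed(17)
  for (i in 1:5) {
    si <- runif(12, 0, 4)
    rc <- 3 * si^2 - 2 * si + 5 + rnorm(12, 0, 2)
    m <- fit_primary(si, rc)
    o <- oracle_quadfit(si, rc)
    expect_lt(abs(m$a - o["a"]), 1e-8)
    expect_lt(abs(m$b - o["b"]), 1e-8)
    expect_lt(abs(m$c - o["c"]), 1e-8)
  }
})

test_that("primary prediction evaluates published coefficients", {
  ref <- reference_models()
  row <- ref[ref$strain == "Fp84" & ref$window == "W3", ]
  m <- primary_model(row$a, row$b, row$c)
  expect_equal(predict_primary(m, 0), -0.134)
  expect_equal(predict_primary(m, 5), 2.544 * 25 - 10.997 * 5 - 0.134)
  row <- ref[ref$strain == "DSM70449" & ref$window == "W4", ]
  expect_equal(predict_primary(primary_model(row$a, row$b, row$c), 2), 22.624)
})

test_that("general model predictions: one-hot, midpoint, weighted mean", {
  ms <- list(W1 = primary_model(0, 1, 0), W3 = primary_model(1, 0, 0),
             W4 = primary_model(0, 2, 5), WS = primary_model(0, 0, 60))
  si <- c(W1 = 2, W3 = 3, W4 = 1, WS = 9)
  g3 <- general_model(ms, c(W1 = 0, W3 = 1, W4 = 0))
  expect_equal(predict_general(g3, si), predict_primary(ms$W3, si["W3"]),
               ignore_attr = TRUE)
  # members predicting 40 and 60 with equal weights -> 50
  g2 <- general_model(list(A = primary_model(0, 0, 40),
                           B = primary_model(0, 0, 60)),
                      c(A = 0.5, B = 0.5))
  expect_equal(predict_general(g2, c(A = 1, B = 1)), 50)
  # general weighted mean vs brute force
  w <- c(W1 = 0.1, W3 = 0.1, W4 = 0.8)
  g <- general_model(ms, w)
  p <- vapply(names(w), function(n) predict_primary(ms[[n]], si[[n]]),
              numeric(1))
  expect_equal(predict_general(g, si), sum(w * p) / sum(w), tolerance = 1e-12)
  # invariance under weight rescaling
  expect_equal(predict_general(general_model(ms, 7 * w), si),
               predict_general(g, si), tolerance = 1e-12)
  expect_error(general_model(ms, c(W1 = 0, W3 = 0)), "zero")
  expect_error(predict_general(g, si[c("W1", "W3")]), "missing SI")
})

test_that("quartile classification implements round-half-up of rc/25", {
  expect_equal(classify_crc(21.61), 1L)
  expect_equal(classify_crc(72.86), 3L)
  expect_equal(classify_crc(c(50, 100)), c(2L, 4L))
  expect_equal(classify_crc(12.49), 0L)
  expect_equal(classify_crc(12.5), 1L)
  expect_message(neg <- classify_crc(-40), "negative")
  expect_equal(neg, 0L)
  expect_error(classify_crc(NaN))
  # monotone non-decreasing over the modelled range
  rc <- seq(0, 112, by = 0.25)
  expect_true(all(diff(classify_crc(rc)) >= 0))
})

test_that("pearson correlation and its edge contracts", {
  expect_equal(round(pearson_r(c(21.61, 56.09, 97.24), c(25, 50, 100)), 2),
               0.99)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pooled t-test reproduces published p-values and edge cases", {
  expect_equal(round(ttest_predicted_vs_expected(
    c(21.61, 56.09, 97.24), c(25, 50, 100)), 2), 1)
  expect_equal(round(ttest_predicted_vs_expected(
    c(15.54, 60.00, 95.01), c(25, 50, 100)), 2), 0.97)
  expect_equal(ttest_predicted_vs_expected(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(ttest_predicted_vs_expected(c(5, 5), c(7, 7)), 0)
  # matches stats::t.test in the regular case
  set.seed(4)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(ttest_predicted_vs_expected(a, b),
               stats::t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("weight selection: one-hot winners and constructed mixtures", {
  # build primaries where only W3 tracks the dose; others are flat + noise
  set.seed(8)
  rc <- rep(c(0, 25, 50, 100), each = 3)
  si3 <- sqrt(rc / 100) * 2 + rnorm(12, 0, 0.01)
  primaries <- list(
    W1 = fit_primary(rnorm(12, 1, 0.1), rc),
    W2 = fit_primary(rnorm(12, 1, 0.1), rc),
    W3 = fit_primary(si3, rc),
    W4 = fit_primary(rnorm(12, 1, 0.1), rc))
  best <- select_weights(primaries, strategy = "best_r2")
  expect_equal(names(best$weights), "W3")
  si_by_level <- rbind(W1 = rep(1, 3), W2 = rep(1, 3),
                       W3 = sqrt(c(25, 50, 100) / 100) * 2,
                       W4 = rep(1, 3))
  colnames(si_by_level) <- c("RC_L", "RC_M", "RC_H")
  grid_m <- select_weights(primaries, strategy = "grid",
                           si_by_level = si_by_level,
                           expected = c(RC_L = 25, RC_M = 50, RC_H = 100))
  expect_equal(names(grid_m$weights), "W3")

  # data built so a 0.1/0/0.1/0.8 mixture is exactly optimal: member
  # predictions are linear in SI and expected values are the mixture
  lin <- list(W1 = primary_model(0, 1, 0), W2 = primary_model(0, 1, 0),
              W3 = primary_model(0, 1, 0), W4 = primary_model(0, 1, 0))
  target_w <- c(W1 = 0.1, W2 = 0, W3 = 0.1, W4 = 0.8)
  sis <- rbind(W1 = c(10, 60, 90), W2 = c(90, 10, 40),
               W3 = c(50, 20, 130), W4 = c(26.25, 52.5, 97.5))
  colnames(sis) <- c("RC_L", "RC_M", "RC_H")
  expected <- apply(sis, 2, function(s) sum(target_w * s))
  g <- select_weights(lin, strategy = "grid", si_by_level = sis,
                      expected = expected)
  w_full <- c(W1 = 0, W2 = 0, W3 = 0, W4 = 0)
  w_full[names(g$weights)] <- g$weights
  expect_equal(w_full, target_w)

  # manual strategy echoes the configured weights
  man <- select_weights(lin, strategy = "manual",
                        weights = c(W2 = 0.3, W4 = 0.7))
  expect_equal(man$weights, c(W2 = 0.3, W4 = 0.7))
})

test_that("reports evaluate predictions and round-trip through CSV", {
  ms <- list(WS = primary_model(0, 25, 0))   # RC = 25 * SI
  g <- general_model(ms, c(WS = 1), strain = "demo")
  si <- matrix(c(1, 2, 4), nrow = 1,
               dimnames = list("WS", c("RC_L", "RC_M", "RC_H")))
  rep <- build_report(g, si)
  expect_equal(rep$table$predicted, c(25, 50, 100))
  expect_equal(rep$table$crc, c(1L, 2L, 4L))
  expect_true(all(rep$table$match))
  expect_equal(rep$r, 1)
  expect_equal(rep$p_value, 1)

  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep$table, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$predicted, rep$table$predicted)
  expect_equal(back$crc, rep$table$crc)
})
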