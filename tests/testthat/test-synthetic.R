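test_that("noise-free generation is the exact Gaussian band mixture", {
  cfg <- synthetic_config(noise_sd = 0, amp_jitter_sd = 0, bump_sd = 0,
                          drift_sd = 0)
  p <- strain_profiles()$Fp84
  s <- generate_control_spectrum(cfg, p)
  pk <- cfg$peaks
  want <- rowSums(vapply(seq_len(nrow(pk)), function(k) {
    pk$amplitude[k] * exp(-(cfg$grid - pk$center[k])^2 / (2 * pk$width[k]^2))
  }, numeric(length(cfg$grid))))
  expect_lt(max(abs(s$intensities - want)), 1e-14)
  expect_error(synthetic_config(peaks = default_peak_table()[0, ]), "empty")
})

test_that("generation is deterministic under a fixed seed", {
  e1 <- generate_experiment(synthetic_config(replicates = 2L), seed = 123)
  e2 <- generate_experiment(synthetic_config(replicates = 2L), seed = 123)
  expect_identical(e1$counts, e2$counts)
  expect_identical(
    lapply(e1$set$spectra, `[[`, "intensities"),
    lapply(e2$set$spectra, `[[`, "intensities"))
})

test_that("default spectra pass the SNR quality test", {
  set.seed(99)
  cfg <- synthetic_config()
  s <- generate_control_spectrum(cfg, strain_profiles()$Fm17)
  expect_gt(quality_snr(s), 4000)
})

test_that("rc = 0 sits at the noise floor; SI rises strictly with dose", {
  cfg0 <- synthetic_config(noise_sd = 0, amp_jitter_sd = 0, bump_sd = 0,
                           drift_sd = 0)
  profs <- strain_profiles()
  p <- profs$Fp84
  ctrl <- preprocess_spectrum(generate_stressed_spectrum(cfg0, p, 0))
  gsi <- vapply(c(0, 25, 50, 100), function(rc) {
    s <- preprocess_spectrum(generate_stressed_spectrum(cfg0, p, rc))
    stress_index(s, ctrl, min(cfg0$grid), max(cfg0$grid))
  }, numeric(1))
  expect_equal(gsi[1], 0)                 # exact control at rc = 0
  expect_true(all(diff(gsi) > 0))         # strict monotone dose response

  # with noise, an rc = 0 spectrum is within the replicate noise floor
  set.seed(12)
  cfg <- synthetic_config()
  a <- preprocess_spectrum(generate_stressed_spectrum(cfg, p, 0))
  b <- preprocess_spectrum(generate_control_spectrum(cfg, p))
  expect_lt(stress_index(a, b, min(cfg$grid), max(cfg$grid)), 0.1)

  # resistant strain responds less than the intermediate one
  ctrl_r <- preprocess_spectrum(generate_stressed_spectrum(cfg0, profs$Fm17, 0))
  gsi_res <- stress_index(
    preprocess_spectrum(generate_stressed_spectrum(cfg0, profs$Fm17, 100)),
    ctrl_r, min(cfg0$grid), max(cfg0$grid))
  expect_lt(gsi_res, gsi[4])
  # sensitive strain has the lowest response of all
  ctrl_s <- preprocess_spectrum(
    generate_stressed_spectrum(cfg0, profs$DSM70449, 0))
  gsi_sen <- stress_index(
    preprocess_spectrum(generate_stressed_spectrum(cfg0, profs$DSM70449, 100)),
    ctrl_s, min(cfg0$grid), max(cfg0$grid))
  expect_lt(gsi_sen, gsi_res)
})

test_that("kill curves give the archetypal mortalities", {
  e <- generate_experiment(synthetic_config(), seed = 31)
  truth <- e$truth
  m_at <- function(strain, cond) {
    truth$mortality[truth$strain == strain & truth$condition == cond]
  }
  expect_gt(m_at("DSM70449", "RC_H"), 90)      # sensitive: near-total kill
  expect_lt(m_at("Fm17", "RC_H"), 30)          # resistant: low mortality
  expect_equal(m_at("Fp84", "RC_0"), 0)        # survival normalized at rc = 0
  # observed counts track the kill curve within Poisson error
  mort <- mortality_table(e$counts)
  obs <- merge(mort, truth, by = c("strain", "condition"))
  expect_lt(max(abs(obs$mortality.x - obs$mortality.y)), 1)
  ctrl <- e$counts[e$counts$condition == "RC_0", ]
  expect_lt(max(abs(ctrl$cfu_per_ml / 1e8 - 1)), 0.01)
})

test_that("noiseless quadratic fits describe the generating dose-response", {
  cfg <- synthetic_config(noise_sd = 0, amp_jitter_sd = 0, bump_sd = 0,
                          drift_sd = 0)
  for (p in strain_profiles()) {
    ctrl <- preprocess_spectrum(generate_stressed_spectrum(cfg, p, 0))
    si <- vapply(c(25, 50, 100), function(rc) {
      stress_index(preprocess_spectrum(generate_stressed_spectrum(cfg, p, rc)),
                   ctrl, min(cfg$grid), max(cfg$grid))
    }, numeric(1))
    m <- fit_primary(c(0, si), c(0, 25, 50, 100))
    expect_gt(m$r2, 0.999)
  }
})

test_that("model inversion simulates exact and noisy SI points", {
  m <- primary_model(2, 1, 0)               # RC = 2 SI^2 + SI
  pts <- simulate_si_from_model(m, replicates = 2L)
  expect_equal(nrow(pts), 8L)
  expect_equal(predict_primary(m, pts$si), pts$rc, tolerance = 1e-12)
  noisy <- simulate_si_from_model(m, sigma = 0.05, seed = 5)
  expect_gt(max(abs(predict_primary(m, noisy$si) - noisy$rc)), 0.01)
  expect_error(simulate_si_from_model(primary_model(-1, 0, 0),
                                      rc_levels = 50), "no real SI root")
})
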