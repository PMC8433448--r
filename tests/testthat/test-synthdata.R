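## Synthetic dog-at-rest generator: exact construction, segmentation round
## trip, determinism, ground-truth recoverability.

test_that("noiseless generator produces exact cycles and a recoverable segmentation", {
  m <- respiration_model(breath_period_sd = 0, noise_sd = 0, seed = 1)
  gr <- generate_respiration(m, 40000)
  expect_equal(length(gr$segmentation$exhalation_onsets), 40000 / 5000 + 1)
  expect_equal(diff(gr$segmentation$exhalation_onsets), rep(5000, 8))
  seg <- segment_phases(gr$trace, smoothing = 200)
  truth <- gr$segmentation$exhalation_onsets
  found <- seg$exhalation_onsets
  for (on in truth[truth > 1000 & truth < 39000])
    expect_lt(min(abs(found - on)), 50)
})

test_that("drift leaves the estimated segmentation essentially unchanged", {
  m0 <- respiration_model(breath_period_sd = 0, noise_sd = 0, seed = 2)
  m1 <- respiration_model(breath_period_sd = 0, noise_sd = 0, seed = 2,
                          drift_slope = 3e-5)
  s0 <- segment_phases(generate_respiration(m0, 40000)$trace, smoothing = 200)
  s1 <- segment_phases(generate_respiration(m1, 40000)$trace, smoothing = 200)
  n <- min(length(s0$exhalation_onsets), length(s1$exhalation_onsets))
  expect_equal(s1$exhalation_onsets[1:n], s0$exhalation_onsets[1:n],
               tolerance = 0.02)
})

test_that("generator outputs are pure functions of model and seed", {
  m <- respiration_model(seed = 9)
  g1 <- generate_respiration(m, 30000)
  g2 <- generate_respiration(m, 30000)
  expect_identical(g1$trace$value, g2$trace$value)
  g3 <- generate_respiration(respiration_model(seed = 10), 30000)
  expect_false(identical(g1$trace$value, g3$trace$value))
})

test_that("zero noise and constant C give intervals exactly G(c)", {
  ct <- structure(list(time_ms = seq(0, 60000, by = 10),
                       C = rep(0.6, 6001)), class = "coefficient_trace")
  truth <- rsa_ground_truth(rr_noise_sd = 0, seed = 3)
  peaks <- generate_rr_series(ct, truth)
  expected <- truth$x1 * 0.36 + truth$x2 * 0.6 + truth$x3
  expect_equal(diff(peaks), rep(expected, length(peaks) - 1), tolerance = 1e-6)
})

test_that("ground-truth G is recovered within 2% from noiseless generated data", {
  m <- respiration_model(seed = 4, noise_sd = 0)
  gr <- generate_respiration(m, 138000)
  cp <- breathing_coeff_params()
  ct <- compute_breathing_coefficient(gr$segmentation, cp, t_range = c(0, 138000))
  truth <- rsa_ground_truth(rr_noise_sd = 0, seed = 5)
  peaks <- generate_rr_series(ct, truth)
  ## same C parameterization: the quadratic must come back almost exactly
  ac <- vapply(seq_len(length(peaks) - 1), function(i)
    average_coefficient(ct, c(peaks[i], peaks[i + 1])), 0)
  g <- fit_G(diff(peaks), ac)
  expect_gt(g$r_squared, 0.999)
  expect_equal(g$x3, truth$x3, tolerance = 0.02)
  expect_equal(predict_G(g, 0.8), predict_G(truth, 0.8), tolerance = 0.02)
})

test_that("more noise strictly lowers the achieved R-squared", {
  m <- respiration_model(seed = 6)
  gr <- generate_respiration(m, 120000)
  ct <- compute_breathing_coefficient(gr$segmentation, breathing_coeff_params(),
                                      t_range = c(0, 120000))
  r2 <- vapply(c(0, 94, 188), function(sd_) {
    peaks <- generate_rr_series(ct, rsa_ground_truth(rr_noise_sd = sd_, seed = 7))
    ac <- vapply(seq_len(length(peaks) - 1), function(i)
      average_coefficient(ct, c(peaks[i], peaks[i + 1])), 0)
    fit_G(diff(peaks), ac)$r_squared
  }, 0)
  expect_true(all(diff(r2) < 0))
})

test_that("validation dataset has the documented durations and is deterministic", {
  ds <- cached("valdata_1", make_validation_dataset(1))
  expect_equal(max(ds$evaluation$trace$time_ms), 140000)      # 140 s run
  expect_equal(max(ds$gfit_data$trace$time_ms), 138000)       # 2.3 min
  ds2 <- make_validation_dataset(1)
  expect_identical(ds$gfit_data$r_peaks, ds2$gfit_data$r_peaks)
  ## fixture writer emits the CSV set + manifest
  dir <- tempfile()
  write_validation_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("respiration_calibration.csv", "respiration_evaluation.csv",
      "respiration_gfit.csv", "rpeaks_gfit.csv", "manifest.json")))))
  rp <- read_rpeaks(file.path(dir, "rpeaks_gfit.csv"))
  expect_equal(rp, ds$gfit_data$r_peaks)
})

test_that("default synthetic data carry R-R intervals up to the 900-1000 ms regime", {
  ds <- cached("valdata_1", make_validation_dataset(1))
  rr <- diff(ds$gfit_data$r_peaks)
  expect_gt(max(rr), 850)
  expect_lt(min(rr), 520)
})
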