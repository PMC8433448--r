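## RSA feedback chain: segmentation, breathing coefficient, G fit, H
## calibration primitives and spike encoding.

test_that("segmentation of a pure sinusoid finds the extrema, alternating", {
  tt <- seq(0, 30000, by = 10)
  tr <- respiratory_trace(tt, sin(2 * pi * tt / 5000))
  seg <- segment_phases(tr, smoothing = 200)
  ## minima at 3750 + k 5000, maxima at 1250 + k 5000
  expect_gt(length(seg$exhalation_onsets), 3)
  for (on in seg$exhalation_onsets)
    expect_lt(min(abs(on - (3750 + 5000 * (0:6)))), 60)
  for (on in seg$inhalation_onsets)
    expect_lt(min(abs(on - (1250 + 5000 * (0:6)))), 60)
  ## onsets alternate
  ev <- sort(c(seg$exhalation_onsets, seg$inhalation_onsets))
  typ <- ifelse(ev %in% seg$exhalation_onsets, "e", "i")
  expect_true(all(typ[-1] != typ[-length(typ)]))
})

test_that("segmentation is invariant to a strong linear drift and fails on a constant trace", {
  tt <- seq(0, 40000, by = 10)    # 8 full cycles -> exact detrend
  base <- sin(2 * pi * tt / 5000)
  s1 <- segment_phases(respiratory_trace(tt, base), smoothing = 200)
  s2 <- segment_phases(respiratory_trace(tt, base + 4e-4 * tt), smoothing = 200)
  n <- min(length(s1$exhalation_onsets), length(s2$exhalation_onsets))
  expect_equal(s2$exhalation_onsets[1:n], s1$exhalation_onsets[1:n], tolerance = 0.005)
  expect_error(segment_phases(respiratory_trace(tt, rep(1, length(tt)))),
               "constant")
})

test_that("breathing coefficient: reset at exhalation onset, phase monotonicity, decay to zero", {
  ## property-style: random breathing patterns
  for (seed in 1:5) {
    set.seed(seed)
    exh <- cumsum(runif(8, 3000, 7000))
    inh <- exh + runif(8, 1500, 2800)   # always before the next exhalation
    seg <- structure(list(exhalation_onsets = exh, inhalation_onsets = inh),
                     class = "phase_segmentation")
    p <- breathing_coeff_params(steepness_exh = runif(1, 5e-4, 3e-3),
                                steepness_inh = runif(1, 5e-4, 3e-3),
                                midpoint_exh = runif(1, 500, 2000),
                                midpoint_inh = runif(1, 400, 1500))
    ct <- compute_breathing_coefficient(seg, p, grid_dt = 5)
    expect_true(all(ct$C >= 0))
    ## first grid point at/after each exhalation onset carries at most a
    ## few ms of ramp
    at0 <- function(t) ct$C[min(which(ct$time_ms >= t - 1e-9))]
    for (i in seq_along(exh)) {
      expect_lt(at0(exh[i]), 0.02)                      # reset to 0
      sel <- ct$time_ms >= exh[i] & ct$time_ms < inh[i]
      expect_true(all(diff(ct$C[sel]) >= -1e-12))       # rising in exhalation
      nxt <- if (i < length(exh)) exh[i + 1] else max(ct$time_ms)
      sel2 <- ct$time_ms >= inh[i] & ct$time_ms < nxt
      expect_true(all(diff(ct$C[sel2]) <= 1e-12))       # falling in inhalation
    }
  }
  ## long inhalation approaches zero
  seg1 <- structure(list(exhalation_onsets = 0, inhalation_onsets = 2500),
                    class = "phase_segmentation")
  ct1 <- compute_breathing_coefficient(seg1, breathing_coeff_params(),
                                       grid_dt = 10, t_range = c(0, 30000))
  expect_lt(ct1$C[length(ct1$C)], 0.01)
})

test_that("average coefficient is exact on constant, ramp and piecewise fixtures", {
  ct <- structure(list(time_ms = seq(0, 1000, by = 10), C = rep(0.4, 101)),
                  class = "coefficient_trace")
  expect_equal(average_coefficient(ct, c(100, 900)), 0.4)
  ct2 <- structure(list(time_ms = seq(0, 1000, by = 10),
                        C = seq(0, 1, length.out = 101)),
                   class = "coefficient_trace")
  expect_equal(average_coefficient(ct2, c(0, 1000)), 0.5, tolerance = 1e-9)
  ## piecewise: C = 0 on [0,500], 1 on (500,1000] (linear join over one step)
  ct3 <- structure(list(time_ms = seq(0, 1000, by = 10),
                        C = c(rep(0, 51), rep(1, 50))),
                   class = "coefficient_trace")
  ## analytic integral of the piecewise-linear interpolant:
  ## 0 on [0,500], ramp over [500,510] (area 5), 1 on [510,1000]
  expect_equal(average_coefficient(ct3, c(0, 1000)), 495 / 1000,
               tolerance = 1e-6)
  expect_error(average_coefficient(ct, c(900, 1200)), "outside")
})

test_that("fit_G recovers a noiseless quadratic exactly and validates inputs", {
  C <- seq(0, 1, length.out = 40)
  rr <- 300 * C^2 + 150 * C + 450
  g <- fit_G(rr, C)
  expect_equal(c(g$x1, g$x2, g$x3), c(300, 150, 450), tolerance = 1e-8)
  expect_equal(g$r_squared, 1)
  expect_error(fit_G(rr[1:9], C[1:9]), "at least 10")
  expect_error(fit_G(rr, rep(0.5, 40)), "degenerate")
})

test_that("coefficient-parameter optimization never degrades the initial fit", {
  ds <- cached("synth_small", {
    m <- respiration_model(seed = 31)
    gr <- generate_respiration(m, 90000)
    ct <- compute_breathing_coefficient(gr$segmentation, breathing_coeff_params(),
                                        t_range = c(0, 90000))
    rp <- generate_rr_series(ct, rsa_ground_truth(seed = 32))
    list(gr = gr, ct = ct, rp = rp)
  })
  init <- breathing_coeff_params()
  base_ac <- vapply(seq_len(length(ds$rp) - 1), function(i)
    average_coefficient(ds$ct, c(ds$rp[i], ds$rp[i + 1])), 0)
  base_r2 <- fit_G(diff(ds$rp), base_ac)$r_squared
  opt <- optimize_coefficient_params(ds$gr$segmentation, ds$rp, initial = init)
  expect_gte(opt$r_squared, base_r2 - 1e-9)
})

test_that("fit_H inverts a probe table monotonically with flat extrapolation", {
  tab <- data.frame(rate = c(0, 50, 100, 200, 300, 400),
                    period = c(450, 470, 500, 560, 650, NA))
  h <- fit_H(tab)
  expect_equal(predict_H(h, 450)$rate, 0)           # anchored at rate 0
  ## round trip at the probed periods
  for (i in 1:5)
    expect_equal(predict_H(h, tab$period[i])$rate, tab$rate[i], tolerance = 1e-9)
  ## interpolation is monotone
  r <- predict_H(h, seq(450, 650, by = 10))$rate
  expect_true(all(diff(r) >= 0))
  ## flat extrapolation beyond the table, flagged
  out <- predict_H(h, 900)
  expect_equal(out$rate, 300)
  expect_true(out$extrapolated)
  ## non-monotone table -> monotone regression + warning
  tab2 <- tab; tab2$period[3] <- 480; tab2$period[2] <- 495
  expect_warning(fit_H(tab2), "monotone")
  expect_error(fit_H(data.frame(rate = 0:2, period = c(450, 500, NA))), "at least 4")
})

test_that("deterministic spike encoding: uniform rate, zero rate, integral count", {
  prof <- list(time_ms = seq(0, 1000, by = 1), rate = rep(100, 1001))
  plan <- encode_spike_train(prof, duration = 1001)
  expect_equal(length(plan$spikes[[1]]), 100)
  expect_equal(diff(plan$spikes[[1]]), rep(10, 99), tolerance = 1e-9)
  plan0 <- encode_spike_train(list(time_ms = 0:100, rate = rep(0, 101)), 100)
  expect_equal(length(plan0$spikes[[1]]), 0)
  set.seed(5)
  r <- pmax(0, 150 + 80 * sin(seq(0, 20, length.out = 5001)) + rnorm(5001, 0, 10))
  prof2 <- list(time_ms = seq(0, 5000, by = 1), rate = r)
  plan2 <- encode_spike_train(prof2, duration = 5001)
  integral <- sum(r[-length(r)] * diff(prof2$time_ms)) / 1000
  expect_equal(length(plan2$spikes[[1]]), floor(integral))
  expect_error(encode_spike_train(prof2, 5001, method = "poisson"), "seed")
})

test_that("rate profile follows C pointwise, guards negatives, notes clamping", {
  g <- structure(list(x1 = 300, x2 = 150, x3 = 450, r_squared = 1,
                      c_range = c(0, 1)), class = "g_fit")
  h <- fit_H(data.frame(rate = c(0, 100, 200, 300),
                        period = c(450, 520, 640, 800)))
  ct <- structure(list(time_ms = 0:100 * 10, C = c(rep(0, 50), rep(0.8, 51))),
                  class = "coefficient_trace")
  prof <- build_rate_profile(ct, g, list(h = h, T_thr = Inf, k = 0, s = 1))
  expect_equal(prof$rate[1], 0)                      # C = 0 -> minimal rate
  expect_equal(which(diff(prof$rate) > 0), 50)       # steps up with C
  ## exponential correction contributes exactly s at T_h = T_thr
  Th0 <- predict_G(g, 0.8)
  prof2 <- build_rate_profile(ct, g, list(h = h, T_thr = Th0, k = 0.01, s = 2))
  expect_equal(prof2$rate[101],
               2 * (predict_H(h, Th0)$rate + 1), tolerance = 1e-9)
  ## C outside the fitted range is clamped and flagged
  ct2 <- structure(list(time_ms = c(0, 10, 20), C = c(0, 1.5, 0.5)),
                   class = "coefficient_trace")
  prof3 <- build_rate_profile(ct2, g, list(h = h, T_thr = Inf, k = 0, s = 1))
  expect_gt(prof3$clamped_fraction, 0)
})

test_that("respiration and R-peak CSV round-trips; calibration JSON round-trips", {
  tt <- seq(0, 5000, by = 10)
  tr <- respiratory_trace(tt, sin(tt / 400))
  f1 <- tempfile(fileext = ".csv")
  write_respiration(tr, f1)
  tr2 <- read_respiration(f1)
  expect_equal(tr2$value, tr$value)
  f2 <- tempfile(fileext = ".csv")
  write_rpeaks(c(100, 600, 1150), f2)
  expect_equal(read_rpeaks(f2), c(100, 600, 1150))
  h <- fit_H(data.frame(rate = c(0, 100, 200, 300),
                        period = c(450, 520, 640, 800)))
  cal <- list(gfit = structure(list(x1 = 1, x2 = 2, x3 = 3, r_squared = 0.5,
                                    c_range = c(0, 1)), class = "g_fit"),
              cparams = breathing_coeff_params(),
              calibrations = list(RA = list(h = h, T_thr = 600, k = 0.01, s = 1)))
  f3 <- tempfile(fileext = ".json")
  write_calibration(cal, f3)
  rt <- read_calibration(f3)
  expect_equal(rt$gfit$x2, 2)
  expect_equal(rt$calibrations$RA$h$period, h$period)
})
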