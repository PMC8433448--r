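## Readout: activity-trace kernel, threshold/hysteresis activations,
## rhythm metrics and order checking on constructed fixtures.

test_that("activity trace matches the kernel definition and is additive", {
  spk <- data.frame(neuron_id = 1L, time_ms = 100)
  tr <- compute_activity_trace(spk, tau = 50, grid_dt = 0.5, duration = 300)
  at <- function(t) tr$value[which.min(abs(tr$time - t))]
  expect_equal(at(100), 1)
  expect_equal(at(150), exp(-1), tolerance = 1e-9)
  ## k simultaneous spikes peak at k
  spk5 <- data.frame(neuron_id = 1:5, time_ms = rep(100, 5))
  tr5 <- compute_activity_trace(spk5, tau = 50, grid_dt = 0.5, duration = 200)
  expect_equal(max(tr5$value), 5)
  ## empty stream -> all-zero trace
  tr0 <- compute_activity_trace(spk[0, ], tau = 50, grid_dt = 1, duration = 100)
  expect_true(all(tr0$value == 0))
})

test_that("on-grid recursive trace equals event-driven evaluation to 1e-9 relative", {
  set.seed(21)
  st <- sort(runif(200, 0, 900))
  spk <- data.frame(neuron_id = 1L, time_ms = st)
  tr <- compute_activity_trace(spk, tau = 50, grid_dt = 0.7, duration = 1000)
  idx <- seq(1, length(tr$time), by = 37)
  direct <- vapply(tr$time[idx], function(t)
    sum(exp(-(t - st[st <= t + 1e-12]) / 50)), 0)
  expect_equal(tr$value[idx], direct, tolerance = 1e-9)
})

test_that("steady periodic train plateaus at the geometric-series value", {
  ## one population neuron firing every 10 ms, tau 50: plateau 1/(1-exp(-10/50))
  spk <- data.frame(neuron_id = 1L, time_ms = seq(0, 2000, by = 10))
  tr <- compute_activity_trace(spk, tau = 50, grid_dt = 0.1, duration = 2000)
  plateau <- 1 / (1 - exp(-10 / 50))
  expect_equal(max(tr$value[tr$time > 1500]), plateau, tolerance = 1e-6)
})

test_that("activation detection: synchronized burst, hysteresis, two-burst fixture", {
  ## 16 neurons firing within 5 ms -> exactly one activation near onset
  spk <- data.frame(neuron_id = 1:16, time_ms = seq(100, 105, length.out = 16))
  tr <- compute_activity_trace(spk, tau = 50, grid_dt = 0.1, duration = 1000)
  act <- detect_activations(tr, 0.5, 16)
  expect_equal(nrow(act), 1)
  expect_lt(abs(act$time_ms - 102), 3)
  ## trace forever below threshold -> empty
  spk2 <- data.frame(neuron_id = 1:4, time_ms = rep(100, 4))
  tr2 <- compute_activity_trace(spk2, tau = 50, grid_dt = 0.1, duration = 500)
  expect_equal(nrow(detect_activations(tr2, 0.5, 16)), 0)
  ## two bursts 500 ms apart with full decay between -> exactly 2
  spk3 <- rbind(spk, transform(spk, time_ms = time_ms + 500))
  tr3 <- compute_activity_trace(spk3, tau = 50, grid_dt = 0.1, duration = 1500)
  expect_equal(nrow(detect_activations(tr3, 0.5, 16)), 2)
})

test_that("hysteresis bounds activation count by burst count", {
  set.seed(4)
  ## 30 noisy bursts
  bursts <- seq(200, by = 300, length.out = 30)
  spk <- do.call(rbind, lapply(bursts, function(b)
    data.frame(neuron_id = 1:16, time_ms = b + runif(16, 0, 8))))
  tr <- compute_activity_trace(spk, tau = 50, grid_dt = 0.5,
                               duration = max(bursts) + 200)
  act <- detect_activations(tr, 0.5, 16, min_separation = 0)
  expect_lte(nrow(act), 30)
})

test_that("rhythm metrics on a noiseless fixture give exact delays and zero CV", {
  n <- 20
  ra <- 1000 + 555 * (0:n)
  acts <- list(RA = ra, LA = ra + 15, V = ra + 125)
  m <- measure_rhythm(acts, c("RA", "LA", "V"))
  expect_equal(m$periods$mean, rep(555, 3))
  expect_equal(m$periods$cv_pct, rep(0, 3))
  expect_equal(m$delays$mean, c(15, 110, 430))
  expect_equal(m$delays$cv_pct, rep(0, 3), tolerance = 1e-9)
  expect_equal(m$skipped_cycles, 0)
})

test_that("delay CV matches sd/mean on a jittered fixture; CV is scale invariant", {
  set.seed(8)
  n <- 200
  ra <- 1000 + 555 * (0:n)
  jit <- rnorm(n + 1, 0, 3)
  acts <- list(RA = ra, LA = ra + 110 + jit, V = ra + 300)
  m <- measure_rhythm(acts, c("RA", "LA", "V"))
  d <- m$delays[m$delays$pair == "RA-LA", ]
  expect_equal(d$mean, mean(110 + jit), tolerance = 1e-9)
  expect_equal(d$cv_pct, 100 * sd(110 + jit) / mean(110 + jit), tolerance = 1e-9)
  expect_equal(d$cv_pct, 2.7, tolerance = 0.25)  # sd 3 on mean 110
  ## scaling all times leaves CV unchanged
  m2 <- measure_rhythm(lapply(acts, `*`, 3.7), c("RA", "LA", "V"))
  expect_equal(m2$delays$cv_pct, m$delays$cv_pct, tolerance = 1e-9)
})

test_that("skipped cycles are excluded from the pairing", {
  ra <- 1000 + 500 * (0:10)
  la <- ra + 50
  la <- la[-4]  # LA skips one cycle
  m <- measure_rhythm(list(RA = ra, LA = la), c("RA", "LA"))
  expect_gt(m$skipped_cycles, 0)
  expect_equal(m$delays$mean[m$delays$pair == "RA-LA"], 50, tolerance = 1e-9)
})

test_that("activation order checking flags early and late events precisely", {
  ra <- 1000 + 500 * (0:9)
  acts <- list(RA = ra, LA = ra + 20, V = ra + 120)
  expect_equal(nrow(check_activation_order(acts, c("RA", "LA", "V"))), 0)
  ## move one LA activation before its RA -> violation(s) in that cycle only
  acts2 <- acts
  acts2$LA[5] <- acts2$RA[5] - 5
  v <- check_activation_order(acts2, c("RA", "LA", "V"))
  expect_gt(nrow(v), 0)
  expect_true(all(abs(v$time_ms - ra[5]) < 600))
  expect_true("LA" %in% v$population)
})
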