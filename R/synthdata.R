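## Synthetic dog-at-rest respiration and R-R data generator.  The real
## recordings behind the validation (surface ECG + respiration of resting
## dogs) are not public; this module generates series with the same
## statistical structure: quasi-periodic breathing (~5 s cycles) with
## distinct exhalation / inhalation phases, baseline drift and noise, and
## R-R intervals lengthening with the average breathing coefficient
## according to a known quadratic ground truth.

#' Respiration generator model
#'
#' Defaults emulate a large dog breathing at rest: 5 +/- 0.5 s breathing
#' cycles, slightly longer exhalation than inhalation, slow baseline
#' wander plus a linear drift, and additive measurement noise.
#'
#' @param breath_period_mean,breath_period_sd breathing cycle length (ms).
#' @param exhalation_fraction fraction of the cycle spent in exhalation.
#' @param drift_slope linear baseline drift (units/ms).
#' @param wander_amplitude amplitude of a slow (60 s) baseline wander.
#' @param noise_sd additive white noise sd (signal units; waveform
#'   amplitude is 1).
#' @param dt sampling step (ms).
#' @param seed integer seed.
#' @return an object of class `respiration_model`.
#' @export
respiration_model <- function(breath_period_mean = 5000, breath_period_sd = 500,
                              exhalation_fraction = 0.55,
                              drift_slope = 0, wander_amplitude = 0,
                              noise_sd = 0.03, dt = 10, seed = 1L) {
  stopifnot(breath_period_mean > 0, breath_period_sd >= 0,
            exhalation_fraction > 0, exhalation_fraction < 1,
            noise_sd >= 0, dt > 0)
  structure(list(breath_period_mean = breath_period_mean,
                 breath_period_sd = breath_period_sd,
                 exhalation_fraction = exhalation_fraction,
                 drift_slope = drift_slope,
                 wander_amplitude = wander_amplitude,
                 noise_sd = noise_sd, dt = dt, seed = as.integer(seed)),
            class = "respiration_model")
}

#' RSA ground truth for the R-R generator
#'
#' The true quadratic `T_h = G(C)` used to place synthetic heart beats,
#' plus the beat-to-beat noise.  Defaults give a baseline R-R of 450 ms
#' rising to ~950 ms at full breathing coefficient, spanning the 400--1000
#' ms range of resting-dog R-R intervals, with the noise sd calibrated
#' once (see the package vignette) so that the quadratic fit on generated
#' data attains the reference goodness of fit (R^2 ~ 0.64).
#'
#' @param x1,x2,x3 quadratic coefficients of the true G (ms per C-unit
#'   powers).
#' @param rr_noise_sd additive Gaussian noise per interval (ms).
#' @param seed integer seed.
#' @return an object of class `rsa_ground_truth`.
#' @export
rsa_ground_truth <- function(x1 = 320, x2 = 180, x3 = 450,
                             rr_noise_sd = 94, seed = 1L) {
  stopifnot(x3 > 0, rr_noise_sd >= 0)
  structure(list(x1 = x1, x2 = x2, x3 = x3, rr_noise_sd = rr_noise_sd,
                 seed = as.integer(seed)), class = "rsa_ground_truth")
}

#' Generate a synthetic respiratory trace with ground-truth phase onsets
#'
#' Piecewise raised-cosine waveform: the signal rises from -1 to 1 over
#' each exhalation and falls back over the inhalation, with per-cycle
#' period jitter, drift, slow wander and additive noise.  The true onsets
#' are returned for segmentation round-trip testing.
#'
#' @param model a [respiration_model()].
#' @param duration trace length (ms), at least two breaths.
#' @return list with `trace` ([respiratory_trace()]) and `segmentation`
#'   (ground-truth `phase_segmentation`).
#' @export
generate_respiration <- function(model = respiration_model(), duration) {
  stopifnot(duration >= 2 * model$breath_period_mean)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(model$seed)

  ## draw cycle lengths until the duration is covered
  periods <- c()
  while (sum(periods) < duration + model$breath_period_mean) {
    p <- rnorm(1, model$breath_period_mean, model$breath_period_sd)
    p <- max(p, 0.4 * model$breath_period_mean)
    periods <- c(periods, p)
  }
  exh_on <- cumsum(c(0, head(periods, -1)))
  inh_on <- exh_on + model$exhalation_fraction * periods

  tt <- seq(0, duration, by = model$dt)
  v <- numeric(length(tt))
  for (i in seq_along(periods)) {
    e0 <- exh_on[i]; i0 <- inh_on[i]; e1 <- exh_on[i] + periods[i]
    sel <- tt >= e0 & tt < i0
    v[sel] <- -cos(pi * (tt[sel] - e0) / (i0 - e0))        # -1 -> 1
    sel <- tt >= i0 & tt < e1
    v[sel] <- cos(pi * (tt[sel] - i0) / (e1 - i0))         # 1 -> -1
  }
  v <- v + model$drift_slope * tt
  if (model$wander_amplitude > 0)
    v <- v + model$wander_amplitude * sin(2 * pi * tt / 60000)
  if (model$noise_sd > 0) v <- v + rnorm(length(v), 0, model$noise_sd)

  keep_e <- exh_on <= duration
  keep_i <- inh_on <= duration
  list(trace = respiratory_trace(tt, v),
       segmentation = structure(list(exhalation_onsets = exh_on[keep_e],
                                     inhalation_onsets = inh_on[keep_i]),
                                class = "phase_segmentation"))
}

#' Generate synthetic R-peak times driven by the breathing coefficient
#'
#' Beats are placed sequentially: the next R-R interval equals the true
#' quadratic `G(average C over the interval)` plus Gaussian noise, solved
#' per beat by fixed-point iteration (the average depends on the interval
#' length).  Intervals are constrained positive.
#'
#' @param ctrace a `coefficient_trace` (from the true or estimated
#'   segmentation).
#' @param truth an [rsa_ground_truth()].
#' @param t_start first beat time (ms).
#' @return numeric vector of R-peak times (ms).
#' @export
generate_rr_series <- function(ctrace, truth = rsa_ground_truth(),
                               t_start = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(truth$seed)

  t_end <- max(ctrace$time_ms)
  t <- if (is.null(t_start)) ctrace$time_ms[1] else t_start
  peaks <- t
  g <- function(C) truth$x1 * C^2 + truth$x2 * C + truth$x3
  repeat {
    eps <- rnorm(1, 0, truth$rr_noise_sd)
    rr <- g(0)  # initial guess
    for (iter in 1:30) {
      if (t + rr > t_end) break
      ac <- average_coefficient(ctrace, c(t, t + rr))
      rr_new <- max(g(ac) + eps, 150)
      if (abs(rr_new - rr) < 0.5) { rr <- rr_new; break }
      if (iter == 30) stop("beat placement did not converge")
      rr <- rr_new
    }
    if (t + rr > t_end) break
    t <- t + rr
    peaks <- c(peaks, t)
  }
  peaks
}

#' Build the full synthetic validation dataset
#'
#' One call produces the fixtures used by the calibration and acceptance
#' pipelines: a calibration respiration trace, a 140 s evaluation trace
#' (the duration of the reference closed-loop run) and a 2.3 min trace
#' with matching R-peaks for the quadratic G fit, all deterministic in
#' the seed.
#'
#' @param seed integer master seed.
#' @param cparams [breathing_coeff_params()] used for the ground-truth
#'   coefficient traces.
#' @return list with `calibration`, `evaluation`, `gfit_data` (each:
#'   `trace`, `segmentation`, `ctrace`, and for `gfit_data` also
#'   `r_peaks`), plus `truth` and `model` parameter records.
#' @export
make_validation_dataset <- function(seed = 1L, cparams = breathing_coeff_params()) {
  seed <- as.integer(seed)
  model_cal <- respiration_model(seed = seed)
  model_eval <- respiration_model(seed = seed + 101L,
                                  drift_slope = 2e-6, wander_amplitude = 0.15)
  model_g <- respiration_model(seed = seed + 202L,
                               drift_slope = -1e-6, wander_amplitude = 0.1)
  truth <- rsa_ground_truth(seed = seed + 303L)

  mk <- function(model, dur) {
    gr <- generate_respiration(model, dur)
    gr$ctrace <- compute_breathing_coefficient(gr$segmentation, cparams,
                                               t_range = c(0, dur))
    gr
  }
  cal <- mk(model_cal, 120000)
  ev <- mk(model_eval, 140000)     # 140 s evaluation run
  gd <- mk(model_g, 138000)        # 2.3 min for the G fit
  gd$r_peaks <- generate_rr_series(gd$ctrace, truth)

  list(calibration = cal, evaluation = ev, gfit_data = gd,
       truth = truth,
       model = list(calibration = model_cal, evaluation = model_eval,
                    gfit = model_g))
}

#' Write the synthetic dataset as CSV fixtures + manifest
#'
#' Emits the CSV formats consumed by the feedback pipeline (respiration
#' traces `time_ms,value`, R-peaks `time_ms`) and a JSON manifest with
#' every generator parameter and seed.
#'
#' @param dataset a [make_validation_dataset()] result.
#' @param dir output directory (created if needed).
#' @export
write_validation_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_respiration(dataset$calibration$trace, file.path(dir, "respiration_calibration.csv"))
  write_respiration(dataset$evaluation$trace, file.path(dir, "respiration_evaluation.csv"))
  write_respiration(dataset$gfit_data$trace, file.path(dir, "respiration_gfit.csv"))
  write_rpeaks(dataset$gfit_data$r_peaks, file.path(dir, "rpeaks_gfit.csv"))
  manifest <- list(truth = unclass(dataset$truth),
                   model = lapply(dataset$model, unclass))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
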