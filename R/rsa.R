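## Respiratory-feedback chain: breathing-phase segmentation, breathing
## coefficient C(t), quadratic R-R model G(C), inhibitory rate calibration
## H (base table, exponential correction, per-oscillator scaling),
## deterministic rate-to-spike encoding, and the closed loop.

#' Respiratory trace container
#'
#' @param time_ms uniformly sampled times (ms).
#' @param value respiratory signal values (arbitrary units; an increase
#'   corresponds to exhalation, a decrease to inhalation).
#' @return an object of class `respiratory_trace`.
#' @export
respiratory_trace <- function(time_ms, value) {
  stopifnot(length(time_ms) == length(value), length(time_ms) >= 2,
            all(is.finite(value)))
  dt <- diff(time_ms)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) stop("sampling must be uniform")
  structure(list(time_ms = time_ms, value = value, dt = dt[1]),
            class = "respiratory_trace")
}

#' Read / write respiratory traces and R-peak lists as CSV
#' @param trace a [respiratory_trace()].
#' @param path file path.
#' @export
write_respiration <- function(trace, path) {
  write.csv(data.frame(time_ms = trace$time_ms, value = trace$value),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_respiration
#' @export
read_respiration <- function(path) {
  x <- read.csv(path)
  respiratory_trace(x$time_ms, x$value)
}

#' @rdname write_respiration
#' @param r_peaks numeric vector of R-peak times (ms).
#' @export
write_rpeaks <- function(r_peaks, path) {
  write.csv(data.frame(time_ms = r_peaks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_respiration
#' @export
read_rpeaks <- function(path) read.csv(path)$time_ms

#' Segment a respiratory trace into exhalation / inhalation phases
#'
#' Exhalation onsets are the local minima of the (detrended, smoothed)
#' respiratory signal -- the points where the value starts increasing --
#' and inhalation onsets the local maxima.  Only the extremum TIMES are
#' used downstream, which makes the segmentation robust to baseline drift
#' and offsets; a linear trend is removed before extremum detection for
#' the same reason.  Alternation is enforced by keeping the most prominent
#' of consecutive same-type extrema.
#'
#' @param trace a [respiratory_trace()].
#' @param smoothing moving-average window (ms, default 400).
#' @param prominence minimal extremum prominence as a fraction of the
#'   detrended signal range (default 0.2).
#' @param detrend remove a linear trend first (default TRUE).
#' @return an object of class `phase_segmentation`: list with
#'   `exhalation_onsets`, `inhalation_onsets` (ms), strictly alternating.
#' @export
segment_phases <- function(trace, smoothing = 400, prominence = 0.2,
                           detrend = TRUE) {
  v <- trace$value
  tt <- trace$time_ms
  if (diff(range(v)) == 0) stop("constant trace: no respiratory phases found")
  if (detrend) v <- v - fitted(lm(v ~ tt))
  k <- max(1L, round(smoothing / trace$dt))
  if (k > 1) {
    kern <- rep(1 / k, k)
    v <- as.numeric(stats::filter(v, kern, sides = 2))
    ## fill the convolution edges
    v[is.na(v)] <- v[!is.na(v)][c(rep(1, sum(is.na(v) & seq_along(v) < k)),
                                  rep(sum(!is.na(v)), sum(is.na(v) & seq_along(v) >= k)))]
  }
  dv <- diff(v)
  sgn <- sign(dv); sgn[sgn == 0] <- NA
  sgn <- zoo_fill(sgn)
  flips <- which(diff(sgn) != 0) + 1L
  if (!length(flips)) stop("no extrema found in respiratory trace")
  typ <- ifelse(sgn[flips] > 0, "min", "max")  # rising after the flip = minimum
  ext <- data.frame(idx = flips, time = tt[flips], type = typ,
                    value = v[flips], stringsAsFactors = FALSE)
  ## prominence filter
  thr <- prominence * diff(range(v))
  keep <- rep(TRUE, nrow(ext))
  for (i in seq_len(nrow(ext))) {
    lo <- if (i == 1) v[1] else ext$value[i - 1]
    hi <- if (i == nrow(ext)) v[length(v)] else ext$value[i + 1]
    if (abs(ext$value[i] - lo) < thr && abs(ext$value[i] - hi) < thr)
      keep[i] <- FALSE
  }
  ext <- ext[keep, ]
  if (nrow(ext) < 2) stop("no prominent extrema found in respiratory trace")
  ## enforce alternation: among consecutive same-type extrema keep the
  ## more extreme one
  i <- 2L
  while (i <= nrow(ext)) {
    if (ext$type[i] == ext$type[i - 1]) {
      better_i <- if (ext$type[i] == "min") ext$value[i] < ext$value[i - 1]
                  else ext$value[i] > ext$value[i - 1]
      ext <- ext[-(if (better_i) i - 1 else i), ]
    } else i <- i + 1L
  }
  structure(list(exhalation_onsets = ext$time[ext$type == "min"],
                 inhalation_onsets = ext$time[ext$type == "max"]),
            class = "phase_segmentation")
}

## carry last observation forward/backward for a vector with NAs
zoo_fill <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cumsum(ok)
  filled <- c(x[ok][1], x[ok])[idx + 1]
  filled
}

#' Breathing-coefficient parameters (pinned logistic ramps)
#'
#' The breathing coefficient C rises during exhalation as a logistic ramp
#' pinned to 0 at the exhalation onset and falls back towards 0 during
#' inhalation as a mirrored logistic; the parameters control the
#' amplitude, steepness and midpoints of the two ramps.
#'
#' @param amplitude logistic amplitude L (dimensionless, > 0).
#' @param steepness_exh,steepness_inh logistic steepness (1/ms, > 0).
#' @param midpoint_exh,midpoint_inh logistic midpoint offsets (ms).
#' @return an object of class `breathing_coeff_params`.
#' @export
breathing_coeff_params <- function(amplitude = 1,
                                   steepness_exh = 0.0015, midpoint_exh = 1300,
                                   steepness_inh = 0.0022, midpoint_inh = 900) {
  stopifnot(amplitude > 0, steepness_exh > 0, steepness_inh > 0)
  structure(list(amplitude = amplitude,
                 steepness_exh = steepness_exh, midpoint_exh = midpoint_exh,
                 steepness_inh = steepness_inh, midpoint_inh = midpoint_inh),
            class = "breathing_coeff_params")
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Compute the breathing-coefficient trace C(t)
#'
#' C is reset to 0 at the beginning of every exhalation phase, increases
#' monotonically during exhalation (pinned logistic ramp) and decreases
#' monotonically back towards 0 during inhalation.  It depends only on
#' the phase-onset times, never on signal amplitudes.
#'
#' @param seg a [segment_phases()] result.
#' @param params a [breathing_coeff_params()].
#' @param grid_dt sampling step of the returned trace (ms, default 10).
#' @param t_range optional `c(t0, t1)`; defaults to the span of the
#'   segmentation.
#' @return an object of class `coefficient_trace`: list with `time_ms`,
#'   `C`.
#' @export
compute_breathing_coefficient <- function(seg, params = breathing_coeff_params(),
                                          grid_dt = 10, t_range = NULL) {
  ev <- rbind(data.frame(time = seg$exhalation_onsets, type = "exh"),
              data.frame(time = seg$inhalation_onsets, type = "inh"))
  ev <- ev[order(ev$time), ]
  if (is.null(t_range)) t_range <- range(ev$time)
  tt <- seq(t_range[1], t_range[2], by = grid_dt)
  C <- numeric(length(tt))
  p <- params
  c_entry <- 0
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$time[i]
    t1 <- if (i < nrow(ev)) ev$time[i + 1] else t_range[2] + grid_dt
    sel <- tt >= t0 & tt < t1
    if (!any(sel)) next
    dt_loc <- tt[sel] - t0
    if (ev$type[i] == "exh") {
      ## pinned logistic: C(onset) = 0 exactly
      base <- logistic(-p$steepness_exh * p$midpoint_exh)
      C[sel] <- p$amplitude *
        (logistic(p$steepness_exh * (dt_loc - p$midpoint_exh)) - base) / (1 - base)
      c_entry <- p$amplitude *
        (logistic(p$steepness_exh * ((t1 - t0) - p$midpoint_exh)) - base) / (1 - base)
    } else {
      base <- logistic(-p$steepness_inh * p$midpoint_inh)
      ramp <- (logistic(p$steepness_inh * (dt_loc - p$midpoint_inh)) - base) / (1 - base)
      C[sel] <- pmax(c_entry * (1 - ramp), 0)
      c_entry <- 0
    }
  }
  ## before the first onset C is 0
  C[tt < ev$time[1]] <- 0
  structure(list(time_ms = tt, C = pmax(C, 0)), class = "coefficient_trace")
}

#' Time-average of the breathing coefficient over an interval
#'
#' Trapezoidal time-average of C over `[t_a, t_b]`, the quantity paired
#' with each R-R interval.
#'
#' @param ctrace a `coefficient_trace`.
#' @param interval `c(t_a, t_b)` (ms), within the trace span.
#' @return scalar average.
#' @export
average_coefficient <- function(ctrace, interval) {
  stopifnot(interval[2] > interval[1])
  tt <- ctrace$time_ms
  if (interval[1] < tt[1] - 1e-9 || interval[2] > tt[length(tt)] + 1e-9)
    stop("interval outside coefficient trace")
  ## integrate the piecewise-linear interpolant exactly
  xs <- sort(unique(c(interval, tt[tt > interval[1] & tt < interval[2]])))
  ys <- approx(tt, ctrace$C, xout = xs)$y
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2) / diff(interval)
}

#' Fit the quadratic R-R interval model G(C)
#'
#' Least-squares fit of `T_h = x1 C^2 + x2 C + x3` relating each R-R
#' interval to its average breathing coefficient; reports R-squared.
#'
#' @param rr_intervals R-R interval durations (ms).
#' @param avg_C matching average breathing coefficients.
#' @return an object of class `g_fit` with `x1`, `x2`, `x3`, `r_squared`,
#'   `c_range`.
#' @export
fit_G <- function(rr_intervals, avg_C) {
  stopifnot(length(rr_intervals) == length(avg_C))
  if (length(rr_intervals) < 10) stop("need at least 10 (R-R, C) pairs")
  if (diff(range(avg_C)) < 1e-12) stop("degenerate design: all C equal")
  fit <- lm(rr_intervals ~ avg_C + I(avg_C^2))
  cf <- coef(fit)
  r2 <- 1 - sum(residuals(fit)^2) / sum((rr_intervals - mean(rr_intervals))^2)
  structure(list(x1 = unname(cf[3]), x2 = unname(cf[2]), x3 = unname(cf[1]),
                 r_squared = r2, c_range = range(avg_C)), class = "g_fit")
}

#' Evaluate a fitted G(C)
#' @param gfit a `g_fit` (or compatible list with x1, x2, x3).
#' @param C breathing coefficient value(s).
#' @export
predict_G <- function(gfit, C) gfit$x1 * C^2 + gfit$x2 * C + gfit$x3

#' Optimize the breathing-coefficient parameters for the best G(C) fit
#'
#' Derivative-free (Nelder-Mead) search over the logistic parameters of C
#' maximizing the R-squared of the quadratic fit of the R-R intervals on
#' the average coefficient, as in the model's calibration procedure.
#'
#' @param seg a [segment_phases()] result.
#' @param r_peaks R-peak times (ms).
#' @param initial a [breathing_coeff_params()] starting point.
#' @param grid_dt C-trace sampling (ms).
#' @return list with `params` (best found), `r_squared`, `gfit`.
#' @export
optimize_coefficient_params <- function(seg, r_peaks,
                                        initial = breathing_coeff_params(),
                                        grid_dt = 20) {
  rr <- diff(r_peaks)
  eval_theta <- function(theta) {
    p <- breathing_coeff_params(amplitude = 1,
                                steepness_exh = exp(theta[1]),
                                midpoint_exh = theta[2],
                                steepness_inh = exp(theta[3]),
                                midpoint_inh = theta[4])
    ct <- compute_breathing_coefficient(seg, p, grid_dt = grid_dt)
    ok <- r_peaks[-length(r_peaks)] >= ct$time_ms[1] &
      r_peaks[-1] <= ct$time_ms[length(ct$time_ms)]
    if (sum(ok) < 10) return(list(r2 = -Inf))
    ac <- vapply(which(ok), function(i)
      average_coefficient(ct, c(r_peaks[i], r_peaks[i + 1])), 0)
    if (diff(range(ac)) < 1e-9) return(list(r2 = -Inf))
    g <- fit_G(rr[ok], ac)
    list(r2 = g$r_squared, gfit = g, params = p)
  }
  th0 <- c(log(initial$steepness_exh), initial$midpoint_exh,
           log(initial$steepness_inh), initial$midpoint_inh)
  best0 <- eval_theta(th0)
  opt <- tryCatch(
    optim(th0, function(th) -eval_theta(th)$r2, method = "Nelder-Mead",
          control = list(maxit = 120, reltol = 1e-4)),
    error = function(e) NULL)
  if (is.null(opt) || -opt$value <= best0$r2 + 1e-12) {
    if (is.null(opt)) warning("coefficient-parameter search failed; returning initial parameters")
    res <- best0
  } else res <- eval_theta(opt$par)
  list(params = if (is.null(res$params)) initial else res$params,
       r_squared = res$r2, gfit = res$gfit)
}

#' Probe the inhibitory rate -> oscillation period response
#'
#' Sends constant-rate inhibitory spike trains into one oscillator's
#' feedback source (oscillator isolated, tuned to its maximum needed
#' frequency) and measures the resulting mean period per rate.  Rates
#' that fully suppress the oscillation are recorded as censored.
#'
#' @param instance a `substrate_instance`.
#' @param oscillator oscillator name.
#' @param rate_grid inhibitory input rates (Hz).
#' @param window measurement window per rate (ms).
#' @return data frame `rate`, `period` (NA = censored / suppressed).
#' @export
probe_inhibition_response <- function(instance, oscillator, rate_grid,
                                      window = 10000) {
  sub <- subset_oscillator(decouple_network(instance), oscillator)
  epop <- exc_population(oscillator)
  src <- paste0("fb.", oscillator)
  dur <- window + 3000
  per <- vapply(rate_grid, function(r) {
    ext <- if (r > 0)
      data.frame(source = src, time_ms = seq(0, dur - 1, by = 1000 / r))
    else NULL
    sim <- simulate_substrate(sub, dur, external_spikes = ext)
    acts <- network_activations(sub, sim, populations = epop)[[epop]]
    acts <- acts[acts >= dur - window]
    if (length(acts) < 4) NA_real_ else mean(diff(acts))
  }, 0)
  data.frame(rate = rate_grid, period = per)
}

#' Fit the base period-to-rate map H
#'
#' Inverts the constant-rate probe table into a monotone map from desired
#' oscillation period T_h to inhibitory input rate, using isotone
#' regression (the period is physically non-decreasing in the rate) and
#' monotone interpolation.  The unperturbed period anchors H at rate 0;
#' extrapolation beyond the probed range is flat and flagged.
#'
#' @param table data frame `rate`, `period` from
#'   [probe_inhibition_response()].
#' @return an object of class `h_fit`: monotone table `period` -> `rate`
#'   plus the valid period range.
#' @export
fit_H <- function(table) {
  tab <- table[!is.na(table$period), ]
  if (nrow(tab) < 4) stop("need at least 4 non-censored (rate, period) points")
  tab <- tab[order(tab$rate), ]
  ## isotone regression of period on rate (monotone non-decreasing)
  iso <- isoreg(tab$rate, tab$period)
  if (any(iso$yf != tab$period))
    warning("non-monotone probe table; monotone regression applied")
  per <- iso$yf
  ## collapse duplicated periods (flat stretches) keeping the lowest rate
  keep <- !duplicated(per)
  structure(list(period = per[keep], rate = tab$rate[keep],
                 valid_range = range(per)), class = "h_fit")
}

#' Evaluate a base H map (period -> rate)
#'
#' @param h an `h_fit`.
#' @param period desired period(s) (ms).
#' @return list with `rate` and logical `extrapolated`.
#' @export
predict_H <- function(h, period) {
  r <- approx(h$period, h$rate, xout = period, rule = 2)$y
  list(rate = r,
       extrapolated = period < h$valid_range[1] | period > h$valid_range[2])
}

#' Refine H with an exponentially increasing correction term
#'
#' The base map underestimates the rates needed for long delays under
#' realistic time-varying input.  `T_thr` is set to the maximal delay the
#' oscillator reaches when driven with spike trains derived from the base
#' map and a realistic breathing-coefficient trace; the factor `k` of the
#' additive term `exp((T_h - T_thr) k)` is then escalated until the
#' target maximum delay is achieved.
#'
#' @param instance a `substrate_instance`.
#' @param oscillator oscillator name.
#' @param h base `h_fit`.
#' @param ctrace realistic `coefficient_trace` used for calibration.
#' @param gfit the fitted `g_fit` mapping C to desired periods.
#' @param target_max_delay longest delay to achieve (ms).
#' @param k_grid escalation sequence for k (1/ms).
#' @param scale constant scaling factor s applied to the rate (default 1).
#' @return list with `T_thr`, `k`, `achieved_max` (ms), `converged`.
#' @export
refine_H_exponential <- function(instance, oscillator, h, ctrace, gfit,
                                 target_max_delay,
                                 k_grid = c(0.004, 0.008, 0.012, 0.018, 0.025,
                                            0.035, 0.05, 0.07, 0.1),
                                 scale = 1) {
  max_rr <- function(k, T_thr) {
    prof <- build_rate_profile(ctrace, gfit, list(h = h, T_thr = T_thr, k = k,
                                                  s = scale))
    plan <- encode_spike_train(prof, duration = max(ctrace$time_ms),
                               source = paste0("fb.", oscillator))
    max_interval_under_plan(instance, oscillator, plan)
  }
  base <- max_rr(0, Inf)
  T_thr <- base$max_interval
  if (T_thr >= target_max_delay)
    return(list(T_thr = T_thr, k = 0, achieved_max = T_thr, converged = TRUE))
  achieved <- T_thr; k_best <- 0; k_lo <- 0
  hit <- NULL
  for (k in k_grid) {
    res <- max_rr(k, T_thr)
    if (res$suppressed) break  # escalation cap: oscillation collapsed
    achieved <- res$max_interval; k_best <- k
    if (achieved >= target_max_delay) { hit <- list(k = k, ach = achieved); break }
    k_lo <- k
  }
  if (is.null(hit))
    return(list(T_thr = T_thr, k = k_best, achieved_max = achieved,
                converged = FALSE))
  ## bisect between the last insufficient and the first sufficient factor:
  ## a coarse step can overshoot far past the target, which would make the
  ## closed-loop intervals at high C bimodal
  for (it in 1:5) {
    if (hit$ach <= 1.3 * target_max_delay) break
    k_mid <- (k_lo + hit$k) / 2
    res <- max_rr(k_mid, T_thr)
    if (!res$suppressed && res$max_interval >= target_max_delay)
      hit <- list(k = k_mid, ach = res$max_interval)
    else k_lo <- k_mid
  }
  list(T_thr = T_thr, k = hit$k, achieved_max = hit$ach, converged = TRUE)
}

## longest inter-activation interval of one isolated oscillator driven by a
## feedback spike plan
max_interval_under_plan <- function(instance, oscillator, plan) {
  sub <- subset_oscillator(decouple_network(instance), oscillator)
  src <- paste0("fb.", oscillator)
  times <- plan$spikes[[src]]
  if (is.null(times)) times <- plan$spikes[[1]]
  dur <- plan$duration
  ext <- if (length(times)) data.frame(source = src, time_ms = times) else NULL
  sim <- simulate_substrate(sub, dur, external_spikes = ext)
  epop <- exc_population(oscillator)
  acts <- network_activations(sub, sim, populations = epop)[[epop]]
  acts <- acts[acts >= 2000]
  if (length(acts) < 2)
    return(list(max_interval = dur, suppressed = TRUE))
  list(max_interval = max(diff(acts)),
       suppressed = max(diff(acts)) > 0.5 * dur)
}

#' Harmonize the per-oscillator scaling factors s
#'
#' With all single-oscillator calibrations done, the coupled system is run
#' on the realistic calibration trace and the per-oscillator scaling
#' factors are adjusted from pairwise order checks: the scaling factor of
#' an oscillator that spiked too early is increased (stronger slow-down)
#' and that of one which spiked too late decreased.  The ring's first
#' oscillator is the reference and keeps s = 1.  Pairs are processed
#' sequentially in ring order.
#'
#' @param instance a coupled `substrate_instance`.
#' @param calibrations named list per oscillator: `h`, `T_thr`, `k`, `s`.
#' @param ctrace calibration `coefficient_trace`.
#' @param gfit fitted `g_fit`.
#' @param max_rounds adjustment rounds (default 6).
#' @param step multiplicative adjustment (default 0.15).
#' @return list with updated `calibrations` and the final violation count.
#' @export
harmonize_scaling <- function(instance, calibrations, ctrace, gfit,
                              max_rounds = 6, step = 0.15) {
  ring <- instance$topology$ring_order
  n_viol <- NA_integer_
  for (round in seq_len(max_rounds)) {
    cl <- run_closed_loop(instance, ctrace = ctrace, gfit = gfit,
                          calibrations = calibrations)
    viol <- cl$violations
    n_viol <- nrow(viol)
    if (n_viol == 0) break
    adjusted <- FALSE
    ## sequential pairwise processing in ring order; the reference keeps
    ## s = 1.  "early" rows name the population that fired out of turn;
    ## "late" rows name it in the `expected` column.
    for (o in ring[-1]) {
      n_early <- sum(viol$population == o & viol$verdict == "early")
      n_late <- sum(viol$expected == o & viol$verdict == "late")
      if (n_early > n_late) {
        calibrations[[o]]$s <- calibrations[[o]]$s * (1 + step)
        adjusted <- TRUE
        break
      } else if (n_late > 0) {
        calibrations[[o]]$s <- calibrations[[o]]$s / (1 + step)
        adjusted <- TRUE
        break
      }
    }
    if (!adjusted) break
  }
  list(calibrations = calibrations, violations = n_viol)
}

#' Build the inhibitory rate profile r_inh(t) per oscillator
#'
#' Evaluates `r_inh(t) = (H(G(C(t))) + exp((G(C(t)) - T_thr) k)) * s` on
#' the coefficient-trace grid.  C values outside the fitted G range are
#' clamped (flagged); negative or non-finite rates are guarded to 0.
#'
#' @param ctrace a `coefficient_trace`.
#' @param gfit a `g_fit`.
#' @param calibration list with `h` (`h_fit`), `T_thr` (ms), `k` (1/ms),
#'   `s` (scaling, default 1).
#' @return an object of class `rate_profile`: list with `time_ms`, `rate`
#'   (Hz), `clamped` fraction.
#' @export
build_rate_profile <- function(ctrace, gfit, calibration) {
  s <- if (is.null(calibration$s)) 1 else calibration$s
  C <- ctrace$C
  clamped <- C < gfit$c_range[1] | C > gfit$c_range[2]
  C <- pmin(pmax(C, gfit$c_range[1]), gfit$c_range[2])
  Th <- predict_G(gfit, C)
  r <- predict_H(calibration$h, Th)$rate
  if (is.finite(calibration$T_thr))
    r <- r + exp((Th - calibration$T_thr) * calibration$k)
  r <- r * s
  r[!is.finite(r) | r < 0] <- 0
  structure(list(time_ms = ctrace$time_ms, rate = r,
                 clamped_fraction = mean(clamped)), class = "rate_profile")
}

#' Encode a rate profile into a deterministic spike train
#'
#' Default deterministic time-rescaling: a spike is emitted whenever the
#' running integral of the rate crosses a successive integer, so the spike
#' count equals the floor of the integrated rate.  A Poisson mode (with
#' mandatory seed) is available behind a flag.
#'
#' @param profile a `rate_profile` (or list with `time_ms`, `rate`).
#' @param duration plan duration (ms); spikes beyond it are dropped.
#' @param method `"rescale"` (default, deterministic) or `"poisson"`.
#' @param seed integer seed (required for `"poisson"`).
#' @param source name of the target feedback source (default `"fb"`).
#' @return an object of class `feedback_spike_plan`: list with `spikes`
#'   (named list of sorted spike-time vectors) and `duration`.
#' @export
encode_spike_train <- function(profile, duration, method = c("rescale", "poisson"),
                               seed = NULL, source = "fb") {
  method <- match.arg(method)
  tt <- profile$time_ms
  r <- pmax(profile$rate, 0) / 1000  # spikes per ms
  ## piecewise-constant (left) integrated rate on the grid
  dt <- diff(tt)
  cum <- c(0, cumsum(r[-length(r)] * dt))
  total <- cum[length(cum)]
  if (method == "rescale") {
    if (total < 1) times <- numeric(0)
    else {
      targets <- seq_len(floor(total))
      times <- approx(cum, tt, xout = targets, ties = "ordered")$y
    }
  } else {
    if (is.null(seed)) stop("poisson encoding requires a seed")
    set.seed(seed)
    n <- stats::rpois(1, total)
    u <- sort(runif(n, 0, total))
    times <- approx(cum, tt, xout = u, ties = "ordered")$y
  }
  times <- times[!is.na(times) & times < duration]
  plan <- list(spikes = setNames(list(sort(times)), source), duration = duration)
  structure(plan, class = "feedback_spike_plan")
}

#' Run the closed-loop adaptive pacemaker
#'
#' Builds the per-oscillator inhibitory rate profiles from the breathing
#' coefficient, encodes them into deterministic spike trains, simulates
#' the coupled network under this respiratory feedback, and extracts the
#' ventricular activations as R-peak analogues.  Each R-R interval is
#' paired with its time-averaged breathing coefficient and the quadratic
#' G fit on those pairs is reported.
#'
#' @param instance a tuned, coupled `substrate_instance`.
#' @param respiration optional [respiratory_trace()]; segmented with
#'   defaults if `ctrace` not given.
#' @param ctrace optional precomputed `coefficient_trace` (takes
#'   precedence).
#' @param cparams [breathing_coeff_params()] used when segmenting.
#' @param gfit fitted `g_fit` (target relation to reproduce).
#' @param calibrations named list per oscillator (`h`, `T_thr`, `k`, `s`);
#'   a single calibration is recycled to all oscillators.
#' @param settle initial transient excluded from the pairing (ms).
#' @return list with `activations`, `r_peaks`, `pairs` (data frame
#'   `avg_C`, `rr_ms`), `gfit_dyn` (quadratic fit on the generated pairs,
#'   or NULL), `r_squared`, `violations`, `metrics`, `sim`.
#' @export
run_closed_loop <- function(instance, respiration = NULL, ctrace = NULL,
                            cparams = breathing_coeff_params(),
                            gfit, calibrations, settle = 3000) {
  ring <- instance$topology$ring_order
  if (is.null(ctrace)) {
    if (is.null(respiration)) stop("need a respiration trace or a coefficient trace")
    seg <- segment_phases(respiration)
    ctrace <- compute_breathing_coefficient(seg, cparams,
                                            t_range = range(respiration$time_ms))
  }
  if (!is.null(names(calibrations)) && all(c("h", "T_thr", "k") %in% names(calibrations)))
    calibrations <- setNames(rep(list(calibrations), length(ring)), ring)
  dur <- max(ctrace$time_ms)
  ## feedback spike plans per oscillator
  ext <- NULL
  for (o in ring) {
    prof <- build_rate_profile(ctrace, gfit, calibrations[[o]])
    plan <- encode_spike_train(prof, dur, source = paste0("fb.", o))
    times <- plan$spikes[[1]]
    if (length(times))
      ext <- rbind(ext, data.frame(source = paste0("fb.", o), time_ms = times))
  }
  ## warm-up stagger as in the tuned baseline
  wp <- warmup_plan(instance, if (!is.null(instance$stagger)) instance$stagger
                    else (seq_along(ring) - 1) * 180)
  ext <- rbind(ext, wp$external_spikes)
  ext <- ext[order(ext$time_ms), ]
  sim <- simulate_substrate(wp$instance, dur, external_spikes = ext)
  epops <- vapply(ring, exc_population, "")
  acts <- network_activations(wp$instance, sim, populations = epops)
  names(acts) <- ring
  vpop <- ring[length(ring)]
  r_peaks <- acts[[vpop]]
  r_peaks <- r_peaks[r_peaks >= settle]
  pairs <- NULL
  if (length(r_peaks) >= 3) {
    lo <- ctrace$time_ms[1]; hi <- max(ctrace$time_ms)
    idx <- which(r_peaks[-length(r_peaks)] >= lo & r_peaks[-1] <= hi)
    pairs <- data.frame(
      avg_C = vapply(idx, function(i)
        average_coefficient(ctrace, c(r_peaks[i], r_peaks[i + 1])), 0),
      rr_ms = diff(r_peaks)[idx])
  }
  gdyn <- NULL; r2 <- NA_real_
  if (!is.null(pairs) && nrow(pairs) >= 10 && diff(range(pairs$avg_C)) > 1e-9) {
    gdyn <- fit_G(pairs$rr_ms, pairs$avg_C)
    r2 <- gdyn$r_squared
  }
  viol <- check_activation_order(acts, ring, window = c(settle, dur))
  metrics <- tryCatch(measure_rhythm(acts, ring, window = c(settle, dur)),
                      error = function(e) NULL)
  list(activations = acts, r_peaks = r_peaks, pairs = pairs,
       gfit_dyn = gdyn, r_squared = r2, violations = viol,
       metrics = metrics, sim = sim)
}

#' Persist / restore a full RSA calibration as JSON
#'
#' @param calibration list with `gfit`, `cparams`, and per-oscillator
#'   `calibrations` (h table, T_thr, k, s).
#' @param path file path.
#' @export
write_calibration <- function(calibration, path) {
  ser <- list(
    gfit = unclass(calibration$gfit),
    cparams = unclass(calibration$cparams),
    calibrations = lapply(calibration$calibrations, function(cc)
      list(h = list(period = cc$h$period, rate = cc$h$rate,
                    valid_range = cc$h$valid_range),
           T_thr = cc$T_thr, k = cc$k, s = cc$s)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(gfit = structure(x$gfit, class = "g_fit"),
       cparams = structure(x$cparams, class = "breathing_coeff_params"),
       calibrations = lapply(x$calibrations, function(cc) {
         cc$h <- structure(list(period = cc$h$period, rate = cc$h$rate,
                                valid_range = cc$h$valid_range), class = "h_fit")
         cc
       }))
}
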