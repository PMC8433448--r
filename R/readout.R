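## Readout: population activity traces (exponential kernel), threshold
## activations with hysteresis, and rhythm metrics (periods, chamber
## delays, CVs, order checks).

#' Exponentially weighted population activity trace
#'
#' `value(t) = sum over spikes s <= t of exp(-(t - t_s) / tau)`: every
#' spike contributes a kernel of peak amplitude 1, so a trace value of k
#' means "k population spikes within the recent tau window".  Computed on
#' a regular grid with a recursive update that is exact at the grid points
#' (identical to direct event-driven evaluation up to rounding).
#'
#' @param spikes data frame `neuron_id`, `time_ms` (a `spike_sim$spikes`).
#' @param neuron_ids ids forming the population.
#' @param tau kernel time constant (ms, default 50).
#' @param grid_dt trace sampling step (ms, default 0.1 = simulation dt).
#' @param duration trace end time (ms); defaults to the last spike time.
#' @param population optional population label stored in the result.
#' @return an object of class `activity_trace`: list with `time`, `value`,
#'   `tau`, `grid_dt`, `population`.
#' @export
compute_activity_trace <- function(spikes, neuron_ids = NULL, tau = 50,
                                   grid_dt = 0.1, duration = NULL,
                                   population = NA_character_) {
  stopifnot(tau > 0, grid_dt > 0)
  st <- spikes$time_ms
  if (!is.null(neuron_ids)) st <- st[spikes$neuron_id %in% neuron_ids]
  st <- sort(st)
  if (is.null(duration)) duration <- if (length(st)) max(st) else grid_dt
  tgrid <- seq(0, duration, by = grid_dt)
  imp <- numeric(length(tgrid))
  if (length(st)) {
    ## bucket each spike into the first grid point >= its time
    idx <- pmin(length(tgrid), findInterval(st - 1e-9, tgrid) + 1L)
    contrib <- exp(-(tgrid[idx] - st) / tau)
    agg <- rowsum(contrib, idx)
    imp[as.integer(rownames(agg))] <- agg[, 1]
  }
  val <- as.numeric(stats::filter(imp, exp(-grid_dt / tau), method = "recursive"))
  structure(list(time = tgrid, value = val, tau = tau, grid_dt = grid_dt,
                 population = population), class = "activity_trace")
}

#' Detect population activations by threshold crossing with hysteresis
#'
#' A population counts as activated when its activity trace crosses
#' `threshold_fraction * population_size` upward (50\% for excitatory,
#' 25\% for inhibitory populations by convention); a new activation
#' requires the trace to fall below the threshold first.  The activation
#' timestamp is the linearly interpolated upward crossing time.
#'
#' @param trace an `activity_trace`.
#' @param threshold_fraction fraction in (0, 1).
#' @param population_size number of neurons in the population.
#' @param min_separation debounce interval (ms): a population burst whose
#'   trace briefly dips below the threshold mid-burst (staggered
#'   recruitment) counts as a single activation; crossings closer than
#'   this to the previous kept one are discarded.
#' @return data frame `population`, `time_ms` (possibly 0 rows).
#' @export
detect_activations <- function(trace, threshold_fraction, population_size,
                               min_separation = 100) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1, population_size >= 1)
  theta <- threshold_fraction * population_size
  v <- trace$value; tt <- trace$time
  above <- v >= theta
  if (!any(above)) return(data.frame(population = character(0), time_ms = numeric(0)))
  up <- which(above & !c(TRUE, above[-length(above)]))  # FALSE -> TRUE transitions
  times <- tt[up - 1] + (theta - v[up - 1]) / (v[up] - v[up - 1]) * (tt[up] - tt[up - 1])
  if (above[1]) times <- c(tt[1], times)  # already above at start
  if (min_separation > 0 && length(times) > 1) {
    keep <- c(TRUE, diff(times) >= min_separation)
    while (!all(keep)) {   # re-evaluate separations after dropping
      times <- times[keep]
      keep <- c(TRUE, diff(times) >= min_separation)
    }
  }
  data.frame(population = trace$population, time_ms = times)
}

## convenience: activation times of every population of an instance
#' Activation times of all populations of a simulated network
#'
#' @param instance the `substrate_instance` that produced the simulation.
#' @param sim a `spike_sim`.
#' @param tau activity-trace time constant (ms).
#' @param grid_dt trace grid step (ms); defaults to the simulation dt.
#' @param populations which populations (default: all).
#' @return named list of numeric activation-time vectors.
#' @export
network_activations <- function(instance, sim, tau = 50, grid_dt = NULL,
                                populations = NULL) {
  if (is.null(grid_dt)) grid_dt <- sim$dt
  pops <- instance$populations
  if (!is.null(populations)) pops <- pops[pops$name %in% populations, ]
  out <- list()
  for (i in seq_len(nrow(pops))) {
    tr <- compute_activity_trace(sim$spikes, population_ids(instance, pops$name[i]),
                                 tau = tau, grid_dt = grid_dt,
                                 duration = sim$duration, population = pops$name[i])
    out[[pops$name[i]]] <- detect_activations(tr, pops$threshold_fraction[i], pops$n[i])$time_ms
  }
  out
}

#' Rhythm metrics: periods, inter-oscillator delays and their CVs
#'
#' Periods are successive-activation differences per population; the delay
#' of an ordered pair is the time from each activation of the predecessor
#' to the next activation of the successor.  Cycles in which the successor
#' skips (no activation before the predecessor's next one) are flagged and
#' excluded from the pairing.
#'
#' @param activations named list of activation-time vectors (one per
#'   population, e.g. from [network_activations()]), restricted to the
#'   populations named in `ring_order`.
#' @param ring_order character vector of population names in ring order.
#' @param window optional `c(t0, t1)` (ms) restricting the analysis.
#' @return an object of class `rhythm_metrics`: list with data frames
#'   `periods` (population, mean, sd, cv_pct, n) and `delays` (pair, mean,
#'   sd, cv_pct, n), plus `cycle_count` and `skipped_cycles`.
#' @export
measure_rhythm <- function(activations, ring_order, window = NULL) {
  acts <- lapply(ring_order, function(p) {
    a <- activations[[p]]
    if (is.null(a)) stop("no activations for population ", p)
    if (!is.null(window)) a <- a[a >= window[1] & a <= window[2]]
    sort(a)
  })
  names(acts) <- ring_order
  if (any(vapply(acts, length, 1L) < 3))
    stop("need at least 3 activations per population in the window")

  periods <- do.call(rbind, lapply(ring_order, function(p) {
    d <- diff(acts[[p]])
    data.frame(population = p, mean = mean(d), sd = sd(d),
               cv_pct = 100 * sd(d) / mean(d), n = length(d))
  }))

  k <- length(ring_order)
  skipped <- 0L
  delays <- do.call(rbind, lapply(seq_len(k), function(i) {
    pre <- acts[[i]]; suc <- acts[[i %% k + 1L]]
    d <- rep(NA_real_, length(pre))
    for (j in seq_along(pre)) {
      nxt <- suc[suc > pre[j]]
      nxt_pre <- pre[pre > pre[j]]
      if (length(nxt) == 0) next
      if (length(nxt_pre) > 0 && nxt[1] > nxt_pre[1]) next  # successor skipped
      d[j] <- nxt[1] - pre[j]
    }
    skipped <<- skipped + sum(is.na(d[-length(d)]))
    d <- d[!is.na(d)]
    pair <- paste0(ring_order[i], "-", ring_order[i %% k + 1L])
    if (length(d) < 2)
      return(data.frame(pair = pair, mean = if (length(d)) d else NA_real_,
                        sd = NA_real_, cv_pct = NA_real_, n = length(d)))
    data.frame(pair = pair, mean = mean(d), sd = sd(d),
               cv_pct = 100 * sd(d) / mean(d), n = length(d))
  }))

  structure(list(periods = periods, delays = delays,
                 cycle_count = min(vapply(acts, length, 1L)) - 1L,
                 skipped_cycles = skipped),
            class = "rhythm_metrics")
}

#' @export
print.rhythm_metrics <- function(x, ...) {
  cat("rhythm metrics over", x$cycle_count, "cycles\n")
  cat("periods:\n"); print(x$periods, row.names = FALSE, digits = 4)
  cat("delays:\n"); print(x$delays, row.names = FALSE, digits = 4)
  if (x$skipped_cycles > 0) cat("skipped cycles:", x$skipped_cycles, "\n")
  invisible(x)
}

#' Check that populations activate in ring order
#'
#' Walks the merged, time-sorted activation sequence and compares it with
#' the expected cyclic order.  A population appearing before its
#' predecessor's slot is reported as `"early"`, a skipped slot as
#' `"late"` for the population that missed it.
#'
#' @param activations named list of activation times.
#' @param ring_order character vector of population names in ring order.
#' @param window optional `c(t0, t1)` restriction.
#' @return data frame `time_ms`, `population`, `expected`, `verdict`
#'   (rows only for violations; zero rows = perfect order), with attribute
#'   `n_events`.
#' @export
check_activation_order <- function(activations, ring_order, window = NULL) {
  ev <- do.call(rbind, lapply(ring_order, function(p) {
    a <- activations[[p]]
    if (!is.null(window)) a <- a[a >= window[1] & a <= window[2]]
    if (length(a) == 0) return(NULL)
    data.frame(time_ms = a, population = p, stringsAsFactors = FALSE)
  }))
  ev <- ev[order(ev$time_ms), ]
  k <- length(ring_order)
  idx <- match(ev$population, ring_order)
  out <- NULL
  expected <- idx[1]
  for (j in seq_len(nrow(ev))) {
    if (idx[j] == expected) {
      expected <- expected %% k + 1L
    } else {
      ## if the observed population is the one after the expected slot, the
      ## expected population missed its slot ("late"); otherwise the
      ## observed one fired out of turn ("early")
      verdict <- if (idx[j] == expected %% k + 1L) "late" else "early"
      out <- rbind(out, data.frame(time_ms = ev$time_ms[j],
                                   population = ev$population[j],
                                   expected = ring_order[expected],
                                   verdict = verdict, stringsAsFactors = FALSE))
      expected <- idx[j] %% k + 1L  # resynchronize on the observed event
    }
  }
  if (is.null(out))
    out <- data.frame(time_ms = numeric(0), population = character(0),
                      expected = character(0), verdict = character(0))
  attr(out, "n_events") <- nrow(ev)
  out
}
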