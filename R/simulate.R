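## Fixed-step network simulation (R front end to the C++ core) and the
## CSV / JSON external interfaces for spike streams and configurations.

#' Simulate a substrate instance
#'
#' Integrates the AdExp membrane and exponential synaptic current dynamics
#' with a fixed-step exponential-Euler scheme (default dt = 0.1 ms).
#' Spikes are registered at step boundaries; a neuron crossing its spike
#' cutoff is reset and held for its refractory period.  External spike
#' events target the instance's registered external sources (feedback or
#' warm-up inputs) and are delivered through the corresponding realized
#' synapses.
#'
#' @param instance a `substrate_instance`.
#' @param duration simulation duration (ms).
#' @param external_spikes optional data frame with columns `source`
#'   (external source name or id) and `time_ms` (< duration).
#' @param record_membrane optional integer vector of neuron ids whose
#'   membrane traces are recorded every step.
#' @param dt integration step (ms).
#' @return an object of class `spike_sim`: list with `spikes` (data frame
#'   `neuron_id`, `time_ms`, time-sorted), optional `membrane` (data frame
#'   `time_ms`, `neuron_id`, `v_mV`), `duration`, `dt`.
#' @export
simulate_substrate <- function(instance, duration, external_spikes = NULL,
                               record_membrane = NULL, dt = 0.1) {
  stopifnot(inherits(instance, "substrate_instance"), duration > 0, dt > 0)
  n <- nrow(instance$neurons)
  n_ext <- if (is.null(instance$ext_sources)) 0L else nrow(instance$ext_sources)

  ext_pre <- integer(0); ext_time <- numeric(0)
  if (!is.null(external_spikes) && nrow(external_spikes) > 0) {
    src <- external_spikes$source
    if (is.character(src)) {
      idx <- match(src, instance$ext_sources$name)
      if (anyNA(idx)) stop("unknown external source name")
      src <- instance$ext_sources$id[idx]
    }
    if (any(src <= n) || any(src > n + n_ext)) stop("external source id out of range")
    if (any(external_spikes$time_ms >= duration) || any(external_spikes$time_ms < 0))
      stop("external spike times must lie in [0, duration)")
    o <- order(external_spikes$time_ms)
    ext_pre <- as.integer(src[o]); ext_time <- as.numeric(external_spikes$time_ms[o])
  }

  nrn <- instance$neurons
  nrn_list <- list(rest_potential = nrn$rest_potential, exp_threshold = nrn$exp_threshold,
                   slope_factor = nrn$slope_factor, spike_cutoff = nrn$spike_cutoff,
                   reset_potential = nrn$reset_potential, refractory = nrn$refractory,
                   membrane_tau = nrn$membrane_tau, rm = 1000 / nrn$leak_conductance,
                   adapt_a = nrn$adapt_a, adapt_b = nrn$adapt_b,
                   adapt_tau = ifelse(nrn$adapt_a == 0 & nrn$adapt_b == 0, 0, nrn$adapt_tau),
                   dc = nrn$dc)
  w_eff <- effective_weights(instance)
  keep <- which(w_eff != 0)
  syn_list <- list(pre = as.integer(instance$synapses$pre[keep]),
                   post = as.integer(instance$synapses$post[keep]),
                   w_eff = w_eff[keep], tau = instance$synapses$tau[keep])

  rec <- if (is.null(record_membrane)) integer(0) else as.integer(record_membrane)
  res <- .sim_core(nrn_list, syn_list, ext_pre, ext_time, duration, dt, rec,
                   as.integer(n + n_ext))

  out <- list(spikes = data.frame(neuron_id = res$neuron_id, time_ms = res$time_ms),
              duration = duration, dt = dt)
  if (length(rec)) {
    tgrid <- seq(0, by = dt, length.out = nrow(res$vrec))
    out$membrane <- data.frame(
      time_ms = rep(tgrid, times = length(rec)),
      neuron_id = rep(rec, each = length(tgrid)),
      v_mV = as.vector(res$vrec))
  }
  structure(out, class = "spike_sim")
}

#' @export
print.spike_sim <- function(x, ...) {
  cat(sprintf("spike_sim: %d spikes over %.0f ms (dt = %g ms)\n",
              nrow(x$spikes), x$duration, x$dt))
  invisible(x)
}

#' Read / write spike streams as CSV
#'
#' Spike streams are exchanged as CSV with header `neuron_id,time_ms`,
#' membrane traces as `time_ms,neuron_id,v_mV`.
#'
#' @param spikes data frame `neuron_id`, `time_ms`.
#' @param path file path.
#' @return `read_spikes` returns the data frame, time-sorted.
#' @export
write_spikes <- function(spikes, path) {
  write.csv(spikes[c("neuron_id", "time_ms")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  x <- read.csv(path)
  stopifnot(all(c("neuron_id", "time_ms") %in% names(x)))
  x[order(x$time_ms), c("neuron_id", "time_ms")]
}

#' Save / load a network configuration (topology + mismatch) as JSON
#'
#' The configuration round-trips: `read_network_config(write_network_config(x))`
#' reproduces the same topology and mismatch specification.
#'
#' @param topology a `network_topology`.
#' @param mismatch a [mismatch_spec()].
#' @param path file path.
#' @export
write_network_config <- function(topology, mismatch, path) {
  obj <- list(populations = topology$populations,
              neuron_nominals = lapply(topology$neuron_nominals, unclass),
              dc = as.list(topology$dc),
              classes = topology$classes,
              ext_sources = topology$ext_sources,
              ring_order = topology$ring_order,
              mismatch = unclass(mismatch))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_config
#' @return `read_network_config` returns `list(topology, mismatch)`.
#' @export
read_network_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- structure(list(
    populations = as.data.frame(obj$populations),
    neuron_nominals = lapply(obj$neuron_nominals, function(p)
      structure(p, class = "neuron_params")),
    dc = unlist(obj$dc),
    classes = as.data.frame(obj$classes),
    ext_sources = if (!is.null(obj$ext_sources) && length(obj$ext_sources))
      as.data.frame(obj$ext_sources) else NULL,
    ring_order = obj$ring_order), class = "network_topology")
  mm <- do.call(mismatch_spec, obj$mismatch)
  list(topology = topo, mismatch = mm)
}
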