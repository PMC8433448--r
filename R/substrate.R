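## Substrate: AdExp neuron / exponential-current synapse parameter types,
## the device-mismatch sampler, and the closed-form firing-period oracle.
##
## Units used throughout the package: time ms, voltage mV, current nA,
## conductance nS, capacitance pF.  With these, capacitance / conductance
## is already in ms and 1000 / leak_conductance is the membrane resistance
## in mV per nA.

#' AdExp neuron parameter set
#'
#' Nominal parameters of one adaptive exponential integrate-and-fire
#' neuron.  The membrane time constant is derived as
#' `capacitance / leak_conductance` (pF / nS = ms).  Adaptation is
#' disabled by default (`adapt_a = adapt_b = 0`), mirroring a pacemaker
#' configuration in which spike-frequency adaptation is switched off.
#'
#' @param capacitance membrane capacitance (pF).
#' @param leak_conductance leak conductance (nS).
#' @param rest_potential resting / leak reversal potential (mV).
#' @param exp_threshold soft spike-initiation threshold `V_T` (mV).
#' @param slope_factor exponential slope factor `Delta_T` (mV), > 0.
#' @param spike_cutoff numerical spike cutoff (mV); crossing it registers a
#'   spike.
#' @param reset_potential post-spike reset potential (mV).
#' @param refractory absolute refractory period (ms).
#' @param adapt_a subthreshold adaptation conductance (nS); 0 disables.
#' @param adapt_b spike-triggered adaptation increment (nA); 0 disables.
#' @param adapt_tau adaptation time constant (ms).
#' @return an object of class `neuron_params` (a named list with the
#'   derived `membrane_tau` in ms).
#' @export
neuron_params <- function(capacitance = 1000, leak_conductance = 20,
                          rest_potential = -70, exp_threshold = -50,
                          slope_factor = 2, spike_cutoff = -30,
                          reset_potential = -70, refractory = 3,
                          adapt_a = 0, adapt_b = 0, adapt_tau = 100) {
  stopifnot(capacitance > 0, leak_conductance > 0, slope_factor > 0,
            refractory >= 0, adapt_tau > 0, adapt_a >= 0, adapt_b >= 0,
            spike_cutoff > reset_potential)
  p <- list(capacitance = capacitance, leak_conductance = leak_conductance,
            rest_potential = rest_potential, exp_threshold = exp_threshold,
            slope_factor = slope_factor, spike_cutoff = spike_cutoff,
            reset_potential = reset_potential, refractory = refractory,
            membrane_tau = capacitance / leak_conductance,
            adapt_a = adapt_a, adapt_b = adapt_b, adapt_tau = adapt_tau)
  structure(p, class = "neuron_params")
}

#' Exponential current synapse parameter set
#'
#' @param sign `"excitatory"` or `"inhibitory"`; fixed at construction.
#' @param weight post-synaptic current jump per presynaptic spike (nA, >= 0).
#' @param tau synaptic current decay time constant (ms, > 0).
#' @param gain dimensionless multiplier on the weight.
#' @return an object of class `synapse_params`.
#' @export
synapse_params <- function(sign = c("excitatory", "inhibitory"),
                           weight, tau = 30, gain = 1) {
  sign <- match.arg(sign)
  stopifnot(weight >= 0, tau > 0, gain > 0)
  structure(list(sign = sign, weight = weight, tau = tau, gain = gain),
            class = "synapse_params")
}

#' Device-mismatch specification
#'
#' Coefficients of variation with which per-element parameters deviate
#' from their class nominals, emulating fabrication mismatch of analog
#' neuron and synapse circuits.  Synaptic time constants of classes at the
#' calibration nominal (`synapse_tau_nominal`, default 30 ms) are drawn
#' with absolute standard deviation `synapse_tau_sd` (default 4 ms,
#' i.e. the measured 30 +/- 4 ms core calibration); other classes use
#' `synapse_tau_cv`.
#'
#' @param neuron_tau_cv CV of membrane time constants (default 0.15, the
#'   midpoint of the reported 13--18\% range).
#' @param synapse_tau_cv CV of synaptic time constants for classes away
#'   from the calibration nominal (default 0.085, midpoint of 7--10\%).
#' @param weight_cv CV of synaptic weights (default 0.22, midpoint of
#'   14--30\%).
#' @param synapse_tau_nominal calibration nominal for synaptic tau (ms).
#' @param synapse_tau_sd absolute sd at the calibration nominal (ms).
#' @param seed integer seed controlling all mismatch draws.
#' @return an object of class `mismatch_spec`.
#' @export
mismatch_spec <- function(neuron_tau_cv = 0.15, synapse_tau_cv = 0.085,
                          weight_cv = 0.22, synapse_tau_nominal = 30,
                          synapse_tau_sd = 4, seed = 1L) {
  stopifnot(neuron_tau_cv >= 0, synapse_tau_cv >= 0, weight_cv >= 0,
            synapse_tau_nominal > 0, synapse_tau_sd >= 0)
  structure(list(neuron_tau_cv = neuron_tau_cv,
                 synapse_tau_cv = synapse_tau_cv, weight_cv = weight_cv,
                 synapse_tau_nominal = synapse_tau_nominal,
                 synapse_tau_sd = synapse_tau_sd, seed = as.integer(seed)),
            class = "mismatch_spec")
}

## Truncated-Gaussian draw: resample non-positive values.  Warns when more
## than 1% of draws needed re-truncation (CV too large for a positive
## physical quantity).
truncated_gaussian <- function(n, mean, sd, what = "parameter") {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  n_resampled <- 0L
  while (length(bad) > 0) {
    n_resampled <- n_resampled + length(bad)
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x <= 0)
  }
  if (n_resampled > 0.01 * n)
    warning(sprintf("mismatch sampling of %s: %d/%d draws re-truncated (CV too large?)",
                    what, n_resampled, n))
  x
}

#' Sample a concrete substrate instance from nominal parameters
#'
#' Realizes per-neuron and per-synapse parameters by drawing each from a
#' truncated Gaussian centered on its class nominal with the class CV from
#' the mismatch specification.  Membrane time constants are perturbed via
#' the capacitance (the leak conductance, and hence input resistance, is
#' shared per core in the emulated device).  The same seed always yields
#' the identical instance.
#'
#' @param topology a network topology as built by `network_topology` (or
#'   by the higher-level [build_oscillator()] / [build_coupled_network()]).
#' @param mismatch a [mismatch_spec()].
#' @param seed optional integer overriding `mismatch$seed`.
#' @return an object of class `substrate_instance`: a list with data frames
#'   `neurons` (realized per-neuron parameters), `synapses` (realized
#'   per-synapse parameters incl. the mismatch multipliers), `populations`,
#'   `ext_sources`, the class nominal weight table `class_weights`, and the
#'   provenance fields `topology`, `mismatch`, `seed`.
#' @export
sample_substrate <- function(topology, mismatch = mismatch_spec(), seed = NULL) {
  stopifnot(inherits(topology, "network_topology"), inherits(mismatch, "mismatch_spec"))
  if (nrow(topology$populations) == 0) stop("topology has no populations")
  seed <- as.integer(if (is.null(seed)) mismatch$seed else seed)

  pops <- topology$populations
  n_total <- sum(pops$n)
  ## assemble per-neuron nominal table
  rows <- vector("list", nrow(pops))
  id0 <- 0L
  for (i in seq_len(nrow(pops))) {
    np <- topology$neuron_nominals[[pops$name[i]]]
    if (any(unlist(np[c("capacitance", "leak_conductance", "slope_factor", "adapt_tau")]) <= 0))
      stop("non-positive nominal neuron parameter in population ", pops$name[i])
    rows[[i]] <- data.frame(
      id = id0 + seq_len(pops$n[i]), population = pops$name[i],
      capacitance = np$capacitance, leak_conductance = np$leak_conductance,
      rest_potential = np$rest_potential, exp_threshold = np$exp_threshold,
      slope_factor = np$slope_factor, spike_cutoff = np$spike_cutoff,
      reset_potential = np$reset_potential, refractory = np$refractory,
      adapt_a = np$adapt_a, adapt_b = np$adapt_b, adapt_tau = np$adapt_tau,
      dc = topology$dc[[pops$name[i]]], stringsAsFactors = FALSE)
    id0 <- id0 + pops$n[i]
  }
  neurons <- do.call(rbind, rows)

  ## expand all-to-all synapse classes into individual synapses
  pop_ids <- split(neurons$id, neurons$population)
  cls <- topology$classes
  if (any(cls$weight < 0) || any(cls$tau <= 0))
    stop("non-positive nominal synapse parameter")
  syn_rows <- vector("list", nrow(cls))
  for (i in seq_len(nrow(cls))) {
    pre <- pop_ids[[cls$pre_pop[i]]]
    post <- pop_ids[[cls$post_pop[i]]]
    gr <- expand.grid(pre = pre, post = post)
    if (cls$pre_pop[i] == cls$post_pop[i]) gr <- gr[gr$pre != gr$post, , drop = FALSE]
    if (nrow(gr) == 0) next
    syn_rows[[i]] <- data.frame(class = cls$class[i], pre = gr$pre, post = gr$post,
                                sign = cls$sign[i], tau_nominal = cls$tau[i],
                                gain = cls$gain[i], stringsAsFactors = FALSE)
  }
  ## external sources appended after real neurons
  ext <- topology$ext_sources
  ext_ids <- integer(0)
  if (!is.null(ext) && nrow(ext) > 0) {
    ext_ids <- n_total + seq_len(nrow(ext))
    for (i in seq_len(nrow(ext))) {
      post <- pop_ids[[ext$post_pop[i]]]
      syn_rows[[length(syn_rows) + 1L]] <-
        data.frame(class = ext$class[i], pre = ext_ids[i], post = post,
                   sign = ext$sign[i], tau_nominal = ext$tau[i],
                   gain = ext$gain[i], stringsAsFactors = FALSE)
    }
  }
  synapses <- do.call(rbind, syn_rows)
  rownames(synapses) <- NULL

  ## mismatch draws under a private RNG stream
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  m <- mismatch
  neurons$capacitance <- truncated_gaussian(
    nrow(neurons), neurons$capacitance, m$neuron_tau_cv * neurons$capacitance, "membrane tau")
  neurons$membrane_tau <- neurons$capacitance / neurons$leak_conductance

  ## synaptic tau: absolute 30 +/- 4 calibration at the nominal, relative
  ## CV elsewhere
  at_cal <- abs(synapses$tau_nominal - m$synapse_tau_nominal) < 1e-9
  tau_sd <- ifelse(at_cal, m$synapse_tau_sd, m$synapse_tau_cv * synapses$tau_nominal)
  synapses$tau <- truncated_gaussian(nrow(synapses), synapses$tau_nominal, tau_sd, "synapse tau")
  synapses$w_mult <- truncated_gaussian(nrow(synapses), rep(1, nrow(synapses)),
                                        m$weight_cv, "synapse weight")

  class_weights <- setNames(c(cls$weight, if (length(ext_ids)) ext$weight),
                            c(cls$class, if (length(ext_ids)) ext$class))

  inst <- structure(list(
    neurons = neurons, synapses = synapses, populations = pops,
    ext_sources = if (length(ext_ids)) cbind(ext, id = ext_ids) else ext,
    class_weights = class_weights, topology = topology,
    mismatch = mismatch, seed = seed), class = "substrate_instance")
  inst
}

#' @export
print.substrate_instance <- function(x, ...) {
  cat(sprintf("substrate_instance: %d neurons, %d synapses, %d populations, seed %d\n",
              nrow(x$neurons), nrow(x$synapses), nrow(x$populations), x$seed))
  invisible(x)
}

## realized signed synaptic jumps (nA): class nominal weight x frozen
## mismatch multiplier x gain, signed
effective_weights <- function(instance) {
  w_nom <- instance$class_weights[instance$synapses$class]
  sgn <- ifelse(instance$synapses$sign == "inhibitory", -1, 1)
  unname(w_nom * instance$synapses$w_mult * instance$synapses$gain * sgn)
}

#' Set the nominal weight of a synapse class
#'
#' The per-synapse mismatch multipliers are frozen at sampling time, so
#' rescaling a class weight preserves the realized heterogeneity pattern.
#' This (together with [set_dc()]) is the tunable handle of an otherwise
#' immutable instance.
#'
#' @param instance a `substrate_instance`.
#' @param class synapse class name(s) (e.g. `"b.RA"`, `"d.RA-LA"`).
#' @param weight new nominal weight(s) (nA, >= 0), recycled.
#' @return the modified instance.
#' @export
set_class_weight <- function(instance, class, weight) {
  stopifnot(all(class %in% names(instance$class_weights)), all(weight >= 0))
  instance$class_weights[class] <- weight
  instance
}

#' Set the constant current input of an excitatory population
#'
#' @param instance a `substrate_instance`.
#' @param population population name(s).
#' @param dc new DC input(s) (nA), recycled.
#' @return the modified instance.
#' @export
set_dc <- function(instance, population, dc) {
  stopifnot(all(population %in% instance$populations$name))
  for (i in seq_along(population))
    instance$neurons$dc[instance$neurons$population == population[i]] <-
      rep(dc, length.out = length(population))[i]
  instance
}

#' Closed-form constant-input firing period (LIF limit)
#'
#' Independent oracle for the inter-spike interval of an isolated leaky
#' integrate-and-fire neuron under constant current, valid when the
#' exponential slope factor is negligible:
#' `T = refractory + tau_m * log((V_inf - V_reset) / (V_inf - V_cut))`
#' with `V_inf = E_L + R * I`.
#'
#' @param params a [neuron_params()].
#' @param dc constant input current (nA).
#' @return period in ms, or `Inf` for subthreshold input.
#' @export
firing_period_oracle <- function(params, dc) {
  stopifnot(inherits(params, "neuron_params"))
  rm_ <- 1000 / params$leak_conductance
  vinf <- params$rest_potential + rm_ * dc
  if (vinf <= params$spike_cutoff) return(Inf)
  params$refractory + params$membrane_tau *
    log((vinf - params$reset_potential) / (vinf - params$spike_cutoff))
}
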