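## Network construction: the E/I oscillator building block and the ring of
## three coupled oscillators with external feedback inputs.
##
## Synapse class naming: "a.RA" (E->E self-excitation of oscillator RA),
## "b.RA" (E->I), "c.RA" (I->E, slow inhibition), "d.RA-LA" (E->E ring
## coupling), "e.RA-LA" (I->I ring coupling), "fb.RA" (external inhibitory
## feedback onto E), "warm.RA" (warm-up stagger input onto E).

#' Specification of a single E/I neuronal oscillator
#'
#' An oscillator is an excitatory population E (default n = 16) and an
#' inhibitory population I (default n = 4), reciprocally connected
#' all-to-all: self-excitation `a` (E->E), drive `b` (E->I) and slow
#' inhibition `c` (I->E).  Every E neuron receives a constant current
#' `dc_input`.  The interplay of the recurrent burst (a), the inhibitory
#' reset (c) and the slow recovery from inhibition produces the population
#' oscillation; `dc_input` is the coarse and `b` the fine frequency knob.
#'
#' @param name oscillator name (e.g. `"RA"`).
#' @param n_exc,n_inh population sizes (each >= 4; smaller populations are
#'   subject to small-size effects and are rejected).
#' @param w_self_exc weight `a` (nA).
#' @param w_exc_to_inh weight `b` (nA).
#' @param w_inh_to_exc weight `c` (nA).
#' @param dc_input DC drive of the E population (nA).
#' @param tau_exc excitatory synaptic time constant (ms; `a`, `b`).
#' @param tau_inh slow inhibitory synaptic time constant (ms; `c`).
#' @param exc_params,inh_params [neuron_params()] of the two populations.
#' @return an object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(name, n_exc = 16, n_inh = 4,
                            w_self_exc = 1.0, w_exc_to_inh = 0.10,
                            w_inh_to_exc = 40, dc_input = 0.8,
                            tau_exc = 30, tau_inh = 90,
                            exc_params = neuron_params(),
                            inh_params = neuron_params(capacitance = 1200,
                                                       leak_conductance = 40,
                                                       refractory = 120)) {
  if (n_exc < 4 || n_inh < 4)
    stop("population sizes below 4 are rejected (small-size effects)")
  stopifnot(w_self_exc >= 0, w_exc_to_inh >= 0, w_inh_to_exc >= 0,
            dc_input >= 0, tau_exc > 0, tau_inh > 0)
  structure(list(name = name, n_exc = n_exc, n_inh = n_inh,
                 w_self_exc = w_self_exc, w_exc_to_inh = w_exc_to_inh,
                 w_inh_to_exc = w_inh_to_exc, dc_input = dc_input,
                 tau_exc = tau_exc, tau_inh = tau_inh,
                 exc_params = exc_params, inh_params = inh_params),
            class = "oscillator_spec")
}

#' Specification of a ring of coupled oscillators
#'
#' Oscillators are coupled in the given order by excitatory E->E
#' connections (weights `d`, one per directed ring edge) and inhibitory
#' I->I connections (weights `e`).  Ring edges follow the list order, with
#' the last oscillator coupling back to the first.  Feedback-flagged
#' oscillators additionally receive an external inhibitory input source
#' onto their E population (used for respiratory feedback), and every
#' oscillator gets a warm-up stagger source used to break the initial
#' phase symmetry of the deterministic simulation.
#'
#' @param oscillators list of [oscillator_spec()]s in ring order.
#' @param coupling_exc weights `d` per directed ring edge (nA), recycled.
#' @param coupling_inh weights `e` per directed ring edge (nA), recycled.
#' @param feedback_targets logical per oscillator, recycled.
#' @param tau_coupling synaptic tau of the `d` and `e` coupling edges (ms).
#' @param w_feedback weight of the external feedback synapses (nA).
#' @param tau_feedback synaptic tau of feedback and warm-up synapses (ms).
#' @return an object of class `coupled_network_spec`.
#' @export
coupled_network_spec <- function(oscillators,
                                 coupling_exc = 0.002, coupling_inh = 0.1,
                                 feedback_targets = TRUE,
                                 tau_coupling = 120,
                                 w_feedback = 0.05, tau_feedback = 90) {
  if (length(oscillators) < 2) stop("need at least 2 oscillators")
  nm <- vapply(oscillators, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("oscillator names must be unique")
  k <- length(oscillators)
  structure(list(oscillators = oscillators,
                 ring_order = nm,
                 coupling_exc = rep_len(coupling_exc, k),
                 coupling_inh = rep_len(coupling_inh, k),
                 feedback_targets = rep_len(feedback_targets, k),
                 tau_coupling = tau_coupling,
                 w_feedback = w_feedback, tau_feedback = tau_feedback),
            class = "coupled_network_spec")
}

## assemble a network_topology from oscillator specs (+ optional coupling)
network_topology_from_specs <- function(oscillators, net = NULL) {
  pops <- list(); nominals <- list(); dc <- c(); classes <- list(); ext <- list()
  for (os in oscillators) {
    e_name <- paste0(os$name, ".E"); i_name <- paste0(os$name, ".I")
    pops[[length(pops) + 1L]] <- data.frame(
      name = c(e_name, i_name), role = c("exc", "inh"),
      n = c(os$n_exc, os$n_inh), threshold_fraction = c(0.5, 0.25),
      oscillator = os$name, stringsAsFactors = FALSE)
    nominals[[e_name]] <- os$exc_params
    nominals[[i_name]] <- os$inh_params
    dc[e_name] <- os$dc_input; dc[i_name] <- 0
    classes[[length(classes) + 1L]] <- data.frame(
      class = paste0(c("a.", "b.", "c."), os$name),
      pre_pop = c(e_name, e_name, i_name),
      post_pop = c(e_name, i_name, e_name),
      sign = c("excitatory", "excitatory", "inhibitory"),
      weight = c(os$w_self_exc, os$w_exc_to_inh, os$w_inh_to_exc),
      tau = c(os$tau_exc, os$tau_exc, os$tau_inh),
      gain = 1, stringsAsFactors = FALSE)
  }
  ring <- vapply(oscillators, `[[`, "", "name")
  if (!is.null(net)) {
    k <- length(ring)
    for (i in seq_len(k)) {
      j <- i %% k + 1L
      edge <- paste0(ring[i], "-", ring[j])
      classes[[length(classes) + 1L]] <- data.frame(
        class = paste0(c("d.", "e."), edge),
        pre_pop = paste0(ring[i], c(".E", ".I")),
        post_pop = paste0(ring[j], c(".E", ".I")),
        sign = c("excitatory", "inhibitory"),
        weight = c(net$coupling_exc[i], net$coupling_inh[i]),
        tau = net$tau_coupling, gain = 1, stringsAsFactors = FALSE)
    }
  }
  w_fb <- if (is.null(net)) 0.05 else net$w_feedback
  tau_fb <- if (is.null(net)) 90 else net$tau_feedback
  fb_flag <- if (is.null(net)) rep(TRUE, length(ring)) else net$feedback_targets
  for (i in seq_along(ring)) {
    if (fb_flag[i])
      ext[[length(ext) + 1L]] <- data.frame(
        name = paste0("fb.", ring[i]), class = paste0("fb.", ring[i]),
        post_pop = paste0(ring[i], ".E"), sign = "inhibitory",
        weight = w_fb, tau = tau_fb, gain = 1, stringsAsFactors = FALSE)
    ext[[length(ext) + 1L]] <- data.frame(
      name = paste0("warm.", ring[i]), class = paste0("warm.", ring[i]),
      post_pop = paste0(ring[i], ".E"), sign = "inhibitory",
      weight = 0, tau = tau_fb, gain = 1, stringsAsFactors = FALSE)
  }
  structure(list(populations = do.call(rbind, pops),
                 neuron_nominals = nominals, dc = dc,
                 classes = do.call(rbind, classes),
                 ext_sources = do.call(rbind, ext),
                 ring_order = ring),
            class = "network_topology")
}

#' Build a single oscillator on a mismatched substrate
#'
#' @param spec an [oscillator_spec()].
#' @param mismatch a [mismatch_spec()].
#' @param seed integer seed (defaults to `mismatch$seed`).
#' @return a `substrate_instance` containing one E/I oscillator with its
#'   feedback and warm-up sources.
#' @export
build_oscillator <- function(spec, mismatch = mismatch_spec(), seed = NULL) {
  stopifnot(inherits(spec, "oscillator_spec"))
  topo <- network_topology_from_specs(list(spec))
  sample_substrate(topo, mismatch, seed)
}

#' Build a ring of coupled oscillators on a mismatched substrate
#'
#' @param spec a [coupled_network_spec()].
#' @param mismatch a [mismatch_spec()].
#' @param seed integer seed (defaults to `mismatch$seed`).
#' @return a `substrate_instance` with all within- and between-oscillator
#'   synapse classes and the external feedback / warm-up sources.
#' @export
build_coupled_network <- function(spec, mismatch = mismatch_spec(), seed = NULL) {
  stopifnot(inherits(spec, "coupled_network_spec"))
  if (is.null(seed) && is.null(mismatch$seed)) stop("mismatch seed required")
  topo <- network_topology_from_specs(spec$oscillators, spec)
  inst <- sample_substrate(topo, mismatch, seed)
  inst$network_spec <- spec
  inst
}

#' Zero the coupling weights of a network instance
#'
#' Returns a copy of the instance with all ring coupling classes (`d.*`,
#' `e.*`) set to zero, so that each oscillator runs in isolation.  Used by
#' the per-oscillator tuning and probing stages.
#'
#' @param instance a `substrate_instance`.
#' @return the modified copy.
#' @export
decouple_network <- function(instance) {
  cls <- names(instance$class_weights)
  sel <- grepl("^[de]\\.", cls)
  instance$class_weights[sel] <- 0
  instance
}

## Extract a single oscillator (its two populations, within-oscillator
## synapses and external sources) as a standalone instance with reindexed
## neuron ids.  Used to speed up isolated-oscillator measurements.
subset_oscillator <- function(instance, oscillator) {
  pops <- instance$populations[instance$populations$oscillator == oscillator, ]
  keep_n <- instance$neurons$population %in% pops$name
  neurons <- instance$neurons[keep_n, ]
  id_map <- setNames(seq_len(nrow(neurons)), neurons$id)
  neurons$id <- seq_len(nrow(neurons))

  ext <- instance$ext_sources
  keep_e <- if (is.null(ext)) logical(0) else ext$post_pop %in% pops$name
  old_ext_ids <- if (any(keep_e)) ext$id[keep_e] else integer(0)
  new_ext_ids <- nrow(neurons) + seq_along(old_ext_ids)
  id_map[as.character(old_ext_ids)] <- new_ext_ids

  syn <- instance$synapses
  keep_s <- (as.character(syn$pre) %in% names(id_map)) &
    (as.character(syn$post) %in% names(id_map))
  syn <- syn[keep_s, ]
  syn$pre <- unname(id_map[as.character(syn$pre)])
  syn$post <- unname(id_map[as.character(syn$post)])

  out <- instance
  out$neurons <- neurons
  out$populations <- pops
  out$synapses <- syn
  if (any(keep_e)) {
    out$ext_sources <- ext[keep_e, ]
    out$ext_sources$id <- new_ext_ids
  } else out$ext_sources <- NULL
  out$class_weights <- instance$class_weights
  out$topology$ring_order <- oscillator
  out
}

## neuron ids of one population
population_ids <- function(instance, population) {
  instance$neurons$id[instance$neurons$population == population]
}

## E-population name of an oscillator
exc_population <- function(oscillator) paste0(oscillator, ".E")

## ring edges as data frame (from, to, edge label)
ring_edges <- function(ring_order) {
  k <- length(ring_order)
  to <- ring_order[c(seq_len(k)[-1], 1L)]
  data.frame(from = ring_order, to = to,
             edge = paste0(ring_order, "-", to), stringsAsFactors = FALSE)
}

#' Warm-up stagger spikes for a coupled network run
#'
#' The deterministic simulation starts all oscillators from identical
#' initial conditions; a single inhibitory spike per oscillator at t = 1 ms
#' (with a per-oscillator weight derived from the requested stagger delay
#' and the current DC margin) breaks the symmetry and starts the ring near
#' the requested phase arrangement.  On noisy hardware this role is played
#' by the substrate noise itself.
#'
#' @param instance a `substrate_instance`.
#' @param stagger_ms numeric vector of initial delays per oscillator (ms),
#'   in ring order; 0 means no pulse.
#' @return a list with the updated instance (warm-up class weights set) and
#'   the external spike data frame to pass to [simulate_substrate()].
#' @export
warmup_plan <- function(instance, stagger_ms) {
  ring <- instance$topology$ring_order
  stagger_ms <- rep_len(stagger_ms, length(ring))
  ext <- NULL
  for (i in seq_along(ring)) {
    cl <- paste0("warm.", ring[i])
    if (!cl %in% names(instance$class_weights)) next
    if (stagger_ms[i] <= 0) { instance$class_weights[cl] <- 0; next }
    epop <- exc_population(ring[i])
    np <- instance$topology$neuron_nominals[[epop]]
    dc <- instance$neurons$dc[match(population_ids(instance, epop)[1], instance$neurons$id)]
    rheo <- (np$exp_threshold - np$rest_potential) * np$leak_conductance / 1000
    margin <- max(dc - rheo, 0.05)
    tau_fb <- instance$ext_sources$tau[match(cl, instance$ext_sources$class)]
    ## weight such that the pulse delays the first burst by ~stagger_ms
    instance$class_weights[cl] <- margin * expm1(stagger_ms[i] / tau_fb)
    ext <- rbind(ext, data.frame(source = cl, time_ms = 1))
  }
  list(instance = instance, external_spikes = ext)
}
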