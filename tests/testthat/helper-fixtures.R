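## Shared fixtures: small substrate builders and cached expensive objects.

## never terminate the run early on accumulated failures
options(testthat.progress.max_fails = 1000)

## single isolated neuron as a substrate instance (no synapses beyond a
## dummy self-free topology); used for LIF-limit and membrane tests
single_neuron_instance <- function(params = neuron_params(), dc = 0,
                                   mismatch = mismatch_spec(neuron_tau_cv = 0,
                                                            synapse_tau_cv = 0,
                                                            weight_cv = 0,
                                                            synapse_tau_sd = 0,
                                                            seed = 1)) {
  topo <- structure(list(
    populations = data.frame(name = "X", role = "exc", n = 1,
                             threshold_fraction = 0.5, oscillator = "X",
                             stringsAsFactors = FALSE),
    neuron_nominals = list(X = params),
    dc = c(X = dc),
    classes = data.frame(class = "a.X", pre_pop = "X", post_pop = "X",
                         sign = "excitatory", weight = 0, tau = 30, gain = 1,
                         stringsAsFactors = FALSE),
    ext_sources = data.frame(name = "in.X", class = "in.X", post_pop = "X",
                             sign = "excitatory", weight = 0.1, tau = 30,
                             gain = 1, stringsAsFactors = FALSE),
    ring_order = "X"), class = "network_topology")
  sample_substrate(topo, mismatch)
}

## LIF-limit parameters: negligible exponential term (soft threshold moved
## to the cutoff)
lif_params <- function(refractory = 2) {
  neuron_params(exp_threshold = -30, slope_factor = 1e-4,
                spike_cutoff = -30, refractory = refractory)
}

## mismatch with everything switched off (nominal substrate)
no_mismatch <- function(seed = 1) {
  mismatch_spec(neuron_tau_cv = 0, synapse_tau_cv = 0, weight_cv = 0,
                synapse_tau_sd = 0, seed = seed)
}

default_ring_spec <- function() {
  coupled_network_spec(list(oscillator_spec("RA"), oscillator_spec("LA"),
                            oscillator_spec("V")))
}

## cache expensive shared objects across test files (single process run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}
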