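## Substrate: mismatch sampler statistics, determinism, the closed-form
## firing-period oracle, and core simulation properties.

test_that("mismatch sampler reproduces the 30 +/- 4 ms core calibration over 256 synapses", {
  spec <- oscillator_spec("X")  # 256 synapses at the default 30 ms calibration: 240 a + ... use a dedicated topology
  topo <- structure(list(
    populations = data.frame(name = c("A", "B"), role = c("exc", "exc"),
                             n = c(16, 16), threshold_fraction = 0.5,
                             oscillator = "X", stringsAsFactors = FALSE),
    neuron_nominals = list(A = neuron_params(), B = neuron_params()),
    dc = c(A = 0, B = 0),
    classes = data.frame(class = "w", pre_pop = "A", post_pop = "B",
                         sign = "excitatory", weight = 1, tau = 30, gain = 1,
                         stringsAsFactors = FALSE),
    ext_sources = NULL, ring_order = c("X")), class = "network_topology")
  inst <- sample_substrate(topo, mismatch_spec(seed = 7))
  expect_equal(nrow(inst$synapses), 256)
  expect_equal(mean(inst$synapses$tau), 30, tolerance = 0.03)
  expect_equal(sd(inst$synapses$tau), 4, tolerance = 0.15)
})

test_that("sample CV of each mismatch class is close to the configured CV", {
  ## 256 draws per class; within 30% relative error of the target CV
  inst <- cached("ring_seed11", build_coupled_network(default_ring_spec(),
                                                      mismatch_spec(seed = 11)))
  ## per-neuron capacitance relative to its population nominal
  nominal <- ifelse(grepl("\\.E$", inst$neurons$population), 1000, 1200)
  rel <- inst$neurons$capacitance / nominal
  expect_lt(abs(sd(rel) / mean(rel) - 0.15) / 0.15, 0.30)
  wm <- inst$synapses$w_mult
  expect_lt(abs(sd(wm) / mean(wm) - 0.22) / 0.22, 0.30)
})

test_that("zero CVs give exactly nominal parameters; same seed gives identical instances", {
  spec <- default_ring_spec()
  inst0 <- build_coupled_network(spec, no_mismatch())
  expect_true(all(inst0$synapses$w_mult == 1))
  expect_true(all(inst0$neurons$membrane_tau[inst0$neurons$population == "RA.E"] == 50))
  a <- build_coupled_network(spec, mismatch_spec(seed = 5))
  b <- build_coupled_network(spec, mismatch_spec(seed = 5))
  expect_identical(a$neurons, b$neurons)
  expect_identical(a$synapses, b$synapses)
  c2 <- build_coupled_network(spec, mismatch_spec(seed = 6))
  expect_false(identical(a$synapses$tau, c2$synapses$tau))
})

test_that("firing period oracle: subthreshold sentinel, analytic value, monotonicity", {
  p <- lif_params(refractory = 0)
  rheo <- (p$spike_cutoff - p$rest_potential) * p$leak_conductance / 1000
  expect_identical(firing_period_oracle(p, rheo * 0.9), Inf)
  ## V_inf - EL = 2 (Vcut - EL) at dc = 2 rheobase -> T = tau ln 2
  expect_equal(firing_period_oracle(p, 2 * rheo), p$membrane_tau * log(2),
               tolerance = 1e-12)
  periods <- vapply(seq(1.2, 4, by = 0.4) * rheo,
                    function(i) firing_period_oracle(p, i), 0)
  expect_true(all(diff(periods) < 0))
})

test_that("simulated neuron matches the LIF closed form within 1% over a DC grid", {
  p <- lif_params(refractory = 2)
  rheo <- (p$spike_cutoff - p$rest_potential) * p$leak_conductance / 1000
  for (mult in seq(1.3, 4.9, length.out = 10)) {
    dc <- mult * rheo
    inst <- single_neuron_instance(p, dc = dc)
    sim <- simulate_substrate(inst, 3000)
    isi <- diff(sim$spikes$time_ms)
    expect_gt(length(isi), 5)
    expect_equal(mean(isi), firing_period_oracle(p, dc), tolerance = 0.01)
  }
})

test_that("no drive produces no spikes; refractory period is respected", {
  inst <- single_neuron_instance(lif_params(), dc = 0)
  expect_equal(nrow(simulate_substrate(inst, 1000)$spikes), 0)
  inst2 <- single_neuron_instance(lif_params(refractory = 7), dc = 5)
  sim <- simulate_substrate(inst2, 2000)
  expect_true(all(diff(sim$spikes$time_ms) >= 7))
})

test_that("a small excitatory input depolarizes without spiking; drive is linear", {
  p <- neuron_params()
  inst <- single_neuron_instance(p, dc = 0)
  spk <- data.frame(source = "in.X", time_ms = 100)
  sim1 <- simulate_substrate(inst, 400, external_spikes = spk,
                             record_membrane = 1)
  expect_equal(nrow(sim1$spikes), 0)
  v1 <- sim1$membrane$v_mV
  expect_gt(max(v1), p$rest_potential + 0.01)   # depolarized
  expect_lt(max(v1), p$exp_threshold)           # subthreshold
  expect_equal(v1[length(v1)], p$rest_potential, tolerance = 0.2)  # relaxed back
  ## doubling the input weight doubles the peak deflection (small-signal)
  inst2 <- set_class_weight(inst, "in.X", 0.2)
  sim2 <- simulate_substrate(inst2, 400, external_spikes = spk,
                             record_membrane = 1)
  d1 <- max(v1) - p$rest_potential
  d2 <- max(sim2$membrane$v_mV) - p$rest_potential
  expect_equal(d2 / d1, 2, tolerance = 0.05)
})

test_that("simulation is deterministic and spike stream is time-sorted", {
  inst <- cached("osc_seed3", build_oscillator(oscillator_spec("X"),
                                               mismatch_spec(seed = 3)))
  s1 <- simulate_substrate(inst, 3000)
  s2 <- simulate_substrate(inst, 3000)
  expect_identical(s1$spikes, s2$spikes)
  expect_true(!is.unsorted(s1$spikes$time_ms))
})

test_that("spike stream CSV and network config JSON round-trip", {
  tmp <- tempfile(fileext = ".csv")
  spk <- data.frame(neuron_id = c(2L, 1L, 3L), time_ms = c(5, 1.5, 20))
  write_spikes(spk, tmp)
  back <- read_spikes(tmp)
  expect_equal(back$time_ms, sort(spk$time_ms))

  spec <- default_ring_spec()
  topo <- cpgpace:::network_topology_from_specs(spec$oscillators, spec)
  mm <- mismatch_spec(seed = 9)
  tmp2 <- tempfile(fileext = ".json")
  write_network_config(topo, mm, tmp2)
  rt <- read_network_config(tmp2)
  expect_equal(rt$mismatch, mm)
  i1 <- sample_substrate(topo, mm)
  i2 <- sample_substrate(rt$topology, rt$mismatch)
  expect_equal(i1$synapses$tau, i2$synapses$tau)
})
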