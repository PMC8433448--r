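## Network construction: synapse counting, degenerate-weight behaviour,
## construction purity and the decoupled limit.

test_that("single oscillator has the all-to-all synapse counts", {
  inst <- build_oscillator(oscillator_spec("X"), mismatch_spec(seed = 2))
  syn <- inst$synapses
  expect_equal(sum(syn$class == "a.X"), 16 * 15)   # E->E without self-loops
  expect_equal(sum(syn$class == "b.X"), 16 * 4)
  expect_equal(sum(syn$class == "c.X"), 4 * 16)
  expect_true(all(syn$pre %in% c(inst$neurons$id, inst$ext_sources$id)))
  expect_true(all(syn$post %in% inst$neurons$id))
})

test_that("ring of three adds 3 x (256 + 16) coupling synapses", {
  inst <- cached("ring_seed11", build_coupled_network(default_ring_spec(),
                                                      mismatch_spec(seed = 11)))
  n_d <- sum(grepl("^d\\.", inst$synapses$class))
  n_e <- sum(grepl("^e\\.", inst$synapses$class))
  expect_equal(n_d, 3 * 256)
  expect_equal(n_e, 3 * 16)
  expect_equal(n_d + n_e, 816)
})

test_that("population sizes below 4 are rejected", {
  expect_error(oscillator_spec("X", n_inh = 3), "small-size")
  expect_error(oscillator_spec("X", n_exc = 2), "small-size")
})

test_that("b = 0 silences the inhibitory population; c = 0 gives tonic unreset firing", {
  inst <- cached("osc_seed3", build_oscillator(oscillator_spec("X"),
                                               mismatch_spec(seed = 3)))
  i0 <- set_class_weight(inst, "b.X", 0)
  sim <- simulate_substrate(i0, 4000)
  iids <- population_ids <- inst$neurons$id[inst$neurons$population == "X.I"]
  expect_equal(sum(sim$spikes$neuron_id %in% iids), 0)
  ## without inhibition the E population fires tonically: far more spikes
  ## and no inter-burst silence
  i1 <- set_class_weight(inst, "c.X", 0)
  sim1 <- simulate_substrate(i1, 4000)
  eids <- inst$neurons$id[inst$neurons$population == "X.E"]
  et_tonic <- sort(sim1$spikes$time_ms[sim1$spikes$neuron_id %in% eids])
  sim2 <- simulate_substrate(inst, 4000)
  et_osc <- sort(sim2$spikes$time_ms[sim2$spikes$neuron_id %in% eids])
  expect_gt(length(et_tonic), 3 * length(et_osc))
  expect_lt(max(diff(et_tonic[et_tonic > 1000])), 50)   # never reset
  expect_gt(max(diff(et_osc[et_osc > 1000])), 200)      # inter-burst gaps
})

test_that("construction is pure and the decoupled limit recovers isolated periods", {
  spec <- default_ring_spec()
  a <- build_coupled_network(spec, mismatch_spec(seed = 13))
  b <- build_coupled_network(spec, mismatch_spec(seed = 13))
  expect_identical(a$synapses, b$synapses)
  ## d = e = 0: coupled simulation periods match isolated measurements to 2%
  dec <- decouple_network(a)
  sim <- simulate_substrate(dec, 9000)
  for (o in c("RA", "LA", "V")) {
    ep <- paste0(o, ".E")
    acts <- network_activations(dec, sim, populations = ep)[[ep]]
    acts <- acts[acts >= 2000]
    iso <- measure_period(a, o, window = 6000)
    expect_equal(mean(diff(acts)), iso, tolerance = 0.02)
  }
})

test_that("inhibitory-only coupling keeps neighbours apart (anti-phase) for a range of weights", {
  spec <- default_ring_spec()
  inst <- cached("ring_seed11", build_coupled_network(spec, mismatch_spec(seed = 11)))
  for (dcl in paste0("d.", c("RA-LA", "LA-V", "V-RA")))
    inst <- set_class_weight(inst, dcl, 0)
  for (e0 in c(0.02, 0.1, 0.5)) {
    i2 <- inst
    for (ecl in paste0("e.", c("RA-LA", "LA-V", "V-RA")))
      i2 <- set_class_weight(i2, ecl, e0)
    mc <- measure_coupled(i2, 8000, stagger_ms = c(0, 180, 360))
    expect_false(is.null(mc$metrics))
    ## periodic oscillation persists and neighbours stay phase-separated
    expect_true(all(mc$metrics$periods$cv_pct < 5))
    expect_true(all(mc$metrics$delays$mean > 30))
  }
})

test_that("warm-up plan delays the first burst by roughly the requested stagger", {
  inst <- cached("ring_seed11", build_coupled_network(default_ring_spec(),
                                                      mismatch_spec(seed = 11)))
  dec <- decouple_network(inst)
  wp0 <- warmup_plan(dec, c(0, 0, 0))
  s0 <- simulate_substrate(wp0$instance, 3000)
  wp1 <- warmup_plan(dec, c(0, 200, 400))
  s1 <- simulate_substrate(wp1$instance, 3000, external_spikes = wp1$external_spikes)
  first_burst <- function(sim, inst, pop) {
    a <- network_activations(inst, sim, populations = pop)[[pop]]
    a[1]
  }
  for (k in 2:3) {
    pop <- paste0(c("RA", "LA", "V")[k], ".E")
    shift <- first_burst(s1, inst, pop) - first_burst(s0, inst, pop)
    expect_gt(shift, 50 * (k - 1))   # staggered in the right order
  }
})
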