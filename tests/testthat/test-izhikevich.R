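# Izhikevich dynamics and COBA synapses.

test_that("a neuron at the spike cutoff takes the reset branch", {
  p <- izhikevich_params("RS")
  st <- neuron_state(V = 31, U = 6.2)
  out <- step_izhikevich(st, p, I_syn = 0, dt = 1)
  expect_true(out$spiked)
  expect_equal(out$state$V, -65)
  expect_equal(out$state$U, 6.2 + 8)
})

test_that("the resting fixed point of the RS neuron is preserved", {
  # 0.04 V^2 + 5V + 140 - U = 0 and bV = U at V = -70, U = -14.
  p <- izhikevich_params("RS")
  st <- neuron_state(V = -70, U = -14)
  out <- step_izhikevich(st, p, I_syn = 0, dt = 1)
  expect_false(out$spiked)
  expect_equal(out$state$V, -70)
  expect_equal(out$state$U, -14)
})

test_that("non-finite state or current is rejected", {
  p <- izhikevich_params("RS")
  expect_error(step_izhikevich(neuron_state(V = NaN), p), "non-finite")
  expect_error(step_izhikevich(neuron_state(), p, I_syn = Inf), "non-finite")
  expect_error(step_izhikevich(neuron_state(), p, dt = 0), "dt")
})

test_that("membrane potential never exceeds the 30 mV cutoff after any step", {
  p <- izhikevich_params("RS")
  st <- neuron_state()
  for (i in 1:500) {
    out <- step_izhikevich(st, p, I_syn = 20, dt = 1)
    expect_lte(out$state$V, 30)
    st <- out$state
  }
})

test_that("COBA current is zero with zero conductance and at the NMDA reversal gate", {
  syn <- synapse_params()
  g0 <- receptor_conductances()
  expect_equal(synaptic_current(-65, g0, syn), 0)
  # (V + 80) = 0 annihilates the NMDA magnesium gate
  gN <- receptor_conductances(NMDA = 2.5)
  expect_equal(synaptic_current(-80, gN, syn), 0)
  # AMPA drive of magnitude g*(V - v_rev) = 65, depolarizing
  gA <- receptor_conductances(AMPA = 1)
  expect_equal(synaptic_current(-65, gA, syn), 65)
  # GABAa below its reversal potential hyperpolarizes
  ga <- receptor_conductances(GABAa = 1)
  expect_lt(synaptic_current(-65, ga, syn), 0)
})

test_that("conductances decay exponentially and jump on arrivals", {
  syn <- synapse_params()
  g <- receptor_conductances(AMPA = 1)
  # 5 steps of 1 ms = one AMPA time constant
  for (i in 1:5) g <- update_conductances(g, dt = 1, syn = syn)
  expect_equal(g$AMPA, exp(-1), tolerance = 1e-12)
  # an excitatory arrival increments both AMPA and NMDA by its weight
  g <- update_conductances(receptor_conductances(), exc = 0.7, dt = 1)
  expect_equal(g$AMPA, 0.7)
  expect_equal(g$NMDA, 0.7)
  expect_equal(g$GABAa, 0)
  # an inhibitory arrival increments both GABA receptors
  g <- update_conductances(receptor_conductances(), inh = 0.3, dt = 1)
  expect_equal(g$GABAa, 0.3)
  expect_equal(g$GABAb, 0.3)
  # zero in, zero out
  g <- update_conductances(receptor_conductances(), dt = 1)
  expect_true(all(unlist(g) == 0))
  expect_error(update_conductances(receptor_conductances(), exc = -1), "non-negative")
})

test_that("with no input the population raster is empty, with drive it is not", {
  conn <- population_connectivity(3, izhikevich_params("RS"), n_inputs = 1,
                                  W_in_exc = matrix(0.5, 3, 1))
  out <- simulate_population(conn, NULL, duration = 200)
  expect_s3_class(out, "spike_raster")
  expect_equal(nrow(out), 0)
  # 400 Hz Poisson drive with sufficient weight elicits spikes
  set.seed(99)
  tt <- which(runif(1000) < 0.4) - 1
  drive <- spike_raster(rep(1L, length(tt)), tt, n_neurons = 1, duration = 1000)
  out2 <- simulate_population(conn, drive, duration = 1000)
  expect_gt(nrow(out2), 0)
})

test_that("simulation is deterministic given identical inputs", {
  set.seed(5)
  tt <- sort(runif(300, 0, 500))
  drive <- spike_raster(sample(1:2, 300, TRUE), tt, n_neurons = 2, duration = 500)
  conn <- population_connectivity(4, izhikevich_params("RS"), n_inputs = 2,
                                  W_in_exc = matrix(0.4, 4, 2))
  r1 <- simulate_population(conn, drive, duration = 500)
  r2 <- simulate_population(conn, drive, duration = 500)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("FS neurons outfire RS neurons under identical strong constant drive", {
  # constant drive approximated by a every-step input spike of fixed weight
  drive <- spike_raster(rep(1L, 1000), 0:999, n_neurons = 1, duration = 1000)
  count_for <- function(preset) {
    conn <- population_connectivity(1, izhikevich_params(preset), n_inputs = 1,
                                    W_in_exc = matrix(0.3, 1, 1))
    nrow(simulate_population(conn, drive, duration = 1000))
  }
  expect_gt(count_for("FS"), count_for("RS"))
})


test_that("a 3-neuron hand-wired circuit matches the straight-line reference step by step", {
  set.seed(21)
  n_steps <- 600
  dt <- 1
  # neuron 1 and 2 driven by independent Poisson inputs; neuron 3 gets
  # feedforward drive and inhibition from neurons 1 and 2
  W_in <- rbind(c(0.5, 0), c(0, 0.4), c(0.2, 0.2))
  W_inh <- rbind(c(0, 0, 0), c(0, 0, 0), c(0.3, 0.3, 0))
  drive_bins <- matrix(rbinom(2 * n_steps, 1, 0.25), 2, n_steps)
  params <- izhikevich_params("RS")
  syn <- synapse_params()

  ref <- reference_circuit(W_in, W_inh, drive_bins, n_steps, dt, params, syn)

  hits <- which(drive_bins == 1, arr.ind = TRUE)
  drive <- spike_raster(hits[, 1], (hits[, 2] - 1) * dt, n_neurons = 2,
                        duration = n_steps * dt)
  conn <- population_connectivity(3, params, n_inputs = 2, W_in_exc = W_in,
                                  W_rec_inh = W_inh, syn = syn)
  out <- simulate_population(conn, drive, duration = n_steps * dt, dt = dt)

  ref_r <- ref$spikes
  expect_gt(nrow(out), 0) # the circuit actually fires
  expect_equal(nrow(out), NROW(ref_r))
  o <- order(out$time, out$neuron)
  ro <- order(ref_r[, 2], ref_r[, 1])
  expect_equal(out$neuron[o], ref_r[ro, 1])
  expect_equal(out$time[o], ref_r[ro, 2])
})

test_that("a single RS neuron matches the reference voltage trajectory under tonic drive", {
  # tonic spiking: reference integrator and simulate_population agree on the
  # spike count under sustained input
  n_steps <- 1000
  drive_bins <- matrix(1, 1, n_steps)
  params <- izhikevich_params("RS")
  syn <- synapse_params()
  ref <- reference_circuit(matrix(0.25, 1, 1), NULL, drive_bins, n_steps, 1,
                           params, syn)
  drive <- spike_raster(rep(1L, n_steps), 0:(n_steps - 1), n_neurons = 1,
                        duration = n_steps)
  conn <- population_connectivity(1, params, n_inputs = 1,
                                  W_in_exc = matrix(0.25, 1, 1), syn = syn)
  out <- simulate_population(conn, drive, duration = n_steps)
  expect_gt(nrow(out), 5)
  expect_lte(abs(nrow(out) - NROW(ref$spikes)), 1)
})

test_that("spike rasters round-trip through CSV", {
  r <- spike_raster(c(3L, 1L, 2L), c(0.5, 10, 12.25), n_neurons = 5, duration = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_raster(r, path)
  back <- read_spike_raster(path)
  expect_equal(as.data.frame(back), as.data.frame(r))
  expect_equal(attr(back, "n_neurons"), 5L)
  expect_equal(attr(back, "duration"), 100)
})
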