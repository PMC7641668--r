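# Izhikevich point neurons with conductance-based (COBA) synapses.
#
# The two-variable quadratic model
#   dV/dt = 0.04 V^2 + 5 V + 140 - U + I_syn
#   dU/dt = a (b V - U)
# spikes by reset: when V reaches 30 mV, V := c and U := U + d.
# Synaptic drive comes through four receptor channels (AMPA, NMDA, GABAa,
# GABAb) whose conductances decay exponentially and jump when presynaptic
# spikes arrive.

#' Izhikevich neuron parameters
#'
#' Returns the `(a, b, c, d)` parameter set of the Izhikevich model, either
#' one of the two canonical presets or user-supplied values. Regular-spiking
#' (RS, excitatory) neurons use `a = 0.02, b = 0.2, c = -65, d = 8`;
#' fast-spiking (FS, inhibitory) neurons use `a = 0.1, b = 0.2, c = -65,
#' d = 2`. Each field may also be a per-neuron vector for heterogeneous
#' populations.
#'
#' @param preset `"RS"` or `"FS"`. Ignored when `a` is given.
#' @param a,b,c,d explicit parameter values (all four must be supplied
#'   together); `a` is the recovery time scale (1/ms), `b` the recovery
#'   sensitivity, `c` the reset potential (mV), `d` the post-spike recovery
#'   increment.
#' @return An object of class `izhikevich_params`.
#' @export
#' @examples
#' izhikevich_params("RS")
#' izhikevich_params(a = 0.02, b = 0.25, c = -65, d = 2) # low-threshold spiking
izhikevich_params <- function(preset = c("RS", "FS"),
                              a = NULL, b = NULL, c = NULL, d = NULL) {
  if (is.null(a)) {
    preset <- match.arg(preset)
    p <- switch(preset,
      RS = list(a = 0.02, b = 0.2, c = -65, d = 8),
      FS = list(a = 0.1,  b = 0.2, c = -65, d = 2)
    )
    p$preset <- preset
  } else {
    if (is.null(b) || is.null(c) || is.null(d))
      stop("supply all of a, b, c, d or none")
    stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
    p <- list(a = a, b = b, c = c, d = d, preset = "custom")
  }
  structure(p, class = "izhikevich_params")
}

#' @export
print.izhikevich_params <- function(x, ...) {
  cat(sprintf("Izhikevich parameters [%s]: a=%s b=%s c=%s d=%s\n", x$preset,
              paste(unique(x$a), collapse = ","), paste(unique(x$b), collapse = ","),
              paste(unique(x$c), collapse = ","), paste(unique(x$d), collapse = ",")))
  invisible(x)
}

#' Membrane state of one or more Izhikevich neurons
#'
#' @param n number of neurons.
#' @param V initial membrane potential(s), mV.
#' @param U initial recovery variable(s); defaults to `b * V`, the value of
#'   the U-nullcline at `V`.
#' @param b recovery sensitivity used for the default `U`.
#' @return An object of class `neuron_state` with fields `V` and `U`.
#' @export
neuron_state <- function(n = 1, V = -65, U = NULL, b = 0.2) {
  V <- rep_len(as.numeric(V), n)
  U <- if (is.null(U)) rep_len(b, n) * V else rep_len(as.numeric(U), n)
  structure(list(V = V, U = U), class = "neuron_state")
}

#' Advance Izhikevich neurons by one time step
#'
#' Neurons at or above the 30 mV spike cutoff at step entry take the reset
#' branch (`V := c`, `U := U + d`) and are flagged as spiking; all other
#' neurons are integrated with two half-steps of `dt/2` for `V` (clamped at
#' 30 mV if the cutoff is crossed mid-step, so the spike is registered on the
#' following step) and one full Euler step for `U`. This is the update
#' ordering of the original published implementation of the model.
#'
#' @param state a [neuron_state()].
#' @param params an [izhikevich_params()]; fields may be per-neuron vectors.
#' @param I_syn synaptic current (model units), scalar or per-neuron.
#' @param dt time step, ms.
#' @return `list(state = <new neuron_state>, spiked = <logical vector>)`.
#' @export
step_izhikevich <- function(state, params, I_syn = 0, dt = 1) {
  if (!inherits(state, "neuron_state")) stop("state must be a neuron_state")
  if (dt <= 0) stop("dt must be positive")
  V <- state$V
  U <- state$U
  n <- length(V)
  I <- rep_len(as.numeric(I_syn), n)
  if (!all(is.finite(V)) || !all(is.finite(U)))
    stop("non-finite membrane state")
  if (!all(is.finite(I)))
    stop("non-finite synaptic current")
  a <- rep_len(params$a, n); b <- rep_len(params$b, n)
  cc <- rep_len(params$c, n); d <- rep_len(params$d, n)

  spiked <- V >= 30
  if (any(spiked)) {
    V[spiked] <- cc[spiked]
    U[spiked] <- U[spiked] + d[spiked]
  }
  sub <- !spiked
  if (any(sub)) {
    half <- dt / 2
    v <- V[sub]; u <- U[sub]; i <- I[sub]
    v <- pmin(v + half * (0.04 * v * v + 5 * v + 140 - u + i), 30)
    v <- pmin(v + half * (0.04 * v * v + 5 * v + 140 - u + i), 30)
    u <- u + dt * a[sub] * (b[sub] * v - u)
    V[sub] <- v
    U[sub] <- u
  }
  list(state = structure(list(V = V, U = U), class = "neuron_state"),
       spiked = spiked)
}

#' Synapse model parameters
#'
#' Decay time constants and reversal potentials of the four receptor
#' channels. Defaults: `tau` = 5 (AMPA), 150 (NMDA), 6 (GABAa), 150 (GABAb)
#' ms; `v_rev` = 0 (AMPA, NMDA), -70 (GABAa), -90 (GABAb) mV. The reversal
#' potentials are the standard values of the CARLsim-family simulators.
#'
#' @param tau named numeric vector of decay constants (ms).
#' @param v_rev named numeric vector of reversal potentials (mV).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(tau = c(AMPA = 5, NMDA = 150, GABAa = 6, GABAb = 150),
                           v_rev = c(AMPA = 0, NMDA = 0, GABAa = -70, GABAb = -90)) {
  rec <- c("AMPA", "NMDA", "GABAa", "GABAb")
  if (!all(rec %in% names(tau)) || !all(rec %in% names(v_rev)))
    stop("tau and v_rev must name all four receptors")
  if (any(tau[rec] <= 0)) stop("decay constants must be positive")
  structure(list(tau = tau[rec], v_rev = v_rev[rec]), class = "synapse_params")
}

#' Per-neuron receptor conductances
#'
#' @param n number of neurons.
#' @param AMPA,NMDA,GABAa,GABAb initial conductances (non-negative, model
#'   units).
#' @return An object of class `receptor_conductances`: four numeric vectors.
#' @export
receptor_conductances <- function(n = 1, AMPA = 0, NMDA = 0, GABAa = 0, GABAb = 0) {
  g <- list(AMPA = rep_len(AMPA, n), NMDA = rep_len(NMDA, n),
            GABAa = rep_len(GABAa, n), GABAb = rep_len(GABAb, n))
  if (any(unlist(g) < 0)) stop("conductances must be non-negative")
  structure(g, class = "receptor_conductances")
}

#' Total COBA synaptic current
#'
#' Combines the four receptor currents `i_r = g_r * gate_r * (V - v_rev_r)`
#' where the gate is 1 except for NMDA, which carries the voltage-dependent
#' magnesium-block factor `((V+80)/60)^2 / (1 + ((V+80)/60)^2)`. The sign of
#' the returned current follows the convention that the drive is injected as
#' `I_syn = -sum_r i_r` into the Izhikevich equation, so that excitatory
#' conductance (v_rev = 0 mV, V near rest) depolarizes.
#'
#' @param V membrane potential(s), mV.
#' @param g a [receptor_conductances()] (vectors conformable with `V`).
#' @param syn a [synapse_params()].
#' @return Numeric vector of synaptic currents (model units).
#' @export
synaptic_current <- function(V, g, syn = synapse_params()) {
  if (!all(is.finite(V))) stop("non-finite membrane potential")
  vr <- syn$v_rev
  x <- ((V + 80) / 60)^2
  gate <- x / (1 + x)
  drive <- g$AMPA * (V - vr[["AMPA"]]) +
    g$NMDA * gate * (V - vr[["NMDA"]]) +
    g$GABAa * (V - vr[["GABAa"]]) +
    g$GABAb * (V - vr[["GABAb"]])
  -drive
}

#' Decay conductances and add arriving spikes
#'
#' Each conductance decays by the exact exponential factor `exp(-dt/tau_r)`
#' and is then incremented by the summed synaptic weights of spikes arriving
#' during this step: excitatory arrivals increment both `g_AMPA` and
#' `g_NMDA`, inhibitory arrivals both `g_GABAa` and `g_GABAb`.
#'
#' @param g a [receptor_conductances()].
#' @param exc,inh summed weights of arriving excitatory / inhibitory spikes
#'   (scalar or per-neuron, non-negative).
#' @param dt elapsed time, ms.
#' @param syn a [synapse_params()].
#' @return Updated [receptor_conductances()].
#' @export
update_conductances <- function(g, exc = 0, inh = 0, dt = 1, syn = synapse_params()) {
  if (dt <= 0) stop("dt must be positive")
  if (any(exc < 0) || any(inh < 0)) stop("spike weights must be non-negative")
  tau <- syn$tau
  structure(list(
    AMPA  = g$AMPA  * exp(-dt / tau[["AMPA"]])  + exc,
    NMDA  = g$NMDA  * exp(-dt / tau[["NMDA"]])  + exc,
    GABAa = g$GABAa * exp(-dt / tau[["GABAa"]]) + inh,
    GABAb = g$GABAb * exp(-dt / tau[["GABAb"]]) + inh
  ), class = "receptor_conductances")
}

#' Spike raster container
#'
#' A data frame of `(neuron, time)` pairs plus the population size and the
#' simulated duration as attributes.
#'
#' @param neuron integer neuron indices (1-based).
#' @param time spike times, ms.
#' @param n_neurons population size.
#' @param duration simulated duration, ms.
#' @return A `spike_raster` (also a `data.frame`).
#' @export
spike_raster <- function(neuron = integer(), time = numeric(),
                         n_neurons, duration = NA_real_) {
  if (length(neuron) != length(time)) stop("neuron and time lengths differ")
  if (length(neuron) && (min(neuron) < 1 || max(neuron) > n_neurons))
    stop("neuron index out of range")
  structure(data.frame(neuron = as.integer(neuron), time = as.numeric(time)),
            n_neurons = as.integer(n_neurons), duration = duration,
            class = c("spike_raster", "data.frame"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d spikes from %d neurons over %s ms\n",
              nrow(x), attr(x, "n_neurons"),
              format(attr(x, "duration"))))
  invisible(x)
}

#' Per-neuron spike counts of a raster
#'
#' @param raster a [spike_raster()].
#' @return Integer vector of length `n_neurons`.
#' @export
raster_counts <- function(raster) {
  tabulate(raster$neuron, nbins = attr(raster, "n_neurons"))
}

#' Write / read a spike raster as CSV
#'
#' Two columns (`neuron`, `time`); the population size and duration are kept
#' in a `#`-prefixed header line so the round trip preserves both.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @return `write_spike_raster` returns `path` invisibly; `read_spike_raster`
#'   returns a [spike_raster()].
#' @export
write_spike_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d duration=%s", attr(raster, "n_neurons"),
                     format(attr(raster, "duration"), digits = 15)), con)
  utils::write.csv(as.data.frame(raster), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_raster
#' @export
read_spike_raster <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("n_neurons=(\\d+) duration=([0-9.eE+-]+|NA)", hdr))[[1]]
  if (length(m) != 3) stop("missing raster header in ", path)
  df <- utils::read.csv(path, comment.char = "#")
  spike_raster(df$neuron, df$time, n_neurons = as.integer(m[2]),
               duration = suppressWarnings(as.numeric(m[3])))
}

#' Population connectivity
#'
#' Wiring of a simulated population: per-neuron Izhikevich parameters plus
#' non-negative weight matrices split by synapse sign. `W_in_*` map external
#' input spike trains onto the population; `W_rec_*` map the population onto
#' itself (row = postsynaptic, column = presynaptic). Any matrix may be a
#' base matrix or a sparse `Matrix`.
#'
#' @param n_neurons population size.
#' @param params an [izhikevich_params()] (fields scalar or per-neuron).
#' @param n_inputs number of external input channels.
#' @param W_in_exc,W_in_inh `n_neurons x n_inputs` non-negative weights for
#'   excitatory / inhibitory input synapses (or `NULL`).
#' @param W_rec_exc,W_rec_inh `n_neurons x n_neurons` non-negative recurrent
#'   weights (or `NULL`).
#' @param syn a [synapse_params()].
#' @return An object of class `population_connectivity`.
#' @export
population_connectivity <- function(n_neurons, params = izhikevich_params("RS"),
                                    n_inputs = 0,
                                    W_in_exc = NULL, W_in_inh = NULL,
                                    W_rec_exc = NULL, W_rec_inh = NULL,
                                    syn = synapse_params()) {
  chk <- function(W, nr, nc, what) {
    if (is.null(W)) return(invisible(NULL))
    if (nrow(W) != nr || ncol(W) != nc)
      stop(sprintf("%s must be %d x %d (got %d x %d)", what, nr, nc, nrow(W), ncol(W)))
    if (min(W) < 0) stop(what, " must be non-negative")
  }
  chk(W_in_exc, n_neurons, n_inputs, "W_in_exc")
  chk(W_in_inh, n_neurons, n_inputs, "W_in_inh")
  chk(W_rec_exc, n_neurons, n_neurons, "W_rec_exc")
  chk(W_rec_inh, n_neurons, n_neurons, "W_rec_inh")
  structure(list(n_neurons = as.integer(n_neurons), params = params,
                 n_inputs = as.integer(n_inputs),
                 W_in_exc = W_in_exc, W_in_inh = W_in_inh,
                 W_rec_exc = W_rec_exc, W_rec_inh = W_rec_inh, syn = syn),
            class = "population_connectivity")
}

#' Simulate a population of COBA Izhikevich neurons
#'
#' Advances all neurons and receptor conductances over `duration` ms in steps
#' of `dt`. Per step: conductances decay exponentially, arriving input spikes
#' (binned at `dt`) and recurrent spikes from the previous step increment
#' them, the COBA current is computed, and the membrane equations are
#' stepped. The simulation is fully deterministic given the connectivity and
#' the input raster; `seed` is accepted for interface symmetry with the
#' stochastic stages and seeds R's RNG when non-`NULL`.
#'
#' @param conn a [population_connectivity()].
#' @param input_spikes a [spike_raster()] over the `n_inputs` channels, or
#'   `NULL` for no input. Spike times must lie in `[0, duration)`.
#' @param duration simulated time, ms.
#' @param dt integration step, ms.
#' @param seed optional RNG seed (the integrator itself is deterministic).
#' @param V0,U0 optional initial state vectors.
#' @return A [spike_raster()] of the population's spikes.
#' @export
simulate_population <- function(conn, input_spikes = NULL, duration, dt = 1,
                                seed = NULL, V0 = NULL, U0 = NULL) {
  if (!inherits(conn, "population_connectivity")) stop("conn must be a population_connectivity")
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- conn$n_neurons
  n_steps <- as.integer(round(duration / dt))
  syn <- conn$syn

  # Pre-reduce input spikes to per-step summed synaptic drive.
  exc_in <- inh_in <- NULL
  if (!is.null(input_spikes) && nrow(input_spikes) > 0) {
    if (attr(input_spikes, "n_neurons") != conn$n_inputs)
      stop(sprintf("input raster has %d channels, connectivity expects %d",
                   attr(input_spikes, "n_neurons"), conn$n_inputs))
    bin <- pmin(floor(input_spikes$time / dt) + 1L, n_steps)
    S <- Matrix::sparseMatrix(i = input_spikes$neuron, j = bin, x = 1,
                              dims = c(conn$n_inputs, n_steps))
    if (!is.null(conn$W_in_exc)) exc_in <- as.matrix(conn$W_in_exc %*% S)
    if (!is.null(conn$W_in_inh)) inh_in <- as.matrix(conn$W_in_inh %*% S)
  }

  dec <- exp(-dt / syn$tau)
  gA <- gN <- ga <- gb <- numeric(n)
  V <- if (is.null(V0)) rep_len(rep_len(conn$params$c, n), n) else rep_len(V0, n)
  U <- if (is.null(U0)) rep_len(conn$params$b, n) * V else rep_len(U0, n)
  state <- structure(list(V = V, U = U), class = "neuron_state")
  prev_spiked <- logical(n)
  vr <- syn$v_rev

  out_neuron <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    exc <- if (is.null(exc_in)) 0 else exc_in[, s]
    inh <- if (is.null(inh_in)) 0 else inh_in[, s]
    if (any(prev_spiked)) {
      sp <- as.numeric(prev_spiked)
      if (!is.null(conn$W_rec_exc)) exc <- exc + as.vector(conn$W_rec_exc %*% sp)
      if (!is.null(conn$W_rec_inh)) inh <- inh + as.vector(conn$W_rec_inh %*% sp)
    }
    gA <- gA * dec[["AMPA"]] + exc
    gN <- gN * dec[["NMDA"]] + exc
    ga <- ga * dec[["GABAa"]] + inh
    gb <- gb * dec[["GABAb"]] + inh
    Vm <- state$V
    x <- ((Vm + 80) / 60)^2
    I <- -(gA * (Vm - vr[["AMPA"]]) + gN * (x / (1 + x)) * (Vm - vr[["NMDA"]]) +
             ga * (Vm - vr[["GABAa"]]) + gb * (Vm - vr[["GABAb"]]))
    st <- step_izhikevich(state, conn$params, I, dt)
    state <- st$state
    prev_spiked <- st$spiked
    if (any(st$spiked)) out_neuron[[s]] <- which(st$spiked)
  }
  ns <- lengths(out_neuron)
  spike_raster(neuron = unlist(out_neuron),
               time = rep.int(seq_len(n_steps) * dt, ns),
               n_neurons = n, duration = duration)
}
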