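# Independent reference implementations used as oracles by the unit and
# acceptance tests. Both are deliberately written as naive straight-line
# code, separate from the package's vectorized paths.

# Straight-line scalar reference of the documented dynamics: entry-test
# spike/reset, two half-steps for V clamped at 30, one Euler step for U,
# exact-exponential conductance decay, COBA current with the NMDA gate.
reference_circuit <- function(W_in_exc, W_rec_inh, drive_bins, n_steps, dt,
                              params, syn) {
  n <- nrow(W_in_exc)
  V <- rep(params$c, n); U <- params$b * V
  gA <- gN <- ga <- gb <- rep(0, n)
  prev <- rep(FALSE, n)
  Vtrace <- matrix(NA_real_, n_steps, n)
  spikes <- list()
  for (s in seq_len(n_steps)) {
    for (i in seq_len(n)) {
      exc <- sum(W_in_exc[i, ] * drive_bins[, s])
      inh <- 0
      if (!is.null(W_rec_inh)) inh <- sum(W_rec_inh[i, ] * as.numeric(prev))
      gA[i] <- gA[i] * exp(-dt / syn$tau[["AMPA"]]) + exc
      gN[i] <- gN[i] * exp(-dt / syn$tau[["NMDA"]]) + exc
      ga[i] <- ga[i] * exp(-dt / syn$tau[["GABAa"]]) + inh
      gb[i] <- gb[i] * exp(-dt / syn$tau[["GABAb"]]) + inh
    }
    now <- rep(FALSE, n)
    for (i in seq_len(n)) {
      x <- ((V[i] + 80) / 60)^2
      I <- -(gA[i] * (V[i] - syn$v_rev[["AMPA"]]) +
               gN[i] * x / (1 + x) * (V[i] - syn$v_rev[["NMDA"]]) +
               ga[i] * (V[i] - syn$v_rev[["GABAa"]]) +
               gb[i] * (V[i] - syn$v_rev[["GABAb"]]))
      if (V[i] >= 30) {
        now[i] <- TRUE
        V[i] <- params$c
        U[i] <- U[i] + params$d
      } else {
        for (k in 1:2)
          V[i] <- min(V[i] + dt / 2 * (0.04 * V[i]^2 + 5 * V[i] + 140 - U[i] + I), 30)
        U[i] <- U[i] + dt * params$a * (params$b * V[i] - U[i])
      }
      Vtrace[s, i] <- V[i]
    }
    if (any(now)) spikes[[length(spikes) + 1]] <- cbind(which(now), s * dt)
    prev <- now
  }
  list(V = Vtrace, spikes = do.call(rbind, spikes))
}

# Independent brute-force voltage: literal double sum over grid points and
# spikes, with the kernel written out inline.
brute_voltage <- function(t_grid, spikes, w, tau, tau_s, v0, v_rest = 0) {
  vapply(t_grid, function(t) {
    v <- v_rest
    for (i in seq_along(spikes)) {
      d <- t - spikes[i]
      if (d > 0) v <- v + w[i] * v0 * (exp(-d / tau) - exp(-d / tau_s))
    }
    v
  }, numeric(1))
}
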