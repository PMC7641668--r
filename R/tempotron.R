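# The tempotron: a leaky-integrator decision neuron whose subthreshold
# voltage is a weighted sum of normalized difference-of-exponentials PSP
# kernels, trained with the error-correcting P+/P- rule. Ten output neurons
# share the presynaptic latency pattern; the class read out is the output
# with the highest peak voltage.

#' PSP kernel normalization constant
#'
#' The kernel `K(t) = V_0 (exp(-t/tau) - exp(-t/tau_s))` peaks at
#' `t* = tau tau_s log(tau/tau_s) / (tau - tau_s)`; `V_0` is chosen so the
#' peak equals 1. At the default constants (tau = 16 ms, tau_s = 4 ms) this
#' gives `V_0 = 2.12` (two decimals).
#'
#' @param tau membrane integration decay constant, ms.
#' @param tau_s synaptic current decay constant, ms; must satisfy
#'   `tau > tau_s > 0`.
#' @return The scalar `V_0`.
#' @export
compute_v0 <- function(tau = 16, tau_s = 4) {
  if (!(tau > tau_s && tau_s > 0)) stop("need tau > tau_s > 0")
  ts <- kernel_peak_time(tau, tau_s)
  1 / (exp(-ts / tau) - exp(-ts / tau_s))
}

#' @rdname compute_v0
#' @export
kernel_peak_time <- function(tau = 16, tau_s = 4) {
  if (!(tau > tau_s && tau_s > 0)) stop("need tau > tau_s > 0")
  tau * tau_s * log(tau / tau_s) / (tau - tau_s)
}

#' Tempotron kernel and threshold parameters
#'
#' @param tau,tau_s decay constants, ms (`tau > tau_s > 0`).
#' @param v_rest resting potential of the decision neurons (voltage units of
#'   the kernel; default 0).
#' @param v_threshold firing threshold (default 1, i.e. one full PSP from a
#'   unit-weight synapse just reaches threshold).
#' @return An object of class `kernel_params` (includes the computed `v0`).
#' @export
kernel_params <- function(tau = 16, tau_s = 4, v_rest = 0, v_threshold = 1) {
  structure(list(tau = tau, tau_s = tau_s, v0 = compute_v0(tau, tau_s),
                 v_rest = v_rest, v_threshold = v_threshold),
            class = "kernel_params")
}

#' Normalized PSP kernel
#'
#' `K(t - t_i) = V_0 [exp(-(t - t_i)/tau) - exp(-(t - t_i)/tau_s)]` for
#' `t > t_i`, and 0 otherwise (causality). Vectorized over `t` and `t_i`.
#'
#' @param t evaluation time(s), ms.
#' @param t_i presynaptic spike time(s), ms.
#' @param params a [kernel_params()].
#' @return Kernel value(s) in `[0, 1]`.
#' @export
psp_kernel <- function(t, t_i = 0, params = kernel_params()) {
  d <- t - t_i
  out <- params$v0 * (exp(-d / params$tau) - exp(-d / params$tau_s))
  out[d <= 0] <- 0
  out
}

# Kernel matrix: rows = grid times, cols = spike times. Exponentials are
# evaluated only on the causal (t > t_i) part.
.psp_matrix <- function(t_grid, spk, params) {
  d <- outer(t_grid, spk, "-")
  K <- array(0, dim(d))
  pos <- which(d > 0)
  if (length(pos)) {
    dp <- d[pos]
    K[pos] <- params$v0 * (exp(-dp / params$tau) - exp(-dp / params$tau_s))
  }
  K
}

# Analytic voltage at arbitrary times (pre-spike / unshunted form).
.voltage_at <- function(t, spk, w, params) {
  vapply(t, function(tt) sum(w * psp_kernel(tt, spk, params)), numeric(1)) +
    params$v_rest
}

#' Membrane voltage trace of one output neuron
#'
#' Evaluates `V(t) = sum_i w_i sum_{t_i} K(t - t_i) + V_rest` on a regular
#' grid over `[0, T]`. Only active afferents (spike time strictly inside the
#' window) contribute. If the voltage crosses threshold, the output spike is
#' recorded and all input spikes arriving after it are shunted: the
#' post-spike trace contains only the PSPs of inputs that arrived before the
#' output spike, so it decays back towards rest.
#'
#' @param pattern a `latency_pattern`.
#' @param w afferent weight vector of length `pattern$N`.
#' @param params a [kernel_params()].
#' @param dt_eval grid resolution, ms.
#' @param T window length, ms (defaults to the pattern's).
#' @return An object of class `membrane_trace`: `times`, `v` (shunted trace),
#'   `v_unshunted`, `spike_time` (`NA` if subthreshold), `t_max` and `v_max`
#'   of the unshunted trace, plus the contributing spikes for refinement.
#' @export
membrane_trace <- function(pattern, w, params = kernel_params(), dt_eval = 1,
                           T = pattern$T) {
  if (length(w) != pattern$N)
    stop(sprintf("weight vector length %d does not match %d afferents",
                 length(w), pattern$N))
  t_grid <- seq(0, T, by = dt_eval)
  act <- which(pattern$active)
  spk <- pattern$times[act]
  wa <- w[act]
  if (length(spk) == 0) {
    v <- rep(params$v_rest, length(t_grid))
    K <- matrix(0, length(t_grid), 0)
  } else {
    K <- .psp_matrix(t_grid, spk, params)
    v <- as.vector(K %*% wa) + params$v_rest
  }
  imax <- which.max(v)
  spike_time <- NA_real_
  v_sh <- v
  cross <- which(v >= params$v_threshold)
  if (length(cross)) {
    spike_time <- t_grid[cross[1]]
    post <- t_grid > spike_time
    keep <- spk < spike_time
    v_sh[post] <- (if (any(keep)) as.vector(K[post, keep, drop = FALSE] %*% wa[keep]) else 0) +
      params$v_rest
  }
  structure(list(times = t_grid, v = v_sh, v_unshunted = v,
                 spike_time = spike_time,
                 t_max = t_grid[imax], v_max = v[imax],
                 spikes = spk, weights = wa, params = params),
            class = "membrane_trace")
}

#' Time of maximal voltage
#'
#' Returns the grid time at which the (unshunted) voltage is maximal, with
#' ties broken by the earliest time. With `refine = TRUE` the analytic
#' voltage is maximized by golden-section search between the neighbouring
#' grid points, resolving the peak below the grid resolution.
#'
#' @param trace a [membrane_trace()].
#' @param refine refine the grid maximum by golden-section search.
#' @param tol time tolerance of the refinement, ms.
#' @return `t_max` in ms.
#' @export
find_tmax <- function(trace, refine = FALSE, tol = 1e-4) {
  if (!length(trace$times)) stop("empty trace")
  i <- which.max(trace$v_unshunted)
  t0 <- trace$times[i]
  if (!refine || length(trace$spikes) == 0) return(t0)
  dt <- if (length(trace$times) > 1) diff(trace$times[1:2]) else 1
  lo <- max(min(trace$times), t0 - dt)
  hi <- min(max(trace$times), t0 + dt)
  stats::optimize(function(t) .voltage_at(t, trace$spikes, trace$weights, trace$params),
                  c(lo, hi), maximum = TRUE, tol = tol)$maximum
}

#' Tempotron weight update
#'
#' The error-correcting rule: on a P+ error (the neuron should have fired
#' but did not) every afferent spiking before `t_max` is potentiated by
#' `lambda * K(t_max - t_i)`; on a P- error (fired but should not have) it is
#' depressed by the same amount; otherwise no change. Afferents spiking at or
#' after `t_max`, and inactive afferents (edge-of-window spikes), contribute
#' nothing.
#'
#' @param pattern a `latency_pattern`.
#' @param error_type `"none"`, `"P+"` or `"P-"`.
#' @param t_max time of maximal postsynaptic voltage, ms (in `[0, T]`).
#' @param lambda learning rate.
#' @param params a [kernel_params()].
#' @return Weight change vector of length `pattern$N`.
#' @export
weight_update <- function(pattern, error_type = c("none", "P+", "P-"), t_max,
                          lambda = 0.001, params = kernel_params()) {
  error_type <- match.arg(error_type)
  if (t_max < 0 || t_max > pattern$T) stop("t_max outside [0, T]")
  dw <- numeric(pattern$N)
  if (error_type == "none" || lambda == 0) return(dw)
  act <- which(pattern$active)
  k <- psp_kernel(t_max, pattern$times[act], params)
  dw[act] <- if (error_type == "P+") lambda * k else -lambda * k
  dw
}

#' Multiclass tempotron model
#'
#' One output neuron per class, fully connected to the `n_afferents`
#' presynaptic neurons; all weights start at `w_init` (0.001 by default, so
#' training gradually grows them until the correct output fires).
#'
#' @param n_afferents number of presynaptic neurons (3136 for a 4-pool 28x28
#'   V2 layer).
#' @param classes class labels, one per output neuron.
#' @param kernel a [kernel_params()].
#' @param lambda learning rate(s); `lambda_plus`/`lambda_minus` may differ.
#' @param lambda_minus learning rate of P- depression (defaults to `lambda`).
#' @param T encoding window, ms.
#' @param w_init initial weight.
#' @param dt_eval voltage grid resolution, ms.
#' @return An object of class `tempotron_model` with weight matrix `W`
#'   (`n_afferents x n_classes`).
#' @export
tempotron_model <- function(n_afferents, classes = 0:9,
                            kernel = kernel_params(), lambda = 0.001,
                            lambda_minus = lambda, T = 400, w_init = 0.001,
                            dt_eval = 1) {
  structure(list(W = matrix(w_init, n_afferents, length(classes)),
                 classes = classes, kernel = kernel,
                 lambda = lambda, lambda_minus = lambda_minus,
                 T = T, dt_eval = dt_eval),
            class = "tempotron_model")
}

#' @export
print.tempotron_model <- function(x, ...) {
  cat(sprintf("tempotron_model: %d x %d weights, tau=%g tau_s=%g V0=%.4g T=%g ms lambda=%g\n",
              nrow(x$W), ncol(x$W), x$kernel$tau, x$kernel$tau_s, x$kernel$v0,
              x$T, x$lambda))
  invisible(x)
}

# Unshunted voltage traces of all outputs: list(v = grid x classes matrix,
# K = kernel matrix over active spikes, act = active indices).
.output_voltages <- function(pattern, model) {
  t_grid <- seq(0, model$T, by = model$dt_eval)
  act <- which(pattern$active)
  if (length(act) == 0)
    return(list(v = matrix(model$kernel$v_rest, length(t_grid), ncol(model$W)),
                K = matrix(0, length(t_grid), 0), act = act, t_grid = t_grid))
  K <- .psp_matrix(t_grid, pattern$times[act], model$kernel)
  list(v = K %*% model$W[act, , drop = FALSE] + model$kernel$v_rest,
       K = K, act = act, t_grid = t_grid)
}

#' Classify a latency pattern
#'
#' Evaluates every output neuron's voltage over the window and returns the
#' class of the output with the highest peak voltage (computed without
#' shunting -- shunting only shapes spike generation during training). Ties
#' are broken by the lowest class index.
#'
#' @param model a [tempotron_model()].
#' @param pattern a `latency_pattern`.
#' @return The predicted class label.
#' @export
classify <- function(model, pattern) {
  ov <- .output_voltages(pattern, model)
  peaks <- apply(ov$v, 2, max)
  model$classes[which.max(peaks)]
}

#' Peak output voltages for a pattern
#'
#' @param model a [tempotron_model()].
#' @param pattern a `latency_pattern`.
#' @return Named numeric vector of per-class peak voltages.
#' @export
output_peaks <- function(model, pattern) {
  ov <- .output_voltages(pattern, model)
  stats::setNames(apply(ov$v, 2, max), model$classes)
}

#' Train the multiclass tempotron
#'
#' Samples are visited in a seed-controlled shuffled order each epoch. For
#' each sample the labeled output is the P+ neuron (it must fire) and the
#' other outputs are P- neurons (they must stay silent). All outputs are
#' re-evaluated after each round of corrections and the weight updates of
#' [weight_update()] are applied to every erring output, repeatedly, until
#' all conditions hold or `max_inner` rounds are reached. `t_max` is taken
#' from the unshunted trace (the maximal postsynaptic potential). Training
#' stops after an epoch with no errors or after `max_epochs`.
#'
#' @param model a [tempotron_model()].
#' @param patterns list of `latency_pattern`s.
#' @param labels class label per pattern (values in `model$classes`).
#' @param max_inner cap on per-sample correction rounds.
#' @param max_epochs cap on training epochs.
#' @param seed RNG seed controlling presentation order.
#' @param verbose print per-epoch error counts.
#' @return `list(model, record)` where `record` holds per-sample P+/P-
#'   correction counts and per-epoch error counts.
#' @export
train_multiclass <- function(model, patterns, labels, max_inner = 100,
                             max_epochs = 5, seed = NULL, verbose = FALSE) {
  if (length(patterns) == 0) stop("empty training set")
  if (length(labels) != length(patterns)) stop("labels and patterns lengths differ")
  cls <- match(labels, model$classes)
  if (anyNA(cls)) stop("labels outside the model's classes")
  if (!is.null(seed)) set.seed(seed)
  thr <- model$kernel$v_threshold
  n <- length(patterns)
  p_plus <- integer(n); p_minus <- integer(n)
  epoch_errors <- integer(0)
  for (epoch in seq_len(max_epochs)) {
    order_ <- sample.int(n)
    errs <- 0L
    for (s in order_) {
      pat <- patterns[[s]]
      ov <- .output_voltages(pat, model)
      first <- TRUE
      for (iter in seq_len(max_inner)) {
        peaks <- apply(ov$v, 2, max)
        fired <- peaks >= thr
        want <- cls[s]
        bad_plus <- !fired[want]
        bad_minus <- which(fired & seq_along(fired) != want)
        if (!bad_plus && length(bad_minus) == 0) break
        if (first) { errs <- errs + 1L; first <- FALSE }
        if (length(ov$act)) {
          if (bad_plus) {
            imax <- which.max(ov$v[, want])
            model$W[ov$act, want] <- model$W[ov$act, want] +
              model$lambda * ov$K[imax, ]
            p_plus[s] <- p_plus[s] + 1L
          }
          for (j in bad_minus) {
            imax <- which.max(ov$v[, j])
            model$W[ov$act, j] <- model$W[ov$act, j] -
              model$lambda_minus * ov$K[imax, ]
            p_minus[s] <- p_minus[s] + 1L
          }
          ov$v <- ov$K %*% model$W[ov$act, , drop = FALSE] + model$kernel$v_rest
        } else break # no active spikes: the P+ condition cannot be met
      }
    }
    epoch_errors <- c(epoch_errors, errs)
    if (verbose)
      message(sprintf("epoch %d: %d/%d samples needed correction", epoch, errs, n))
    if (errs == 0L) break
  }
  list(model = model,
       record = list(p_plus = p_plus, p_minus = p_minus,
                     epoch_errors = epoch_errors))
}

#' Save / load a tempotron checkpoint
#'
#' JSON container holding the kernel constants, window, learning rates,
#' classes and the full weight matrix.
#'
#' @param model a [tempotron_model()].
#' @param path file path.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(list(
    n_afferents = nrow(model$W), classes = model$classes,
    tau = model$kernel$tau, tau_s = model$kernel$tau_s,
    v_rest = model$kernel$v_rest, v_threshold = model$kernel$v_threshold,
    lambda = model$lambda, lambda_minus = model$lambda_minus,
    T = model$T, dt_eval = model$dt_eval, W = as.vector(model$W)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- tempotron_model(n_afferents = x$n_afferents, classes = x$classes,
                       kernel = kernel_params(x$tau, x$tau_s, x$v_rest, x$v_threshold),
                       lambda = x$lambda, lambda_minus = x$lambda_minus,
                       T = x$T, dt_eval = x$dt_eval)
  m$W <- matrix(as.numeric(x$W), x$n_afferents, length(x$classes))
  m
}
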