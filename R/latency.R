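# Single-spike latency coding: V2 firing-rate maps are normalized to [0, 1]
# and mapped to one spike per neuron at t = (1 - f) * T. Stronger responses
# fire earlier; a neuron with f = 0 lands exactly on the window edge T and is
# flagged inactive, because the edge time is excluded from synaptic learning.

#' Normalize firing rates to [0, 1]
#'
#' `f_i = rate_i / denominator`, where the denominator is the per-image
#' maximum rate (default, so every image's strongest neuron fires at t = 0
#' and the encoding is contrast-invariant) or a global rate constant. An
#' all-zero input maps to all-zero `f`.
#'
#' @param response an `orientation_response`, or a bare non-negative numeric
#'   vector/array of rates in Hz.
#' @param method `"per_image"` (divide by `max(rates)`) or `"global"`
#'   (divide by `rate_max`, clipped at 1).
#' @param rate_max global denominator, Hz (used by `method = "global"`).
#' @return Numeric vector of normalized frequencies in `[0, 1]`, in the
#'   flattened (column-major) neuron order of the response.
#' @export
normalize_rates <- function(response, method = c("per_image", "global"),
                            rate_max = 400) {
  method <- match.arg(method)
  rates <- if (inherits(response, "orientation_response")) response$rates else response
  rates <- as.vector(rates)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (method == "per_image") {
    m <- max(rates)
    if (m == 0) return(rates)
    rates / m
  } else {
    pmin(rates / rate_max, 1)
  }
}

#' Encode normalized frequencies as single-spike latencies
#'
#' `t_i = (1 - f_i) * T`. Each neuron fires exactly once inside the window
#' `[0, T]`; neurons with `t_i = T` (that is, `f_i = 0`) are flagged inactive
#' and are excluded from membrane integration and synaptic learning.
#'
#' @param f normalized frequencies in `[0, 1]`.
#' @param T encoding window length, ms.
#' @return An object of class `latency_pattern` with fields `times` (length
#'   `N`), `active` (logical), `T` and `N`.
#' @export
encode_latency <- function(f, T = 400) {
  f <- as.vector(f)
  if (T <= 0) stop("T must be positive")
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("normalized frequencies must lie in [0, 1]")
  times <- (1 - f) * T
  structure(list(times = times, active = f > 0, T = T, N = length(f)),
            class = "latency_pattern")
}

#' Latency-encode an orientation response
#'
#' Composition of [normalize_rates()] and [encode_latency()].
#'
#' @param response an `orientation_response` or rate vector.
#' @param T encoding window, ms.
#' @inheritParams normalize_rates
#' @return A `latency_pattern`.
#' @export
latency_encode <- function(response, T = 400, method = "per_image", rate_max = 400) {
  encode_latency(normalize_rates(response, method = method, rate_max = rate_max), T = T)
}

#' @export
print.latency_pattern <- function(x, ...) {
  cat(sprintf("latency_pattern: %d afferents, %d active spikes in [0, %g) ms\n",
              x$N, sum(x$active), x$T))
  invisible(x)
}

#' Write / read a latency pattern as CSV
#'
#' Active spikes as `(neuron, time)` rows; `N` and `T` kept in a header line.
#'
#' @param pattern a `latency_pattern`.
#' @param path file path.
#' @export
write_latency_pattern <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%d T=%s", pattern$N, format(pattern$T, digits = 15)), con)
  idx <- which(pattern$active)
  utils::write.csv(data.frame(neuron = idx, time = pattern$times[idx]),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_latency_pattern
#' @export
read_latency_pattern <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("N=(\\d+) T=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3) stop("missing latency header in ", path)
  N <- as.integer(m[2]); T <- as.numeric(m[3])
  df <- utils::read.csv(path, comment.char = "#")
  f <- numeric(N)
  f[df$neuron] <- 1 - df$time / T
  encode_latency(f, T = T)
}
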