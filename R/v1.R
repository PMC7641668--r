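# V1 front end: oriented derivative-of-Gaussian filter bank, complex-cell
# energy responses, and Poisson spike generation.
#
# A static image is expanded into a short movie (the energy model expects a
# stimulus over time), filtered by a bank of oriented kernels at several
# spatial scales, pooled into phase-invariant complex-cell energy, mapped to
# firing rates, and finally turned into Poisson spike trains that drive the
# V2 layer. Because the movie frames of a static image are identical, the
# temporal kernel is all-pass and the per-frame responses are deduplicated.

.sv_cache <- new.env(parent = emptyenv())

#' Movie stimulus from a static image
#'
#' Replicates a grayscale image into `n_frames` identical frames of
#' `frame_ms` each (defaults: 20 frames x 50 ms = 1000 ms). Intensities are
#' scaled to `[0, 1]`: inputs with any value above 1 are assumed to be on the
#' 0--255 scale and divided by 255.
#'
#' @param image numeric matrix of non-negative intensities.
#' @param n_frames number of frames.
#' @param frame_ms frame duration, ms.
#' @return An object of class `movie_stimulus`.
#' @export
expand_image_to_movie <- function(image, n_frames = 20, frame_ms = 50) {
  image <- as.matrix(image)
  if (length(image) == 0) stop("empty image")
  if (!all(is.finite(image)) || min(image) < 0) stop("image must be finite and non-negative")
  if (n_frames < 1 || frame_ms <= 0) stop("invalid frame count or duration")
  if (max(image) > 1) image <- image / 255
  structure(list(frames = rep(list(image), n_frames), frame_ms = frame_ms),
            class = "movie_stimulus")
}

#' Specification of the V1 filter bank
#'
#' Orientations are uniform over `[0, 180)` degrees; each is replicated at
#' every spatial scale, giving `n_orientations * length(sigmas)` channels per
#' pixel (84 at the defaults, matching the three-scale motion-energy front
#' end). Kernel support is truncated at 3 standard deviations.
#'
#' @param n_orientations number of orientation channels.
#' @param sigmas Gaussian standard deviations of the scales, pixels.
#' @param rate_max ceiling of the complex-cell rate map, Hz.
#' @return An object of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(n_orientations = 28, sigmas = c(1, 2, 4), rate_max = 400) {
  if (n_orientations < 1 || length(sigmas) < 1) stop("need at least one orientation and one scale")
  if (any(sigmas <= 0) || rate_max <= 0) stop("sigmas and rate_max must be positive")
  structure(list(n_orientations = as.integer(n_orientations),
                 sigmas = as.numeric(sigmas), rate_max = rate_max),
            class = "filter_bank_spec")
}

# Oriented quadrature pair at angle theta (degrees): Gaussian along the bar,
# second (even) and third (odd) derivative of a Gaussian across it. Both are
# zero-mean and L2-normalized. theta = 0 prefers horizontal bars; rows are
# mapped to a y-up axis so angles follow the mathematical convention.
.oriented_kernels <- function(theta_deg, sigma) {
  r <- ceiling(3 * sigma)
  x <- matrix(rep(-r:r, each = 2 * r + 1), 2 * r + 1)   # column offset
  y <- matrix(rep(r:-r, times = 2 * r + 1), 2 * r + 1)  # row offset, y up
  th <- theta_deg * pi / 180
  v <- -x * sin(th) + y * cos(th)                       # across-bar coordinate
  u <- x * cos(th) + y * sin(th)
  G <- exp(-(u^2 + v^2) / (2 * sigma^2))
  even <- (v^2 / sigma^4 - 1 / sigma^2) * G
  odd <- (3 * v / sigma^4 - v^3 / sigma^6) * G
  even <- even - mean(even)
  odd <- odd - mean(odd)
  list(even = even / sqrt(sum(even^2)), odd = odd / sqrt(sum(odd^2)))
}

#' Build the oriented filter bank
#'
#' @param spec a [filter_bank_spec()].
#' @return An object of class `filter_bank`: per-channel kernels (`even` and
#'   `odd` quadrature pair, both zero-mean), channel metadata (`angle_deg`,
#'   `sigma`), and the per-channel theoretical response ceiling used to map
#'   energy to firing rates.
#' @export
build_filter_bank <- function(spec = filter_bank_spec()) {
  if (!inherits(spec, "filter_bank_spec")) stop("spec must be a filter_bank_spec")
  angles <- seq(0, 180, length.out = spec$n_orientations + 1)[seq_len(spec$n_orientations)]
  channels <- expand.grid(angle_deg = angles, sigma = spec$sigmas,
                          KEEP.OUT.ATTRS = FALSE)
  channels$channel <- seq_len(nrow(channels))
  kernels <- lapply(seq_len(nrow(channels)), function(i)
    .oriented_kernels(channels$angle_deg[i], channels$sigma[i]))
  # Ceiling of the energy response over images valued in [0, 1]: a response
  # to such an image is at most the sum of the kernel's positive part.
  norm <- vapply(kernels, function(k) {
    sqrt(sum(pmax(k$even, 0))^2 + sum(pmax(k$odd, 0))^2)
  }, numeric(1))
  structure(list(spec = spec, channels = channels, kernels = kernels, norm = norm),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("filter_bank: %d orientations x %d scales = %d channels per pixel\n",
              x$spec$n_orientations, length(x$spec$sigmas), length(x$kernels)))
  invisible(x)
}

# Same-size 2-D cross-correlation with zero padding, via FFT. Used with
# cached kernel FFTs; see .bank_ffts.
.xcorr2_same <- function(img_fft, kern_fft, P, Q, H, W, rc_r, rc_c) {
  full <- Re(stats::fft(img_fft * kern_fft, inverse = TRUE)) / (P * Q)
  full[(rc_r + 1):(rc_r + H), (rc_c + 1):(rc_c + W), drop = FALSE]
}

# FFTs of the 180deg-rotated, zero-padded kernels, grouped by scale (kernel
# size); computed once per (bank, image size) and memoized.
.bank_ffts <- function(bank, H, W) {
  key <- paste("bank", bank$spec$n_orientations,
               paste(bank$spec$sigmas, collapse = "_"), H, W, sep = ":")
  hit <- .sv_cache[[key]]
  if (!is.null(hit)) return(hit)
  sizes <- vapply(bank$kernels, function(k) nrow(k$even), integer(1))
  groups <- split(seq_along(bank$kernels), sizes)
  out <- lapply(groups, function(idx) {
    kh <- nrow(bank$kernels[[idx[1]]]$even)
    P <- H + kh - 1; Q <- W + kh - 1
    pad <- function(k) {
      m <- matrix(0, P, Q)
      m[1:kh, 1:kh] <- k[kh:1, kh:1]
      stats::fft(m)
    }
    list(P = P, Q = Q, rc = (kh - 1) %/% 2, kh = kh, idx = idx,
         ffts = lapply(bank$kernels[idx], function(k)
           list(even = pad(k$even), odd = pad(k$odd))))
  })
  .sv_cache[[key]] <- out
  out
}

# Filter one frame against the whole bank; returns list(even, odd) arrays of
# dim (H, W, n_channels).
.filter_frame <- function(frame, bank) {
  H <- nrow(frame); W <- ncol(frame)
  nchan <- length(bank$kernels)
  groups <- .bank_ffts(bank, H, W)
  even <- array(0, c(H, W, nchan))
  odd <- array(0, c(H, W, nchan))
  for (grp in groups) {
    A <- matrix(0, grp$P, grp$Q)
    A[1:H, 1:W] <- frame
    Af <- stats::fft(A)
    for (j in seq_along(grp$idx)) {
      ch <- grp$idx[j]
      even[, , ch] <- .xcorr2_same(Af, grp$ffts[[j]]$even, grp$P, grp$Q, H, W, grp$rc, grp$rc)
      odd[, , ch] <- .xcorr2_same(Af, grp$ffts[[j]]$odd, grp$P, grp$Q, H, W, grp$rc, grp$rc)
    }
  }
  list(even = even, odd = odd)
}

#' V1 simple-cell responses
#'
#' Same-size zero-padded 2-D cross-correlation of every bank kernel with
#' every movie frame. Identical frames (the common case for a static-image
#' movie) are computed once and shared.
#'
#' @param movie a [expand_image_to_movie()] result.
#' @param bank a [build_filter_bank()] result.
#' @return An object of class `simple_responses`: quadrature `even`/`odd`
#'   response arrays of dim `(H, W, n_channels, n_unique_frames)` plus the
#'   frame-to-unique map.
#' @export
simple_cell_responses <- function(movie, bank) {
  frames <- movie$frames
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  kmax <- max(vapply(bank$kernels, function(k) nrow(k$even), integer(1)))
  if (kmax > H || kmax > W)
    stop(sprintf("kernel support %d exceeds image size %dx%d", kmax, H, W))
  frame_map <- integer(length(frames))
  uniq <- list()
  for (i in seq_along(frames)) {
    hit <- 0L
    for (j in seq_along(uniq)) if (identical(uniq[[j]], frames[[i]])) { hit <- j; break }
    if (hit == 0L) { uniq[[length(uniq) + 1L]] <- frames[[i]]; hit <- length(uniq) }
    frame_map[i] <- hit
  }
  resp <- lapply(uniq, .filter_frame, bank = bank)
  nchan <- length(bank$kernels)
  even <- array(0, c(H, W, nchan, length(uniq)))
  odd <- array(0, c(H, W, nchan, length(uniq)))
  for (j in seq_along(resp)) {
    even[, , , j] <- resp[[j]]$even
    odd[, , , j] <- resp[[j]]$odd
  }
  structure(list(even = even, odd = odd, frame_map = frame_map,
                 channels = bank$channels),
            class = "simple_responses")
}

#' V1 complex-cell responses
#'
#' Pools each quadrature pair into phase-invariant energy
#' `sqrt(even^2 + odd^2)`, averages over frames, and maps energy linearly to
#' firing rates in `[0, rate_max]` Hz by dividing by the per-channel
#' theoretical response ceiling.
#'
#' @param simple a [simple_cell_responses()] result.
#' @param bank the [build_filter_bank()] used to produce it.
#' @return An object of class `v1_response`: `rates` array of dim
#'   `(H, W, n_channels)` in Hz plus channel metadata.
#' @export
complex_cell_responses <- function(simple, bank) {
  rate_max <- bank$spec$rate_max
  dims <- dim(simple$even)
  E <- sqrt(simple$even^2 + simple$odd^2)
  wts <- tabulate(simple$frame_map, nbins = dims[4]) / length(simple$frame_map)
  rates <- array(0, dims[1:3])
  for (j in seq_len(dims[4])) rates <- rates + wts[j] * E[, , , j]
  rates <- sweep(rates, 3, bank$norm, "/") * rate_max
  rates <- pmin(pmax(rates, 0), rate_max)
  structure(list(rates = rates, channels = bank$channels, rate_max = rate_max),
            class = "v1_response")
}

#' Image to V1 rate volume
#'
#' Convenience composition of [expand_image_to_movie()],
#' [simple_cell_responses()] and [complex_cell_responses()].
#'
#' @inheritParams expand_image_to_movie
#' @param bank a [build_filter_bank()] result.
#' @return A `v1_response`.
#' @export
v1_rates <- function(image, bank, n_frames = 20, frame_ms = 50) {
  movie <- expand_image_to_movie(image, n_frames = n_frames, frame_ms = frame_ms)
  complex_cell_responses(simple_cell_responses(movie, bank), bank)
}

#' Poisson spike trains from a rate volume
#'
#' Homogeneous Poisson generation by Bernoulli thinning: each channel/pixel
#' emits a spike in each `dt` bin with probability `rate * dt / 1000`.
#' Channel `c` at pixel `(r, col)` maps to train index
#' `(c - 1) * H * W + (col - 1) * H + r` (column-major pixel order).
#'
#' @param rates a `v1_response` or a non-negative array `(H, W, C)` of rates
#'   in Hz.
#' @param duration train length, ms.
#' @param dt bin width, ms; `rate * dt` must stay below 1000.
#' @param seed RNG seed for reproducible trains.
#' @return A [spike_raster()] over `H * W * C` input channels.
#' @export
rates_to_poisson_spikes <- function(rates, duration = 1000, dt = 1, seed = NULL) {
  if (inherits(rates, "v1_response") || inherits(rates, "orientation_response"))
    rates <- rates$rates
  if (min(rates) < 0) stop("rates must be non-negative")
  if (max(rates) * dt >= 1000) stop("rate * dt must be below 1000")
  if (!is.null(seed)) set.seed(seed)
  dims <- dim(rates)
  npix <- dims[1] * dims[2]
  n_steps <- as.integer(round(duration / dt))
  neuron <- list(); tim <- list()
  for (ch in seq_len(dims[3])) {
    p <- as.vector(rates[, , ch]) * dt / 1000
    if (all(p == 0)) next
    u <- matrix(stats::runif(npix * n_steps), npix, n_steps)
    hit <- which(u < p)  # p recycled down columns: row = pixel
    if (length(hit)) {
      pix <- (hit - 1L) %% npix + 1L
      bin <- (hit - 1L) %/% npix + 1L
      neuron[[length(neuron) + 1L]] <- (ch - 1L) * npix + pix
      tim[[length(tim) + 1L]] <- (bin - 1L) * dt
    }
  }
  spike_raster(unlist(neuron), unlist(tim),
               n_neurons = npix * dims[3], duration = duration)
}
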