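# V1 front end: movie expansion, oriented filter bank, complex-cell energy,
# Poisson generation.

test_that("a static image expands to a 20-frame, 50 ms movie scaled to [0,1]", {
  img <- matrix(0, 28, 28)
  img[10:18, 14] <- 255
  movie <- expand_image_to_movie(img)
  expect_length(movie$frames, 20)
  expect_equal(movie$frame_ms, 50)
  expect_equal(length(movie$frames) * movie$frame_ms, 1000)
  expect_equal(max(movie$frames[[1]]), 1)
  expect_true(all(vapply(movie$frames, identical, logical(1), movie$frames[[1]])))
  # all-zero image stays all-zero; empty image is rejected
  z <- expand_image_to_movie(matrix(0, 5, 5))
  expect_true(all(z$frames[[1]] == 0))
  expect_error(expand_image_to_movie(matrix(numeric(0), 0, 0)), "empty")
})

test_that("the default bank has 84 zero-mean kernels", {
  bank <- default_bank()
  expect_length(bank$kernels, 84)
  expect_equal(nrow(bank$channels), 28 * 3)
  sums <- vapply(bank$kernels, function(k) c(sum(k$even), sum(k$odd)), numeric(2))
  expect_lt(max(abs(sums)), 1e-6)
  expect_error(build_filter_bank(filter_bank_spec(0)), "at least one")
})

test_that("kernels at orthogonal angles are 90-degree rotations of each other", {
  bank <- default_bank()
  ch <- bank$channels
  rot90 <- function(m) t(m)[, nrow(m):1] # counterclockwise quarter turn
  for (k in c(1, 5, 12)) {
    # 28 orientations over 180 degrees: +90 degrees = +14 channels
    a <- bank$kernels[[k]]
    b <- bank$kernels[[k + 14]]
    expect_equal(ch$angle_deg[k + 14], ch$angle_deg[k] + 90)
    d1 <- max(abs(b$odd - rot90(a$odd)))
    d2 <- max(abs(b$odd - rot90(rot90(rot90(a$odd)))))
    expect_lt(min(d1, d2), 1e-8)
  }
})

test_that("simple-cell responses equal brute-force correlation and are linear", {
  bank <- small_bank()
  set.seed(3)
  img <- matrix(runif(28 * 28), 28)
  movie <- expand_image_to_movie(img, n_frames = 1)
  resp <- simple_cell_responses(movie, bank)
  # brute-force zero-padded cross-correlation for one channel
  k <- bank$kernels[[3]]$odd
  r <- (nrow(k) - 1) / 2
  brute <- matrix(0, 28, 28)
  for (row in 1:28) for (col in 1:28) {
    s <- 0
    for (dy in -r:r) for (dx in -r:r) {
      rr <- row + dy; cc <- col + dx
      if (rr >= 1 && rr <= 28 && cc >= 1 && cc <= 28)
        s <- s + img[rr, cc] * k[dy + r + 1, dx + r + 1]
    }
    brute[row, col] <- s
  }
  expect_lt(max(abs(resp$odd[, , 3, 1] - brute)), 1e-10)
  # zero movie -> zero responses; doubling contrast doubles responses
  z <- simple_cell_responses(expand_image_to_movie(matrix(0, 28, 28), 2), bank)
  expect_true(all(z$even == 0) && all(z$odd == 0))
  resp2 <- simple_cell_responses(expand_image_to_movie(img / 2, 1), bank)
  expect_equal(resp$odd, 2 * resp2$odd, tolerance = 1e-10)
  # oversized kernel is rejected
  big <- build_filter_bank(filter_bank_spec(2, sigmas = 12))
  expect_error(simple_cell_responses(movie, big), "exceeds image size")
})

test_that("a vertical bar maximally drives a vertically tuned channel", {
  bank <- default_bank()
  v1 <- v1_rates(bar_image(90), bank)
  best <- which.max(apply(v1$rates, 3, sum))
  expect_equal(bank$channels$angle_deg[best], 90)
})

test_that("complex responses have 84 channels within [0, 400] Hz", {
  bank <- default_bank()
  v1 <- v1_rates(bar_image(45), bank)
  expect_equal(dim(v1$rates), c(28, 28, 84))
  expect_gte(min(v1$rates), 0)
  expect_lte(max(v1$rates), 400)
  expect_true(all(is.finite(v1$rates)))
  # zero image -> zero rates
  z <- v1_rates(matrix(0, 28, 28), bank)
  expect_true(all(z$rates == 0))
})

test_that("rotating a bar by one angular step shifts the argmax channel by one", {
  # asserted at the coarsest scale: on a 28x28 grid only that scale's
  # support can express a 6.4-degree rotation without pixel-grid snapping
  bank <- default_bank()
  idx <- which(bank$channels$sigma == 4)
  step <- 180 / 28
  for (k0 in c(2, 9, 16, 23)) {
    a0 <- (k0 - 1) * step
    i1 <- which.max(apply(v1_rates(bar_image(a0, length = 24), bank)$rates[, , idx], 3, sum))
    i2 <- which.max(apply(v1_rates(bar_image(a0 + step, length = 24), bank)$rates[, , idx], 3, sum))
    expect_equal(i1, k0)
    expect_equal(i2, k0 %% 28 + 1)
  }
})

test_that("Poisson trains recover the requested rate and are seed-deterministic", {
  rates <- array(0, c(2, 2, 1))
  rates[1, 1, 1] <- 100
  # count over many repetitions: 99% binomial interval around 100 per second
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(i) {
    nrow(rates_to_poisson_spikes(rates, duration = 1000, dt = 1, seed = 1000 + i))
  }, numeric(1))
  p <- 100 / 1000
  ci <- qbinom(c(0.005, 0.995), size = 1000 * n_rep, prob = p)
  expect_gte(sum(counts), ci[1])
  expect_lte(sum(counts), ci[2])
  # empirical rate within 5% at a 10 s horizon
  long <- rates_to_poisson_spikes(rates, duration = 10000, dt = 1, seed = 7)
  expect_lt(abs(nrow(long) / 10 - 100) / 100, 0.05)
  # zero rate -> empty train; same seed -> identical trains
  expect_equal(nrow(rates_to_poisson_spikes(array(0, c(2, 2, 1)), 1000, seed = 1)), 0)
  a <- rates_to_poisson_spikes(rates, 500, seed = 11)
  b <- rates_to_poisson_spikes(rates, 500, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(rates_to_poisson_spikes(array(-1, c(1, 1, 1)), 100), "non-negative")
})
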