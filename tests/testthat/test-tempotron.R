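# Tempotron kernel, membrane integration, the P+/P- update and multiclass
# training.


test_that("the kernel normalization constant matches dense grid maximization", {
  v0 <- compute_v0(16, 4)
  expect_equal(round(v0, 2), 2.12)
  grid <- seq(0.001, 100, by = 0.001)
  k <- psp_kernel(grid, 0, kernel_params(16, 4))
  expect_lt(abs(max(k) - 1), 1e-4)
  expect_equal(grid[which.max(k)], kernel_peak_time(16, 4), tolerance = 1e-3)
  # holds for other tau > tau_s pairs, including the tau = 2 tau_s regime
  for (pair in list(c(8, 4), c(20, 3), c(10, 9))) {
    kp <- kernel_params(pair[1], pair[2])
    kk <- psp_kernel(grid, 0, kp)
    expect_lt(abs(max(kk) - 1), 1e-4)
    # grid maximizer agrees with the closed-form peak time
    expect_equal(grid[which.max(kk)], kernel_peak_time(pair[1], pair[2]),
                 tolerance = 1e-2)
  }
  expect_error(compute_v0(4, 16), "tau > tau_s")
})

test_that("the PSP kernel is causal and decays to zero", {
  kp <- kernel_params()
  expect_equal(psp_kernel(c(0, 5, 10), t_i = 10, kp), c(0, 0, 0))
  expect_equal(psp_kernel(10 + kernel_peak_time(16, 4), 10, kp), 1, tolerance = 1e-12)
  expect_lt(psp_kernel(10 + 500, 10, kp), 1e-10)
})

test_that("membrane traces match the brute-force double-sum oracle", {
  set.seed(8)
  kp <- kernel_params()
  worst <- 0
  for (rep in 1:100) {
    n <- 50
    f <- runif(n)
    f[sample(n, 5)] <- 0 # a few inactive afferents
    pat <- encode_latency(f, T = 400)
    w <- rnorm(n, 0, 0.05)
    tr <- membrane_trace(pat, w, kp, dt_eval = 1)
    act <- which(pat$active)
    ref <- brute_voltage(tr$times, pat$times[act], w[act], 16, 4, kp$v0)
    worst <- max(worst, max(abs(tr$v_unshunted - ref)))
  }
  expect_lt(worst, 1e-9)
})

test_that("a unit-weight single spike reaches exactly threshold", {
  pat <- encode_latency(c(0.75), T = 400) # one spike at 100 ms
  kp <- kernel_params()
  tr <- membrane_trace(pat, 1, kp, dt_eval = 0.01)
  expect_equal(max(tr$v_unshunted), 1, tolerance = 1e-4)
  expect_equal(find_tmax(tr, refine = TRUE), 100 + kernel_peak_time(16, 4),
               tolerance = 0.01)
  # grid t_max without refinement lands on the nearest grid point
  tr1 <- membrane_trace(pat, 1, kp, dt_eval = 1)
  expect_equal(find_tmax(tr1), 107)
})

test_that("no input spikes give a flat trace at rest with t_max at the origin", {
  pat <- encode_latency(rep(0, 10), T = 400)
  tr <- membrane_trace(pat, rep(1, 10))
  expect_true(all(tr$v == 0))
  expect_true(is.na(tr$spike_time))
  expect_equal(find_tmax(tr), 0) # earliest tie on a flat trace
  expect_error(membrane_trace(pat, rep(1, 3)), "does not match")
})

test_that("a trace still rising at the window edge peaks at the final grid point", {
  # a spike 1 ms before the window edge: its kernel peaks ~7.4 ms later,
  # outside the window, so the voltage is still rising at T
  pat <- encode_latency(1 - 399 / 400, T = 400)
  tr <- membrane_trace(pat, 1)
  expect_equal(find_tmax(tr), 400)
})

test_that("shunting freezes out inputs arriving after the output spike", {
  kp <- kernel_params()
  f <- c(0.9, 0.8, 0.2) # spikes at 40, 80, 320 ms
  pat <- encode_latency(f, T = 400)
  w <- c(1.2, 1.2, 5)
  tr <- membrane_trace(pat, w, kp)
  expect_false(is.na(tr$spike_time))
  expect_lt(tr$spike_time, 320)
  # after the output spike the trace ignores the late heavy spike
  late <- tr$times > 330
  expect_true(all(tr$v[late] < kp$v_threshold))
  expect_gt(max(tr$v_unshunted[late]), 1) # unshunted trace would cross again
})

test_that("the weight update obeys the error-correcting contract", {
  set.seed(12)
  f <- runif(30); f[1:3] <- 0
  pat <- encode_latency(f, T = 400)
  kp <- kernel_params()
  # no error or zero learning rate: no change
  expect_equal(weight_update(pat, "none", t_max = 200), rep(0, 30))
  expect_equal(weight_update(pat, "P+", t_max = 200, lambda = 0), rep(0, 30))
  dw <- weight_update(pat, "P+", t_max = 200, lambda = 0.001, params = kp)
  expect_true(all(dw >= 0))
  # afferents spiking at or after t_max contribute nothing
  expect_true(all(dw[pat$times >= 200] == 0))
  expect_true(any(dw[pat$times < 200 & pat$active] > 0))
  # inactive afferents (edge spikes) never contribute
  expect_true(all(dw[!pat$active] == 0))
  # P- mirrors P+ with opposite sign
  dm <- weight_update(pat, "P-", t_max = 200, lambda = 0.001, params = kp)
  expect_equal(dm, -dw)
  expect_error(weight_update(pat, "P+", t_max = 500), "t_max")
})

test_that("a single P+ update strictly raises the labeled output's peak", {
  set.seed(23)
  f <- runif(40)
  pat <- encode_latency(f, T = 400)
  model <- tempotron_model(40, classes = 0:1, T = 400)
  peak0 <- output_peaks(model, pat)[["0"]]
  tr <- membrane_trace(pat, model$W[, 1], model$kernel)
  dw <- weight_update(pat, "P+", find_tmax(tr), lambda = model$lambda,
                      params = model$kernel)
  model$W[, 1] <- model$W[, 1] + dw
  expect_gt(output_peaks(model, pat)[["0"]], peak0)
})

test_that("training initializes weights at 0.001 and leaves correct samples alone", {
  model <- tempotron_model(20, classes = 0:1)
  expect_true(all(model$W == 0.001))
  expect_equal(dim(model$W), c(20, 2))
  # one strongly separable pair, trained to convergence
  set.seed(4)
  f0 <- c(runif(10, 0.7, 1), rep(0, 10))
  f1 <- c(rep(0, 10), runif(10, 0.7, 1))
  pats <- list(encode_latency(f0), encode_latency(f1))
  fit <- train_multiclass(model, pats, c(0, 1), max_epochs = 200, seed = 1)
  expect_equal(utils::tail(fit$record$epoch_errors, 1), 0L)
  # a converged model is a fixed point: retraining changes nothing
  fit2 <- train_multiclass(fit$model, pats, c(0, 1), max_epochs = 1, seed = 2)
  expect_equal(fit2$model$W, fit$model$W)
  expect_equal(fit2$record$p_plus, c(0L, 0L))
  expect_equal(fit2$record$p_minus, c(0L, 0L))
  # and classifies its training set perfectly
  expect_equal(classify(fit$model, pats[[1]]), 0)
  expect_equal(classify(fit$model, pats[[2]]), 1)
  expect_error(train_multiclass(model, list(), integer(0)), "empty")
})

test_that("ties in peak voltage resolve to the lowest class index", {
  pat <- encode_latency(rep(0, 5))
  model <- tempotron_model(5, classes = 0:9, w_init = 0) # all peaks 0
  expect_equal(classify(model, pat), 0)
  # determinism of prediction
  set.seed(31)
  f <- runif(5)
  p2 <- encode_latency(f)
  model2 <- tempotron_model(5, classes = 0:9)
  expect_identical(classify(model2, p2), classify(model2, p2))
})

test_that("random separable single-spike tasks train to zero error", {
  # capacity sanity at small scale: K patterns over 100 afferents
  set.seed(77)
  ok <- 0
  for (rep in 1:3) {
    pats <- lapply(1:10, function(i) {
      f <- numeric(100)
      f[sample(100, 15)] <- runif(15, 0.3, 1)
      encode_latency(f, T = 400)
    })
    labs <- rep(0:4, each = 2)
    model <- tempotron_model(100, classes = 0:4)
    fit <- train_multiclass(model, pats, labs, max_epochs = 500, seed = rep)
    if (utils::tail(fit$record$epoch_errors, 1) == 0L) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("model checkpoints round-trip and reproduce classification", {
  set.seed(9)
  model <- tempotron_model(25, classes = 0:3, lambda = 0.002, T = 300)
  model$W <- matrix(runif(100), 25, 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$W, model$W)
  expect_equal(back$classes, model$classes)
  expect_equal(back$kernel$v0, model$kernel$v0)
  expect_equal(back$T, model$T)
  f <- runif(25)
  expect_identical(classify(back, encode_latency(f, 300)),
                   classify(model, encode_latency(f, 300)))
})
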