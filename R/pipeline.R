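# Pipeline orchestration: preprocess (image -> V2 orientation rates, with
# caching), latency encoding, tempotron training, evaluation and parameter
# sweeps. A single top-level seed is split into independent per-stage
# substreams so dataset generation, Poisson sampling and presentation order
# are reproducible without coupling.

#' Derive a per-stage RNG seed
#'
#' @param seed top-level seed.
#' @param stage small integer identifying the stage.
#' @return A derived seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + 101 * stage) %% 2147483629)
}

#' Pipeline configuration
#'
#' Defaults are the model's operating point: encoding window `T = 400` ms,
#' learning rate `lambda = 0.001`, four orientation pools, 1 ms integration
#' and voltage-grid steps.
#'
#' @param T latency-encoding window, ms.
#' @param lambda tempotron learning rate.
#' @param n_directions V2 pool count (2, 4 or 8).
#' @param dt spiking integration step, ms.
#' @param dt_eval tempotron voltage grid step, ms.
#' @param duration spiking-path simulation window per image, ms.
#' @param seed top-level seed.
#' @param normalization latency normalization mode (see [normalize_rates()]).
#' @param preprocess `"rate"` (deterministic shortcut) or `"spiking"` (full
#'   Poisson + Izhikevich path).
#' @param max_inner,max_epochs tempotron training caps.
#' @param bank_spec a [filter_bank_spec()].
#' @param layer_spec an [orientation_layer_spec()]; built from `n_directions`
#'   when omitted.
#' @param tau,tau_s,w_init tempotron kernel constants and initial weight.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(T = 400, lambda = 0.001, n_directions = 4,
                            dt = 1, dt_eval = 1, duration = 1000, seed = 1,
                            normalization = "per_image",
                            preprocess = c("rate", "spiking"),
                            max_inner = 100, max_epochs = 5,
                            bank_spec = filter_bank_spec(),
                            layer_spec = NULL,
                            tau = 16, tau_s = 4, w_init = 0.001) {
  preprocess <- match.arg(preprocess)
  if (is.null(layer_spec)) layer_spec <- orientation_layer_spec(n_directions)
  structure(list(T = T, lambda = lambda, n_directions = layer_spec$n_directions,
                 dt = dt, dt_eval = dt_eval, duration = duration, seed = seed,
                 normalization = normalization, preprocess = preprocess,
                 max_inner = max_inner, max_epochs = max_epochs,
                 bank_spec = bank_spec, layer_spec = layer_spec,
                 tau = tau, tau_s = tau_s, w_init = w_init),
            class = "pipeline_config")
}

# Fingerprint of everything that determines preprocessing output.
.prep_fingerprint <- function(config) {
  ls <- config$layer_spec; bs <- config$bank_spec
  paste("prep", config$preprocess, ls$n_directions, ls$sigma_deg, ls$inhibition,
        ls$weight_scale, ls$rate_max, bs$n_orientations,
        paste(bs$sigmas, collapse = "_"), bs$rate_max,
        config$dt, config$duration, config$seed, sep = "|")
}

#' Preprocess a dataset into cached V2 orientation rates
#'
#' Computes the V2 rate map of every image, either through the deterministic
#' rate-based shortcut or through the full Poisson + spiking path, and
#' returns them as a sample-by-neuron matrix. When `cache` names a file and
#' it holds a store with a matching configuration fingerprint, the
#' computation is skipped and the store is loaded (idempotence); a corrupt or
#' stale cache triggers recomputation with a warning. Feather is used when
#' the `arrow` package is installed and the path ends in `.feather`,
#' otherwise CSV.
#'
#' @param dataset a [labeled_image_set()].
#' @param config a [pipeline_config()].
#' @param cache optional cache file path.
#' @param verbose print progress.
#' @return An `orientation_store`: `rates` matrix (`n x pixels*n_directions`,
#'   Hz), `labels`, the preprocessing fingerprint, and attribute
#'   `"from_cache"` saying whether computation was skipped.
#' @export
run_preprocess <- function(dataset, config = pipeline_config(), cache = NULL,
                           verbose = FALSE) {
  fp <- .prep_fingerprint(config)
  if (!is.null(cache) && file.exists(cache)) {
    store <- tryCatch(load_store(cache), error = function(e) {
      warning("cache unreadable, recomputing: ", conditionMessage(e))
      NULL
    })
    if (!is.null(store)) {
      if (identical(store$fingerprint, fp) &&
          nrow(store$rates) == dim(dataset$images)[1]) {
        attr(store, "from_cache") <- TRUE
        return(store)
      }
      warning("cache fingerprint mismatch, recomputing")
    }
  }
  bank <- build_filter_bank(config$bank_spec)
  spec <- config$layer_spec
  n <- dim(dataset$images)[1]
  npix <- prod(spec$grid)
  rates <- matrix(0, n, npix * spec$n_directions)
  conn <- if (config$preprocess == "spiking") build_v2_projection(spec, bank)
  for (i in seq_len(n)) {
    img <- get_image(dataset, i)
    if (config$preprocess == "rate") {
      resp <- rate_based_shortcut(img, spec, bank)
    } else {
      v1 <- v1_rates(img, bank)
      spikes <- rates_to_poisson_spikes(v1, duration = config$duration,
                                        dt = config$dt,
                                        seed = derive_seed(config$seed, 7 + i))
      raster <- simulate_v2(conn, spikes, duration = config$duration, dt = config$dt)
      resp <- measure_rates(raster, config$duration, spec)
    }
    rates[i, ] <- as.vector(resp$rates)
    if (verbose && i %% 50 == 0) message(sprintf("preprocessed %d/%d", i, n))
  }
  store <- structure(list(rates = rates, labels = dataset$labels,
                          fingerprint = fp, n_directions = spec$n_directions),
                     class = "orientation_store")
  attr(store, "from_cache") <- FALSE
  if (!is.null(cache)) save_store(store, cache)
  store
}

#' Save / load an orientation store
#'
#' The rate matrix goes to Feather (if `arrow` is installed and the path
#' ends in `.feather`) or CSV; labels and the configuration fingerprint go
#' to a JSON sidecar (`<path>.json`).
#'
#' @param store an `orientation_store`.
#' @param path file path.
#' @export
save_store <- function(store, path) {
  df <- as.data.frame(store$rates)
  if (grepl("\\.feather$", path) && requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_feather(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  jsonlite::write_json(list(fingerprint = store$fingerprint,
                            labels = store$labels,
                            n_directions = store$n_directions),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- if (grepl("\\.feather$", path) && requireNamespace("arrow", quietly = TRUE)) {
    as.data.frame(arrow::read_feather(path))
  } else {
    utils::read.csv(path)
  }
  rates <- as.matrix(df)
  dimnames(rates) <- NULL
  structure(list(rates = rates, labels = as.integer(meta$labels),
                 fingerprint = meta$fingerprint,
                 n_directions = meta$n_directions),
            class = "orientation_store")
}

# Latency patterns of every store row.
.store_patterns <- function(store, config) {
  lapply(seq_len(nrow(store$rates)), function(i)
    latency_encode(store$rates[i, ], T = config$T,
                   method = config$normalization,
                   rate_max = config$layer_spec$rate_max))
}

#' Train the tempotron on a preprocessed store
#'
#' Latency-encodes every cached V2 response and trains the multiclass
#' tempotron. Output classes default to the labels present in the store.
#'
#' @param store an `orientation_store` from [run_preprocess()].
#' @param config a [pipeline_config()].
#' @param classes output classes (defaults to `sort(unique(labels))`).
#' @param log_path optional CSV path for the per-sample training log.
#' @return `list(model, record, log)`; the model carries the preprocessing
#'   fingerprint for compatibility checks at evaluation time.
#' @export
run_train <- function(store, config = pipeline_config(), classes = NULL,
                      log_path = NULL) {
  if (!inherits(store, "orientation_store"))
    stop("store must come from run_preprocess()")
  labels <- store$labels
  if (is.null(classes)) classes <- sort(unique(labels))
  patterns <- .store_patterns(store, config)
  model <- tempotron_model(n_afferents = ncol(store$rates), classes = classes,
                           kernel = kernel_params(config$tau, config$tau_s),
                           lambda = config$lambda, T = config$T,
                           w_init = config$w_init, dt_eval = config$dt_eval)
  fit <- train_multiclass(model, patterns, labels,
                          max_inner = config$max_inner,
                          max_epochs = config$max_epochs,
                          seed = derive_seed(config$seed, 2))
  fit$model$fingerprint <- store$fingerprint
  log <- data.frame(sample = seq_along(labels), label = labels,
                    p_plus_iters = fit$record$p_plus,
                    p_minus_iters = fit$record$p_minus)
  if (!is.null(log_path)) utils::write.csv(log, log_path, row.names = FALSE)
  list(model = fit$model, record = fit$record, log = log)
}

#' Evaluate a trained model on a preprocessed store
#'
#' Weights are frozen; every sample is latency-encoded and classified by
#' argmax peak voltage. Refuses to evaluate against a store whose
#' preprocessing fingerprint differs from the one the model was trained on.
#'
#' @param model a trained [tempotron_model()].
#' @param store an `orientation_store` of the evaluation set.
#' @param config a [pipeline_config()].
#' @return An `eval_report`: `accuracy`, `confusion` (rows = truth),
#'   `n`, `predictions`, `fingerprint`.
#' @export
run_evaluate <- function(model, store, config = pipeline_config()) {
  if (!is.null(model$fingerprint) &&
      !identical(model$fingerprint, store$fingerprint))
    stop("model and store come from different preprocessing configurations")
  labels <- store$labels
  if (!all(labels %in% model$classes)) stop("store labels outside the model's classes")
  patterns <- .store_patterns(store, config)
  pred <- vapply(patterns, function(p) classify(model, p), model$classes[1])
  confusion <- table(truth = factor(labels, levels = model$classes),
                     predicted = factor(pred, levels = model$classes))
  structure(list(accuracy = mean(pred == labels), confusion = confusion,
                 n = length(labels), predictions = pred,
                 fingerprint = store$fingerprint),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.3f on %d samples\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Run the full pipeline on a train/test pair
#'
#' @param train_set,test_set [labeled_image_set()]s.
#' @param config a [pipeline_config()].
#' @param cache_train,cache_test optional cache paths.
#' @return `list(model, report, log)`.
#' @export
run_pipeline <- function(train_set, test_set, config = pipeline_config(),
                         cache_train = NULL, cache_test = NULL) {
  tr <- run_preprocess(train_set, config, cache = cache_train)
  te <- run_preprocess(test_set, config, cache = cache_test)
  fit <- run_train(tr, config)
  report <- run_evaluate(fit$model, te, config)
  list(model = fit$model, report = report, log = fit$log)
}

#' Parameter sweep
#'
#' Re-trains and re-evaluates the pipeline for each value of one parameter,
#' sharing seeds and, where the parameter does not affect preprocessing
#' (`T`, `lambda`, `n_train`, `n_test`), sharing the preprocessed stores.
#'
#' @param train_set,test_set [labeled_image_set()]s.
#' @param parameter one of `"T"`, `"lambda"`, `"n_directions"`, `"n_train"`,
#'   `"n_test"`.
#' @param values vector of parameter values.
#' @param config base [pipeline_config()].
#' @return A data frame with one row per value: `parameter`, `value`,
#'   `accuracy`, `n_train`, `n_test`.
#' @export
run_sweep <- function(train_set, test_set, parameter, values,
                      config = pipeline_config()) {
  parameter <- match.arg(parameter,
                         c("T", "lambda", "n_directions", "n_train", "n_test"))
  if (length(values) == 0) stop("no sweep values")
  reuse_prep <- parameter != "n_directions"
  tr <- te <- NULL
  if (reuse_prep) {
    tr <- run_preprocess(train_set, config)
    te <- run_preprocess(test_set, config)
  }
  rows <- lapply(values, function(v) {
    cfg <- config
    if (parameter %in% c("T", "lambda")) cfg[[parameter]] <- v
    if (parameter == "n_directions") {
      cfg$layer_spec <- orientation_layer_spec(v)
      cfg$n_directions <- as.integer(v)
    }
    trv <- tr; tev <- te
    if (!reuse_prep) {
      trv <- run_preprocess(train_set, cfg)
      tev <- run_preprocess(test_set, cfg)
    }
    if (parameter == "n_train") trv <- .subset_store(trv, v, cfg$seed)
    if (parameter == "n_test") tev <- .subset_store(tev, v, cfg$seed)
    fit <- run_train(trv, cfg, classes = sort(unique(trv$labels)))
    rep <- run_evaluate(fit$model, tev, cfg)
    data.frame(parameter = parameter, value = v, accuracy = rep$accuracy,
               n_train = nrow(trv$rates), n_test = nrow(tev$rates))
  })
  do.call(rbind, rows)
}

# Class-balanced seeded subset of a store.
.subset_store <- function(store, n, seed) {
  if (n >= nrow(store$rates)) return(store)
  set.seed(derive_seed(seed, 3))
  cls <- unique(store$labels)
  per <- max(1, floor(n / length(cls)))
  idx <- unlist(lapply(cls, function(cl) {
    i <- which(store$labels == cl)
    sample(i, min(per, length(i)))
  }))
  out <- store
  out$rates <- store$rates[idx, , drop = FALSE]
  out$labels <- store$labels[idx]
  out
}
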