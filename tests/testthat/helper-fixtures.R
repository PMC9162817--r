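# Shared fixtures.  Expensive objects (simulated datasets, trained models)
# are built once per test run and cached in this environment; everything is
# generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), .fixture_cache)
  }
  get(key, .fixture_cache, inherits = FALSE)
}

easy_dataset <- function() {
  cached("easy_ds", function() simulate_dataset(sway_params("easy", seed = 7)))
}

hard_dataset <- function() {
  cached("hard_ds", function() simulate_dataset(sway_params("hard", seed = 7)))
}

# standardized T1 train/test sets on the easy dataset
easy_t1_sets <- function() {
  cached("easy_t1", function() {
    data <- build_task(cop_tasks()$T1, easy_dataset(), seed = 7)
    z <- standardize(data$train, data$test)
    list(train = z$train, test = z$test)
  })
}

# an MSRC model trained on easy T1 (moderate length run; reused by the
# class-recovery and feature-visualization checks)
easy_trained_msrc <- function() {
  cached("easy_msrc", function() {
    sets <- easy_t1_sets()
    cfg <- train_config(epochs = 20, repeats = 3, seed = 7)
    copnet:::run_on_sets(sets$train, sets$test, model_spec("MSRC"), cfg,
                         tag = "T1-MSRC-fixture", store_features = TRUE)
  })
}

# short synthetic recording built directly from white noise (no simulator),
# for windowing/task plumbing tests
toy_recording <- function(sid, n = 2200L, seed = 1L, sd = 1) {
  level <- substr(sid, 1L, 1L)
  copnet:::with_seed(seed + nchar(sid), {
    cop_recording(sid, level, rnorm(n, sd = sd), rnorm(n, sd = sd))
  })
}

# small random sample_set with balanced labels
toy_sample_set <- function(n = 12L, n_in = 20L, seed = 1L) {
  copnet:::with_seed(seed, {
    sample_set(array(rnorm(2 * n_in * n), c(2L, n_in, n)),
               rep(0:2, length.out = n),
               rep(c("H#1", "M#1", "N#1"), length.out = n))
  })
}

# multi-channel oracle: same-padded conv of a [C, N] matrix with kernels
# W [C, K, F] via the naive single-series ops, channel contributions summed
oracle_conv_same_multi <- function(x_mat, W, b) {
  f_n <- dim(W)[3L]
  out <- matrix(0, f_n, ncol(x_mat))
  for (f in seq_len(f_n)) {
    acc <- rep(b[f], ncol(x_mat))
    for (ch in seq_len(nrow(x_mat))) {
      acc <- acc + conv1d_same(x_mat[ch, ], W[ch, , f])
    }
    out[f, ] <- acc
  }
  out
}
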