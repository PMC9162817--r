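# Training loop mechanics, evaluation rules, and the sweep helpers
# (kept small: a tiny model on a tiny synthetic problem).

tiny_spec <- function() {
  model_spec("DSCNN", n_in = 40L, filters = 4L, single_scale_kernel = 5L,
             fc_hidden = 16L, blocks_per_branch = 1L)
}

# easily separable 2-class-style sample set: per-class variance differs a lot
tiny_sets <- function(n_per_class = 30L, seed = 5L) {
  copnet:::with_seed(seed, {
    make <- function(cls, sdv) {
      sample_set(array(rnorm(2 * 40 * n_per_class, sd = sdv),
                       c(2, 40, n_per_class)),
                 rep(cls, n_per_class),
                 rep(paste0(c("H", "M", "N")[cls + 1], "#1"), n_per_class))
    }
    train <- copnet:::bind_sample_sets(list(make(0L, 0.3), make(1L, 1),
                                            make(2L, 3)))
    test <- copnet:::bind_sample_sets(list(make(0L, 0.3), make(1L, 1),
                                           make(2L, 3)))
    list(train = train, test = test)
  })
}

test_that("mini-batch bookkeeping: 1200 samples at batch 8 give 150 batches", {
  # the short-batch rule: ceiling(n / batch) batches, last one kept
  expect_equal(length(seq.int(1L, 1200L, by = 8L)), 150L)
  # exercised through training: loss history length equals epochs
  sets <- tiny_sets()
  fit <- train_model(build_model(tiny_spec(), 1), sets$train,
                     train_config(epochs = 2, seed = 3), 1)
  expect_length(fit$loss_history, 2L)
  expect_true(all(is.finite(fit$loss_history)))
})

test_that("zero learning rate leaves parameters unchanged", {
  sets <- tiny_sets()
  m <- build_model(tiny_spec(), 2)
  fit <- train_model(m, sets$train,
                     train_config(epochs = 1, learning_rate = 0, seed = 3), 1)
  expect_equal(unlist(fit$model$params), unlist(m$params), tolerance = 0)
})

test_that("training reduces the loss on separable synthetic data", {
  sets <- tiny_sets()
  fit <- train_model(build_model(tiny_spec(), 3), sets$train,
                     train_config(epochs = 25, learning_rate = 2e-3,
                                  seed = 11), 1)
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  ev <- evaluate_model(fit$model, sets$test)
  expect_gt(ev$accuracy, 0.5)
})

test_that("training is reproducible from its seeds", {
  sets <- tiny_sets()
  cfg <- train_config(epochs = 2, seed = 17)
  f1 <- train_model(build_model(tiny_spec(), 4), sets$train, cfg, "r")
  f2 <- train_model(build_model(tiny_spec(), 4), sets$train, cfg, "r")
  expect_identical(f1$loss_history, f2$loss_history)
  expect_equal(unlist(f1$model$params), unlist(f2$model$params),
               tolerance = 0)
})

test_that("validation_fraction records a monitoring loss curve", {
  sets <- tiny_sets()
  fit <- train_model(build_model(tiny_spec(), 5), sets$train,
                     train_config(epochs = 2, seed = 3,
                                  validation_fraction = 0.2), 1)
  expect_length(fit$val_loss_history, 2L)
  expect_true(all(is.finite(fit$val_loss_history)))
})

test_that("evaluation applies the lowest-index tie rule and confusion identity", {
  sets <- tiny_sets(n_per_class = 10L)
  # a model with an all-zero head predicts the uniform distribution;
  # argmax with ties toward the lowest index labels everything class 0
  m <- build_model(tiny_spec(), 6)
  m$params$fc2$W[] <- 0
  m$params$fc2$b[] <- 0
  ev <- evaluate_model(m, sets$test)
  expect_equal(ev$accuracy, 1 / 3)
  expect_equal(unname(colSums(ev$confusion)), c(30, 0, 0))
  # accuracy == trace / total, rows sum to per-class counts
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(unname(rowSums(ev$confusion)), rep(10, 3))

  # accuracy invariant under test-set reordering
  m2 <- build_model(tiny_spec(), 7)
  perm <- rev(seq_len(n_samples(sets$test)))
  ev_a <- evaluate_model(m2, sets$test)
  ev_b <- evaluate_model(m2, copnet:::subset_samples(sets$test, perm))
  expect_equal(ev_a$accuracy, ev_b$accuracy)
})

test_that("run_task averages repeats and is reproducible", {
  recs <- list(`H#1` = toy_recording("H#1", n = 700L, sd = 0.3),
               `M#1` = toy_recording("M#1", n = 700L, sd = 1),
               `N#1` = toy_recording("N#1", n = 700L, sd = 3))
  task <- task_spec("toy", c("H#1", "M#1", "N#1"), n_train = 30L,
                    n_test = 15L)
  cfg <- train_config(epochs = 2, repeats = 2, seed = 5)
  res <- run_task(task, recs, cfg = cfg, spec = tiny_spec())
  expect_length(res$per_repeat_test_accuracy, 2L)
  expect_equal(res$mean_test_accuracy, mean(res$per_repeat_test_accuracy))
  expect_equal(sum(res$confusion), 2 * 15)

  res2 <- run_task(task, recs, cfg = cfg, spec = tiny_spec())
  expect_identical(res$per_repeat_test_accuracy,
                   res2$per_repeat_test_accuracy)
})

test_that("nested subsampling is balanced and truly nested", {
  labels <- rep(0:2, each = 40L)
  idx <- copnet:::nested_subsample_indices(labels, c(6L, 30L, 60L), seed = 9)
  for (i in seq_along(idx)) {
    expect_equal(unname(tabulate(labels[idx[[i]]] + 1L, 3L)),
                 rep(c(2L, 10L, 20L)[i], 3L))
  }
  expect_true(all(idx[[1L]] %in% idx[[2L]]))
  expect_true(all(idx[[2L]] %in% idx[[3L]]))
  expect_error(copnet:::nested_subsample_indices(labels, 300L, 1),
               "insufficient data")
})

test_that("ablation helpers return one row per setting", {
  recs <- list(`H#1` = toy_recording("H#1", n = 700L, sd = 0.3),
               `M#1` = toy_recording("M#1", n = 700L, sd = 1),
               `N#1` = toy_recording("N#1", n = 700L, sd = 3))
  task <- task_spec("toy", c("H#1", "M#1", "N#1"), n_train = 30L,
                    n_test = 15L)
  cfg <- train_config(epochs = 1, repeats = 1, seed = 5)
  base <- model_spec("DSCNN", n_in = 40L, filters = 2L,
                     single_scale_kernel = 5L, fc_hidden = 8L,
                     blocks_per_branch = 1L)
  ft <- ablate_filters(task, recs, filter_counts = c(1L, 2L), cfg = cfg,
                       base_spec = base)
  expect_equal(ft$filters, c(1L, 2L))
  expect_true(all(ft$mean_accuracy >= 0 & ft$mean_accuracy <= 1))

  st <- ablate_samples(task, recs, train_sizes = c(15L, 30L), cfg = cfg,
                       spec = base)
  expect_equal(st$n_train, c(15L, 30L))
})

test_that("divergence is reported with the epoch", {
  sets <- tiny_sets(n_per_class = 5L)
  m <- build_model(tiny_spec(), 8)
  expect_error(
    train_model(m, sets$train,
                train_config(epochs = 2, learning_rate = 1e154, seed = 1), 1),
    "diverged.*epoch")
})
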