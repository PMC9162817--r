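# Mini-batch Adam training, repeat-averaged task evaluation, and the two
# ablation sweeps (filter count, training-set size).

#' Training configuration
#'
#' Defaults follow the standard setup for this problem: mini-batches of 8,
#' 100 epochs, Adam at learning rate 1e-4, cross-entropy loss, and every
#' experiment repeated 3 times with averaged results.
#'
#' @param batch_size Samples per mini-batch.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param repeats Independent training repetitions per experiment.
#' @param seed Integer seed from which shuffling, initialization and dropout
#'   streams are derived.
#' @param validation_fraction Fraction of the training set held out purely
#'   for per-epoch loss monitoring (no early stopping or model selection is
#'   performed, so the default is 0 and the full training set is used).
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, epochs = 100L,
                         learning_rate = 1e-4, repeats = 3L, seed = 1L,
                         validation_fraction = 0,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(batch_size >= 1L, epochs >= 1L, learning_rate >= 0,
            repeats >= 1L, validation_fraction >= 0,
            validation_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "train_config")
}

adam_init <- function(params) {
  # two independent zero trees: the moments are updated in place
  list(m = tree_pmap(function(p) p * 0, list(params)),
       v = tree_pmap(function(p) p * 0, list(params)),
       t = 0L)
}

# In-place fused update: params, m and v must be private copies owned by
# the training loop (train_model deep-copies params before the first step).
adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  c1 <- 1 - cfg$beta1^state$t
  c2 <- 1 - cfg$beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        if (!is.null(p[[i]])) walk(p[[i]], g[[i]], m[[i]], v[[i]])
      }
    } else {
      cpp_adam_update(p, m, v, g, cfg$learning_rate, cfg$beta1, cfg$beta2,
                      cfg$adam_eps, c1, c2)
    }
  }
  walk(params, grads, state$m, state$v)
  list(params = params, state = state)
}

#' Train a model on a sample set
#'
#' Runs `epochs` passes of randomly shuffled mini-batches (a short final
#' batch is kept, not dropped), updating parameters with Adam on the mean
#' cross-entropy of each batch.  Fully reproducible from
#' `(cfg$seed, repeat_tag)`.
#'
#' @param model A [cop_model()][build_model()].
#' @param train A [sample_set()].
#' @param cfg A [train_config()].
#' @param repeat_tag Character or integer distinguishing repeats; seeds the
#'   shuffle/dropout stream together with `cfg$seed`.
#' @return List with the trained `model`, `loss_history` (mean training
#'   loss per epoch) and, if `validation_fraction > 0`, `val_loss_history`.
#' @export
train_model <- function(model, train, cfg = train_config(),
                        repeat_tag = 1L) {
  stopifnot(inherits(model, "cop_model"), inherits(train, "sample_set"),
            n_samples(train) > 0L)
  spec <- model$spec
  # private deep copy: Adam updates these arrays in place
  params <- tree_pmap(function(p) p + 0, list(model$params))
  state <- adam_init(params)
  loss_history <- numeric(cfg$epochs)
  val_history <- if (cfg$validation_fraction > 0) numeric(cfg$epochs)
  with_seed(derive_seed(cfg$seed, paste0("train-", repeat_tag)), {
    n <- n_samples(train)
    train_idx <- seq_len(n)
    val_idx <- integer(0)
    if (cfg$validation_fraction > 0) {
      n_val <- max(1L, floor(cfg$validation_fraction * n))
      val_idx <- sample(train_idx, n_val)
      train_idx <- setdiff(train_idx, val_idx)
    }
    for (e in seq_len(cfg$epochs)) {
      perm <- sample(train_idx)
      starts <- seq.int(1L, length(perm), by = cfg$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + cfg$batch_size - 1L,
                                   length(perm))]
        X <- train$samples[, , idx, drop = FALSE]
        y <- train$labels[idx]
        fw <- model_forward(params, spec, X, training = TRUE,
                            keep_cache = TRUE)
        loss <- mean_cross_entropy(fw$probs, y)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", e)
        }
        batch_losses[bi] <- loss
        dlogits <- (fw$probs - one_hot(y, spec$n_classes)) / length(y)
        grads <- model_backward(params, spec, fw$cache, dlogits)
        upd <- adam_step(params, grads, state, cfg)
        params <- upd$params
        state <- upd$state
      }
      loss_history[e] <- mean(batch_losses)
      if (length(val_idx) > 0L) {
        vp <- model_forward(params, spec,
                            train$samples[, , val_idx, drop = FALSE])$probs
        val_history[e] <- mean_cross_entropy(vp, train$labels[val_idx])
      }
    }
  })
  model$params <- params
  list(model = model, loss_history = loss_history,
       val_loss_history = val_history)
}

#' Evaluate a model on a test set
#'
#' Predictions are the argmax of the softmax output, with ties broken
#' toward the lowest class index.
#'
#' @param model A trained [cop_model()][build_model()].
#' @param test A [sample_set()].
#' @return List with `accuracy` (fraction correct) and `confusion`
#'   (3x3 count matrix, rows = true level, columns = predicted).
#' @export
evaluate_model <- function(model, test) {
  stopifnot(n_samples(test) > 0L)
  probs <- predict(model, test)
  pred <- max.col(probs, ties.method = "first") - 1L
  confusion <- table(
    true = factor(BALANCE_LEVELS[test$labels + 1L], BALANCE_LEVELS),
    predicted = factor(BALANCE_LEVELS[pred + 1L], BALANCE_LEVELS)
  )
  list(accuracy = mean(pred == test$labels),
       confusion = unclass(confusion))
}

run_on_sets <- function(train, test, spec, cfg, tag,
                        store_features = FALSE) {
  accs <- numeric(cfg$repeats)
  histories <- vector("list", cfg$repeats)
  confusion <- matrix(0L, 3L, 3L,
                      dimnames = list(true = BALANCE_LEVELS,
                                      predicted = BALANCE_LEVELS))
  features <- NULL
  for (r in seq_len(cfg$repeats)) {
    model <- build_model(spec,
                         seed = derive_seed(cfg$seed,
                                            paste0("init-", tag, "-", r)))
    fit <- train_model(model, train, cfg,
                       repeat_tag = paste0(tag, "-", r))
    ev <- evaluate_model(fit$model, test)
    accs[r] <- ev$accuracy
    histories[[r]] <- fit$loss_history
    confusion <- confusion + ev$confusion
    if (store_features && r == cfg$repeats) {
      features <- list(matrix = extract_features(fit$model, test),
                       labels = test$labels)
    }
  }
  structure(list(tag = tag, method = spec$kind, spec = spec,
                 per_repeat_test_accuracy = accs,
                 mean_test_accuracy = mean(accs),
                 loss_history = histories, confusion = confusion,
                 features = features),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result %s %s: mean accuracy %.4f (repeats: %s)>\n",
              x$tag, x$method, x$mean_test_accuracy,
              paste(sprintf("%.4f", x$per_repeat_test_accuracy),
                    collapse = ", ")))
  invisible(x)
}

#' Run one task with one method, repeat-averaged
#'
#' Builds the task's train/test sets, trains `cfg$repeats` independently
#' initialized models, evaluates each on the fixed test set, and averages.
#'
#' @param task A [task_spec()].
#' @param recordings Named list of [cop_recording()] or
#'   [simulate_dataset()] output.
#' @param method Architecture kind (see [model_spec()]); ignored when
#'   `spec` is supplied.
#' @param cfg A [train_config()].
#' @param spec Optional explicit [model_spec()] (e.g. for ablations).
#' @param stride Window stride (default `n_in/2`).
#' @param standardize_inputs Z-score both sets with training statistics
#'   (default TRUE; set FALSE for raw pass-through).
#' @param store_features Keep the final repeat's test-set FC features for
#'   visualization.
#' @return A `run_result` with per-repeat and mean test accuracies, loss
#'   histories, and the pooled confusion matrix.
#' @export
run_task <- function(task, recordings, method = "MSRC",
                     cfg = train_config(), spec = NULL, stride = NULL,
                     standardize_inputs = TRUE, store_features = FALSE) {
  if (is.null(spec)) spec <- model_spec(kind = method)
  if (is.null(stride)) stride <- spec$n_in %/% 2L
  data <- build_task(task, recordings, n_in = spec$n_in, stride = stride,
                     seed = cfg$seed)
  if (standardize_inputs) {
    z <- standardize(data$train, data$test)
    data <- list(train = z$train, test = z$test)
  }
  res <- run_on_sets(data$train, data$test, spec, cfg,
                     tag = paste0(task$name, "-", spec$kind),
                     store_features = store_features)
  res$task <- task$name
  res
}

#' Sweep the number of convolutional filters
#'
#' Re-runs a task with identical data and seeds while varying
#' `filters` in the model specification.
#'
#' @param task,recordings,cfg As in [run_task()].
#' @param filter_counts Integer vector of filter counts to try.
#' @param base_spec Template [model_spec()] (default MSRC).
#' @return Data frame with columns `filters` and `mean_accuracy` (plus the
#'   per-repeat accuracies as a list column `per_repeat`).
#' @export
ablate_filters <- function(task, recordings,
                           filter_counts = c(1L, 5L, 10L, 15L, 20L),
                           cfg = train_config(), base_spec = NULL) {
  stopifnot(all(filter_counts >= 1L))
  if (is.null(base_spec)) base_spec <- model_spec("MSRC")
  rows <- lapply(filter_counts, function(fc) {
    spec <- model_spec(kind = base_spec$kind, n_in = base_spec$n_in,
                       kernel_sizes = base_spec$kernel_sizes,
                       blocks_per_branch = base_spec$blocks_per_branch,
                       convs_per_block = base_spec$convs_per_block,
                       filters = fc, pool_size = base_spec$pool_size,
                       fc_hidden = base_spec$fc_hidden,
                       leaky_slope = base_spec$leaky_slope,
                       dropout = base_spec$dropout,
                       residual = base_spec$residual)
    res <- run_task(task, recordings, cfg = cfg, spec = spec)
    data.frame(filters = fc, mean_accuracy = res$mean_test_accuracy)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Nested, class-balanced subsample chain: the index set for a smaller size
# is always a subset of every larger one, so accuracy curves are comparable.
nested_subsample_indices <- function(labels, sizes, seed) {
  stopifnot(all(sizes %% 3L == 0L))
  orders <- with_seed(seed, {
    lapply(0:2, function(cl) sample(which(labels == cl)))
  })
  per_class <- min(lengths(orders))
  lapply(sizes, function(sz) {
    need <- sz %/% 3L
    if (need > per_class) {
      stop("insufficient data: requested ", sz, " training samples but only ",
           3L * per_class, " are available class-balanced")
    }
    sort(unlist(lapply(orders, head, need)))
  })
}

#' Sweep the training-set size
#'
#' Trains on nested, class-balanced subsamples of the task's training set
#' (each smaller set is contained in every larger one) and evaluates on the
#' fixed full test set.
#'
#' @param task,recordings,cfg As in [run_task()].
#' @param train_sizes Training-set sizes (each divisible by 3).
#' @param spec Model specification (default MSRC).
#' @return Data frame with columns `n_train` and `mean_accuracy`.
#' @export
ablate_samples <- function(task, recordings,
                           train_sizes = c(300L, 600L, 900L, 1200L),
                           cfg = train_config(), spec = NULL) {
  if (is.null(spec)) spec <- model_spec("MSRC")
  data <- build_task(task, recordings, n_in = spec$n_in, seed = cfg$seed)
  z <- standardize(data$train, data$test)
  idx_sets <- nested_subsample_indices(
    z$train$labels, as.integer(train_sizes),
    derive_seed(cfg$seed, paste0("subsample-", task$name))
  )
  rows <- lapply(seq_along(train_sizes), function(i) {
    sub <- subset_samples(z$train, idx_sets[[i]])
    res <- run_on_sets(sub, z$test, spec, cfg,
                       tag = paste0(task$name, "-n", train_sizes[i]))
    data.frame(n_train = train_sizes[i],
               mean_accuracy = res$mean_test_accuracy)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Visualize learned features with t-SNE
#'
#' Embeds the stored FC-layer test features of a run into two dimensions
#' with exact t-SNE, reports the silhouette score of the embedding with
#' respect to the true classes, and builds a scatter plot.
#'
#' @param result A `run_result` produced with `store_features = TRUE`, or a
#'   list with elements `matrix` (features) and `labels`.
#' @param perplexity t-SNE perplexity.
#' @param seed Integer seed for the embedding initialization.
#' @param max_iter t-SNE gradient iterations.
#' @param file Optional path; if given the plot is saved there.
#' @return List with `embedding` (`n x 2` matrix), `silhouette` (mean
#'   silhouette width over the true classes) and `plot` (a ggplot object),
#'   or `NULL` (with a warning) for degenerate features.
#' @export
visualize_features <- function(result, perplexity = 30, seed = 1L,
                               max_iter = 400L, file = NULL) {
  feats <- if (inherits(result, "run_result")) result$features else result
  if (is.null(feats)) {
    stop("no stored features; rerun with store_features = TRUE")
  }
  X <- feats$matrix
  labels <- feats$labels
  stopifnot(nrow(X) >= 10L)
  if (all(apply(X, 2L, function(col) diff(range(col))) < 1e-12)) {
    warning("features are degenerate (all rows identical); skipping plot")
    return(NULL)
  }
  Y <- tsne_embed(X, perplexity = perplexity, max_iter = max_iter,
                  seed = seed)
  sil <- mean(cluster::silhouette(labels + 1L, dist(Y))[, "sil_width"])
  df <- data.frame(dim1 = Y[, 1L], dim2 = Y[, 2L],
                   level = factor(BALANCE_LEVELS[labels + 1L],
                                  BALANCE_LEVELS))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = dim1, y = dim2,
                                        color = level)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = "Level",
                  subtitle = sprintf("silhouette = %.3f", sil)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 5, height = 4)
  list(embedding = Y, silhouette = sil, plot = p)
}
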