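# Declarative model specifications and the network builder.
#
# Five architectures share one interface:
#   MSRC  - the multi-scale residual network: three parallel convolutional
#           branches (kernel sizes 3/10/20), two residual blocks per branch,
#           features concatenated into an FC-128 head.
#   DSCNN - single-scale variant (one branch, middle kernel size).
#   WORES - MSRC with the shortcut connections removed.
#   NN    - one hidden layer of 1000 units on the flattened window.
#   DNN   - hidden layers of 1000/1000/500 units.
# All use Leaky ReLU, dropout before the classifier, and a softmax head.

#' Describe a model architecture
#'
#' @param kind One of `"MSRC"`, `"NN"`, `"DNN"`, `"DSCNN"`, `"WORES"`.
#' @param n_in Input window length in time steps (default 200).
#' @param n_channels Input channels (2: anteroposterior + mediolateral).
#' @param n_classes Number of balance levels (3).
#' @param kernel_sizes Kernel size per convolutional branch (default
#'   `c(3, 10, 20)`: local to global temporal scales).
#' @param blocks_per_branch Residual blocks per branch (default 2).
#' @param convs_per_block Convolution layers inside a block (default 2).
#' @param filters Convolution filters per layer (default 10).
#' @param pool_size Max-pool size applied after each block (default 2).
#' @param fc_hidden Width of the fully connected feature layer (default 128).
#' @param leaky_slope Leaky ReLU negative-side slope (default 0.01).
#' @param dropout Dropout rate applied before the classifier (default 0.2).
#' @param residual Whether blocks carry an additive shortcut; defaults to
#'   `TRUE` except for `"WORES"`.
#' @param single_scale_kernel Kernel size used when `kind = "DSCNN"`
#'   (default 10, the middle scale).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("MSRC", "NN", "DNN", "DSCNN", "WORES"),
                       n_in = 200L, n_channels = 2L, n_classes = 3L,
                       kernel_sizes = c(3L, 10L, 20L),
                       blocks_per_branch = 2L, convs_per_block = 2L,
                       filters = 10L, pool_size = 2L, fc_hidden = 128L,
                       leaky_slope = 0.01, dropout = 0.2, residual = NULL,
                       single_scale_kernel = 10L) {
  kind <- match.arg(kind)
  if (is.null(residual)) residual <- kind != "WORES"
  if (kind == "WORES" && residual) {
    stop("WORES is the no-shortcut ablation; residual must be FALSE")
  }
  if (kind == "DSCNN") kernel_sizes <- single_scale_kernel
  mlp_hidden <- switch(kind, NN = 1000L, DNN = c(1000L, 1000L, 500L),
                       integer(0))
  stopifnot(n_in >= 1L, n_channels >= 1L, n_classes >= 2L,
            all(kernel_sizes >= 1L), blocks_per_branch >= 1L,
            convs_per_block >= 1L, filters >= 1L, pool_size >= 1L,
            fc_hidden >= 1L, leaky_slope > 0, leaky_slope < 1,
            dropout >= 0, dropout < 1)
  spec <- structure(list(kind = kind, n_in = as.integer(n_in),
                         n_channels = as.integer(n_channels),
                         n_classes = as.integer(n_classes),
                         kernel_sizes = as.integer(kernel_sizes),
                         blocks_per_branch = as.integer(blocks_per_branch),
                         convs_per_block = as.integer(convs_per_block),
                         filters = as.integer(filters),
                         pool_size = as.integer(pool_size),
                         fc_hidden = as.integer(fc_hidden),
                         leaky_slope = leaky_slope, dropout = dropout,
                         residual = residual,
                         single_scale_kernel = as.integer(single_scale_kernel)),
                    class = "model_spec")
  if (spec$kind %in% c("MSRC", "DSCNN", "WORES")) branch_out_len(spec)
  spec
}

# pooled length of every branch after all blocks; errors if a branch
# collapses to zero length
branch_out_len <- function(spec) {
  len <- spec$n_in
  for (j in seq_len(spec$blocks_per_branch)) {
    len <- len %/% spec$pool_size
    if (len < 1L) {
      stop("branch with kernel size ", spec$kernel_sizes[1L],
           ": pooled feature length reaches 0 at block ", j,
           " (n_in too short for ", spec$blocks_per_branch,
           " blocks of pool size ", spec$pool_size, ")")
    }
  }
  len
}

is_conv_kind <- function(spec) spec$kind %in% c("MSRC", "DSCNN", "WORES")

#' @export
print.model_spec <- function(x, ...) {
  if (is_conv_kind(x)) {
    cat(sprintf(
      "<model_spec %s: %d branch(es) k=%s, %d blocks x %d convs, %d filters,%s FC-%d>\n",
      x$kind, length(x$kernel_sizes),
      paste(x$kernel_sizes, collapse = "/"), x$blocks_per_branch,
      x$convs_per_block, x$filters,
      if (x$residual) " residual," else " no shortcuts,", x$fc_hidden))
  } else {
    cat(sprintf("<model_spec %s: hidden %s>\n", x$kind,
                paste(switch(x$kind, NN = 1000, DNN = c(1000, 1000, 500)),
                      collapse = "/")))
  }
  invisible(x)
}

init_uniform <- function(dims, fan_in) {
  lim <- sqrt(1 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

#' Build a network from a specification
#'
#' Allocates and seeds all trainable parameters.  Convolution kernels and
#' dense weights use a uniform fan-in initialization
#' (`U[-1/sqrt(fan_in), 1/sqrt(fan_in)]`); biases start at zero.  When a
#' residual block's input and output channel counts differ (the first block
#' maps 2 input channels to `filters`), the shortcut is a trainable
#' 1x1 convolution so the additive bypass is shape-compatible.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the weight draws.
#' @return An object of class `cop_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  params <- with_seed(seed, {
    if (is_conv_kind(spec)) {
      branches <- lapply(spec$kernel_sizes, function(k) {
        c_in <- spec$n_channels
        blocks <- lapply(seq_len(spec$blocks_per_branch), function(j) {
          block_in <- c_in
          convs <- lapply(seq_len(spec$convs_per_block), function(ci) {
            ci_in <- if (ci == 1L) block_in else spec$filters
            conv <- list(W = init_uniform(c(ci_in, k, spec$filters),
                                          ci_in * k),
                         b = numeric(spec$filters))
            conv
          })
          proj <- NULL
          if (spec$residual && block_in != spec$filters) {
            proj <- list(W = init_uniform(c(block_in, 1L, spec$filters),
                                          block_in),
                         b = numeric(spec$filters))
          }
          c_in <<- spec$filters
          list(convs = convs, proj = proj)
        })
        blocks
      })
      d <- length(spec$kernel_sizes) * spec$filters * branch_out_len(spec)
      list(branches = branches,
           fc1 = list(W = init_uniform(c(d, spec$fc_hidden), d),
                      b = numeric(spec$fc_hidden)),
           fc2 = list(W = init_uniform(c(spec$fc_hidden, spec$n_classes),
                                       spec$fc_hidden),
                      b = numeric(spec$n_classes)))
    } else {
      hidden <- switch(spec$kind, NN = 1000L, DNN = c(1000L, 1000L, 500L))
      sizes <- c(spec$n_channels * spec$n_in, hidden, spec$n_classes)
      layers <- lapply(seq_len(length(sizes) - 1L), function(i) {
        list(W = init_uniform(c(sizes[i], sizes[i + 1L]), sizes[i]),
             b = numeric(sizes[i + 1L]))
      })
      list(layers = layers)
    }
  })
  structure(list(spec = spec, params = params, init_seed = as.integer(seed)),
            class = "cop_model")
}

#' @export
print.cop_model <- function(x, ...) {
  cat(sprintf("<cop_model %s, %d trainable parameters>\n", x$spec$kind,
              count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters of a model
#'
#' @param model A [cop_model()][build_model()].
#' @return Total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cop_model"))
  as.integer(tree_sum(model$params, length))
}

# ---- forward / backward ----------------------------------------------------

forward_conv_net <- function(params, spec, X, training = FALSE,
                             keep_cache = FALSE) {
  slope <- spec$leaky_slope
  n <- dim(X)[3L]
  branch_mats <- vector("list", length(params$branches))
  branch_caches <- vector("list", length(params$branches))
  branch_dims <- vector("list", length(params$branches))
  for (b in seq_along(params$branches)) {
    h <- X
    blocks <- params$branches[[b]]
    bl_caches <- vector("list", length(blocks))
    for (j in seq_along(blocks)) {
      blk <- blocks[[j]]
      inp <- h
      cur <- h
      conv_caches <- vector("list", length(blk$convs))
      z_last <- NULL
      for (ci in seq_along(blk$convs)) {
        z <- cpp_conv1d_same_forward(cur, blk$convs[[ci]]$W,
                                     blk$convs[[ci]]$b)
        conv_caches[[ci]] <- list(input = cur, z = z)
        if (ci < length(blk$convs)) cur <- lrelu_arr(z, slope) else z_last <- z
      }
      if (spec$residual) {
        sc <- if (!is.null(blk$proj)) {
          cpp_conv1d_same_forward(inp, blk$proj$W, blk$proj$b)
        } else {
          inp
        }
        s <- z_last + sc
      } else {
        s <- z_last
      }
      a <- lrelu_arr(s, slope)
      pooled <- cpp_maxpool_forward(a, spec$pool_size)
      bl_caches[[j]] <- list(inp = inp, convs = conv_caches, s = s,
                             pool_idx = pooled$idx, len_in = dim(a)[2L],
                             pre_pool = a)
      h <- pooled$y
    }
    branch_dims[[b]] <- dim(h)[1:2]
    branch_mats[[b]] <- flatten_cube(h)
    branch_caches[[b]] <- bl_caches
  }
  feat <- do.call(cbind, branch_mats)
  u <- add_bias_rows(feat %*% params$fc1$W, params$fc1$b)
  fh <- lrelu_arr(u, slope)
  mask <- NULL
  fd <- fh
  if (training && spec$dropout > 0) {
    mask <- (matrix(runif(length(fh)), nrow(fh), ncol(fh)) >= spec$dropout) /
      (1 - spec$dropout)
    fd <- fh * mask
  }
  logits <- add_bias_rows(fd %*% params$fc2$W, params$fc2$b)
  probs <- softmax_rows(logits)
  cache <- NULL
  if (keep_cache) {
    cache <- list(branches = branch_caches, branch_dims = branch_dims,
                  feat = feat, u = u, fd = fd, mask = mask, n = n)
  }
  list(probs = probs, features = fh, cache = cache)
}

backward_conv_net <- function(params, spec, cache, dlogits) {
  slope <- spec$leaky_slope
  g_fc2 <- list(W = crossprod(cache$fd, dlogits), b = colSums(dlogits))
  dfd <- dlogits %*% t(params$fc2$W)
  dfh <- if (is.null(cache$mask)) dfd else dfd * cache$mask
  du <- dfh * lrelu_grad(cache$u, slope)
  g_fc1 <- list(W = crossprod(cache$feat, du), b = colSums(du))
  dfeat <- du %*% t(params$fc1$W)
  g_branches <- vector("list", length(params$branches))
  col0 <- 0L
  for (b in seq_along(params$branches)) {
    fdim <- cache$branch_dims[[b]]
    width <- fdim[1L] * fdim[2L]
    dmat <- dfeat[, (col0 + 1L):(col0 + width), drop = FALSE]
    col0 <- col0 + width
    dh <- unflatten_cube(dmat, fdim[1L], fdim[2L])
    blocks <- params$branches[[b]]
    g_blocks <- vector("list", length(blocks))
    for (j in rev(seq_along(blocks))) {
      blk <- blocks[[j]]
      bc <- cache$branches[[b]][[j]]
      da <- cpp_maxpool_backward(dh, bc$pool_idx, bc$len_in)
      ds <- da * lrelu_grad(bc$s, slope)
      g_proj <- NULL
      d_inp_shortcut <- NULL
      if (spec$residual) {
        if (!is.null(blk$proj)) {
          pb <- cpp_conv1d_same_backward(bc$inp, blk$proj$W, ds)
          g_proj <- list(W = pb$dw, b = as.numeric(pb$db))
          d_inp_shortcut <- pb$dx
        } else {
          d_inp_shortcut <- ds
        }
      }
      g_convs <- vector("list", length(blk$convs))
      dcur <- ds
      for (ci in rev(seq_along(blk$convs))) {
        cc <- bc$convs[[ci]]
        cb <- cpp_conv1d_same_backward(cc$input, blk$convs[[ci]]$W, dcur)
        g_convs[[ci]] <- list(W = cb$dw, b = as.numeric(cb$db))
        if (ci > 1L) {
          dcur <- cb$dx * lrelu_grad(bc$convs[[ci - 1L]]$z, slope)
        } else {
          dcur <- cb$dx
        }
      }
      dh <- if (is.null(d_inp_shortcut)) dcur else dcur + d_inp_shortcut
      g_blocks[[j]] <- list(convs = g_convs, proj = g_proj)
    }
    g_branches[[b]] <- g_blocks
  }
  list(branches = g_branches, fc1 = g_fc1, fc2 = g_fc2)
}

forward_mlp <- function(params, spec, X, training = FALSE,
                        keep_cache = FALSE) {
  slope <- spec$leaky_slope
  d <- dim(X)
  a <- t(matrix(X, d[1L] * d[2L], d[3L]))
  n_layers <- length(params$layers)
  layer_caches <- vector("list", n_layers)
  features <- NULL
  for (i in seq_len(n_layers)) {
    z <- add_bias_rows(a %*% params$layers[[i]]$W, params$layers[[i]]$b)
    if (i < n_layers) {
      h <- lrelu_arr(z, slope)
      features <- h
      mask <- NULL
      out <- h
      if (training && spec$dropout > 0) {
        mask <- (matrix(runif(length(h)), nrow(h), ncol(h)) >=
                   spec$dropout) / (1 - spec$dropout)
        out <- h * mask
      }
      layer_caches[[i]] <- list(input = a, z = z, mask = mask)
      a <- out
    } else {
      layer_caches[[i]] <- list(input = a, z = z, mask = NULL)
      a <- z
    }
  }
  probs <- softmax_rows(a)
  cache <- if (keep_cache) list(layers = layer_caches) else NULL
  list(probs = probs, features = features, cache = cache)
}

backward_mlp <- function(params, spec, cache, dlogits) {
  slope <- spec$leaky_slope
  n_layers <- length(params$layers)
  g_layers <- vector("list", n_layers)
  dcur <- dlogits
  for (i in rev(seq_len(n_layers))) {
    lc <- cache$layers[[i]]
    g_layers[[i]] <- list(W = crossprod(lc$input, dcur), b = colSums(dcur))
    if (i > 1L) {
      dprev <- dcur %*% t(params$layers[[i]]$W)
      pc <- cache$layers[[i - 1L]]
      if (!is.null(pc$mask)) dprev <- dprev * pc$mask
      dcur <- dprev * lrelu_grad(pc$z, slope)
    }
  }
  list(layers = g_layers)
}

model_forward <- function(params, spec, X, training = FALSE,
                          keep_cache = FALSE) {
  if (is_conv_kind(spec)) {
    forward_conv_net(params, spec, X, training, keep_cache)
  } else {
    forward_mlp(params, spec, X, training, keep_cache)
  }
}

model_backward <- function(params, spec, cache, dlogits) {
  if (is_conv_kind(spec)) {
    backward_conv_net(params, spec, cache, dlogits)
  } else {
    backward_mlp(params, spec, cache, dlogits)
  }
}

as_input_array <- function(batch, spec) {
  X <- if (inherits(batch, "sample_set")) batch$samples else batch
  stopifnot(is.array(X), length(dim(X)) == 3L)
  if (dim(X)[1L] != spec$n_channels || dim(X)[2L] != spec$n_in) {
    stop("input shape [", dim(X)[1L], ", ", dim(X)[2L],
         "] does not match spec [", spec$n_channels, ", ", spec$n_in, "]")
  }
  X
}

#' Predict class probabilities
#'
#' Runs the network forward in evaluation mode (dropout disabled); each row
#' of the result is a positive probability vector summing to one.
#'
#' @param object A [cop_model()][build_model()].
#' @param batch A [sample_set()] or array `[2, n_in, n]`.
#' @param chunk_size Samples per forward chunk (bounds memory).
#' @param ... Unused.
#' @return Matrix `[n, n_classes]` of probabilities.
#' @export
predict.cop_model <- function(object, batch, chunk_size = 256L, ...) {
  X <- as_input_array(batch, object$spec)
  n <- dim(X)[3L]
  out <- matrix(0, n, object$spec$n_classes)
  for (i0 in seq.int(1L, n, by = chunk_size)) {
    idx <- i0:min(i0 + chunk_size - 1L, n)
    out[idx, ] <- model_forward(object$params, object$spec,
                                X[, , idx, drop = FALSE])$probs
  }
  out
}

#' Extract learned features at the fully connected layer
#'
#' Returns the post-activation values of the FC feature layer (width
#' `fc_hidden`, default 128) for each input, in evaluation mode.  For the
#' dense baselines the last hidden layer plays this role.  These are the
#' representations visualized with t-SNE.
#'
#' @inheritParams predict.cop_model
#' @param model A [cop_model()][build_model()].
#' @return Matrix `[n, n_features]`.
#' @export
extract_features <- function(model, batch, chunk_size = 256L) {
  stopifnot(inherits(model, "cop_model"))
  X <- as_input_array(batch, model$spec)
  n <- dim(X)[3L]
  parts <- list()
  for (i0 in seq.int(1L, n, by = chunk_size)) {
    idx <- i0:min(i0 + chunk_size - 1L, n)
    parts[[length(parts) + 1L]] <-
      model_forward(model$params, model$spec,
                    X[, , idx, drop = FALSE])$features
  }
  do.call(rbind, parts)
}
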