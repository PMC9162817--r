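# Seed plumbing shared by the simulator, task assembly and training.

#' Derive a reproducible sub-seed from a global seed and a label
#'
#' All randomness in the package (simulation, shuffling, weight
#' initialization, dropout, embeddings) flows from a single integer seed.
#' Sub-experiments draw their own seeds through this deterministic hash of
#' `(seed, label)`, so any stage can be replayed in isolation.
#'
#' @param seed Integer global seed.
#' @param label Character tag naming the consumer (e.g. `"sway-H#1"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + abs(as.numeric(seed)) * 7919) %% 2147483647)
}

# Run `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Apply f over the leaves of parallel nested lists (parameters, gradients,
# optimizer moments).  NULL leaves (e.g. absent shortcut projections) are kept.
tree_pmap <- function(f, trees) {
  first <- trees[[1L]]
  if (is.list(first)) {
    out <- vector("list", length(first))
    names(out) <- names(first)
    for (i in seq_along(first)) {
      if (is.null(first[[i]])) next
      out[[i]] <- tree_pmap(f, lapply(trees, `[[`, i))
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_sum <- function(tree, f = identity) {
  if (is.list(tree)) {
    sum(vapply(tree, tree_sum, numeric(1), f = f))
  } else if (is.null(tree)) {
    0
  } else {
    sum(f(tree))
  }
}
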