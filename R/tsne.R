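# Exact t-SNE for embedding learned feature matrices in 2D.
#
# The feature sets visualized here are a few hundred rows, so the exact
# O(n^2) formulation (full affinity matrix, per-point precision calibrated
# by binary search to a target perplexity, early exaggeration, momentum +
# adaptive gains) is used; no tree approximation is needed at this scale.

utils::globalVariables(c("dim1", "dim2", "level", ".data"))

# per-row conditional affinities with precision beta_i tuned so the
# distribution's entropy matches log(perplexity)
tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    di <- D2[i, -i]
    for (k in seq_len(max_tries)) {
      p <- exp(-di * beta)
      sum_p <- sum(p)
      if (sum_p < 1e-300) sum_p <- 1e-300
      h <- log(sum_p) + beta * sum(di * p) / sum_p
      if (abs(h - log_u) < tol) break
      if (h > log_u) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum_p
  }
  P
}

#' Embed a feature matrix in two dimensions with exact t-SNE
#'
#' @param X Numeric matrix `[n, d]` of features (one row per sample).
#' @param perplexity Effective neighborhood size; must satisfy
#'   `3 * perplexity < n - 1` and is shrunk with a warning otherwise.
#' @param max_iter Gradient-descent iterations.
#' @param seed Integer seed for the random initialization.
#' @param eta Learning rate.
#' @return Matrix `[n, 2]`, centered.
#' @export
tsne_embed <- function(X, perplexity = 30, max_iter = 400L, seed = 1L,
                       eta = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 10L)
  if (3 * perplexity >= n - 1) {
    perplexity <- max(2, floor((n - 1) / 3))
    warning("perplexity too large for n = ", n, "; using ", perplexity)
  }
  D2 <- as.matrix(dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(derive_seed(seed, "tsne"), {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (iter in seq_len(max_iter)) {
      ex <- if (iter <= 100L) 4 else 1     # early exaggeration
      momentum <- if (iter <= 250L) 0.5 else 0.8
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      inc <- momentum * inc - eta * (gains * grad)
      Y <- Y + inc
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    Y
  })
}
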