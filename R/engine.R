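# Internal differentiable layer primitives of the CNN engine.
#
# Forward passes delegate the convolution/pooling hot loops to compiled code
# (src/conv1d.cpp); dense algebra stays in R where BLAS does the work.  The
# naive single-series implementations in net_core.R are the independent
# oracle these layers are validated against.

# which() keeps non-finite values flowing through untouched, so a diverging
# run surfaces as a non-finite loss rather than an indexing error
lrelu_arr <- function(v, slope) {
  neg <- which(v < 0)
  v[neg] <- v[neg] * slope
  v
}

lrelu_grad <- function(z, slope) {
  g <- array(1, dim = dim(z))
  g[which(z < 0)] <- slope
  g
}

# cube [F, S, n] -> matrix [n, F*S] (sample-major flattening)
flatten_cube <- function(h) {
  d <- dim(h)
  t(matrix(h, d[1L] * d[2L], d[3L]))
}

# matrix [n, F*S] -> cube [F, S, n]
unflatten_cube <- function(m, f, s) array(t(m), dim = c(f, s, nrow(m)))

add_bias_rows <- function(m, b) m + rep(b, each = nrow(m))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

one_hot <- function(labels, n_classes) {
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

mean_cross_entropy <- function(probs, labels) {
  -mean(log(pmin(pmax(probs[cbind(seq_along(labels), labels + 1L)],
                      1e-12), 1)))
}
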