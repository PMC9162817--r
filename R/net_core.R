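# Reference implementations of the network's elementary computations.
#
# These are deliberately naive (explicit loops, no vectorization tricks) so
# they can serve as an independent oracle for the compiled CNN engine used
# by the model builder.  They are pure, deterministic, and forward-only.

#' Extract a contiguous window from a series
#'
#' Returns the concatenation vector `(x[i], ..., x[i + f_l - 1])`, the local
#' receptive field of a 1D convolution anchored at position `i` (1-based).
#'
#' @param x Numeric series.
#' @param i Start index (1-based).
#' @param f_l Window (kernel) length.
#' @return Numeric vector of length `f_l`.
#' @export
concat_window <- function(x, i, f_l) {
  stopifnot(f_l >= 1L)
  if (i < 1L || i + f_l - 1L > length(x)) {
    stop("window [", i, ", ", i + f_l - 1L, "] exceeds series of length ",
         length(x))
  }
  x[i:(i + f_l - 1L)]
}

#' Valid 1D convolution of a single series with a single kernel
#'
#' Slides the kernel over every full window of the series and applies the
#' activation to `w . x_window + bias`.  The cross-correlation convention is
#' used (no kernel flip), so the output has length `N - F_L + 1`.
#'
#' @param x Numeric series of length `N`.
#' @param w Kernel weights of length `F_L`.
#' @param bias Scalar bias, default 0.
#' @param activation `"identity"` or `"leaky_relu"`.
#' @param slope Leaky ReLU negative-side slope.
#' @return Feature map of length `N - F_L + 1`.
#' @export
conv1d_valid <- function(x, w, bias = 0,
                         activation = c("identity", "leaky_relu"),
                         slope = 0.01) {
  activation <- match.arg(activation)
  f_l <- length(w)
  n <- length(x)
  if (n < f_l) {
    stop("series length ", n, " is shorter than the kernel (", f_l, ")")
  }
  out <- numeric(n - f_l + 1L)
  for (i in seq_along(out)) {
    s <- bias
    for (j in seq_len(f_l)) s <- s + w[j] * x[i + j - 1L]
    out[i] <- s
  }
  if (activation == "leaky_relu") out <- leaky_relu(out, slope)
  out
}

#' Same-padded 1D convolution (output length preserved)
#'
#' Zero-pads the series with `floor((F_L - 1)/2)` zeros on the left and the
#' remaining `ceiling((F_L - 1)/2)` on the right, then applies
#' [conv1d_valid()].  The output always has the length of the input, which
#' is what makes additive shortcut connections across convolution stacks
#' well defined.
#'
#' @inheritParams conv1d_valid
#' @export
conv1d_same <- function(x, w, bias = 0,
                        activation = c("identity", "leaky_relu"),
                        slope = 0.01) {
  f_l <- length(w)
  pl <- (f_l - 1L) %/% 2L
  pr <- f_l - 1L - pl
  conv1d_valid(c(numeric(pl), x, numeric(pr)), w, bias,
               match.arg(activation), slope)
}

#' Non-overlapping max pooling of a feature map
#'
#' Partitions the map into consecutive blocks of size `p` and keeps the
#' maximum of each block.  A trailing remainder shorter than `p` is dropped,
#' so the output length is `floor(length(k)/p)`.
#'
#' @param k Numeric feature map.
#' @param p Pool size (`>= 1`).
#' @export
maxpool1d <- function(k, p) {
  stopifnot(p >= 1L)
  if (length(k) < p) stop("feature map shorter than pool size")
  s <- length(k) %/% p
  out <- numeric(s)
  for (z in seq_len(s)) out[z] <- max(k[((z - 1L) * p + 1L):(z * p)])
  out
}

#' Leaky rectified linear unit
#'
#' @param v Numeric vector.
#' @param slope Negative-side slope, in (0, 1).
#' @export
leaky_relu <- function(v, slope = 0.01) {
  stopifnot(slope > 0, slope < 1)
  ifelse(v >= 0, v, slope * v)
}

#' Numerically stable softmax
#'
#' Maps confidence values to positive probabilities summing to one; the
#' maximum is subtracted before exponentiation so large inputs do not
#' overflow.
#'
#' @param z Numeric vector of confidence values.
#' @export
softmax <- function(z) {
  stopifnot(all(is.finite(z)))
  e <- exp(z - max(z))
  e / sum(e)
}

#' Cross-entropy loss of a predicted probability vector
#'
#' @param p Probability vector (sums to one).
#' @param label True class as a 0-based integer in `[0, length(p) - 1]`
#'   (the package encodes levels H, M, N as 0, 1, 2).
#' @export
cross_entropy <- function(p, label) {
  if (label < 0L || label >= length(p)) {
    stop("label ", label, " out of range [0, ", length(p) - 1L, "]")
  }
  -log(min(max(p[label + 1L], 1e-12), 1))
}

#' Residual (shortcut) forward pass
#'
#' Computes `inner(x) + x`: the inner function's output is added element-wise
#' to its input, the additive bypass that eases gradient flow in deep
#' networks.  `inner` must preserve length (guaranteed for stacks of
#' same-padded convolutions).
#'
#' @param x Numeric vector.
#' @param inner Function from vector to vector of the same length.
#' @export
residual_forward <- function(x, inner) {
  r <- inner(x)
  if (length(r) != length(x)) {
    stop("inner function changed length: ", length(x), " -> ", length(r))
  }
  r + x
}
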