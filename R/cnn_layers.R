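# R-side numerics for the native CNN. The heavy kernels (im2col
# convolution, 2x2 max pool, fused batch-norm + ReLU) live in
# src/cnn_ops.cpp; activations are column-major matrices with one column
# per channel and rows ordered pixel-within-image fastest, then image:
#   row = (n - 1) * H * W + (c - 1) * H + r
# so matrix(A, c(H, W, N, C)) recovers the spatial array.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

add_cols <- function(A, v) {
  for (j in seq_along(v)) A[, j] <- A[, j] + v[j]
  A
}

# Flatten (H*W*N x C) activations to per-image rows (N x H*W*C).
flatten_forward <- function(x, H, W, N) {
  C <- ncol(x)
  ap <- aperm(array(x, c(H, W, N, C)), c(1L, 2L, 4L, 3L))
  t(matrix(ap, H * W * C, N))
}

flatten_backward <- function(dX, H, W, N, C) {
  ap <- array(t(dX), c(H, W, C, N))
  matrix(aperm(ap, c(1L, 2L, 4L, 3L)), H * W * N, C)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy loss and gradient for integer class labels.
softmax_ce <- function(logits, y_int, n_classes) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  picked <- p[cbind(seq_len(n), y_int)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), y_int)] <-
    dlogits[cbind(seq_len(n), y_int)] - 1
  list(loss = loss, dlogits = dlogits / n, prob = p)
}
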