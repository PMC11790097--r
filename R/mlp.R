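# Minimal dense-network engine used by both the policy and the backbone.
# Layers are fully connected with ReLU activations between them; the output
# layer is linear (the caller applies softmax or sigmoid as needed).
# Parameters are plain matrices so snapshots and bitwise resets are trivial.

# Glorot-uniform initialisation; consumes the current RNG stream.
mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_out, fan_in)
    b[[l]] <- numeric(fan_out)
  }
  list(W = W, b = b, sizes = sizes)
}

# Forward pass for a batch X (n x d).  Returns logits (n x out) and the
# per-layer activations needed for backprop.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% t(net$W[[l]])
    Z <- sweep(Z, 2L, net$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) relu(Z) else Z
  }
  list(logits = A[[L + 1L]], activations = A)
}

# Backprop from an output-layer gradient dZ (n x out, d objective / d logits).
# Returns per-layer gradients summed over the batch.
mlp_backprop <- function(net, activations, dZ) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- t(dZ) %*% activations[[l]]
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% net$W[[l]]
      dZ <- dA * (activations[[l]] > 0)
    }
  }
  list(dW = dW, db = db)
}

# theta <- theta + step * grad
mlp_axpy <- function(net, grad, step) {
  for (l in seq_along(net$W)) {
    net$W[[l]] <- net$W[[l]] + step * grad$dW[[l]]
    net$b[[l]] <- net$b[[l]] + step * grad$db[[l]]
  }
  net
}

mlp_grad_norm <- function(grad) {
  sqrt(sum(vapply(grad$dW, function(m) sum(m^2), numeric(1))) +
         sum(vapply(grad$db, function(v) sum(v^2), numeric(1))))
}

mlp_check_finite <- function(grad) {
  for (l in seq_along(grad$dW)) {
    if (!all(is.finite(grad$dW[[l]])) || !all(is.finite(grad$db[[l]])))
      stopf("non-finite gradient in layer %d", l)
  }
  invisible(TRUE)
}
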