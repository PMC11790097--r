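#' Create a stochastic wavelet-selection policy
#'
#' The policy \eqn{\pi_\theta} maps a raw signal to a probability vector
#' over the `Na` catalog indices.  The raw leads-by-time matrix is average
#' pooled per lead to `pool_len` points and standardised per record, then
#' passed through a small fully connected network with ReLU hidden layers
#' and a single softmax head of width `Na`.
#'
#' @param input_shape integer `c(leads, length)` of the raw signals, or a
#'   single integer for an already-vectorised input (as in the bandit
#'   tests, where pooling is skipped).
#' @param Na number of actions (catalog size).
#' @param hidden integer vector of hidden-layer widths (may be empty for a
#'   linear softmax policy).
#' @param pool_len per-lead pooled length fed to the network.
#' @param streams an [rng_streams()] object; initialisation draws from its
#'   `"policy"` stream.
#' @param norm optional input-normalisation statistics: a list with
#'   `center` and `scale` vectors (length `in_dim`) applied to the pooled
#'   input before the first layer, in the role of the batch-normalisation
#'   stage of the policy network.  [run_training()] fits them on the
#'   training split.
#' @param prior optional length-`Na` vector of initial action
#'   probabilities; the softmax head's bias is initialised to its
#'   log-odds, so a fresh policy samples from `prior` (up to the small
#'   random weight initialisation).  [run_training()] uses a
#'   family-balanced prior so that large wavelet families do not dominate
#'   early exploration.
#' @return an object of class `rlwbs_policy`.
#' @export
policy_new <- function(input_shape, Na, hidden = 32, pool_len = 64,
                       streams = rng_streams(1), norm = NULL, prior = NULL) {
  stopifnot(Na >= 1)
  if (length(input_shape) == 1L) {
    in_dim <- as.integer(input_shape)
    pool_len <- NA_integer_
  } else {
    pool_len <- min(pool_len, max(floor(input_shape[2] / 2), 1L))
    in_dim <- as.integer(input_shape[1] * pool_len)
  }
  sizes <- c(in_dim, hidden, Na)
  net <- with_stream(streams, "policy", mlp_init(sizes))
  # damp the softmax head so the fresh policy is near-uniform (or near the
  # supplied prior): exploration starts from maximum entropy
  net$W[[length(net$W)]] <- net$W[[length(net$W)]] * 0.3
  if (!is.null(prior)) {
    stopifnot(length(prior) == Na, all(prior > 0))
    net$b[[length(net$b)]] <- log(prior / sum(prior))
  }
  if (!is.null(norm))
    stopifnot(length(norm$center) == in_dim, length(norm$scale) == in_dim)
  pol <- list(net = net, input_shape = as.integer(input_shape),
              pool_len = pool_len, Na = as.integer(Na), norm = norm)
  class(pol) <- "rlwbs_policy"
  pol
}

# Apply the policy's input-normalisation layer to a batch matrix.
policy_apply_norm <- function(policy, X) {
  if (is.null(policy$norm)) return(X)
  sweep(sweep(X, 2L, policy$norm$center, `-`), 2L, policy$norm$scale, `/`)
}

# Fit normalisation statistics from a matrix of pooled inputs.
policy_fit_norm <- function(X) {
  sc <- apply(X, 2L, stats::sd)
  sc[sc < 1e-8] <- 1
  list(center = colMeans(X), scale = sc)
}

# Raw signal (leads x length) -> pooled, standardised feature vector.
policy_preprocess <- function(policy, signal) {
  if (is.list(signal) && !is.null(signal$samples)) signal <- signal$samples
  if (is.na(policy$pool_len)) {
    x <- as.numeric(signal)
    if (length(x) != policy$input_shape[1])
      stopf("policy input shape mismatch: expected length %d, got %d",
            policy$input_shape[1], length(x))
    return(x)
  }
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  if (!identical(dim(signal), policy$input_shape))
    stopf("policy input shape mismatch: expected %s, got %s",
          paste(policy$input_shape, collapse = "x"),
          paste(dim(signal), collapse = "x"))
  policy_input_vector(signal, policy$pool_len)
}

#' Policy forward pass
#'
#' @param policy an `rlwbs_policy`.
#' @param signal one raw signal (leads x length matrix, vector, or an
#'   `ecg_record`), or a list of them.
#' @return for one signal, an object of class `action_distribution` (the
#'   probability vector with attributes); for a list, a matrix of
#'   probabilities with one row per signal.
#' @export
policy_forward <- function(policy, signal) {
  stopifnot(inherits(policy, "rlwbs_policy"))
  if (is.list(signal) && is.null(signal$samples)) {
    X <- do.call(rbind, lapply(signal, function(s) policy_preprocess(policy, s)))
    return(softmax_rows(mlp_forward(policy$net, policy_apply_norm(policy, X))$logits))
  }
  x <- policy_preprocess(policy, signal)
  p <- softmax(drop(mlp_forward(policy$net,
                                policy_apply_norm(policy, matrix(x, 1L)))$logits))
  structure(p, class = "action_distribution")
}

#' Sample an action index from a distribution
#'
#' Draws one catalog index from the policy's probability vector; used in
#' the training stage.  Reproducible under a fixed `"action"` stream state.
#'
#' @param dist probability vector (an `action_distribution`).
#' @param streams an [rng_streams()] object (its `"action"` stream is
#'   consumed), or `NULL` to use the current RNG state.
#' @return integer action index in `1..Na`.
#' @export
sample_action <- function(dist, streams = NULL) {
  p <- as.numeric(dist)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stopf("invalid action distribution (entries must be >= 0 and sum to 1)")
  draw <- function() {
    u <- stats::runif(1)
    as.integer(findInterval(u, cumsum(p)) + 1L)
  }
  a <- if (is.null(streams)) draw() else with_stream(streams, "action", draw())
  min(a, length(p))
}

#' Greedy action (evaluation mode)
#'
#' Returns the index with maximal probability; ties break toward the
#' lowest index so evaluation is deterministic.
#'
#' @param dist probability vector.
#' @return integer action index.
#' @export
greedy_action <- function(dist) {
  which.max(as.numeric(dist))  # which.max takes the first maximum
}

#' REINFORCE policy-gradient update
#'
#' Performs the ascent step
#' \deqn{\theta \leftarrow \theta + \alpha (r - b) \sum_i
#'   \nabla_\theta \log p(a_i \mid x_i)}
#' where the sum runs over the mini-batch, `r` is the shared scalar reward
#' of the iteration and `b` an optional baseline.  All signals in the batch
#' receive the same advantage, matching the joint-log-probability form of
#' the objective.
#'
#' @param policy an `rlwbs_policy`.
#' @param signals list of raw signals (the mini-batch), or a matrix of
#'   preprocessed rows.
#' @param actions integer vector of the actions taken for each signal.
#' @param reward scalar reward (finite).
#' @param baseline scalar baseline subtracted from the reward (default 0).
#' @param alpha learning rate.
#' @return list with `policy` (updated), `grad_norm` (Euclidean norm of the
#'   advantage-weighted gradient estimate) and `logprob` (joint
#'   log-probability of the taken actions before the update).
#' @export
pg_update <- function(policy, signals, actions, reward, baseline = 0,
                      alpha = 0.1) {
  stopifnot(inherits(policy, "rlwbs_policy"))
  if (!is.finite(reward)) stopf("reward must be finite")
  X <- if (is.matrix(signals)) signals else
    do.call(rbind, lapply(signals, function(s) policy_preprocess(policy, s)))
  X <- policy_apply_norm(policy, X)
  B <- nrow(X)
  stopifnot(length(actions) == B, all(actions >= 1L), all(actions <= policy$Na))
  fw <- mlp_forward(policy$net, X)
  P <- softmax_rows(fw$logits)
  onehot <- matrix(0, B, policy$Na)
  onehot[cbind(seq_len(B), actions)] <- 1
  # d/dlogits of sum_i log p(a_i | x_i)
  dZ <- onehot - P
  grad <- mlp_backprop(policy$net, fw$activations, dZ)
  mlp_check_finite(grad)
  adv <- reward - baseline
  net <- mlp_axpy(policy$net, grad, alpha * adv)
  policy$net <- net
  list(policy = policy,
       grad_norm = abs(adv) * mlp_grad_norm(grad),
       logprob = sum(log(pmax(P[cbind(seq_len(B), actions)], .Machine$double.xmin))))
}

#' Save / load a policy checkpoint
#'
#' The checkpoint holds the architecture, weights, the catalog hash it was
#' trained against, and the current stream states; loading against a
#' catalog with a different hash is refused.
#'
#' @param policy an `rlwbs_policy`.
#' @param path file path.
#' @param catalog the `wavelet_catalog` the policy indexes into.
#' @param streams optional [rng_streams()] to snapshot.
#' @return `save_policy` returns `path` invisibly; `load_policy` returns a
#'   list with `policy` and `stream_snapshot`.
#' @export
save_policy <- function(policy, path, catalog, streams = NULL) {
  obj <- list(policy = policy, catalog_hash = catalog$hash,
              stream_snapshot = if (!is.null(streams)) snapshot_streams(streams))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path, catalog) {
  obj <- readRDS(path)
  if (!identical(obj$catalog_hash, catalog$hash))
    stopf("checkpoint catalog hash %s does not match supplied catalog %s",
          obj$catalog_hash, catalog$hash)
  obj
}

#' @export
print.rlwbs_policy <- function(x, ...) {
  cat(sprintf("<rlwbs_policy> input %s -> layers [%s] -> softmax(%d)\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$net$sizes, collapse = ", "), x$Na))
  invisible(x)
}
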