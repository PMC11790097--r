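#' Create the evaluation (backbone) classifier
#'
#' A compact fully connected multi-label classifier over flattened
#' scalogram features: ReLU hidden layers and one sigmoid output per
#' class.  The weights captured at construction are kept as an immutable
#' snapshot; [reset_backbone()] restores them bitwise, which the selection
#' loop does at the end of every iteration so each iteration's reward is
#' measured from an identical starting point.
#'
#' @param input_dim flattened feature length (e.g. `16 * 32`).
#' @param K number of classes (sigmoid outputs).
#' @param hidden integer vector of hidden widths.
#' @param streams an [rng_streams()] object; initialisation draws from its
#'   `"backbone"` stream.
#' @return object of class `rlwbs_backbone`.
#' @export
backbone_new <- function(input_dim, K, hidden = 32, streams = rng_streams(1)) {
  sizes <- c(as.integer(input_dim), hidden, as.integer(K))
  net <- with_stream(streams, "backbone", mlp_init(sizes))
  bb <- list(net = net, initial_snapshot = net, input_dim = as.integer(input_dim),
             K = as.integer(K), trained = FALSE)
  class(bb) <- "rlwbs_backbone"
  bb
}

#' Train the backbone for one iteration
#'
#' Mini-batch gradient descent on the binary (multi-label) cross-entropy
#' of the sigmoid outputs.  Deterministic under a fixed `"backbone"`
#' stream state (which drives the epoch shuffling).
#'
#' @param state an `rlwbs_backbone` (freshly reset).
#' @param features `n x input_dim` matrix of flattened scalogram features.
#' @param labels `n x K` binary matrix.
#' @param epochs number of passes over the data.
#' @param lr learning rate.
#' @param batch_size mini-batch size for the inner SGD.
#' @param streams an [rng_streams()] object, or `NULL` to shuffle with the
#'   current RNG state.
#' @return list with `state` (trained backbone) and `loss` (final mean
#'   binary cross-entropy).
#' @export
train_backbone <- function(state, features, labels, epochs = 5, lr = 0.1,
                           batch_size = 16, streams = NULL) {
  stopifnot(inherits(state, "rlwbs_backbone"))
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (nrow(features) != nrow(labels))
    stopf("features (%d rows) and labels (%d rows) are not aligned",
          nrow(features), nrow(labels))
  if (ncol(features) != state$input_dim)
    stopf("feature width %d does not match backbone input_dim %d",
          ncol(features), state$input_dim)
  n <- nrow(features)
  net <- state$net
  loss <- NA_real_
  run_epochs <- function() {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        fw <- mlp_forward(net, features[idx, , drop = FALSE])
        S <- sigmoid(fw$logits)
        dZ <- -(S - labels[idx, , drop = FALSE]) / length(idx)
        grad <- mlp_backprop(net, fw$activations, dZ)
        net <<- mlp_axpy(net, grad, lr)
      }
    }
    fw <- mlp_forward(net, features)
    S <- pmin(pmax(sigmoid(fw$logits), 1e-12), 1 - 1e-12)
    mean(-(labels * log(S) + (1 - labels) * log(1 - S)))
  }
  loss <- if (is.null(streams)) run_epochs() else
    with_stream(streams, "backbone", run_epochs())
  if (!is.finite(loss))
    stopf("backbone training diverged: non-finite loss %s", format(loss))
  state$net <- net
  state$trained <- epochs > 0
  list(state = state, loss = loss)
}

#' Reset the backbone to its initial weights
#'
#' @param state an `rlwbs_backbone`.
#' @return the backbone with weights bitwise equal to the construction-time
#'   snapshot.
#' @export
reset_backbone <- function(state) {
  stopifnot(inherits(state, "rlwbs_backbone"))
  state$net <- state$initial_snapshot
  state$trained <- FALSE
  state
}

#' Per-class prediction scores
#'
#' @param state an `rlwbs_backbone`.
#' @param features `n x input_dim` matrix.
#' @return `n x K` matrix of sigmoid scores in `[0, 1]`; hard labels are
#'   obtained by thresholding at 0.5.
#' @export
predict_backbone <- function(state, features) {
  stopifnot(inherits(state, "rlwbs_backbone"))
  features <- as.matrix(features)
  if (ncol(features) != state$input_dim)
    stopf("feature width %d does not match backbone input_dim %d",
          ncol(features), state$input_dim)
  sigmoid(mlp_forward(state$net, features)$logits)
}

#' @export
print.rlwbs_backbone <- function(x, ...) {
  cat(sprintf("<rlwbs_backbone> layers [%s], %strained\n",
              paste(x$net$sizes, collapse = ", "),
              if (x$trained) "" else "un"))
  invisible(x)
}
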