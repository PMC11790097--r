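#' Named random-number streams
#'
#' Training uses three independent sources of randomness: policy-network
#' initialisation, action/mini-batch sampling, and backbone training
#' (initialisation and epoch shuffling).  Keeping them in separate streams
#' makes ablations independent: changing the backbone seed does not perturb
#' the sequence of sampled actions, and vice versa.  Each stream is a saved
#' base-R RNG state; [with_stream()] swaps it in around an expression.
#'
#' @param seed integer master seed (kept below 2^31); per-stream sub-seeds
#'   are derived deterministically from it.
#' @param names character vector of stream names.
#' @return an environment of class `rlwbs_streams` holding one saved RNG
#'   state per stream.
#' @export
#' @examples
#' st <- rng_streams(1)
#' a <- with_stream(st, "action", runif(2))
#' b <- with_stream(st, "action", runif(2))  # continues the stream
rng_streams <- function(seed, names = c("policy", "action", "backbone", "data")) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  env$master_seed <- as.integer(seed)
  old <- get_global_seed()
  on.exit(set_global_seed(old), add = TRUE)
  for (i in seq_along(names)) {
    sub <- (as.integer(seed) %% 1000003L) * 1009L + i * 7919L
    set.seed(sub %% .Machine$integer.max)
    assign(names[i], .GlobalEnv$.Random.seed, envir = env)
  }
  class(env) <- "rlwbs_streams"
  env
}

get_global_seed <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv)
  else NULL
}

set_global_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  } else {
    assign(".Random.seed", state, envir = .GlobalEnv)
  }
}

#' Evaluate an expression under a named RNG stream
#'
#' Swaps in the stream's saved state, evaluates `expr`, saves the advanced
#' state back into the stream, and restores the caller's RNG state.
#'
#' @param streams an object from [rng_streams()].
#' @param name stream name.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_stream <- function(streams, name, expr) {
  stopifnot(inherits(streams, "rlwbs_streams"))
  if (!exists(name, envir = streams, inherits = FALSE))
    stopf("unknown RNG stream '%s'", name)
  outer <- get_global_seed()
  set_global_seed(get(name, envir = streams))
  ok <- FALSE
  tryCatch({
    val <- expr
    ok <- TRUE
  }, finally = {
    if (ok) assign(name, .GlobalEnv$.Random.seed, envir = streams)
    set_global_seed(outer)
  })
  val
}

#' Snapshot / restore all stream states
#'
#' Used to make a training iteration atomic: states are captured before the
#' iteration and restored if it fails.
#' @param streams an `rlwbs_streams` object.
#' @return a named list of RNG states.
#' @keywords internal
snapshot_streams <- function(streams) {
  nms <- setdiff(ls(streams), "master_seed")
  stats::setNames(lapply(nms, function(n) get(n, envir = streams)), nms)
}

restore_streams <- function(streams, snapshot) {
  for (n in names(snapshot)) assign(n, snapshot[[n]], envir = streams)
  invisible(streams)
}
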