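#' Training configuration
#'
#' Collects every tunable of the selection loop with validated defaults.
#'
#' @param B mini-batch size (>= 1).
#' @param alpha policy learning rate (> 0).
#' @param alpha_decay multiplicative per-iteration decay of the policy
#'   learning rate (1 = constant).
#' @param gamma discount factor kept for fidelity with the episodic
#'   objective; iterations are single-step episodes, so it is inert
#'   (default 1).
#' @param E backbone training epochs per iteration.
#' @param backbone_lr,backbone_batch backbone SGD learning rate and
#'   mini-batch size.
#' @param reward reward metric name (see [reward_metric()]).
#' @param baseline logical; subtract an exponential-moving-average reward
#'   baseline (variance reduction).  Off by default.
#' @param baseline_decay EMA decay of the baseline.
#' @param max_iterations hard iteration cap.
#' @param term_window,term_eps stop early once the standard deviation of
#'   the last `term_window` rewards falls below `term_eps`.
#' @param M,f_min,f_max scale count and pseudo-frequency band (Hz) of the
#'   scalograms.
#' @param feat_height,feat_width fixed feature size fed to the backbone.
#' @param pool_len,policy_hidden policy input pooling length and hidden
#'   widths.
#' @param backbone_hidden backbone hidden widths.
#' @param seeds named list/vector with elements `policy`, `action`,
#'   `backbone` seeding the three independent RNG streams.
#' @param checkpoint_every,checkpoint_dir checkpoint cadence (iterations)
#'   and directory (`NULL` disables checkpointing).
#' @return object of class `training_config` (a validated named list).
#' @export
training_config <- function(B = 16, alpha = 0.05, alpha_decay = 1,
                            gamma = 1, E = 5,
                            backbone_lr = 0.5, backbone_batch = 16,
                            reward = "macro_f1", baseline = FALSE,
                            baseline_decay = 0.9, max_iterations = 200,
                            term_window = 10, term_eps = 1e-4,
                            M = 64, f_min = 0.5, f_max = 40,
                            feat_height = 16, feat_width = 32,
                            pool_len = 64, policy_hidden = 32,
                            backbone_hidden = 32,
                            seeds = list(policy = 1, action = 2, backbone = 3),
                            checkpoint_every = 25, checkpoint_dir = NULL) {
  if (B < 1) stopf("B must be >= 1 (got %s)", format(B))
  if (alpha <= 0) stopf("alpha must be > 0 (got %s)", format(alpha))
  if (alpha_decay <= 0 || alpha_decay > 1)
    stopf("alpha_decay must be in (0, 1]")
  if (gamma < 0 || gamma > 1) stopf("gamma must be in [0, 1]")
  if (term_window < 2) stopf("term_window must be >= 2")
  if (term_eps <= 0) stopf("term_eps must be > 0")
  if (E < 0) stopf("E must be >= 0")
  if (max_iterations < 1) stopf("max_iterations must be >= 1")
  if (!all(c("policy", "action", "backbone") %in% names(seeds)))
    stopf("seeds must name 'policy', 'action' and 'backbone'")
  cfg <- list(B = as.integer(B), alpha = alpha, alpha_decay = alpha_decay,
              gamma = gamma,
              E = as.integer(E), backbone_lr = backbone_lr,
              backbone_batch = as.integer(backbone_batch), reward = reward,
              baseline = isTRUE(baseline), baseline_decay = baseline_decay,
              max_iterations = as.integer(max_iterations),
              term_window = as.integer(term_window), term_eps = term_eps,
              M = as.integer(M), f_min = f_min, f_max = f_max,
              feat_height = as.integer(feat_height),
              feat_width = as.integer(feat_width),
              pool_len = as.integer(pool_len), policy_hidden = policy_hidden,
              backbone_hidden = backbone_hidden,
              seeds = lapply(seeds, as.integer),
              checkpoint_every = as.integer(checkpoint_every),
              checkpoint_dir = checkpoint_dir)
  class(cfg) <- "training_config"
  cfg
}

config_streams <- function(config) {
  s <- config$seeds
  env <- new.env(parent = emptyenv())
  env$master_seed <- s$policy
  old <- get_global_seed()
  on.exit(set_global_seed(old), add = TRUE)
  for (nm in c("policy", "action", "backbone")) {
    set.seed(s[[nm]] %% .Machine$integer.max)
    assign(nm, .GlobalEnv$.Random.seed, envir = env)
  }
  set.seed((s$action * 2654435761) %% .Machine$integer.max)
  assign("data", .GlobalEnv$.Random.seed, envir = env)
  class(env) <- "rlwbs_streams"
  env
}

#' Load a configuration file
#'
#' Reads a YAML file with optional top-level sections `training` and
#' `synthetic`.  Missing keys take their defaults; unknown keys are an
#' error (listed by name).  An empty file yields all defaults.
#'
#' @param path YAML file path.
#' @return list with elements `training` (a [training_config()]) and
#'   `synthetic` (a [synthetic_spec()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad_top <- setdiff(names(raw), c("training", "synthetic"))
  if (length(bad_top) > 0)
    stopf("unknown top-level config section(s): %s",
          paste(bad_top, collapse = ", "))
  tr <- raw$training %||% list()
  sy <- raw$synthetic %||% list()
  bad_tr <- setdiff(names(tr), names(formals(training_config)))
  if (length(bad_tr) > 0)
    stopf("unknown training config key(s): %s", paste(bad_tr, collapse = ", "))
  bad_sy <- setdiff(names(sy), names(formals(synthetic_spec)))
  if (length(bad_sy) > 0)
    stopf("unknown synthetic config key(s): %s", paste(bad_sy, collapse = ", "))
  if (!is.null(sy$classes)) {
    sy$classes <- lapply(sy$classes, function(cl) {
      cl$scale_range <- as.numeric(cl$scale_range)
      cl
    })
  }
  list(training = do.call(training_config, tr),
       synthetic = do.call(synthetic_spec, sy))
}

#' Save a configuration to YAML
#'
#' @param training a [training_config()].
#' @param synthetic a [synthetic_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(training, synthetic, path) {
  sy <- unclass(synthetic)
  sy <- sy[intersect(names(sy), names(formals(synthetic_spec)))]
  yaml::write_yaml(list(training = unclass(training), synthetic = sy), path)
  invisible(path)
}

#' @export
print.training_config <- function(x, ...) {
  cat(sprintf(
    "<training_config> B=%d alpha=%g E=%d reward=%s baseline=%s max_iter=%d M=%d\n",
    x$B, x$alpha, x$E, x$reward, x$baseline, x$max_iterations, x$M))
  invisible(x)
}
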