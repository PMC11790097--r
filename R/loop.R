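#' One learning iteration of the selection loop
#'
#' Executes the eight steps of a training iteration in order: sample a
#' mini-batch from the training split (without replacement within the
#' iteration); sample one base index per signal from the policy; look up
#' the corresponding scalogram features; train the freshly reset backbone
#' on them; greedily select bases for the whole evaluation split and score
#' it with the trained backbone; use that score as the reward for a
#' REINFORCE update of the policy; and hand back the trained backbone so
#' the caller can reset it.  The iteration is atomic: if any step fails,
#' the caller's policy, backbone and stream states are unchanged.
#'
#' @param policy an `rlwbs_policy`.
#' @param backbone a freshly reset `rlwbs_backbone`.
#' @param store an [build_feature_store()] result.
#' @param split_idx list with integer vectors `train` and `eval` (row
#'   indices into the store).
#' @param config a [training_config()].
#' @param streams an [rng_streams()] object.
#' @param t iteration number (for the record).
#' @param baseline_value current reward baseline (0 when disabled).
#' @return list with `policy` (updated), `backbone_trained`, `record`
#'   (one-row tibble: `iteration`, `reward`, `grad_norm`, `loss`,
#'   `wall_time`, list-columns `batch` and `actions`), and `metrics`.
#' @export
run_iteration <- function(policy, backbone, store, split_idx, config,
                          streams, t = 1L, baseline_value = 0) {
  stopifnot(inherits(policy, "rlwbs_policy"),
            inherits(backbone, "rlwbs_backbone"),
            inherits(store, "rlwbs_feature_store"))
  if (length(split_idx$train) < config$B)
    stopf("training split (%d records) smaller than mini-batch B = %d",
          length(split_idx$train), config$B)
  snap <- snapshot_streams(streams)
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch({
    batch <- with_stream(streams, "action",
                         sample(split_idx$train, config$B, replace = FALSE))
    X <- store$policy_inputs[batch, , drop = FALSE]
    P <- softmax_rows(mlp_forward(policy$net,
                                  policy_apply_norm(policy, X))$logits)
    u <- with_stream(streams, "action", stats::runif(config$B))
    actions <- vapply(seq_len(config$B), function(i)
      min(findInterval(u[i], cumsum(P[i, ])) + 1L, policy$Na), integer(1))
    feat <- feature_rows(store, batch, actions)
    tr <- train_backbone(backbone, feat, store$labels[batch, , drop = FALSE],
                         epochs = config$E, lr = config$backbone_lr,
                         batch_size = config$backbone_batch, streams = streams)
    ev <- evaluate_on(policy, tr$state, store, split_idx$eval, config)
    eta <- ev$reward
    upd <- pg_update(policy, X, actions, reward = eta,
                     baseline = baseline_value,
                     alpha = config$alpha * config$alpha_decay^(t - 1))
    list(policy = upd$policy, backbone_trained = tr$state,
         metrics = ev$metrics,
         record = tibble::tibble(
           iteration = as.integer(t), reward = eta,
           grad_norm = upd$grad_norm, loss = tr$loss,
           wall_time = proc.time()[["elapsed"]] - t0,
           batch = list(store$record_id[batch]),
           actions = list(actions)))
  }, error = function(e) {
    restore_streams(streams, snap)
    stop(e)
  })
  res
}

# Gather flattened features for (record index, action) pairs.
feature_rows <- function(store, idx, actions) {
  out <- matrix(0, length(idx), store$D)
  for (i in seq_along(idx)) out[i, ] <- store$features[idx[i], actions[i], ]
  out
}

# Greedy evaluation of a policy + trained backbone on a set of records.
evaluate_on <- function(policy, backbone, store, idx, config) {
  Xv <- policy_apply_norm(policy, store$policy_inputs[idx, , drop = FALSE])
  Pv <- softmax_rows(mlp_forward(policy$net, Xv)$logits)
  av <- max.col(Pv, ties.method = "first")
  feat <- feature_rows(store, idx, av)
  scores <- predict_backbone(backbone, feat)
  labels <- store$labels[idx, , drop = FALSE]
  hard <- (scores >= 0.5) * 1
  report <- compute_metrics(confusion(labels, hard), scores, labels)
  list(reward = reward_metric(report, config$reward), metrics = report,
       actions = av)
}

#' Termination rule
#'
#' Training stops once the reward trace shows only minor variation: the
#' standard deviation of the last `w` rewards falls below `eps`, or the
#' iteration cap is reached.
#'
#' @param reward_history numeric vector of rewards so far.
#' @param w window length (>= 2).
#' @param eps variation tolerance (> 0).
#' @param max_iterations iteration cap.
#' @return `TRUE` to stop, `FALSE` to continue.
#' @export
check_termination <- function(reward_history, w, eps, max_iterations) {
  stopifnot(w >= 2, eps > 0)
  t <- length(reward_history)
  if (t >= max_iterations) return(TRUE)
  if (t >= w && stats::sd(utils::tail(reward_history, w)) < eps) return(TRUE)
  FALSE
}

#' Train the wavelet-selection policy
#'
#' Runs [run_iteration()] until [check_termination()] fires, logging one
#' row per iteration and optionally writing policy checkpoints.
#'
#' @param dataset an `rlwbs_dataset` (rows with `split` values `train`
#'   and `eval` are used).
#' @param catalog a `wavelet_catalog`.
#' @param config a [training_config()].
#' @param store optional precomputed [build_feature_store()]; built on the
#'   fly otherwise.
#' @return object of class `rlwbs_fit`: list with `policy`, `history`
#'   (tibble of iteration records), `backbone_last` (the trained backbone
#'   of the final iteration), `backbone` (the reset backbone), `config`,
#'   `catalog_hash`, `terminated_early`.
#' @export
run_training <- function(dataset, catalog, config = training_config(),
                         store = NULL) {
  store <- store %||% build_feature_store(dataset, catalog, config)
  if (!identical(store$catalog_hash, catalog$hash))
    stopf("feature store was built against a different catalog")
  split_idx <- list(train = which(dataset$split == "train"),
                    eval = which(dataset$split == "eval"))
  if (length(split_idx$eval) == 0) stopf("dataset has no evaluation split")
  streams <- config_streams(config)
  fam <- vapply(catalog$bases, `[[`, character(1), "family")
  fam_prior <- 1 / (length(unique(fam)) * table(fam)[fam])
  policy <- policy_new(c(store$leads, store$N), Na = catalog$Na,
                       hidden = config$policy_hidden,
                       pool_len = config$pool_len, streams = streams,
                       norm = policy_fit_norm(
                         store$policy_inputs[split_idx$train, , drop = FALSE]),
                       prior = as.numeric(fam_prior))
  backbone <- backbone_new(store$D, K = ncol(store$labels),
                           hidden = config$backbone_hidden, streams = streams)
  history <- list()
  rewards <- numeric(0)
  baseline_value <- 0
  baseline_init <- FALSE
  t <- 0L
  repeat {
    t <- t + 1L
    backbone <- reset_backbone(backbone)
    it <- run_iteration(policy, backbone, store, split_idx, config, streams,
                        t = t,
                        baseline_value = if (config$baseline) baseline_value else 0)
    policy <- it$policy
    history[[t]] <- it$record
    rewards <- c(rewards, it$record$reward)
    if (config$baseline) {
      baseline_value <- if (!baseline_init) it$record$reward else
        config$baseline_decay * baseline_value +
        (1 - config$baseline_decay) * it$record$reward
      baseline_init <- TRUE
    }
    if (!is.null(config$checkpoint_dir) && t %% config$checkpoint_every == 0L) {
      dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_policy(policy,
                  file.path(config$checkpoint_dir,
                            sprintf("policy_iter%05d.rds", t)),
                  catalog, streams)
    }
    if (check_termination(rewards, config$term_window, config$term_eps,
                          config$max_iterations)) break
  }
  fit <- list(policy = policy, history = dplyr::bind_rows(history),
              backbone_last = it$backbone_trained,
              backbone = reset_backbone(backbone), config = config,
              catalog_hash = catalog$hash,
              terminated_early = t < config$max_iterations)
  class(fit) <- "rlwbs_fit"
  fit
}

#' Greedy policy evaluation with selection statistics
#'
#' Applies the trained policy in evaluation mode (highest-probability base
#' per record), scores the records with the supplied trained backbone, and
#' tabulates the per-family selection distribution.
#'
#' @param policy an `rlwbs_policy` (or an `rlwbs_fit`, whose policy and
#'   last trained backbone are used).
#' @param backbone a trained `rlwbs_backbone` (ignored when `policy` is a
#'   fit).
#' @param catalog the `wavelet_catalog`.
#' @param store a feature store covering the records.
#' @param idx integer row indices of the records to evaluate (default all).
#' @param config a [training_config()].
#' @return list with `selection` (tibble: `record_id`, `action`, `name`,
#'   `family`), `metrics` (an `rlwbs_metrics`), and `family_distribution`
#'   (tibble: `family`, `share` summing to 100).
#' @export
evaluate_policy <- function(policy, backbone = NULL, catalog, store,
                            idx = NULL, config = training_config()) {
  if (inherits(policy, "rlwbs_fit")) {
    backbone <- backbone %||% policy$backbone_last
    policy <- policy$policy
  }
  idx <- idx %||% seq_len(dim(store$features)[1])
  if (length(idx) == 0) stopf("no records to evaluate")
  ev <- evaluate_on(policy, backbone, store, idx, config)
  tab <- catalog_table(catalog)
  selection <- tibble::tibble(
    record_id = store$record_id[idx],
    action = ev$actions,
    name = tab$name[ev$actions],
    family = tab$family[ev$actions])
  fams <- unique(tab$family)
  counts <- vapply(fams, function(f) sum(selection$family == f), numeric(1))
  family_distribution <- tibble::tibble(
    family = fams, share = 100 * counts / sum(counts))
  list(selection = selection, metrics = ev$metrics,
       family_distribution = family_distribution)
}

#' Reward trace of a single fixed base at the same budget
#'
#' The fixed-base control: every iteration trains and scores the backbone
#' exactly as the selection loop does, but with one prescribed base for
#' all records, leaving the policy out.  Used to benchmark adaptive
#' selection against the best static choice.
#'
#' @param store a feature store.
#' @param split_idx list with `train` and `eval` index vectors.
#' @param base_index catalog index to force.
#' @param config a [training_config()].
#' @return numeric vector of rewards, one per iteration.
#' @export
fixed_base_trace <- function(store, split_idx, base_index,
                             config = training_config()) {
  streams <- config_streams(config)
  backbone <- backbone_new(store$D, K = ncol(store$labels),
                           hidden = config$backbone_hidden, streams = streams)
  n_eval <- length(split_idx$eval)
  feat_eval <- feature_rows(store, split_idx$eval,
                            rep(base_index, n_eval))
  labels_eval <- store$labels[split_idx$eval, , drop = FALSE]
  rewards <- numeric(config$max_iterations)
  for (t in seq_len(config$max_iterations)) {
    backbone <- reset_backbone(backbone)
    batch <- with_stream(streams, "action",
                         sample(split_idx$train, config$B, replace = FALSE))
    feat <- feature_rows(store, batch, rep(base_index, config$B))
    tr <- train_backbone(backbone, feat, store$labels[batch, , drop = FALSE],
                         epochs = config$E, lr = config$backbone_lr,
                         batch_size = config$backbone_batch, streams = streams)
    scores <- predict_backbone(tr$state, feat_eval)
    hard <- (scores >= 0.5) * 1
    report <- compute_metrics(confusion(labels_eval, hard), scores,
                              labels_eval)
    rewards[t] <- reward_metric(report, config$reward)
  }
  rewards
}

#' Export an iteration history as delimited text
#'
#' @param history the `history` tibble of an `rlwbs_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  flat <- dplyr::mutate(history,
                        batch = vapply(.data$batch, paste, character(1),
                                       collapse = ","),
                        actions = vapply(.data$actions, paste, character(1),
                                         collapse = ","))
  utils::write.table(flat, path, row.names = FALSE, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @export
print.rlwbs_fit <- function(x, ...) {
  cat(sprintf("<rlwbs_fit> %d iterations, final reward %.4f%s\n",
              nrow(x$history), utils::tail(x$history$reward, 1),
              if (x$terminated_early) " (terminated early)" else ""))
  invisible(x)
}
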