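# Self-contained experiments: the enumerable bandit used to validate the
# REINFORCE estimator, and the two-class wavelet-recovery study on
# synthetic records.  Both are called by the test suite and by
# scripts/acceptance.R, so their defaults are the study conditions.

net_to_vec <- function(net) {
  unlist(c(lapply(net$W, as.vector), net$b), use.names = FALSE)
}

vec_to_net <- function(net, v) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    k <- length(net$W[[l]])
    net$W[[l]][] <- v[(pos + 1L):(pos + k)]
    pos <- pos + k
  }
  for (l in seq_along(net$b)) {
    k <- length(net$b[[l]])
    net$b[[l]] <- v[(pos + 1L):(pos + k)]
    pos <- pos + k
  }
  net
}

#' The enumerable three-action bandit
#'
#' A single fixed context vector, three actions with fixed deterministic
#' rewards, and a linear softmax policy.  The expected reward
#' \eqn{J(\theta) = \sum_j p_j r_j} is exactly enumerable, so the
#' REINFORCE gradient estimate and the ascent property can be checked
#' against ground truth.
#'
#' @param rewards length-3 numeric vector of per-action rewards.
#' @param context fixed input vector.
#' @param seed seed for the policy initialisation.
#' @return list with `policy`, `context`, `rewards`, and helper closures
#'   `exact_J(policy)` and `exact_grad(policy, h)` (central finite
#'   differences of `exact_J` in every coordinate).
#' @export
bandit_task <- function(rewards = c(0.9, 0.1, 0.3),
                        context = c(1.5, -1, 0.75, 2), seed = 1) {
  streams <- rng_streams(seed)
  policy <- policy_new(length(context), Na = length(rewards),
                       hidden = integer(0), streams = streams)
  exact_J <- function(pol) {
    p <- as.numeric(policy_forward(pol, context))
    sum(p * rewards)
  }
  exact_grad <- function(pol, h = 1e-5) {
    v <- net_to_vec(pol$net)
    vapply(seq_along(v), function(k) {
      vp <- v; vp[k] <- vp[k] + h
      vm <- v; vm[k] <- vm[k] - h
      pp <- pol; pp$net <- vec_to_net(pol$net, vp)
      pm <- pol; pm$net <- vec_to_net(pol$net, vm)
      (exact_J(pp) - exact_J(pm)) / (2 * h)
    }, numeric(1))
  }
  list(policy = policy, context = context, rewards = rewards,
       exact_J = exact_J, exact_grad = exact_grad, streams = streams)
}

#' Monte-Carlo REINFORCE gradient estimate on the bandit
#'
#' Averages the single-episode policy-gradient contribution
#' \eqn{r_a \nabla_\theta \log p(a)} over sampled episodes, using the same
#' update path ([pg_update()] at unit learning rate) as training.
#'
#' @param task a [bandit_task()].
#' @param episodes number of sampled episodes.
#' @return numeric vector: the estimated gradient in every coordinate.
#' @export
bandit_gradient_estimate <- function(task, episodes = 50000) {
  pol <- task$policy
  x <- matrix(policy_preprocess(pol, task$context), 1L)
  v0 <- net_to_vec(pol$net)
  dist <- policy_forward(pol, task$context)
  acc <- numeric(length(v0))
  for (e in seq_len(episodes)) {
    a <- sample_action(dist, task$streams)
    upd <- pg_update(pol, x, a, reward = task$rewards[a], baseline = 0,
                     alpha = 1)
    acc <- acc + (net_to_vec(upd$policy$net) - v0)
  }
  acc / episodes
}

#' REINFORCE ascent runs on the bandit
#'
#' Repeated single-episode updates with a small learning rate; reports the
#' exact expected reward before and after for each seed.
#'
#' @param seeds integer vector of run seeds.
#' @param iterations updates per run.
#' @param alpha learning rate.
#' @param rewards per-action rewards.
#' @return tibble with `seed`, `J_start`, `J_end`, `improved`,
#'   `p_best_end` (final probability of the best action).
#' @export
bandit_convergence <- function(seeds = 1:100, iterations = 500, alpha = 0.05,
                               rewards = c(0.9, 0.1, 0.3)) {
  rows <- lapply(seeds, function(s) {
    task <- bandit_task(rewards = rewards, seed = s)
    pol <- task$policy
    x <- matrix(policy_preprocess(pol, task$context), 1L)
    J0 <- task$exact_J(pol)
    for (t in seq_len(iterations)) {
      dist <- policy_forward(pol, task$context)
      a <- sample_action(dist, task$streams)
      pol <- pg_update(pol, x, a, reward = task$rewards[a], baseline = 0,
                       alpha = alpha)$policy
    }
    p_end <- as.numeric(policy_forward(pol, task$context))
    tibble::tibble(seed = s, J_start = J0, J_end = task$exact_J(pol),
                   improved = task$exact_J(pol) > J0,
                   p_best_end = p_end[which.max(task$rewards)])
  })
  dplyr::bind_rows(rows)
}

recovery_config <- function(seed) {
  training_config(B = 16, E = 5, M = 32, f_min = 1, f_max = 30,
                  max_iterations = 200, term_eps = 1e-6, alpha = 0.4,
                  alpha_decay = 0.995, policy_hidden = integer(0),
                  backbone_lr = 0.5, backbone_batch = 4, baseline = TRUE,
                  seeds = list(policy = seed, action = seed + 10000,
                               backbone = seed + 20000))
}

#' Two-class wavelet-recovery experiment
#'
#' The headline validation study: two synthetic classes whose beats are
#' built from db4 and bior3.3 atoms respectively, with additive noise and
#' baseline wander.  For each run seed a policy is trained from scratch;
#' recovery is measured by (a) the total-variation distance between the
#' two classes' greedy selected-family histograms on held-out records,
#' (b) the mean reward of the last ten iterations against the best
#' fixed-base control at the same budget, and (c) the improvement of the
#' reward trace over its first ten iterations.
#'
#' @param run_seeds integer vector of training seeds.
#' @param dataset_seed seed of the shared synthetic dataset.
#' @param n_per_class records per class (240 records total by default).
#' @param spec optional [synthetic_spec()] override.
#' @param config_fn function(seed) returning the [training_config()] for a
#'   run; the default is the study configuration (B = 16, E = 5, M = 32,
#'   200 iterations).
#' @param controls if `TRUE`, run the fixed-base control for every catalog
#'   base at the identical budget.
#' @param store optional prebuilt feature store (for reuse across calls).
#' @param verbose print one line per run.
#' @return list with `per_seed` (tibble: seed, tv_distance, first10,
#'   last10, improved), `controls` (tibble: base index/name, mean last-10
#'   reward), `best_control`, `dataset`, `store`, `catalog`.
#' @export
recovery_experiment <- function(run_seeds = 1:10, dataset_seed = 421,
                                n_per_class = 120, spec = NULL,
                                config_fn = recovery_config,
                                controls = TRUE, store = NULL,
                                verbose = FALSE) {
  spec <- spec %||% synthetic_spec()
  dataset <- generate_dataset(spec, n_per_class = n_per_class,
                              seed = dataset_seed)
  catalog <- build_catalog()
  base_cfg <- config_fn(run_seeds[1])
  store <- store %||% build_feature_store(dataset, catalog, base_cfg)
  test_idx <- which(dataset$split == "test")
  classes <- dataset$primary_class
  fams <- unique(catalog_table(catalog)$family)

  per_seed <- lapply(run_seeds, function(s) {
    cfg <- config_fn(s)
    fit <- run_training(dataset, catalog, cfg, store = store)
    ev <- evaluate_policy(fit, catalog = catalog, store = store,
                          idx = test_idx, config = cfg)
    sel <- ev$selection
    sel$class <- classes[test_idx]
    hist_of <- function(cl) {
      f <- sel$family[sel$class == cl]
      vapply(fams, function(fm) mean(f == fm), numeric(1))
    }
    cls <- unique(classes)
    tv <- 0.5 * sum(abs(hist_of(cls[1]) - hist_of(cls[2])))
    r <- fit$history$reward
    row <- tibble::tibble(
      seed = s, tv_distance = tv,
      first10 = mean(r[seq_len(min(10, length(r)))]),
      last10 = mean(utils::tail(r, 10)),
      improved = mean(utils::tail(r, 10)) > mean(r[seq_len(min(10, length(r)))]))
    if (verbose)
      message(sprintf("seed %d: tv=%.2f first10=%.3f last10=%.3f",
                      s, row$tv_distance, row$first10, row$last10))
    row
  })
  per_seed <- dplyr::bind_rows(per_seed)

  controls_tab <- NULL
  best_control <- NA_real_
  if (controls) {
    split_idx <- list(train = which(dataset$split == "train"),
                      eval = which(dataset$split == "eval"))
    cfg0 <- config_fn(run_seeds[1])
    tab <- catalog_table(catalog)
    controls_tab <- dplyr::bind_rows(lapply(seq_len(catalog$Na), function(a) {
      tr <- fixed_base_trace(store, split_idx, a, cfg0)
      tibble::tibble(index = a, name = tab$name[a], family = tab$family[a],
                     last10 = mean(utils::tail(tr, 10)))
    }))
    best_control <- max(controls_tab$last10)
  }
  list(per_seed = per_seed, controls = controls_tab,
       best_control = best_control, dataset = dataset, store = store,
       catalog = catalog)
}
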