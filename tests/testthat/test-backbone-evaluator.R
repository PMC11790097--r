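test_that("backbone reset restores the initial weights bitwise", {
  st <- rng_streams(4)
  bb <- backbone_new(32, K = 2, hidden = 8, streams = st)
  probe <- matrix(rnorm(5 * 32), 5)
  fresh_scores <- predict_backbone(bb, probe)

  X <- matrix(rnorm(20 * 32), 20)
  y <- matrix(rbinom(40, 1, 0.5), 20)
  tr <- train_backbone(bb, X, y, epochs = 3, lr = 0.2, streams = st)
  expect_false(identical(tr$state$net, bb$net))

  back <- reset_backbone(tr$state)
  expect_identical(back$net, back$initial_snapshot)
  expect_identical(back$net, bb$initial_snapshot)
  expect_identical(predict_backbone(back, probe), fresh_scores)
  # idempotent, and the snapshot itself survives
  expect_identical(reset_backbone(back)$net, back$net)
})

test_that("training respects the epoch budget and the rng stream", {
  st <- rng_streams(4)
  bb <- backbone_new(16, K = 2, hidden = 4, streams = st)
  X <- matrix(rnorm(10 * 16), 10)
  y <- matrix(rbinom(20, 1, 0.5), 10)
  tr0 <- train_backbone(bb, X, y, epochs = 0, lr = 0.5, streams = st)
  expect_identical(tr0$state$net, bb$net)

  t1 <- train_backbone(bb, X, y, epochs = 5, lr = 0.5,
                       streams = rng_streams(77))
  t2 <- train_backbone(bb, X, y, epochs = 5, lr = 0.5,
                       streams = rng_streams(77))
  expect_identical(t1$state$net, t2$state$net)
  expect_equal(t1$loss, t2$loss)

  expect_error(train_backbone(bb, X, y[1:5, ], epochs = 1), "aligned")
  expect_error(train_backbone(bb, matrix(0, 4, 7), matrix(0, 4, 2),
                              epochs = 1), "input_dim")
})

test_that("backbone learns a linearly separable toy problem", {
  # verify separability first with a closed-form linear rule
  set.seed(8)
  n <- 40
  X <- rbind(matrix(rnorm(n * 16, mean = 1.5), n),
             matrix(rnorm(n * 16, mean = -1.5), n))
  y <- cbind(rep(c(1, 0), each = n), rep(c(0, 1), each = n))
  linear_rule <- as.numeric(rowMeans(X) > 0)
  expect_equal(linear_rule, y[, 1])  # oracle: a linear classifier exists

  st <- rng_streams(4)
  bb <- backbone_new(16, K = 2, hidden = 8, streams = st)
  tr <- train_backbone(bb, X, y, epochs = 50, lr = 0.3, streams = st)
  acc <- mean(((predict_backbone(tr$state, X) >= 0.5) * 1) == y)
  expect_gte(acc, 0.95)
})

test_that("prediction scores are sigmoid outputs in [0, 1]", {
  st <- rng_streams(4)
  bb <- backbone_new(8, K = 3, hidden = 4, streams = st)
  X <- matrix(rnorm(50 * 8), 50)
  S <- predict_backbone(bb, X)
  expect_true(all(S >= 0 & S <= 1))
  expect_identical(predict_backbone(bb, X), S)

  zero_head <- bb
  L <- length(zero_head$net$W)
  zero_head$net$W[[L]][] <- 0
  zero_head$net$b[[L]][] <- 0
  expect_true(all(predict_backbone(zero_head, X) == 0.5))
})

test_that("diverging training aborts with a diagnostic", {
  st <- rng_streams(4)
  bb <- backbone_new(4, K = 1, hidden = 2, streams = st)
  X <- matrix(1e200, 8, 4)
  y <- matrix(0, 8, 1)
  expect_error(train_backbone(bb, X, y, epochs = 5, lr = 1e200,
                              streams = st), "non-finite|diverged")
})

test_that("confusion counts agree with a per-record loop", {
  expect_error(confusion(matrix(0, 3, 2), matrix(0, 2, 2)), "shapes")
  expect_error(confusion(matrix(2, 3, 2), matrix(0, 3, 2)), "binary")

  # perfect predictions
  y <- matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 10, 1)
  cc <- confusion(y, y)
  expect_equal(cc$tp + cc$tn, 10)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)

  # all-positive predictions against all-negative truth
  cc2 <- confusion(matrix(0, 7, 1), matrix(1, 7, 1))
  expect_equal(cc2$fp, 7)

  set.seed(10)
  y <- matrix(rbinom(500 * 3, 1, 0.4), 500)
  p <- matrix(rbinom(500 * 3, 1, 0.5), 500)
  cc3 <- confusion(y, p)
  for (k in 1:3) {
    tp <- fp <- tn <- fn <- 0
    for (i in 1:500) {
      if (p[i, k] == 1 && y[i, k] == 1) tp <- tp + 1
      if (p[i, k] == 1 && y[i, k] == 0) fp <- fp + 1
      if (p[i, k] == 0 && y[i, k] == 0) tn <- tn + 1
      if (p[i, k] == 0 && y[i, k] == 1) fn <- fn + 1
    }
    expect_equal(unlist(cc3[k, c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(sum(cc3[k, c("tp", "fp", "tn", "fn")]), 500)
  }
})

test_that("metric formulas agree exactly with brute-force computation", {
  set.seed(12)
  for (rep in 1:200) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1)
    tn <- sample(0:20, 1); fn <- sample(0:20, 1)
    counts <- tibble::tibble(class = "c1", tp = tp, fp = fp, tn = tn, fn = fn)
    m <- compute_metrics(counts)$per_class
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    expect_identical(m$precision, prec)
    expect_identical(m$recall, rec)
    expect_identical(m$sensitivity, rec)
    expect_identical(m$specificity, spec)
    expect_identical(m$f1, f1)
    expect_identical(m$mcc, mcc)
    expect_identical(m$auc_sens_spec, rec * spec)
    expect_true(mcc >= -1 && mcc <= 1)
    if (prec > 0 && rec > 0)
      expect_equal(m$f1, 2 / (1 / prec + 1 / rec), tolerance = 1e-12)
  }
})

test_that("macro is the unweighted per-class mean and micro pools counts", {
  set.seed(13)
  y <- matrix(rbinom(200 * 4, 1, 0.3), 200)
  s <- matrix(runif(200 * 4), 200)
  rep <- compute_metrics(confusion(y, (s >= 0.5) * 1), s, y)
  for (col in c("precision", "recall", "specificity", "f1", "mcc")) {
    expect_equal(rep$macro[[col]], mean(rep$per_class[[col]]),
                 tolerance = 1e-12)
  }
  pooled <- compute_metrics(tibble::tibble(
    class = "pooled", tp = sum(rep$per_class$tp), fp = sum(rep$per_class$fp),
    tn = sum(rep$per_class$tn), fn = sum(rep$per_class$fn)))$per_class
  expect_equal(rep$micro$precision, pooled$precision, tolerance = 1e-12)
  expect_equal(rep$micro$recall, pooled$recall, tolerance = 1e-12)
  expect_equal(rep$micro$f1, pooled$f1, tolerance = 1e-12)
})

test_that("rank-based AUROC equals the pairwise oracle and pROC", {
  set.seed(14)
  for (rep in 1:20) {
    n <- 40
    scores <- round(runif(n), 1)  # coarse grid forces ties
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    a <- auroc(scores, labels)
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    wins <- 0
    for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
    expect_equal(a, wins / (length(pos) * length(neg)), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(15)
    scores <- runif(200)
    labels <- rbinom(200, 1, 0.4)
    expect_equal(auroc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_true(is.na(auroc(runif(5), rep(1, 5))))
})

test_that("label-independent predictions give near-zero MCC and 0.5 AUROC", {
  set.seed(16)
  n <- 10000
  y <- matrix(rbinom(n, 1, 0.5), n, 1)
  p <- matrix(rbinom(n, 1, 0.5), n, 1)
  s <- matrix(runif(n), n, 1)
  rep <- compute_metrics(confusion(y, p), s, y)
  expect_lt(abs(rep$per_class$mcc), 0.1)
  expect_lt(abs(rep$per_class$auc - 0.5), 0.05)
})

test_that("reward metric extracts the configured scalar", {
  perfect <- compute_metrics(tibble::tibble(
    class = c("a", "b"), tp = c(5, 4), fp = c(0, 0), tn = c(5, 6),
    fn = c(0, 0)))
  expect_equal(reward_metric(perfect), 1)

  mixed <- compute_metrics(tibble::tibble(
    class = c("a", "b"), tp = c(5, 1), fp = c(0, 1), tn = c(5, 7),
    fn = c(0, 1)))
  expect_equal(mixed$per_class$f1, c(1, 0.5))
  expect_equal(reward_metric(mixed), 0.75)

  set.seed(17)
  y <- matrix(rbinom(4000, 1, 0.5), 2000, 2)
  s <- matrix(runif(4000), 2000, 2)
  rnd <- compute_metrics(confusion(y, (s >= 0.5) * 1), s, y)
  expect_lt(abs(reward_metric(rnd, "macro_auc") - 0.5), 0.05)
  expect_error(reward_metric(rnd, "accuracy_of_vibes"), "unknown")
})

test_that("metric reports tidy and serialize", {
  set.seed(18)
  y <- matrix(rbinom(100, 1, 0.4), 50, 2)
  s <- matrix(runif(100), 50, 2)
  rep <- compute_metrics(confusion(y, (s >= 0.5) * 1), s, y)
  td <- tidy(rep)
  expect_equal(td$level, c("class", "class", "macro", "micro"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(rep, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 4)
})
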