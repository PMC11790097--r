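test_that("a clean single-atom beat correlates with the generating wavelet", {
  spec <- synthetic_spec(
    classes = list(A = list(wavelet = "db4", scale_range = c(8, 8),
                            atoms_per_beat = 1, amplitude = 1, offset = 0)),
    background = NULL, noise_sd = 0, wander_amplitude = 0,
    amplitude_jitter_sd = 0, beat_jitter_sd = 0, random_phase = FALSE)
  rec <- generate_record(spec, 1, streams = rng_streams(1))
  sig <- rec$samples[1, ]
  atom <- rlwbs:::wavelet_atom("db4", 8)
  # one beat sits at the centre of the first period (sample 50 of 100 Hz... )
  # oracle: normalized cross-correlation of the signal with the atom
  xc <- vapply(seq_len(length(sig) - length(atom)), function(s) {
    seg <- sig[s:(s + length(atom) - 1)]
    if (sum(seg^2) == 0) return(0)
    sum(seg * atom) / sqrt(sum(seg^2) * sum(atom^2))
  }, numeric(1))
  expect_gte(max(xc), 0.99)
  # and the peak sits at a beat position (centres at phase + k*period)
  period <- spec$sampling_rate * 60 / spec$beat_rate
  peak <- which.max(xc) + floor(length(atom) / 2)
  expect_lt(min(abs(peak - seq(period / 2, length(sig), by = period))), 3)
})

test_that("zero atoms and zero noise produce the all-zero record", {
  spec <- synthetic_spec(
    classes = list(A = list(wavelet = "db4", scale_range = c(8, 8),
                            atoms_per_beat = 0)),
    background = NULL, noise_sd = 0, wander_amplitude = 0)
  rec <- generate_record(spec, 1, streams = rng_streams(1))
  expect_true(all(rec$samples == 0))
})

test_that("record generation is deterministic per stream state", {
  spec <- synthetic_spec()
  r1 <- generate_record(spec, c(1, 0), streams = rng_streams(5))
  r2 <- generate_record(spec, c(1, 0), streams = rng_streams(5))
  r3 <- generate_record(spec, c(1, 0), streams = rng_streams(6))
  expect_identical(r1$samples, r2$samples)
  expect_false(identical(r1$samples, r3$samples))
  expect_error(generate_record(spec, c(1, 0, 1), streams = rng_streams(1)))
  expect_error(synthetic_spec(classes = list(
    A = list(wavelet = "nope", scale_range = c(4, 4), atoms_per_beat = 1))),
    "nope")
})

test_that("dataset splits are balanced, disjoint and sized as requested", {
  ds <- generate_dataset(fast_spec(), n_per_class = 100,
                         split_fractions = c(train = 0.6, eval = 0.2,
                                             test = 0.2), seed = 3)
  expect_equal(nrow(ds), 200)
  expect_equal(sum(ds$split == "train"), 120)
  expect_equal(sum(ds$split == "eval"), 40)
  expect_equal(sum(ds$split == "test"), 40)
  expect_equal(anyDuplicated(ds$record_id), 0)
  # balanced within splits
  tab <- table(ds$split, ds$primary_class)
  expect_true(all(tab[, "A"] == tab[, "B"]))
  expect_error(generate_dataset(fast_spec(), n_per_class = 2, seed = 1),
               "too small")
})

test_that("co-occurrence probability controls multi-label marginals", {
  spec0 <- fast_spec(co_label_prob = 0)
  ds0 <- generate_dataset(spec0, n_per_class = 20, seed = 2)
  expect_true(all(rowSums(label_matrix(ds0)) == 1))

  spec <- synthetic_spec(
    classes = list(
      A = list(wavelet = "db4", scale_range = c(4, 4), atoms_per_beat = 0),
      B = list(wavelet = "bior3.3", scale_range = c(4, 4), atoms_per_beat = 0)),
    background = NULL, length = 40, sampling_rate = 20, noise_sd = 0,
    wander_amplitude = 0, co_label_prob = 0.3)
  ds <- generate_dataset(spec, n_per_class = 2500, seed = 4)
  frac_multi <- mean(rowSums(label_matrix(ds)) == 2)
  expect_lt(abs(frac_multi - 0.3), 0.02)
})

test_that("generated records concentrate their power below 40 Hz", {
  ds <- generate_dataset(synthetic_spec(), n_per_class = 5, seed = 9)
  frac <- vapply(ds$signal, function(sig) {
    x <- sig[1, ]
    p <- Mod(stats::fft(x))^2
    n <- length(x)
    freqs <- (seq_len(n) - 1) * 100 / n
    half <- freqs > 0 & freqs <= 50
    sum(p[half & freqs <= 40]) / sum(p[half])
  }, numeric(1))
  expect_gt(mean(frac), 0.9)
})

test_that("the matched fixed base beats mismatched foreign-family bases", {
  # well-posedness of the recovery task: a backbone trained on class-A-
  # matched (db4) scalograms outperforms bases matched to neither class
  ds <- generate_dataset(synthetic_spec(), n_per_class = 120, seed = 421)
  cfg <- training_config(M = 32, f_min = 1, f_max = 30)
  cat2 <- build_catalog(c("db4", "coif4", "sym20"))
  store <- build_feature_store(ds, cat2, cfg)
  tr_idx <- which(ds$split == "train")
  ev_idx <- which(ds$split == "eval")
  f1_for <- function(base_i) {
    st <- rng_streams(13)
    mean(vapply(1:6, function(rep) {
      bb <- backbone_new(store$D, 2, streams = st)
      feat <- rlwbs:::feature_rows(store, tr_idx, rep(base_i, length(tr_idx)))
      tr <- train_backbone(bb, feat, store$labels[tr_idx, ], epochs = 30,
                           lr = 0.5, batch_size = 8, streams = st)
      fe <- rlwbs:::feature_rows(store, ev_idx, rep(base_i, length(ev_idx)))
      sc <- predict_backbone(tr$state, fe)
      rep_m <- compute_metrics(confusion(store$labels[ev_idx, ],
                                         (sc >= 0.5) * 1), sc,
                               store$labels[ev_idx, ])
      rep_m$macro$f1
    }, numeric(1)))
  }
  f_matched <- f1_for(1)
  expect_gte(f_matched - f1_for(2), 0.05)
  expect_gte(f_matched - f1_for(3), 0.05)
})

test_that("datasets serialize to plain-text matrices plus a manifest", {
  dir <- withr::local_tempdir()
  ds <- fast_dataset(n_per_class = 3)
  manifest <- write_dataset(ds, dir)
  tab <- utils::read.csv(manifest)
  expect_equal(nrow(tab), 6)
  expect_true(all(c("record_id", "split", "label_1", "label_2") %in%
                    names(tab)))
  sig <- as.matrix(utils::read.table(
    file.path(dir, paste0(tab$record_id[1], ".txt"))))
  expect_equal(unname(sig), unname(ds$signal[[1]]), tolerance = 1e-6)
})

test_that("datasets round-trip through the on-disk format", {
  dir <- withr::local_tempdir()
  ds <- fast_dataset(n_per_class = 3)
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$record_id, ds$record_id)
  expect_equal(back$split, ds$split)
  expect_identical(label_matrix(back), unname(label_matrix(ds)))
  for (i in seq_len(nrow(ds)))
    expect_equal(back$signal[[i]], ds$signal[[i]], tolerance = 1e-6)
  spec <- attr(back, "spec")
  expect_s3_class(spec, "synthetic_spec")
  expect_equal(spec$length, attr(ds, "spec")$length)
  expect_error(read_dataset(file.path(dir, "nope")), "manifest")
})
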