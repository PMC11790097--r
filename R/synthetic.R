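#' Specification for the synthetic ECG generator
#'
#' Generates fixed-length, multi-lead, ECG-like records whose
#' class-discriminative morphology is wavelet-matched: each class's beats
#' are built from scaled/shifted copies of a designated mother wavelet
#' sampled by the same cascade machinery used for feature extraction, so
#' the optimal analysis wavelet genuinely differs by class and
#' base-selection recovery is testable without clinical data.  On top of
#' the beat trains the generator adds white Gaussian noise and a
#' low-frequency sinusoidal baseline wander.
#'
#' @param classes named list of per-class atom recipes; each recipe is a
#'   list with `wavelet` (catalog base name), `scale_range` (length-2,
#'   samples), `atoms_per_beat`, `amplitude` (peak, signal units) and
#'   `offset` (atom position relative to the beat centre, in fractions of
#'   the beat period).  The default two classes use weak db4 and bior3.3
#'   atoms riding on a strong shared background beat.
#' @param background optional recipe (same fields) for a morphology shared
#'   by every record regardless of class, emulating the common PQRST-like
#'   bulk of the signal that carries no class information.
#' @param length record length in samples.
#' @param sampling_rate Hz.
#' @param leads number of leads.
#' @param beat_rate beats per minute.
#' @param noise_sd standard deviation of the additive white noise
#'   (signal units; atom peak amplitude is 1).
#' @param wander_amplitude,wander_freq baseline-wander sinusoid amplitude
#'   (signal units) and frequency (Hz).
#' @param co_label_prob probability that a record additionally carries one
#'   other class's label (and morphology).
#' @param amplitude_jitter_sd multiplicative log-normal amplitude jitter of
#'   each atom (sd of the underlying normal; 0 disables).
#' @param beat_jitter_sd per-beat timing jitter in seconds (0 disables).
#' @param random_phase if `TRUE`, each record's beat train starts at a
#'   uniformly random phase of the beat period.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(classes = list(
                             A = list(wavelet = "db4", scale_range = c(8, 8),
                                      atoms_per_beat = 1, amplitude = 0.35,
                                      offset = 0.35),
                             B = list(wavelet = "bior3.3", scale_range = c(8, 8),
                                      atoms_per_beat = 1, amplitude = 0.35,
                                      offset = 0.35)),
                           background = list(wavelet = "sym5",
                                             scale_range = c(12, 12),
                                             atoms_per_beat = 1, amplitude = 1,
                                             offset = 0),
                           length = 1000, sampling_rate = 100, leads = 1,
                           beat_rate = 60, noise_sd = 0.1,
                           wander_amplitude = 0.2, wander_freq = 0.3,
                           co_label_prob = 0,
                           amplitude_jitter_sd = 0.2, beat_jitter_sd = 0.05,
                           random_phase = TRUE) {
  stopifnot(noise_sd >= 0, beat_rate > 0, sampling_rate > 0, length > 0,
            leads >= 1, co_label_prob >= 0, co_label_prob <= 1)
  check_recipe <- function(r, who) {
    if (is.null(.wavelet_filter_bank[[r$wavelet]]))
      stopf("%s recipe names unknown wavelet '%s'", who, r$wavelet)
    stopifnot(length(r$scale_range) == 2, all(r$scale_range > 0),
              r$atoms_per_beat >= 0)
    r$amplitude <- r$amplitude %||% 1
    r$offset <- r$offset %||% 0
    r
  }
  for (nm in names(classes))
    classes[[nm]] <- check_recipe(classes[[nm]], sprintf("class '%s'", nm))
  if (!is.null(background)) background <- check_recipe(background, "background")
  spec <- list(classes = classes, background = background, K = length(classes),
               length = as.integer(length),
               sampling_rate = sampling_rate, leads = as.integer(leads),
               beat_rate = beat_rate, noise_sd = noise_sd,
               wander_amplitude = wander_amplitude, wander_freq = wander_freq,
               co_label_prob = co_label_prob,
               amplitude_jitter_sd = amplitude_jitter_sd,
               beat_jitter_sd = beat_jitter_sd,
               random_phase = isTRUE(random_phase))
  class(spec) <- "synthetic_spec"
  spec
}

# Unit-peak atom waveform: psi of `wavelet` resampled at dilation `scale`
# (in samples).
wavelet_atom <- function(wavelet, scale) {
  base <- if (inherits(wavelet, "wavelet_base")) wavelet else
    sample_wavelet_function(wavelet)
  k0 <- ceiling(scale * min(base$psi_grid))
  k1 <- floor(scale * max(base$psi_grid))
  w <- stats::approx(base$psi_grid, base$psi_samples, xout = (k0:k1) / scale,
                     yleft = 0, yright = 0)$y
  w / max(abs(w))
}

#' Generate one synthetic record
#'
#' The signal is a periodic beat train: one beat per `60 / beat_rate`
#' seconds, each beat the sum of the active classes' wavelet atoms
#' (centred on the beat, scale drawn uniformly from the class's
#' `scale_range`), plus white noise and baseline wander.  Deterministic
#' for a fixed `"data"` stream state.
#'
#' @param spec a [synthetic_spec()].
#' @param class_assignment binary length-`K` vector of labels.
#' @param streams an [rng_streams()] object (its `"data"` stream is
#'   consumed), or `NULL` to use the current RNG state.
#' @param record_id,group_id identifiers stored on the record.
#' @return object of class `ecg_record`: list with `samples`
#'   (leads x length matrix), `sampling_rate`, `labels`, `record_id`,
#'   `group_id`.
#' @export
generate_record <- function(spec, class_assignment, streams = NULL,
                            record_id = NA_character_, group_id = NA_character_) {
  stopifnot(inherits(spec, "synthetic_spec"),
            length(class_assignment) == spec$K,
            all(class_assignment %in% c(0, 1)))
  build <- function() {
    n <- spec$length
    fs <- spec$sampling_rate
    period <- fs * 60 / spec$beat_rate
    phase <- if (spec$random_phase) stats::runif(1, 0, period) else period / 2
    centers <- seq(phase, n, by = period)
    sig <- matrix(0, spec$leads, n)
    add_atoms <- function(recipe) {
      base <- sample_wavelet_function(recipe$wavelet)
      if (recipe$atoms_per_beat == 0) return(invisible())
      for (ct in centers) {
        if (spec$beat_jitter_sd > 0)
          ct <- ct + stats::rnorm(1, sd = spec$beat_jitter_sd * fs)
        ct <- ct + recipe$offset * period
        for (j in seq_len(recipe$atoms_per_beat)) {
          sc <- stats::runif(1, recipe$scale_range[1], recipe$scale_range[2])
          amp <- recipe$amplitude *
            if (spec$amplitude_jitter_sd > 0)
              exp(stats::rnorm(1, sd = spec$amplitude_jitter_sd)) else 1
          atom <- amp * wavelet_atom(base, sc)
          start <- round(ct - length(atom) / 2)
          idx <- start:(start + length(atom) - 1L)
          ok <- idx >= 1L & idx <= n
          if (!any(ok)) next
          for (ld in seq_len(spec$leads))
            sig[ld, idx[ok]] <<- sig[ld, idx[ok]] + atom[ok]
        }
      }
    }
    if (!is.null(spec$background)) add_atoms(spec$background)
    for (k in seq_len(spec$K)) {
      if (class_assignment[k] == 0) next
      add_atoms(spec$classes[[k]])
    }
    if (spec$noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(length(sig), sd = spec$noise_sd),
                          nrow = spec$leads)
    if (spec$wander_amplitude > 0) {
      phase <- stats::runif(spec$leads, 0, 2 * pi)
      t <- (seq_len(n) - 1) / fs
      for (ld in seq_len(spec$leads))
        sig[ld, ] <- sig[ld, ] + spec$wander_amplitude *
          sin(2 * pi * spec$wander_freq * t + phase[ld])
    }
    sig
  }
  samples <- if (is.null(streams)) build() else with_stream(streams, "data", build())
  rec <- list(samples = samples, sampling_rate = spec$sampling_rate,
              labels = as.integer(class_assignment), record_id = record_id,
              group_id = group_id)
  class(rec) <- "ecg_record"
  rec
}

#' Generate a labeled, split synthetic dataset
#'
#' Balanced classes (each record has one primary class, plus co-occurring
#' labels at `co_label_prob`), split disjointly into training, evaluation
#' and test sets, stratified by primary class.
#'
#' @param spec a [synthetic_spec()].
#' @param n_per_class records per class.
#' @param split_fractions named numeric vector summing to 1 with entries
#'   `train`, `eval`, `test`.
#' @param seed integer seed for the dataset's `"data"` stream.
#' @return object of class `rlwbs_dataset`: a tibble with columns
#'   `record_id`, `group_id`, `primary_class`, `split`, `labels`
#'   (list-column of binary vectors), `signal` (list-column of
#'   leads x length matrices), carrying the `spec` as an attribute.
#' @export
generate_dataset <- function(spec, n_per_class = 120,
                             split_fractions = c(train = 0.6, eval = 0.2,
                                                 test = 0.2),
                             seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"),
            abs(sum(split_fractions) - 1) < 1e-9,
            all(c("train", "eval", "test") %in% names(split_fractions)))
  n_splits <- round(n_per_class * split_fractions)
  if (any(n_splits < 1))
    stopf("n_per_class = %d is too small for split fractions (%s)",
          n_per_class, paste(format(split_fractions), collapse = "/"))
  streams <- rng_streams(seed)
  K <- spec$K
  rows <- list()
  idx <- 0L
  for (k in seq_len(K)) {
    split_vec <- rep(names(split_fractions), times = n_splits)
    length(split_vec) <- n_per_class
    split_vec[is.na(split_vec)] <- "train"
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      labels <- integer(K)
      labels[k] <- 1L
      if (K > 1 && spec$co_label_prob > 0) {
        co <- with_stream(streams, "data",
                          stats::runif(1) < spec$co_label_prob)
        if (co) {
          others <- setdiff(seq_len(K), k)
          other <- with_stream(streams, "data",
                               others[sample.int(length(others), 1L)])
          labels[other] <- 1L
        }
      }
      rid <- sprintf("rec_%04d", idx)
      rec <- generate_record(spec, labels, streams, record_id = rid,
                             group_id = rid)
      rows[[idx]] <- tibble::tibble(
        record_id = rid, group_id = rid,
        primary_class = names(spec$classes)[k] %||% paste0("class_", k),
        split = split_vec[i],
        labels = list(labels), signal = list(rec$samples))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- spec
  class(out) <- c("rlwbs_dataset", class(out))
  out
}

#' Binary label matrix of a dataset (n x K)
#' @param dataset an `rlwbs_dataset` (or subset of its rows).
#' @return integer matrix, one row per record.
#' @export
label_matrix <- function(dataset) {
  do.call(rbind, dataset$labels)
}

#' Write a dataset as plain-text matrices plus a manifest table
#'
#' One whitespace-delimited numeric matrix file per record and a CSV
#' manifest (`record_id`, `group_id`, `split`, label columns).
#'
#' @param dataset an `rlwbs_dataset`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset))) {
    utils::write.table(dataset$signal[[i]],
                       file.path(dir, paste0(dataset$record_id[i], ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  lm <- label_matrix(dataset)
  colnames(lm) <- paste0("label_", seq_len(ncol(lm)))
  manifest <- dplyr::bind_cols(
    dataset[, c("record_id", "group_id", "primary_class", "split")],
    tibble::as_tibble(lm))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  spec <- attr(dataset, "spec")
  if (!is.null(spec)) {
    sy <- unclass(spec)
    sy <- sy[intersect(names(sy), names(formals(synthetic_spec)))]
    yaml::write_yaml(sy, file.path(dir, "dataset_spec.yml"))
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory holding `manifest.csv` and one matrix file per
#'   record (plus the optional `dataset_spec.yml`).
#' @return an `rlwbs_dataset` tibble.
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stopf("no manifest.csv under '%s'", dir)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  label_cols <- grep("^label_", names(manifest), value = TRUE)
  out <- tibble::tibble(
    record_id = manifest$record_id,
    group_id = manifest$group_id,
    primary_class = manifest$primary_class,
    split = manifest$split,
    labels = lapply(seq_len(nrow(manifest)), function(i)
      as.integer(manifest[i, label_cols])),
    signal = lapply(manifest$record_id, function(id)
      as.matrix(utils::read.table(file.path(dir, paste0(id, ".txt")))))
  )
  out$signal <- lapply(out$signal, function(m) {
    dimnames(m) <- NULL
    m
  })
  spec_path <- file.path(dir, "dataset_spec.yml")
  if (file.exists(spec_path)) {
    sy <- yaml::read_yaml(spec_path)
    sy$classes <- lapply(sy$classes, function(cl) {
      cl$scale_range <- as.numeric(cl$scale_range)
      cl
    })
    if (!is.null(sy$background))
      sy$background$scale_range <- as.numeric(sy$background$scale_range)
    attr(out, "spec") <- do.call(synthetic_spec, sy)
  }
  class(out) <- c("rlwbs_dataset", class(out))
  out
}
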