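#' Precompute scalogram features for every (record, base) pair
#'
#' For a fixed dataset and catalog the scalogram of a record under a base
#' is deterministic, so the selection loop looks features up instead of
#' recomputing transforms every iteration.  Kernel spectra are shared
#' across records and the per-record signal FFT is reused across scales
#' and bases; the resulting features agree with [cwt()] +
#' [scalogram_to_feature()] to floating-point rounding.
#'
#' @param dataset an `rlwbs_dataset` (or any tibble with `signal` and
#'   `labels` list-columns and a `record_id` column).
#' @param catalog a `wavelet_catalog`.
#' @param config a [training_config()] (supplies `M`, the frequency band
#'   and the feature dimensions).
#' @param sampling_rate Hz of the signals (taken from the dataset spec if
#'   present).
#' @return object of class `rlwbs_feature_store`: list with `features`
#'   (`n x Na x D` array of flattened features), `policy_inputs`
#'   (`n x P` matrix), `labels` (`n x K`), `record_id`, `catalog_hash`,
#'   and the feature geometry.
#' @export
build_feature_store <- function(dataset, catalog, config,
                                sampling_rate = NULL) {
  stopifnot(inherits(catalog, "wavelet_catalog"))
  spec <- attr(dataset, "spec")
  fs <- sampling_rate %||% (if (!is.null(spec)) spec$sampling_rate else
    stopf("sampling_rate must be given when the dataset carries no spec"))
  n <- nrow(dataset)
  if (n == 0) stopf("dataset has no records")
  sig1 <- dataset$signal[[1]]
  if (is.vector(sig1)) sig1 <- matrix(sig1, nrow = 1L)
  leads <- nrow(sig1)
  N <- ncol(sig1)
  D <- config$feat_height * config$feat_width
  Na <- catalog$Na

  # per-base scale grids and kernel FFTs (shared by all records)
  grids <- lapply(catalog$bases, function(b)
    default_scale_grid(N, fs, M = config$M, f_min = config$f_min,
                       f_max = config$f_max, base = b))
  kernel_info <- vector("list", Na)
  max_len <- 0L
  for (a in seq_len(Na)) {
    base <- catalog$bases[[a]]
    support <- range(base$psi_grid)
    ks <- lapply(grids[[a]]$scales, function(ci) {
      k0 <- ceiling(ci * support[1])
      k1 <- floor(ci * support[2])
      if (k1 - k0 + 1L > 10L * N)
        stopf("scale %g rescales the wavelet to over 10x the signal length", ci)
      kern <- stats::approx(base$psi_grid, base$psi_samples,
                            xout = (k0:k1) / ci, yleft = 0, yright = 0)$y /
        sqrt(ci)
      list(k0 = as.integer(k0), K = as.integer(k1 - k0 + 1), kern = kern)
    })
    kernel_info[[a]] <- ks
    max_len <- max(max_len, vapply(ks, function(k) k$K, integer(1)))
  }
  nf <- stats::nextn(N + max_len - 1L, 2)
  for (a in seq_len(Na)) {
    kernel_info[[a]] <- lapply(kernel_info[[a]], function(k) {
      k$fft <- stats::fft(c(rev(k$kern), numeric(nf - k$K)))
      k$kern <- NULL
      k
    })
  }

  features <- array(0, dim = c(n, Na, D))
  policy_inputs <- matrix(0, n, leads * min(config$pool_len, N))
  for (i in seq_len(n)) {
    sig <- dataset$signal[[i]]
    if (is.vector(sig)) sig <- matrix(sig, nrow = 1L)
    fx <- lapply(seq_len(leads), function(ld)
      stats::fft(c(sig[ld, ], numeric(nf - N))))
    for (a in seq_len(Na)) {
      ks <- kernel_info[[a]]
      W <- matrix(0, config$M, N)
      for (m in seq_len(config$M)) {
        k0 <- ks[[m]]$k0
        K <- ks[[m]]$K
        idx <- seq_len(N) + k0 + K - 1L
        ok <- idx >= 1L & idx <= nf
        acc <- numeric(N)
        for (ld in seq_len(leads)) {
          full <- Re(stats::fft(fx[[ld]] * ks[[m]]$fft, inverse = TRUE)) / nf
          row <- numeric(N)
          row[ok] <- full[idx[ok]]
          acc <- acc + abs(row)
        }
        W[m, ] <- acc / leads
      }
      r <- bilinear_resize(W, config$feat_height, config$feat_width)
      rng <- range(r)
      if (rng[2] - rng[1] > 0) r <- (r - rng[1]) / (rng[2] - rng[1])
      else r[] <- 0
      features[i, a, ] <- as.vector(r)
    }
    policy_inputs[i, ] <- policy_input_vector(sig, config$pool_len)
  }
  labels <- do.call(rbind, dataset$labels)
  store <- list(features = features, policy_inputs = policy_inputs,
                labels = labels, record_id = dataset$record_id,
                catalog_hash = catalog$hash, leads = leads, N = N,
                D = D, Na = Na, feat_height = config$feat_height,
                feat_width = config$feat_width)
  class(store) <- "rlwbs_feature_store"
  store
}

# Policy input front end (shared with policy_preprocess): per lead the
# magnitude spectrum (DC dropped), block-averaged to pool_len bins and
# log-compressed, then standardised per record.  The spectral view is
# invariant to the beat phase of the record, which a small dense network
# needs to judge morphology.
policy_input_vector <- function(signal, pool_len) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  n <- ncol(signal)
  half <- max(floor(n / 2), 1L)
  P <- min(pool_len, half)
  bounds <- floor(seq(0L, half, length.out = P + 1L))
  pooled <- t(apply(signal, 1L, function(row) {
    m <- Mod(stats::fft(row))[2:(half + 1L)]
    vapply(seq_len(P), function(i)
      mean(m[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  }))
  v <- log1p(as.numeric(t(pooled)))
  s <- stats::sd(v)
  if (s > 0) (v - mean(v)) / s else v * 0
}

#' @export
print.rlwbs_feature_store <- function(x, ...) {
  cat(sprintf("<rlwbs_feature_store> %d records x %d bases, feature %dx%d\n",
              dim(x$features)[1], x$Na, x$feat_height, x$feat_width))
  invisible(x)
}
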