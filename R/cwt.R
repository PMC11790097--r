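#' Scale grid for the sampled CWT
#'
#' Scales are chosen on a logarithmic pseudo-frequency grid: the
#' pseudo-frequency of scale \eqn{c} for a base with center frequency
#' \eqn{f_c} at sampling rate \eqn{f_s} is \eqn{f = f_c f_s / c}.  The `M`
#' scales are log-spaced so the pseudo-frequencies span
#' `[f_min, f_max]`; scales are returned strictly increasing (largest
#' scale = lowest frequency last).
#'
#' @param signal_length number of samples `N` of the signals to analyze.
#' @param sampling_rate sampling rate in Hz.
#' @param M number of scales (>= 2).
#' @param f_min,f_max pseudo-frequency band in Hz; requires
#'   `0 < f_min < f_max <= sampling_rate / 2`.
#' @param base the `wavelet_base` whose center frequency converts scale to
#'   frequency.
#' @return object of class `scale_grid`: list with `scales` (ascending),
#'   `pseudo_frequencies` (descending, Hz), `N`, `sampling_rate`.
#' @export
default_scale_grid <- function(signal_length, sampling_rate, M = 64,
                               f_min = 0.5, f_max = 40, base) {
  stopifnot(inherits(base, "wavelet_base"))
  if (M < 2) stopf("M must be >= 2 (got %s)", format(M))
  if (f_min <= 0 || f_min >= f_max)
    stopf("need 0 < f_min < f_max (got f_min=%g, f_max=%g)", f_min, f_max)
  if (f_max > sampling_rate / 2)
    stopf("f_max = %g Hz is above the Nyquist frequency %g Hz", f_max,
          sampling_rate / 2)
  freqs <- exp(seq(log(f_max), log(f_min), length.out = M))
  scales <- base$center_frequency * sampling_rate / freqs
  grid <- list(scales = scales, pseudo_frequencies = freqs,
               N = as.integer(signal_length), sampling_rate = sampling_rate)
  class(grid) <- "scale_grid"
  grid
}

#' Sampled continuous wavelet transform (scalogram)
#'
#' Computes the sampled CWT matrix
#' \deqn{W(c_i, b_j) = \frac{1}{\sqrt{c_i}} \sum_k x(k)\,
#'   \psi\!\left(\frac{k - b_j}{c_i}\right)}
#' the discrete-convolution approximation of the CWT integral, with one
#' shift \eqn{b_j} per signal sample and zero-padding at the boundaries.
#' The wavelet is rescaled per scale by linear interpolation of its cascade
#' samples; scale is expressed in samples, so the energy normalisation
#' \eqn{1/\sqrt{c}} matches the integral form with unit sample spacing.
#'
#' @param signal numeric vector of length `grid$N` (one lead), all finite.
#' @param base a `wavelet_base`.
#' @param grid a `scale_grid`.
#' @param magnitude if `TRUE` (default) return `|W|`, else signed
#'   coefficients.
#' @return object of class `scalogram`: list with `values` (`M x N`
#'   matrix), `scale_grid`, `base_index`, `base_name`, `magnitude`.
#' @export
#' @examples
#' base <- sample_wavelet_function("db4")
#' grid <- default_scale_grid(256, 100, M = 16, f_min = 1, f_max = 30, base = base)
#' s <- cwt(sin(2 * pi * 5 * (0:255) / 100), base, grid)
#' dim(s$values)
cwt <- function(signal, base, grid, magnitude = TRUE) {
  stopifnot(inherits(base, "wavelet_base"), inherits(grid, "scale_grid"))
  signal <- as.numeric(signal)
  if (!all(is.finite(signal))) stopf("signal contains non-finite samples")
  N <- length(signal)
  if (N != grid$N)
    stopf("signal length %d does not match grid N = %d", N, grid$N)
  M <- length(grid$scales)
  vals <- matrix(0, M, N)
  support <- range(base$psi_grid)
  for (i in seq_len(M)) {
    ci <- grid$scales[i]
    k0 <- as.integer(ceiling(ci * support[1]))
    k1 <- as.integer(floor(ci * support[2]))
    K <- k1 - k0 + 1L
    if (K > 10L * N)
      stopf("scale %g rescales the wavelet to %d samples, over 10x the signal length %d",
            ci, K, N)
    kern <- stats::approx(base$psi_grid, base$psi_samples,
                          xout = (k0:k1) / ci, yleft = 0, yright = 0)$y / sqrt(ci)
    full <- conv_full(signal, rev(kern))
    idx <- (seq_len(N) + k0 + K - 1L)
    ok <- idx >= 1L & idx <= length(full)
    row <- numeric(N)
    row[ok] <- full[idx[ok]]
    vals[i, ] <- row
  }
  if (magnitude) vals <- abs(vals)
  s <- list(values = vals, scale_grid = grid, base_index = base$index,
            base_name = base$name, magnitude = magnitude)
  class(s) <- "scalogram"
  s
}

#' Resample a scalogram to a fixed-size feature matrix
#'
#' The backbone classifier needs a uniform input shape regardless of the
#' scale count and signal length.  The coefficient magnitudes are resampled
#' by corner-aligned bilinear interpolation to `out_height x out_width` and
#' min-max scaled to `[0, 1]` per scalogram; an all-constant scalogram maps
#' to all zeros.
#'
#' @param s a `scalogram`.
#' @param out_height,out_width target dimensions (>= 8).
#' @return numeric `out_height x out_width` matrix in `[0, 1]`.
#' @export
scalogram_to_feature <- function(s, out_height = 16, out_width = 32) {
  stopifnot(inherits(s, "scalogram"))
  if (out_height < 8 || out_width < 8)
    stopf("output dimensions must be >= 8 (got %d x %d)", out_height, out_width)
  v <- abs(s$values)
  r <- bilinear_resize(v, out_height, out_width)
  rng <- range(r)
  if (rng[2] - rng[1] <= 0) return(matrix(0, out_height, out_width))
  (r - rng[1]) / (rng[2] - rng[1])
}

#' Write a scalogram with a plain-text metadata header
#'
#' One matrix per record in delimited text, preceded by `# key: value`
#' header lines (base index and name, scales, sampling rate).
#'
#' @param s a `scalogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scalogram <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# base_index: %s", s$base_index),
    sprintf("# base_name: %s", s$base_name),
    sprintf("# magnitude: %s", s$magnitude),
    sprintf("# sampling_rate: %g", s$scale_grid$sampling_rate),
    sprintf("# scales: %s", paste(format(s$scale_grid$scales, digits = 10),
                                  collapse = " "))
  ), con)
  utils::write.table(s$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d scales x %d shifts, base %s%s\n",
              nrow(x$values), ncol(x$values), x$base_name,
              if (x$magnitude) " (magnitude)" else " (signed)"))
  invisible(x)
}

#' Plot a scalogram as a time-frequency heat map
#'
#' @param object a `scalogram`.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot scalogram
#' @export
autoplot.scalogram <- function(object, ...) {
  grid <- object$scale_grid
  df <- tibble::tibble(
    time = rep(seq_len(ncol(object$values)) / grid$sampling_rate,
               times = nrow(object$values)),
    frequency = rep(grid$pseudo_frequencies, each = ncol(object$values)),
    value = as.vector(t(abs(object$values)))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$frequency,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "|W|") +
    ggplot2::labs(x = "time [s]", y = "pseudo-frequency [Hz]",
                  title = sprintf("Scalogram (%s)", object$base_name)) +
    ggplot2::theme_minimal()
}
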