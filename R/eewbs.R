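#' Energy-to-Shannon-entropy wavelet base selection (EE-WBS)
#'
#' The classical static comparator: for each candidate base the scalogram
#' coefficients are computed and scored by the ratio of their energy
#' \eqn{E = \sum_i W_i^2} to the Shannon entropy
#' \eqn{S = -\sum_i p_i \log p_i} of the normalised energies
#' \eqn{p_i = W_i^2 / E}; the base with the largest ratio is selected.
#' A base whose coefficients are all zero scores \eqn{-\infty}.
#'
#' @param signal numeric vector (one lead) or leads x length matrix (the
#'   ratio is computed on the concatenated leads' coefficients).
#' @param catalog a `wavelet_catalog`.
#' @param sampling_rate Hz.
#' @param M,f_min,f_max scale-grid parameters (see
#'   [default_scale_grid()]).
#' @return list with `index` (selected base), `name`, and `scores`
#'   (numeric vector of the energy/entropy ratio per base).
#' @export
ee_wbs_select <- function(signal, catalog, sampling_rate, M = 32,
                          f_min = 0.5, f_max = 40) {
  stopifnot(inherits(catalog, "wavelet_catalog"))
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  scores <- vapply(seq_len(catalog$Na), function(a) {
    base <- catalog$bases[[a]]
    grid <- default_scale_grid(ncol(signal), sampling_rate, M = M,
                               f_min = f_min, f_max = f_max, base = base)
    w2 <- unlist(lapply(seq_len(nrow(signal)), function(ld)
      as.vector(cwt(signal[ld, ], base, grid, magnitude = FALSE)$values)^2))
    energy <- sum(w2)
    if (energy == 0) return(-Inf)
    p <- w2 / energy
    p <- p[p > 0]
    entropy <- -sum(p * log(p))
    energy / entropy
  }, numeric(1))
  idx <- which.max(scores)
  list(index = idx, name = catalog$bases[[idx]]$name, scores = scores)
}
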