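#' Sample a mother wavelet function by the cascade algorithm
#'
#' The compactly supported wavelets of the catalog (Haar, Daubechies,
#' Symlets, Coiflets, spline-biorthogonal) are defined by discrete filter
#' banks and, apart from Haar, have no closed form.  Their wavelet function
#' \eqn{\psi(t)} is obtained by the cascade algorithm: one synthesis step
#' with the high-pass (wavelet) filter followed by repeated upsample +
#' low-pass refinement steps, scaled by \eqn{2^{J/2}} after \eqn{J} levels.
#' This yields \eqn{\psi} on a uniform dyadic grid of step \eqn{2^{-J}}
#' covering its compact support.  For the biorthogonal family the pair
#' generates the analysis (decomposition) wavelet, since the transform here
#' is an analysis transform.
#'
#' @param base_name wavelet name, e.g. `"haar"`, `"db4"`, `"sym10"`,
#'   `"coif3"`, `"bior3.3"`.
#' @param resolution points per unit of support (>= 16).  Rounded up to the
#'   next power of two; the refinement depth is `log2(resolution)`
#'   (default 256 = depth 8).
#' @return an object of class `wavelet_base`: a list with `name`, `family`,
#'   `psi_samples`, `psi_grid` (dimensionless time), `center_frequency`
#'   (cycles per unit), the filter pair, and `index` (`NA` until the base
#'   is placed in a catalog).
#' @export
#' @examples
#' w <- sample_wavelet_function("db4")
#' plot(w$psi_grid, w$psi_samples, type = "l")
sample_wavelet_function <- function(base_name, resolution = 256) {
  fb <- .wavelet_filter_bank[[base_name]]
  if (is.null(fb))
    stopf("unknown wavelet name '%s'; supported names are those of the default catalog (see build_catalog())",
          base_name)
  if (!is.numeric(resolution) || resolution < 16)
    stopf("resolution must be >= 16 points per unit support (got %s)", format(resolution))
  level <- ceiling(log2(resolution))
  psi <- cascade_psi(fb$lo, fb$hi, level)
  step <- 2^-level
  grid <- seq_along(psi) * step
  base <- list(
    index = NA_integer_,
    family = fb$family,
    name = base_name,
    psi_samples = psi,
    psi_grid = grid,
    center_frequency = psi_center_frequency(psi, grid),
    filters = list(lo = fb$lo, hi = fb$hi),
    cascade_level = level
  )
  class(base) <- "wavelet_base"
  base
}

# Synthesis filter-bank cascade: v <- hi; J-1 times (upsample2, conv lo);
# scaled by 2^(J/2).  Grid step 2^-J, support [0, length(lo) - 1].
cascade_psi <- function(lo, hi, level) {
  v <- hi
  if (level >= 2) {
    for (j in seq_len(level - 1L)) {
      up <- numeric(2L * length(v) - 1L)
      up[seq(1L, length(up), by = 2L)] <- v
      v <- conv_full(up, lo)
    }
  }
  2^(level / 2) * v
}

# Dominant-frequency estimate of psi via the position of the FFT modulus
# peak, expressed in cycles per unit of (dimensionless) support time.
psi_center_frequency <- function(psi, grid) {
  domain <- grid[length(grid)] - grid[1]
  mod <- Mod(stats::fft(psi))
  half <- floor(length(psi) / 2)
  idx <- which.max(mod[2:(half + 1L)])  # skip DC
  idx / domain
}

#' @export
print.wavelet_base <- function(x, ...) {
  cat(sprintf("<wavelet_base> %s (%s family)%s\n", x$name, x$family,
              if (is.na(x$index)) "" else sprintf(", catalog index %d", x$index)))
  cat(sprintf("  support [0, %g], %d samples, center frequency %.4f\n",
              max(x$psi_grid), length(x$psi_samples), x$center_frequency))
  invisible(x)
}
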