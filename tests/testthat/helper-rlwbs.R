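# Shared fixtures, built in code at test time.

# A small catalog reused across tests (built once per test run).
tiny_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_catalog(c("haar", "db4", "bior3.3"))
    cache
  }
})

# A fast synthetic specification for loop-level tests: short records, low
# rate, deterministic phase, no nuisance components.
fast_spec <- function(...) {
  synthetic_spec(
    classes = list(
      A = list(wavelet = "db4", scale_range = c(6, 6), atoms_per_beat = 1,
               amplitude = 1, offset = 0),
      B = list(wavelet = "bior3.3", scale_range = c(6, 6), atoms_per_beat = 1,
               amplitude = 1, offset = 0)),
    background = NULL,
    length = 200, sampling_rate = 50, beat_rate = 60,
    noise_sd = 0.05, wander_amplitude = 0, ...)
}

fast_config <- function(...) {
  args <- utils::modifyList(
    list(B = 4, E = 2, M = 8, f_min = 2, f_max = 12,
         feat_height = 8, feat_width = 8, max_iterations = 3,
         term_eps = 1e-9, backbone_hidden = 8, policy_hidden = 8,
         pool_len = 32),
    list(...))
  do.call(training_config, args)
}

fast_dataset <- function(n_per_class = 10, seed = 7, spec = fast_spec()) {
  generate_dataset(spec, n_per_class = n_per_class, seed = seed)
}

# Independent cascade implementation for oracle use: evaluates psi on a
# dyadic grid by plain nested loops (deliberately different code path from
# the package's vectorised convolution cascade).
oracle_cascade_psi <- function(lo, hi, level) {
  v <- hi
  for (j in seq_len(level - 1L)) {
    up <- numeric(2L * length(v) - 1L)
    for (i in seq_along(v)) up[2L * i - 1L] <- v[i]
    out <- numeric(length(up) + length(lo) - 1L)
    for (i in seq_along(up)) {
      for (k in seq_along(lo)) out[i + k - 1L] <- out[i + k - 1L] + up[i] * lo[k]
    }
    v <- out
  }
  2^(level / 2) * v
}

# Evaluate an oracle psi (from oracle_cascade_psi at refinement depth 8,
# the sampling depth the package documents) at arbitrary points by linear
# interpolation of the dyadic samples.
oracle_psi_fun <- function(base_name, level = 8) {
  fb <- rlwbs:::.wavelet_filter_bank[[base_name]]
  psi <- oracle_cascade_psi(fb$lo, fb$hi, level)
  grid <- seq_along(psi) * 2^-level
  function(u) {
    stats::approx(grid, psi, xout = u, yleft = 0, yright = 0)$y
  }
}
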