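test_that("default catalog reproduces the standard 35-entry index mapping", {
  cat35 <- build_catalog()
  tab <- catalog_table(cat35)
  expect_equal(cat35$Na, 35)
  expect_equal(tab$index, 1:35)
  expect_equal(tab$name[1], "haar")
  expect_equal(tab$name[2:20], paste0("db", 2:20))
  expect_equal(tab$name[21:26], paste0("sym", 3:8))
  expect_equal(tab$name[27], "sym10")
  expect_equal(tab$name[28], "sym20")
  expect_equal(tab$name[29:31], paste0("coif", 3:5))
  expect_equal(tab$name[32:35], c("bior1.1", "bior2.2", "bior3.3", "bior4.4"))
  # two default builds are identical
  expect_identical(catalog_table(build_catalog()), tab)
})

test_that("catalog handles singleton specs and rejects unknown names", {
  one <- build_catalog("haar")
  expect_equal(one$Na, 1)
  expect_equal(one$bases[[1]]$name, "haar")
  expect_equal(one$bases[[1]]$index, 1L)
  expect_error(build_catalog(c("haar", "morl")), "morl")
})

test_that("catalog round-trips through its plain-text serialization", {
  path <- withr::local_tempfile(fileext = ".csv")
  cat3 <- tiny_catalog()
  write_catalog(cat3, path)
  again <- read_catalog(path)
  expect_identical(catalog_table(again), catalog_table(cat3))
  # gap in indices is refused
  tab <- utils::read.csv(path)
  tab$index[2] <- 5L
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(read_catalog(path), "1..Na")
})

test_that("haar wavelet function matches its closed form", {
  w <- sample_wavelet_function("haar", 64)
  g <- w$psi_grid
  expect_true(all(abs(w$psi_samples[g > 0.01 & g < 0.49] - 1) < 1e-12))
  expect_true(all(abs(w$psi_samples[g > 0.51 & g < 0.99] + 1) < 1e-12))
})

test_that("sampled wavelets are admissible (near-zero mean)", {
  for (b in build_catalog()$bases) {
    expect_lt(abs(sum(b$psi_samples)), 1e-6 * sum(abs(b$psi_samples)),
              label = sprintf("admissibility of %s", b$name))
  }
})

test_that("db4 cascade samples match the frozen reference values", {
  orc <- utils::read.csv(test_path("db4_psi_oracle.csv"))
  w <- sample_wavelet_function("db4", 256)
  psi_at <- stats::approx(w$psi_grid, w$psi_samples, xout = orc$t)$y
  expect_lt(max(abs(psi_at - orc$psi)), 1e-3)
})

test_that("bior3.3 analysis wavelet matches the frozen reference values", {
  orc <- utils::read.csv(test_path("bior33_psid_oracle.csv"))
  w <- sample_wavelet_function("bior3.3", 256)
  psi_at <- stats::approx(w$psi_grid, w$psi_samples, xout = orc$t)$y
  expect_lt(max(abs(psi_at - orc$psi)), 1e-3)
})

test_that("cascade agrees with an independently coded refinement", {
  fb <- rlwbs:::.wavelet_filter_bank[["db2"]]
  mine <- sample_wavelet_function("db2", 256)$psi_samples
  orc <- oracle_cascade_psi(fb$lo, fb$hi, 8)
  expect_lt(max(abs(mine - orc[seq_along(mine)])), 1e-10)
  expect_error(sample_wavelet_function("db4", resolution = 8), "resolution")
})

test_that("scale grid inverts the pseudo-frequency relation", {
  base <- sample_wavelet_function("haar")
  gr <- default_scale_grid(1000, 100, M = 2, f_min = 1, f_max = 50,
                           base = base)
  # oracle: invert f = fc * fs / c by hand
  f_of <- base$center_frequency * 100 / gr$scales
  expect_lt(abs(f_of[length(f_of)] - 1) / 1, 0.01)   # largest scale -> f_min
  expect_lt(abs(f_of[1] - 50) / 50, 0.01)            # smallest scale -> f_max
  expect_error(default_scale_grid(1000, 100, M = 1, f_min = 5, f_max = 5,
                                  base = base))
  expect_error(default_scale_grid(1000, 100, M = 4, f_min = 1, f_max = 80,
                                  base = base), "Nyquist")
  for (fmax in c(10, 25, 49)) {
    g <- default_scale_grid(500, 100, M = 7, f_min = 0.5, f_max = fmax,
                            base = base)
    expect_true(all(diff(g$scales) > 0))
  }
})

test_that("cwt is linear and maps the zero signal to zero", {
  for (base in tiny_catalog()$bases) {
    grid <- default_scale_grid(128, 100, M = 4, f_min = 2, f_max = 30,
                               base = base)
    expect_true(all(cwt(numeric(128), base, grid)$values == 0))
    set.seed(42)
    x1 <- rnorm(128)
    x2 <- rnorm(128)
    lhs <- cwt(2 * x1 - 3 * x2, base, grid, magnitude = FALSE)$values
    rhs <- 2 * cwt(x1, base, grid, magnitude = FALSE)$values -
      3 * cwt(x2, base, grid, magnitude = FALSE)$values
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("cwt validates inputs and names oversized scales", {
  base <- sample_wavelet_function("haar")
  grid <- default_scale_grid(64, 100, M = 3, f_min = 2, f_max = 30,
                             base = base)
  expect_error(cwt(c(1, NA, numeric(62)), base, grid), "finite")
  expect_error(cwt(numeric(32), base, grid), "length")
  big <- grid
  big$scales[3] <- 1e5
  expect_error(cwt(numeric(64), base, big), "1e\\+05|100000")
})

test_that("discrete cwt matches direct quadrature of the transform integral", {
  set.seed(11)
  for (nm in c("haar", "db4", "bior3.3")) {
    base <- sample_wavelet_function(nm)
    psi_fine <- oracle_psi_fun(nm)
    grid <- default_scale_grid(128, 100, M = 3, f_min = 3, f_max = 12,
                               base = base)
    for (rep in 1:3) {
      x <- rnorm(128)
      W <- cwt(x, base, grid, magnitude = FALSE)$values
      Worc <- matrix(0, 3, 128)
      for (i in 1:3) {
        ci <- grid$scales[i]
        for (b in 1:128) {
          k <- seq_len(128)
          Worc[i, b] <- sum(x * psi_fine((k - b) / ci)) / sqrt(ci)
        }
      }
      expect_lt(norm(W - Worc, "F") / norm(Worc, "F"), 1e-3,
                label = sprintf("quadrature agreement for %s", nm))
    }
  }
})

test_that("haar step-signal column matches the exact continuous integral", {
  base <- sample_wavelet_function("haar")
  grid <- default_scale_grid(128, 100, M = 2, f_min = 5,
    f_max = base$center_frequency * 100 / 8, base = base)
  # grid's smallest scale is exactly 8 by construction
  expect_equal(grid$scales[1], 8, tolerance = 1e-12)
  x <- as.numeric(seq_len(128) >= 64)
  W <- cwt(x, base, grid, magnitude = FALSE)$values[1, ]
  # closed form of (1/sqrt(8)) * int x(t) psi((t - b)/8) dt for the
  # sample-and-hold step (x = 1 on t > 63): with u0 = (63 - b)/8 inside
  # the support, the positive lobe (u0, 1/2] minus the negative lobe
  # (max(u0, 1/2), 1] gives -sqrt(8) * min(u0, 1 - u0)
  bs <- 56:62
  exact <- vapply(bs, function(b) {
    u0 <- (63 - b) / 8
    -sqrt(8) * min(u0, 1 - u0)
  }, numeric(1))
  expect_lt(max(abs(W[bs] - exact) / abs(exact)), 1e-3)
})

test_that("dominant scale moves up as the sinusoid frequency drops", {
  base <- sample_wavelet_function("db4")
  grid <- default_scale_grid(512, 100, M = 16, f_min = 1, f_max = 30,
                             base = base)
  t <- (0:511) / 100
  peak_row <- vapply(c(20, 10, 5, 2), function(f) {
    s <- cwt(sin(2 * pi * f * t), base, grid)
    which.max(rowMeans(s$values))
  }, numeric(1))
  expect_true(all(diff(peak_row) > 0))  # scales ascend as frequency falls
})

test_that("feature resampling follows corner-aligned bilinear interpolation", {
  base <- sample_wavelet_function("haar")
  grid <- default_scale_grid(32, 100, M = 8, f_min = 2, f_max = 30,
                             base = base)
  # all-zero scalogram -> all-zero feature
  s0 <- cwt(numeric(32), base, grid)
  expect_true(all(scalogram_to_feature(s0, 8, 8) == 0))
  expect_error(scalogram_to_feature(s0, 4, 8), ">= 8")

  # identity dims: min-max scaling only
  set.seed(5)
  s <- cwt(rnorm(32), base, grid)
  f <- scalogram_to_feature(s, 8, 32)
  v <- abs(s$values)
  expect_equal(f, (v - min(v)) / (max(v) - min(v)), tolerance = 1e-12)

  # 4x4 checkerboard upsampled to 8x8: hand-computed bilinear formula
  cb <- matrix((outer(1:4, 1:4, `+`) %% 2), 4, 4)
  got <- bilinear <- rlwbs:::bilinear_resize(cb, 8, 8)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) {
    for (j in 1:8) {
      y <- 1 + (i - 1) * 3 / 7
      x <- 1 + (j - 1) * 3 / 7
      y0 <- min(floor(y), 3); x0 <- min(floor(x), 3)
      wy <- y - y0; wx <- x - x0
      oracle[i, j] <- cb[y0, x0] * (1 - wy) * (1 - wx) +
        cb[y0, x0 + 1] * (1 - wy) * wx +
        cb[y0 + 1, x0] * wy * (1 - wx) +
        cb[y0 + 1, x0 + 1] * wy * wx
    }
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("scalogram export writes a readable header and matrix", {
  path <- withr::local_tempfile(fileext = ".txt")
  base <- sample_wavelet_function("db4")
  grid <- default_scale_grid(64, 100, M = 4, f_min = 2, f_max = 30,
                             base = base)
  s <- cwt(sin(2 * pi * 5 * (0:63) / 100), base, grid)
  write_scalogram(s, path)
  lines <- readLines(path)
  expect_true(any(grepl("base_name: db4", lines)))
  vals <- as.matrix(utils::read.table(path, comment.char = "#"))
  expect_equal(unname(vals), unname(s$values), tolerance = 1e-6)
})
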