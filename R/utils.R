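# Internal numeric helpers shared across modules.

# Full (polynomial) convolution of two numeric vectors.
conv_full <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) return(numeric(0))
  if (na * nb < 5000L) {
    out <- numeric(na + nb - 1L)
    for (i in seq_len(nb)) {
      idx <- i:(i + na - 1L)
      out[idx] <- out[idx] + a * b[i]
    }
    return(out)
  }
  n <- na + nb - 1L
  nf <- stats::nextn(n, 2)
  fa <- stats::fft(c(a, numeric(nf - na)))
  fb <- stats::fft(c(b, numeric(nf - nb)))
  Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n)] / nf
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Row-wise softmax for a matrix of logits.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

relu <- function(z) {
  z[z < 0] <- 0
  z
}

#' Bilinear resampling of a numeric matrix
#'
#' Corner-aligned bilinear interpolation: the first and last rows/columns of
#' the source map exactly onto the first and last rows/columns of the target.
#' A source dimension of 1 is broadcast.
#'
#' @param mat numeric matrix.
#' @param out_height,out_width target dimensions (each >= 1).
#' @return an `out_height` x `out_width` numeric matrix.
#' @keywords internal
bilinear_resize <- function(mat, out_height, out_width) {
  src_h <- nrow(mat)
  src_w <- ncol(mat)
  ry <- if (out_height == 1L || src_h == 1L) rep(1, out_height) else
    1 + (seq_len(out_height) - 1) * (src_h - 1) / (out_height - 1)
  rx <- if (out_width == 1L || src_w == 1L) rep(1, out_width) else
    1 + (seq_len(out_width) - 1) * (src_w - 1) / (out_width - 1)
  y0 <- pmin(floor(ry), src_h - (src_h > 1L))
  x0 <- pmin(floor(rx), src_w - (src_w > 1L))
  wy <- ry - y0
  wx <- rx - x0
  y1 <- pmin(y0 + 1L, src_h)
  x1 <- pmin(x0 + 1L, src_w)
  a <- mat[y0, x0, drop = FALSE]
  b <- mat[y0, x1, drop = FALSE]
  d <- mat[y1, x0, drop = FALSE]
  e <- mat[y1, x1, drop = FALSE]
  wym <- matrix(wy, out_height, out_width)
  wxm <- matrix(wx, out_height, out_width, byrow = TRUE)
  a * (1 - wym) * (1 - wxm) + b * (1 - wym) * wxm +
    d * wym * (1 - wxm) + e * wym * wxm
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
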