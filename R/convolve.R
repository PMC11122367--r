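# Separable image filtering with reflective (symmetric) border padding.
# Border rule: the image is mirrored about its edge (edge pixel included),
# so filters see plausible data in a one-radius-wide frame.

.reflect_pad <- function(m, r_row, r_col) {
  h <- nrow(m); w <- ncol(m)
  if (r_row > h || r_col > w) {
    stop("filter radius exceeds image size; reduce the scale/window")
  }
  ri <- c(rev(seq_len(r_row)), seq_len(h), h - seq_len(r_row) + 1)
  ci <- c(rev(seq_len(r_col)), seq_len(w), w - seq_len(r_col) + 1)
  m[ri, ci, drop = FALSE]
}

# Convolve columns with k_row then rows with k_col (both odd-length),
# returning a matrix congruent with `m`.
.conv_sep <- function(m, k_row, k_col) {
  rr <- (length(k_row) - 1L) / 2L
  rc <- (length(k_col) - 1L) / 2L
  p <- .reflect_pad(m, rr, rc)
  f <- stats::filter(p, k_row, method = "convolution", sides = 2)
  f <- t(stats::filter(t(f), k_col, method = "convolution", sides = 2))
  matrix(f[(rr + 1):(rr + nrow(m)), (rc + 1):(rc + ncol(m))],
         nrow(m), ncol(m))
}

# Sampled Gaussian and its exact-moment derivatives. order 0 sums to 1;
# orders 1 and 2 are corrected to zero DC response so a constant image
# yields an exactly zero Hessian.
.gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,
    "2" = (x^2 - sigma^2) / sigma^4 * g,
    stop("order must be 0, 1 or 2")
  )
  if (order == 2L) k <- k - mean(k)
  k
}

.box_mean <- function(m, window) {
  k <- rep(1 / window, window)
  .conv_sep(m, k, k)
}
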