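# Separable bicubic (Keys cubic-convolution, a = -0.5) resampling.
# Implemented as two dense weight-matrix multiplications; edges replicate.

cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  w <- numeric(length(x))
  i1 <- x <= 1
  i2 <- x > 1 & x < 2
  w[i1] <- (a + 2) * x[i1]^3 - (a + 3) * x[i1]^2 + 1
  w[i2] <- a * x[i2]^3 - 5 * a * x[i2]^2 + 8 * a * x[i2] - 4 * a
  w
}

# n_out x n_in weight matrix mapping an input axis onto an output axis with
# centre-aligned sampling, as conventional image resamplers do.
cubic_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5  # 0-based source position
    base <- floor(src)
    taps <- (base - 1):(base + 2)
    wt <- cubic_kernel(src - taps)
    taps <- pmin(pmax(taps, 0), n_in - 1)  # clamp: replicate edge pixels
    for (k in seq_along(taps)) {
      w[i, taps[k] + 1] <- w[i, taps[k] + 1] + wt[k]
    }
  }
  w / rowSums(w)
}

#' Bicubic resize of a matrix
#'
#' Resamples a numeric matrix to the requested size with Keys
#' cubic-convolution interpolation (the classic "bicubic" kernel,
#' \eqn{a = -0.5}), applied separably along rows then columns.
#'
#' @param mat numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return an `out_h` x `out_w` numeric matrix.
#' @export
resize_bicubic <- function(mat, out_h, out_w) {
  if (!is.matrix(mat) || nrow(mat) < 1 || ncol(mat) < 1) {
    degenerate_error("`mat` must be a non-empty matrix.")
  }
  wr <- cubic_weights(nrow(mat), out_h)
  wc <- cubic_weights(ncol(mat), out_w)
  wr %*% mat %*% t(wc)
}
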