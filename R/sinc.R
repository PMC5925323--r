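# Band-limited (sinc) interpolation utilities.
#
# Interpolation is the normalized truncated Whittaker sum
#   x(t) = sum_k w_k(t) x[k] / sum_k w_k(t),  w_k(t) = sinc((t - t_k)/dt),
# which reproduces the original samples exactly (w reduces to a delta there)
# and preserves constants; row normalization tames truncation ripple of the
# finite sum near the series edges.

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))

# point-symmetric (odd) reflection of the sample vector about each end,
# expressed as a matrix acting on the original samples; reduces the
# truncation error of the finite sinc sum away from the edges
odd_extension_matrix <- function(n, reps = 2L) {
  p <- diag(n)
  for (r in seq_len(reps)) {
    m <- nrow(p)
    top <- matrix(2, nrow = m - 1, ncol = 1) %*% p[1, , drop = FALSE] -
      p[m:2, , drop = FALSE]
    bottom <- matrix(2, nrow = m - 1, ncol = 1) %*% p[m, , drop = FALSE] -
      p[(m - 1):1, , drop = FALSE]
    p <- rbind(top, p, bottom)
  }
  p
}

# interpolation matrix from n samples at spacing dt_in (times 0..(n-1)*dt_in)
# to arbitrary target times (seconds)
sinc_matrix <- function(n, dt_in, t_out, reps = 2L) {
  p <- odd_extension_matrix(n, reps)
  m <- nrow(p)
  pad <- (m - n) / 2
  tk <- (seq_len(m) - 1 - pad) * dt_in
  w <- outer(t_out, tk, function(a, b) sinc((a - b) / dt_in))
  (w / rowSums(w)) %*% p
}

#' Sinc upsampling of a timeseries
#'
#' Band-limited interpolation of a regularly sampled series onto a finer
#' temporal grid, preserving the original samples exactly at their time
#' points. Used before the lagged cross-correlation scan so that lags finer
#' than the native sampling interval can be evaluated.
#'
#' @param series Numeric vector, or frames-by-voxels matrix (one series per
#'   column), or 4D array (`x, y, z, t`).
#' @param dt_in Input sampling interval, seconds.
#' @param dt_out Output sampling interval, seconds; must be smaller than
#'   `dt_in`.
#' @return The interpolated series in the same container as the input, with
#'   attribute `dt` set to `dt_out`.
#' @export
upsample_sinc <- function(series, dt_in, dt_out = 0.1) {
  if (dt_out >= dt_in)
    stop("dt_out must be smaller than dt_in")
  m <- as_frame_matrix(series)
  n <- nrow(m)
  t_out <- seq(0, (n - 1) * dt_in, by = dt_out)
  s <- sinc_matrix(n, dt_in, t_out)
  out <- restore_shape(s %*% m, m)
  attr(out, "dt") <- dt_out
  out
}

# evaluate a series at shifted times t_k - lag by sinc interpolation
# (positive lag delays the series)
sinc_shift <- function(series, dt, lag) {
  m <- as_frame_matrix(series)
  n <- nrow(m)
  if (abs(lag) < 1e-12) return(restore_shape(m, m))
  t_out <- (seq_len(n) - 1) * dt - lag
  restore_shape(sinc_matrix(n, dt, t_out) %*% m, m)
}
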