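# Zero-phase frequency-domain filtering.
#
# Filters are realized by masking the discrete Fourier transform with an
# ideal passband whose edges are softened by a one-bin raised-cosine
# transition. This has no group delay, puts the cutoffs exactly where they
# are specified, and attenuates the stopband to numerical zero beyond the
# transition bin.

# weight of frequency f for passband (f_lo, f_hi); df = one bin width
band_weight <- function(f, f_lo, f_hi, df) {
  w <- numeric(length(f))
  lo_ramp <- f >= f_lo - df & f < f_lo + df
  hi_ramp <- f > f_hi - df & f <= f_hi + df
  inside <- f >= f_lo + df & f <= f_hi - df
  w[inside] <- 1
  w[lo_ramp] <- 0.5 * (1 - cos(pi * (f[lo_ramp] - (f_lo - df)) / (2 * df)))
  w[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - (f_hi - df)) / (2 * df)))
  # degenerate overlap (very narrow band): take the min of the two ramps
  both <- lo_ramp & hi_ramp
  if (any(both)) {
    wl <- 0.5 * (1 - cos(pi * (f[both] - (f_lo - df)) / (2 * df)))
    wh <- 0.5 * (1 + cos(pi * (f[both] - (f_hi - df)) / (2 * df)))
    w[both] <- pmin(wl, wh)
  }
  w
}

# core FFT filter on a frames-by-voxels matrix; f_lo = 0 gives a low-pass,
# f_hi = Inf a high-pass; keep_dc controls whether the mean survives
fft_filter <- function(m, dt, f_lo, f_hi, keep_dc = FALSE) {
  n <- nrow(m)
  nyq <- 1 / (2 * dt)
  if (is.finite(f_hi) && f_hi > nyq + 1e-12)
    stop("band upper edge exceeds the Nyquist frequency ", signif(nyq, 6), " Hz")
  if (f_lo < 0 || (is.finite(f_hi) && f_hi <= f_lo))
    stop("invalid band: need 0 <= f_lo < f_hi")
  df <- 1 / (n * dt)
  f <- (seq_len(n) - 1) * df
  f <- pmin(f, n * df - f)            # two-sided spectrum, folded
  w <- if (!is.finite(f_hi)) {
    1 - band_weight(f, 0, f_lo, df)   # high-pass = 1 - low-pass
  } else if (f_lo <= 0) {
    band_weight(f, -Inf, f_hi, df)
  } else {
    band_weight(f, f_lo, f_hi, df)
  }
  w[1] <- if (keep_dc) 1 else 0
  sp <- mvfft(m)
  out <- Re(mvfft(sp * w, inverse = TRUE)) / n
  dimnames(out) <- dimnames(m)
  attributes(out)$orig_dim <- attr(m, "orig_dim")
  attributes(out)$orig_vec <- attr(m, "orig_vec")
  out
}

#' Band-pass filter a timeseries
#'
#' Zero-phase frequency-domain band-pass with one-bin raised-cosine
#' transitions. The default band 0.01-0.071 Hz targets the low-frequency
#' range of spontaneous hemodynamic fluctuations; the DC component is always
#' removed, so the output is zero-mean.
#'
#' @param series Vector, frames-by-voxels matrix, or 4D array.
#' @param dt Sampling interval, seconds.
#' @param band Numeric pair `(f_lo, f_hi)` in Hz; `f_hi` must not exceed the
#'   Nyquist frequency.
#' @return Filtered series in the same container as the input.
#' @export
bandpass <- function(series, dt, band = c(0.01, 0.071)) {
  m <- as_frame_matrix(series)
  restore_shape(fft_filter(m, dt, band[1], band[2], keep_dc = FALSE), m)
}

# high-pass above f_c (DC removed), used by the CBF separation
highpass <- function(series, dt, f_c) {
  m <- as_frame_matrix(series)
  restore_shape(fft_filter(m, dt, f_c, Inf, keep_dc = FALSE), m)
}

# low-pass below f_c (DC kept), used by the BOLD separation
lowpass <- function(series, dt, f_c) {
  m <- as_frame_matrix(series)
  restore_shape(fft_filter(m, dt, 0, f_c, keep_dc = TRUE), m)
}

#' Gaussian spatial smoothing of a 4D series
#'
#' Separable Gaussian smoothing applied volume by volume, with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis expressed in voxel units.
#' The kernel is renormalized at the array boundary so spatially constant
#' volumes are left unchanged.
#'
#' @param series 4D array (`x, y, z, t`) or 3D volume.
#' @param fwhm Full width at half maximum, mm. `0` is the identity.
#' @param voxel_size Numeric triple, mm per voxel along each axis.
#' @return Smoothed array of the same shape.
#' @export
spatial_smooth <- function(series, fwhm = 6, voxel_size = c(3.6, 3.6, 5)) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(series)
  d3 <- length(dim(series)) == 3
  if (d3) series <- array(series, dim = c(dim(series), 1))
  d <- dim(series)
  sigma_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / voxel_size
  out <- series
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8 || d[ax] == 1) next
    half <- max(1L, ceiling(4 * s))
    kern <- exp(-0.5 * (seq(-half, half) / s)^2)
    out <- convolve_axis(out, kern, ax)
  }
  if (d3) out <- out[, , , 1]
  out
}

# 1D convolution along axis ax of a 4D array, kernel renormalized at edges
convolve_axis <- function(a, kern, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:4, ax))
  ap <- aperm(a, perm)
  n <- d[ax]
  m <- matrix(ap, nrow = n)
  half <- (length(kern) - 1L) / 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  wsum <- numeric(n)
  for (j in seq_along(kern)) {
    off <- j - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kern[j] * m[src[ok], ]
    wsum[ok] <- wsum[ok] + kern[j]
  }
  out <- out / wsum
  ap <- array(out, dim = d[perm])
  aperm(ap, order(perm))
}
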