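# shared fixtures, built in code

# small noise-free truth + run for end-to-end checks
small_truth <- function(coupling = 0.8, lag = -1.05, noise_sd = 0,
                        d = c(8L, 8L, 4L)) {
  ground_truth(d, coupling = coupling, lag = lag, noise_sd = noise_sd,
               cbf_fluct_amplitude = 0.15, bold_fluct_amplitude = 0.01)
}

small_acq <- function(d = c(8L, 8L, 4L), n_volumes = 90L) {
  acq_params(matrix_size = d, n_volumes = n_volumes)
}

# frames-by-voxels matrices of a separated_ts restricted to a mask
masked_series <- function(sep, mask) {
  nf <- dim(sep$bold)[4]
  idx <- which(as.logical(mask))
  list(bold = t(matrix(sep$bold, ncol = nf))[, idx, drop = FALSE],
       cbf = t(matrix(sep$cbf, ncol = nf))[, idx, drop = FALSE])
}

# fraction of periodogram power inside a band (excluding DC)
band_power_fraction <- function(x, dt, band) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)
  sum(p[f >= band[1] - 1e-12 & f <= band[2] + 1e-12]) / sum(p[-1])
}
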