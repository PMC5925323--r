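# Synthetic dual-echo pCASL generator.
#
# The forward model provides ground truth for every pipeline stage: voxelwise
# baseline perfusion (through the same single-compartment kinetic model the
# quantification stage inverts), band-limited spontaneous CBF fluctuations,
# BOLD fluctuations coupled to them with a prescribed correlation and lag,
# aliased cardiac/respiratory components, and white thermal noise.

#' Ground truth for a synthetic pCASL experiment
#'
#' Collects the quantities the analysis pipeline is meant to estimate:
#' baseline perfusion, BOLD-CBF coupling strength and lag, fluctuation
#' amplitudes and noise level. Scalars are expanded to voxel maps over an
#' ellipsoidal brain mask.
#'
#' @param matrix_size Integer triple `(nx, ny, nz)`.
#' @param baseline_cbf Baseline perfusion, ml/100g/min (scalar or map).
#' @param coupling Target Pearson correlation between the separated BOLD and
#'   CBF fluctuation series, in `[-1, 1]` (scalar or map).
#' @param lag Temporal lag of BOLD relative to CBF, seconds; positive values
#'   delay BOLD (scalar or map).
#' @param cbf_fluct_amplitude Fractional standard deviation of the spontaneous
#'   perfusion fluctuation (relative to the perfusion-weighted difference
#'   signal).
#' @param bold_fluct_amplitude Fractional standard deviation of the BOLD
#'   fluctuation at the second echo (relative to M0).
#' @param noise_sd Fractional thermal white-noise standard deviation
#'   (relative to M0).
#' @param band Frequency band `(f_lo, f_hi)` in Hz of the fluctuation
#'   processes. The default keeps the processes inside the low-frequency
#'   hemodynamic range while leaving the label/control modulation sidebands
#'   clear of the separation cutoff.
#' @param m0 Equilibrium magnetization inside the brain mask (scalar or map).
#' @param mask Optional logical 3D array; default is an inscribed ellipsoid.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(matrix_size = c(16L, 16L, 8L), baseline_cbf = 60,
                         coupling = 0.24, lag = -0.5,
                         cbf_fluct_amplitude = 0.15,
                         bold_fluct_amplitude = 0.01,
                         noise_sd = 0.005, band = c(0.01, 0.065),
                         m0 = 1000, mask = NULL) {
  stopifnot(length(matrix_size) == 3, cbf_fluct_amplitude >= 0,
            bold_fluct_amplitude >= 0, noise_sd >= 0,
            band[1] > 0, band[1] < band[2])
  d <- as.integer(matrix_size)
  if (is.null(mask)) mask <- ellipsoid_mask(d)
  expand <- function(x) {
    if (length(x) == 1) array(x * as.numeric(mask), dim = d)
    else { stopifnot(all(dim(x) == d)); x }
  }
  coupling_map <- expand(coupling)
  if (any(abs(coupling_map) > 1))
    stop("|coupling| must not exceed 1")
  structure(list(baseline_cbf_map = expand(baseline_cbf),
                 coupling_map = coupling_map,
                 lag_map = expand(lag),
                 cbf_fluct_amplitude = cbf_fluct_amplitude,
                 bold_fluct_amplitude = bold_fluct_amplitude,
                 noise_sd = noise_sd, band = band,
                 m0_map = expand(m0), mask = mask),
            class = "ground_truth")
}

# inscribed ellipsoid, a crude brain-shaped support
ellipsoid_mask <- function(d) {
  cx <- (d + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r <- ((g$x - cx[1]) / (d[1] / 2))^2 + ((g$y - cx[2]) / (d[2] / 2))^2 +
    ((g$z - cx[3]) / (max(d[3], 2) / 2))^2
  array(r <= 1, dim = d)
}

#' Generate a band-limited stochastic process
#'
#' Synthesizes zero-mean processes directly in the frequency domain: every
#' Fourier bin inside the requested band receives unit magnitude and an
#' independent uniform random phase, all other bins are zero. This gives
#' exact band containment, and because the bins are orthogonal over the
#' sample grid the sample standard deviation equals `amplitude` exactly.
#'
#' @param n_points Number of samples.
#' @param dt Sampling interval, seconds.
#' @param band Numeric pair `(f_lo, f_hi)` in Hz; `f_hi` must not exceed the
#'   Nyquist frequency `1/(2 dt)`.
#' @param amplitude Target standard deviation of the process.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param n_series Number of independent processes to generate.
#' @return A numeric vector (`n_series = 1`) or an `n_points` x `n_series`
#'   matrix, with attribute `band`.
#' @export
generate_band_limited_process <- function(n_points, dt, band = c(0.01, 0.065),
                                          amplitude = 1, seed = NULL,
                                          n_series = 1L) {
  stopifnot(n_points >= 4, dt > 0, amplitude >= 0)
  nyq <- 1 / (2 * dt)
  if (band[1] <= 0 || band[2] > nyq + 1e-12 || band[1] >= band[2])
    stop("invalid band: need 0 < f_lo < f_hi <= Nyquist (", signif(nyq, 6), " Hz)")
  n <- as.integer(n_points)
  freqs <- seq_len(floor((n - 1) / 2)) / (n * dt)   # positive, below Nyquist
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (length(in_band) == 0)
    stop("band contains no Fourier bins at this length and sampling interval")
  ph <- with_seed(seed, matrix(runif(length(in_band) * n_series, 0, 2 * pi),
                               nrow = length(in_band)))
  spec <- matrix(0 + 0i, nrow = n, ncol = n_series)
  spec[in_band + 1L, ] <- exp(1i * ph)
  spec[n + 1L - in_band, ] <- Conj(spec[in_band + 1L, ])
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  # each bin contributes sample variance (2/n^2)*(n/2)^2... normalize empirically-exactly:
  # a real sinusoid of spectral magnitude 1 has amplitude 2/n and variance 2/n^2;
  # m orthogonal bins give sd sqrt(m*2)/n
  x <- x * (amplitude / (sqrt(2 * length(in_band)) / n))
  if (n_series == 1L) x <- as.numeric(x)
  attr(x, "band") <- band
  attr(x, "dt") <- dt
  x
}

#' Generate a BOLD series coupled to a CBF series
#'
#' Forward model of dynamic BOLD-CBF coupling: the returned series is the
#' input perfusion fluctuation delayed by `lag` seconds (sinc interpolation)
#' mixed with an independent band-matched noise process so that the
#' population correlation with the lag-aligned CBF series equals `target_r`.
#' Positive `lag` means BOLD is delayed relative to CBF.
#'
#' @param cbf_series Numeric vector or frames-by-voxels matrix of perfusion
#'   fluctuation series.
#' @param target_r Target correlation in `[-1, 1]` (scalar or one per column).
#' @param lag Lag in seconds (scalar or one per column).
#' @param dt Sampling interval, seconds.
#' @param seed Integer seed for the noise process.
#' @param band Band of the noise process; defaults to the `band` attribute of
#'   `cbf_series`.
#' @param amplitude Standard deviation of the returned series.
#' @return Series of the same shape as `cbf_series`.
#' @export
generate_coupled_pair <- function(cbf_series, target_r, lag = 0, dt,
                                  seed = NULL, band = NULL, amplitude = 1) {
  if (any(abs(target_r) > 1))
    stop("|target_r| must not exceed 1")
  if (is.null(band)) band <- attr(cbf_series, "band")
  if (is.null(band)) band <- c(0.01, 0.065)
  m <- as_frame_matrix(cbf_series)
  n <- nrow(m); nv <- ncol(m)
  target_r <- rep_len(target_r, nv)
  lag <- rep_len(lag, nv)
  if (any(abs(lag) >= n * dt / 4))
    stop("|lag| must be below a quarter of the series duration")
  shifted <- m
  for (l in unique(lag)) {
    idx <- which(lag == l)
    if (abs(l) > 1e-12)
      shifted[, idx] <- sinc_matrix(n, dt, (seq_len(n) - 1) * dt - l) %*% m[, idx, drop = FALSE]
  }
  s_sd <- apply(shifted, 2, sd)
  s_sd[s_sd == 0] <- 1
  eps <- generate_band_limited_process(n, dt, band, amplitude = 1,
                                       seed = seed, n_series = nv)
  eps <- matrix(eps, nrow = n)
  e_sd <- apply(eps, 2, sd)
  e_sd[e_sd == 0] <- 1
  out <- sweep(shifted, 2, target_r / s_sd, `*`) +
    sweep(eps, 2, sqrt(pmax(0, 1 - target_r^2)) / e_sd, `*`)
  out <- out * amplitude
  restore_shape(out, m)
}

#' Generate cardiac and respiratory traces
#'
#' Unit-amplitude sinusoidal cardiac and respiratory waveforms sampled at
#' 100 Hz with random initial phases, mimicking a scanner physiological log.
#' Sampled at a 3.5 s repetition time, the 1 Hz cardiac component aliases
#' into the low-frequency band, which is what the RETROICOR stage removes.
#'
#' @param duration Seconds of recording.
#' @param sampling_rate Hz.
#' @param cardiac_freq,resp_freq Fundamental frequencies, Hz.
#' @param seed Integer seed for the initial phases.
#' @return An object of class `physio_trace` with `cardiac` and `respiratory`
#'   waveforms.
#' @export
generate_physio_trace <- function(duration, sampling_rate = 100,
                                  cardiac_freq = 1.0, resp_freq = 0.3,
                                  seed = NULL) {
  stopifnot(duration > 0, sampling_rate > 2 * cardiac_freq)
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  ph <- with_seed(seed, runif(2, 0, 2 * pi))
  structure(list(sampling_rate = sampling_rate,
                 cardiac = sin(2 * pi * cardiac_freq * t + ph[1]),
                 respiratory = sin(2 * pi * resp_freq * t + ph[2]),
                 duration = duration,
                 cardiac_freq = cardiac_freq, resp_freq = resp_freq),
            class = "physio_trace")
}

# linear interpolation of a physio waveform at arbitrary times
physio_at <- function(trace, channel, times) {
  x <- trace[[channel]]
  t <- (seq_along(x) - 1) / trace$sampling_rate
  stats::approx(t, x, xout = pmin(pmax(times, 0), max(t)), rule = 2)$y
}

# slice-mean acquisition time of volume v (1-based)
volume_times <- function(acq) ((seq_len(acq$n_volumes) - 1) + 0.5) * acq$tr

# quantification kernel: CBF = kernel * (SI_C - SI_L) / M0, per slice
quant_kernel <- function(params, slice_index) {
  pld <- slice_pld(slice_index, params)
  6000 * params$lambda_bbp * exp(pld / params$t1a) /
    (2 * params$alpha_label * params$alpha_inv * params$t1a *
       (1 - exp(-params$label_duration / params$t1a)))
}

# quant_params matching a dynamic dual-echo acquisition (no background suppression)
dynamic_quant_params <- function(acq) {
  nz <- acq$matrix_size[3]
  quant_params(alpha_inv = 1, label_duration = acq$label_duration,
               pld_first = acq$pld_first,
               pld_last = acq$pld_first + (nz - 1) * acq$pld_increment,
               n_slices = nz)
}

# per-voxel control-minus-label difference signal implied by a CBF map
delta_m_map <- function(truth, params) {
  d <- dim(truth$baseline_cbf_map)
  kern <- quant_kernel(params, seq_len(d[3]))
  kern_vox <- array(rep(kern, each = d[1] * d[2]), dim = d)
  truth$baseline_cbf_map * truth$m0_map / kern_vox
}

#' Assemble a synthetic dual-echo pCASL run
#'
#' Builds the interleaved control/label dual-echo voxel timeseries implied by
#' a [ground_truth()] object. Per voxel and volume the signal is
#' \deqn{S_e(v) = M_0 (1 + g_e\, b(t_v)) + \frac{c_v}{2}\, \Delta M_e\,(1 + f(t_v))
#'   + M_0\, \gamma\, \mathrm{physio}(t_v) + \varepsilon_v,}
#' where \eqn{c_v = +1} for control and \eqn{-1} for label volumes, \eqn{f}
#' is the band-limited perfusion fluctuation, \eqn{b} the BOLD fluctuation
#' coupled to \eqn{f} with the ground-truth correlation and lag, and
#' \eqn{g_e} the echo-dependent BOLD gain (`te1/te2` at the first echo, 1 at
#' the second: a linear-in-TE approximation, so the short echo carries little
#' but nonzero BOLD weight). \eqn{\Delta M} is obtained by inverting the
#' single-compartment model at each voxel's slice post-label delay, and
#' decays with echo time by `perf_te2_gain` at the second echo. The
#' labeling modulation is represented as a zero-mean alternating carrier
#' (`+dM/2` on control, `-dM/2` on label volumes), so the control-minus-label
#' difference is exactly \eqn{\Delta M (1 + f)}.
#'
#' @param truth A [ground_truth()] object with maps conforming to
#'   `acq$matrix_size`.
#' @param acq An [acq_params()] object.
#' @param physio Optional [generate_physio_trace()] object covering the run.
#' @param physio_gain Fractional amplitude (relative to M0) of each additive
#'   physiological component.
#' @param perf_te2_gain Attenuation of the perfusion-weighted difference at
#'   the second echo (T2* decay of the label signal).
#' @param seed Integer seed.
#' @return An object of class `dual_echo_run`: list with 4D arrays `echo1`,
#'   `echo2`, character `tags` ("control"/"label"), `acq`, and the generating
#'   `truth` attached as attribute `truth`.
#' @export
assemble_dual_echo_run <- function(truth, acq = acq_params(), physio = NULL,
                                   physio_gain = 0.005, perf_te2_gain = 0.7,
                                   seed = NULL) {
  d <- acq$matrix_size
  if (!all(dim(truth$baseline_cbf_map) == d))
    stop("ground-truth maps do not conform to acq$matrix_size")
  if (truth$band[2] > 1 / (4 * acq$tr) + 1e-12)
    stop("fluctuation band upper edge must not exceed 1/(4 TR)")
  nvol <- acq$n_volumes
  nvox <- prod(d)
  tv <- volume_times(acq)
  in_mask <- which(as.logical(truth$mask))
  nm <- length(in_mask)

  # fluctuation processes at the volume sampling grid (masked voxels only)
  f <- matrix(0, nrow = nvol, ncol = nm)
  b <- matrix(0, nrow = nvol, ncol = nm)
  if (truth$cbf_fluct_amplitude > 0 && nm > 0) {
    f <- generate_band_limited_process(nvol, acq$tr, truth$band,
                                       amplitude = truth$cbf_fluct_amplitude,
                                       seed = child_seed(seed, 1),
                                       n_series = nm)
    f <- matrix(f, nrow = nvol)
    if (truth$bold_fluct_amplitude > 0)
      b <- generate_coupled_pair(structure(f, band = truth$band),
                                 target_r = truth$coupling_map[in_mask],
                                 lag = truth$lag_map[in_mask], dt = acq$tr,
                                 seed = child_seed(seed, 2),
                                 amplitude = truth$bold_fluct_amplitude)
  } else if (truth$bold_fluct_amplitude > 0 && nm > 0) {
    b <- generate_band_limited_process(nvol, acq$tr, truth$band,
                                       amplitude = truth$bold_fluct_amplitude,
                                       seed = child_seed(seed, 2),
                                       n_series = nm)
    b <- matrix(b, nrow = nvol)
  }

  carrier <- if (acq$control_first) rep_len(c(1, -1), nvol) else rep_len(c(-1, 1), nvol)
  tags <- ifelse(carrier > 0, "control", "label")
  phys <- if (!is.null(physio)) {
    if (physio$duration < max(tv))
      stop("physio trace shorter than the run")
    physio_gain * (physio_at(physio, "cardiac", tv) +
                   physio_at(physio, "respiratory", tv))
  } else numeric(nvol)

  qp <- dynamic_quant_params(acq)
  dm1 <- delta_m_map(truth, qp)
  m0v <- truth$m0_map[in_mask]
  dm1v <- dm1[in_mask]
  g1 <- acq$te1 / acq$te2

  build_echo <- function(bold_gain, dm_gain, noise_seed) {
    sig <- matrix(0, nrow = nvol, ncol = nvox)
    # voxels in mask: M0(1 + g b) + carrier/2 * dM (1 + f) + physio * M0
    base <- sweep(1 + bold_gain * b, 2, m0v, `*`)
    mod <- sweep((1 + f) * carrier, 2, dm_gain * dm1v / 2, `*`)
    sig[, in_mask] <- base + mod + outer(phys, m0v)
    if (truth$noise_sd > 0) {
      eps <- with_seed(noise_seed,
                       matrix(rnorm(nvol * nm, sd = truth$noise_sd), nrow = nvol))
      sig[, in_mask] <- sig[, in_mask] + sweep(eps, 2, m0v, `*`)
    }
    array(t(sig), dim = c(d, nvol))
  }

  run <- structure(list(echo1 = build_echo(g1, 1, child_seed(seed, 3)),
                        echo2 = build_echo(1, perf_te2_gain, child_seed(seed, 4)),
                        tags = tags, acq = acq),
                   class = "dual_echo_run")
  attr(run, "truth") <- truth
  run
}

#' Assemble a synthetic background-suppressed baseline ASL run
#'
#' Single-echo interleaved control/label run whose temporal-mean difference,
#' fed to [quantify_cbf()] with the generating parameters, returns the
#' injected baseline perfusion map exactly in the noise-free case.
#'
#' @param truth A [ground_truth()] object.
#' @param acq An [acq_params()] object for the baseline acquisition (set
#'   `te2 = NA`); defaults to TR 4.269 s, 60 volumes, label 1750 ms, PLD
#'   1900-2800 ms.
#' @param params A [quant_params()] object consistent with `acq`.
#' @param seed Integer seed for the thermal noise.
#' @return List with elements `run` (list `series` 4D array, `tags`, `acq`)
#'   and `m0` (3D equilibrium magnetization image).
#' @export
assemble_baseline_run <- function(truth,
                                  acq = acq_params(tr = 4.269, te1 = 0.010,
                                                   te2 = NA, n_volumes = 60L,
                                                   matrix_size = dim(truth$mask),
                                                   label_duration = 1.75,
                                                   pld_first = 1.9,
                                                   pld_increment = 0.05),
                                  params = quant_params(n_slices = dim(truth$mask)[3]),
                                  seed = NULL) {
  d <- acq$matrix_size
  if (!all(dim(truth$baseline_cbf_map) == d))
    stop("ground-truth maps do not conform to acq$matrix_size")
  nvol <- acq$n_volumes
  dm <- delta_m_map(truth, params)
  carrier <- if (acq$control_first) rep_len(c(1, -1), nvol) else rep_len(c(-1, 1), nvol)
  tags <- ifelse(carrier > 0, "control", "label")
  nvox <- prod(d)
  sig <- outer(carrier / 2, as.numeric(dm)) +
    matrix(rep(as.numeric(truth$m0_map), each = nvol), nrow = nvol)
  if (truth$noise_sd > 0) {
    eps <- with_seed(seed, matrix(rnorm(nvol * nvox, sd = truth$noise_sd),
                                  nrow = nvol))
    sig <- sig + sweep(eps, 2, as.numeric(truth$m0_map), `*`)
  }
  list(run = list(series = array(t(sig), dim = c(d, nvol)),
                  tags = tags, acq = acq),
       m0 = truth$m0_map)
}

#' Cohort presets for group simulations
#'
#' Subject-level distributions of coupling and lag for two simulated
#' populations: `"young-like"` (mean coupling 0.24, SD 0.03; mean lag
#' -0.5 s) and `"elderly-like"` (mean coupling 0.18, SD 0.04; mean lag
#' -1.8 s). Coupling means and SDs and lag means follow reported group
#' summaries for young and older adults; the between-subject lag SD (0.3 s)
#' is set from the spread of reported regional shifts.
#'
#' @param name `"young-like"` or `"elderly-like"`.
#' @return List with `coupling_mean`, `coupling_sd`, `lag_mean`, `lag_sd`,
#'   `baseline_cbf_mean`, `baseline_cbf_sd`.
#' @export
cohort_preset <- function(name = c("young-like", "elderly-like")) {
  name <- match.arg(name)
  if (name == "young-like")
    list(coupling_mean = 0.24, coupling_sd = 0.03,
         lag_mean = -0.5, lag_sd = 0.3,
         baseline_cbf_mean = 65, baseline_cbf_sd = 8)
  else
    list(coupling_mean = 0.18, coupling_sd = 0.04,
         lag_mean = -1.8, lag_sd = 0.3,
         baseline_cbf_mean = 50, baseline_cbf_sd = 8)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject coupling (on the Fisher-z scale, so `|r| < 1` is
#' guaranteed), lag and baseline perfusion from a preset or explicit
#' template, and generates either full dual-echo runs or
#' separated-level BOLD/CBF fluctuation series for each subject.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param preset A [cohort_preset()] name or list.
#' @param acq An [acq_params()] object.
#' @param seed Integer seed; the whole cohort is reproducible given the seed.
#' @param level `"separated"` returns, per subject, `n_voxels` coupled
#'   BOLD/CBF series at the separated sampling interval `2 TR` with
#'   `n_volumes/2` frames (emulating the output of the separation stage);
#'   `"run"` returns full dual-echo runs with spatially constant subject
#'   truth.
#' @param n_voxels Voxels per subject at `level = "separated"`.
#' @param group_label Label stored in the truth table.
#' @return List with `truth` (data frame: subject, group, coupling, lag,
#'   baseline_cbf) and `subjects` (list of per-subject data).
#' @export
generate_cohort <- function(n_subjects, preset = "young-like",
                            acq = acq_params(), seed = NULL,
                            level = c("separated", "run"), n_voxels = 64L,
                            group_label = NULL) {
  stopifnot(n_subjects >= 2)
  level <- match.arg(level)
  if (is.character(preset)) preset <- cohort_preset(preset)
  if (is.null(group_label))
    group_label <- if (!is.null(preset$name)) preset$name else "group"
  z_mean <- atanh(preset$coupling_mean)
  z_sd <- preset$coupling_sd / (1 - preset$coupling_mean^2)  # delta method
  draws <- with_seed(child_seed(seed, 0), {
    data.frame(subject = sprintf("sub-%02d", seq_len(n_subjects)),
               group = group_label,
               coupling = tanh(rnorm(n_subjects, z_mean, z_sd)),
               lag = rnorm(n_subjects, preset$lag_mean, preset$lag_sd),
               baseline_cbf = pmax(5, rnorm(n_subjects,
                                            preset$baseline_cbf_mean,
                                            preset$baseline_cbf_sd)))
  })
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    si <- child_seed(seed, i)
    if (level == "separated") {
      nf <- acq$n_volumes %/% 2L
      dt <- 2 * acq$tr
      band <- c(0.01, min(0.065, 1 / (2 * dt) * 0.95))
      cbf <- generate_band_limited_process(nf, dt, band, amplitude = 1,
                                           seed = child_seed(si, 1),
                                           n_series = n_voxels)
      cbf <- matrix(cbf, nrow = nf)
      bold <- generate_coupled_pair(structure(cbf, band = band),
                                    target_r = draws$coupling[i],
                                    lag = draws$lag[i], dt = dt,
                                    seed = child_seed(si, 2))
      subjects[[i]] <- list(bold = bold, cbf = cbf, dt = dt)
    } else {
      truth <- ground_truth(matrix_size = acq$matrix_size,
                            baseline_cbf = draws$baseline_cbf[i],
                            coupling = draws$coupling[i], lag = draws$lag[i])
      subjects[[i]] <- assemble_dual_echo_run(truth, acq, seed = si)
    }
  }
  list(truth = draws, subjects = subjects)
}
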