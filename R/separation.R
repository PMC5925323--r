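# Separation of BOLD- and perfusion-weighted components of an interleaved
# control/label pCASL timeseries.
#
# The interleaved series is the sum of a slowly varying BOLD-weighted
# component and a perfusion-weighted component riding on the control/label
# alternation (a carrier at the Nyquist frequency of the volume sampling).
# High-pass filtering above 1/(4 TR) retains the modulated carrier while
# suppressing BOLD contamination; demodulation by cos(pi (n - 1)) moves it to
# baseband, and summing non-overlapping pairs yields the control-minus-label
# perfusion series at a sampling interval of 2 TR. The BOLD series is the
# complementary low-pass below 1/(4 TR) followed by the pair mean.

#' Separation cutoff frequency
#'
#' The high-pass/low-pass split frequency `1/(4 TR)` that divides the
#' label/control modulation sidebands from the slow BOLD-weighted component
#' of an interleaved pCASL series (0.0714 Hz at TR 3.5 s, conventionally
#' printed as 0.071 Hz).
#'
#' @param tr Repetition time, seconds.
#' @return Cutoff in Hz.
#' @export
separation_cutoff <- function(tr) {
  stopifnot(tr > 0)
  1 / (4 * tr)
}

check_tags <- function(tags, n = NULL) {
  if (!is.null(n) && length(tags) != n)
    stop("tag vector length does not match the number of volumes")
  if (!all(tags %in% c("control", "label")))
    stop("tags must be 'control' or 'label'")
  if (length(tags) %% 2L != 0L)
    stop("even volume count required")
  if (any(tags[-1] == tags[-length(tags)]))
    stop("tags must strictly alternate control/label")
  invisible(tags)
}

#' Validate and return the interleaved echo series of a dual-echo run
#'
#' Checks that the control/label tags strictly alternate and returns the two
#' echo timeseries in acquisition order, untouched. This is the hand-off
#' point between preprocessing (performed per tag class) and the separation
#' filters (which need the interleaved series).
#'
#' @param run A `dual_echo_run` (see [assemble_dual_echo_run()]).
#' @return List with `te1`, `te2` (4D arrays), `tags`, and `acq`.
#' @export
split_and_rebuild <- function(run) {
  check_tags(run$tags, dim(run$echo1)[4])
  list(te1 = run$echo1, te2 = run$echo2, tags = run$tags, acq = run$acq)
}

#' Split an interleaved series into its control and label sub-series
#'
#' @param series 4D array (or frames-by-voxels matrix).
#' @param tags Character vector of "control"/"label" per volume.
#' @return List with `control` and `label` series and the index vectors used.
#' @seealso [rebuild_interleaved()] for the exact inverse.
#' @export
split_run <- function(series, tags) {
  m <- as_frame_matrix(series)
  check_tags(tags, nrow(m))
  ic <- which(tags == "control"); il <- which(tags == "label")
  list(control = restore_shape(m[ic, , drop = FALSE], m),
       label = restore_shape(m[il, , drop = FALSE], m),
       control_index = ic, label_index = il)
}

#' Rebuild an interleaved series from control and label sub-series
#'
#' @param control,label Series of equal shape.
#' @param control_first Logical; ordering of the interleave.
#' @return Interleaved series; `split_run()` followed by
#'   `rebuild_interleaved()` is bit-identical.
#' @export
rebuild_interleaved <- function(control, label, control_first = TRUE) {
  mc <- as_frame_matrix(control); ml <- as_frame_matrix(label)
  stopifnot(nrow(mc) == nrow(ml), ncol(mc) == ncol(ml))
  out <- matrix(0, nrow = 2L * nrow(mc), ncol = ncol(mc))
  if (control_first) {
    out[seq(1, nrow(out), 2), ] <- mc; out[seq(2, nrow(out), 2), ] <- ml
  } else {
    out[seq(1, nrow(out), 2), ] <- ml; out[seq(2, nrow(out), 2), ] <- mc
  }
  restore_shape(out, mc)
}

#' Retrospective physiological-noise regression (RETROICOR)
#'
#' Removes cardiac- and respiratory-locked signal components by regressing
#' out sine/cosine terms of the instantaneous cardiac and respiratory phase
#' up to a given harmonic order. Phases are assigned per volume from the
#' recorded traces (peak-to-peak linear phase), at the volume's slice-mean
#' acquisition time. Regressors are centered before projection, so the voxel
#' mean is preserved. Apply to label and control series separately.
#'
#' @param series 4D array, frames-by-voxels matrix, or vector.
#' @param physio A [generate_physio_trace()] object covering the run.
#' @param times Acquisition time of each volume, seconds.
#' @param order Number of harmonics per physiological process (default 2).
#' @return Residual series, same shape as the input.
#' @export
retroicor_regress <- function(series, physio, times, order = 2L) {
  m <- as_frame_matrix(series)
  if (length(times) != nrow(m))
    stop("times must have one entry per volume")
  if (physio$duration < max(times))
    stop("physio trace does not cover the run duration")
  if (order <= 0L) return(series)
  phc <- trace_phase(physio$cardiac, physio$sampling_rate, times)
  phr <- trace_phase(physio$respiratory, physio$sampling_rate, times)
  reg <- do.call(cbind, lapply(seq_len(order), function(k)
    cbind(sin(k * phc), cos(k * phc), sin(k * phr), cos(k * phr))))
  nuisance_regress(series, reg)
}

# instantaneous phase of a quasi-periodic waveform: 0..2pi between
# successive peaks, linearly interpolated; extended periodically at the ends
trace_phase <- function(x, fs, times) {
  n <- length(x)
  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  pk <- pk[x[pk] > mean(x)]
  if (length(pk) < 2)
    stop("could not detect at least two peaks in the physiological trace")
  tp <- (pk - 1) / fs
  period_first <- tp[2] - tp[1]
  period_last <- tp[length(tp)] - tp[length(tp) - 1]
  vapply(times, function(t) {
    if (t < tp[1]) {
      2 * pi * (1 - ((tp[1] - t) / period_first) %% 1)
    } else if (t >= tp[length(tp)]) {
      2 * pi * (((t - tp[length(tp)]) / period_last) %% 1)
    } else {
      i <- findInterval(t, tp)
      2 * pi * (t - tp[i]) / (tp[i + 1] - tp[i])
    }
  }, numeric(1))
}

#' Remove nuisance regressors from a timeseries
#'
#' Voxelwise least-squares projection removal of caller-supplied confound
#' timecourses (e.g. motion parameters, tissue-based regressors). Regressors
#' are centered so the voxel mean is preserved; rank-deficient designs are
#' handled by an SVD pseudo-inverse.
#'
#' @param series 4D array, frames-by-voxels matrix, or vector.
#' @param regressors Numeric matrix with one column per confound and one row
#'   per frame; `NULL` or zero columns is the identity.
#' @return Residual series, same shape as the input.
#' @export
nuisance_regress <- function(series, regressors) {
  m <- as_frame_matrix(series)
  if (is.null(regressors) || NCOL(regressors) == 0) return(series)
  x <- as.matrix(regressors)
  if (nrow(x) != nrow(m))
    stop("regressor length does not match the series length")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  keep <- sv$d > max(sv$d[1], 0) * 1e-10
  if (!any(keep)) return(series)
  u <- sv$u[, keep, drop = FALSE]
  fitted <- u %*% (t(u) %*% m)
  restore_shape(m - fitted, m)
}

#' Extract the perfusion (CBF) fluctuation series from interleaved TE1 data
#'
#' High-pass filters the interleaved series above `1/(4 TR)`, demodulates by
#' `cos(pi (n - 1))` (1-based frame number `n`), and sums non-overlapping
#' pairs. With the control volume first the output approximates the
#' control-minus-label difference series, positive for positive perfusion.
#' Output has half the frames at sampling interval `2 TR`.
#'
#' @param series Interleaved TE1 series: 4D array, frames-by-voxels matrix,
#'   or vector (even number of frames).
#' @param tr Repetition time, seconds.
#' @param control_first Logical; flips the demodulation sign when `FALSE`.
#' @return Perfusion-weighted series, half length, attribute `dt = 2 * tr`.
#' @export
separate_cbf <- function(series, tr, control_first = TRUE) {
  m <- as_frame_matrix(series)
  n <- nrow(m)
  if (n %% 2L != 0L) stop("even number of frames required")
  hp <- fft_filter(m, tr, separation_cutoff(tr), Inf, keep_dc = FALSE)
  demod <- cos(pi * (seq_len(n) - 1)) * if (control_first) 1 else -1
  dm <- hp * demod
  out <- dm[seq(1, n, 2), , drop = FALSE] + dm[seq(2, n, 2), , drop = FALSE]
  out <- restore_shape(out, m)
  attr(out, "dt") <- 2 * tr
  out
}

#' Extract the BOLD fluctuation series from interleaved TE2 data
#'
#' Low-pass filters the interleaved series below `1/(4 TR)` (removing the
#' control/label alternation and its sidebands) and averages non-overlapping
#' pairs. The pair mean (rather than the raw sum) keeps BOLD in signal
#' units; correlation-based results are unaffected by this scaling.
#'
#' @inheritParams separate_cbf
#' @return BOLD-weighted series, half length, attribute `dt = 2 * tr`.
#' @export
separate_bold <- function(series, tr) {
  m <- as_frame_matrix(series)
  n <- nrow(m)
  if (n %% 2L != 0L) stop("even number of frames required")
  lp <- fft_filter(m, tr, 0, separation_cutoff(tr), keep_dc = TRUE)
  out <- (lp[seq(1, n, 2), , drop = FALSE] + lp[seq(2, n, 2), , drop = FALSE]) / 2
  out <- restore_shape(out, m)
  attr(out, "dt") <- 2 * tr
  out
}

#' Full separation of a dual-echo run
#'
#' Convenience wrapper: validates the interleave, optionally applies
#' RETROICOR (per tag class) and nuisance regression, separates the CBF
#' (TE1) and BOLD (TE2) fluctuation series, band-passes both, and optionally
#' smooths spatially.
#'
#' @param run A `dual_echo_run`.
#' @param physio Optional physiological trace for RETROICOR.
#' @param regressors Optional confound matrix (one row per volume).
#' @param band Analysis band, Hz; default 0.01-0.071.
#' @param fwhm Spatial smoothing FWHM in mm (0 disables).
#' @param retroicor_order Harmonics per physiological process.
#' @return Object of class `separated_ts`: list with `bold`, `cbf` (4D arrays
#'   or matrices, `n_volumes/2` frames), `dt = 2 TR`, and `band`.
#' @export
separate_run <- function(run, physio = NULL, regressors = NULL,
                         band = c(0.01, 0.071), fwhm = 0,
                         retroicor_order = 2L) {
  s <- split_and_rebuild(run)
  acq <- s$acq
  tv <- volume_times(acq)
  prep <- function(x) {
    if (!is.null(physio)) {
      # per tag class, then re-interleave
      sp <- split_run(x, s$tags)
      ctl <- retroicor_regress(sp$control, physio, tv[sp$control_index],
                               order = retroicor_order)
      lab <- retroicor_regress(sp$label, physio, tv[sp$label_index],
                               order = retroicor_order)
      x <- rebuild_interleaved(ctl, lab, control_first = s$tags[1] == "control")
    }
    if (!is.null(regressors)) x <- nuisance_regress(x, regressors)
    x
  }
  te1 <- prep(s$te1)
  te2 <- prep(s$te2)
  cbf <- separate_cbf(te1, acq$tr, control_first = s$tags[1] == "control")
  bold <- separate_bold(te2, acq$tr)
  dt <- 2 * acq$tr
  cbf <- bandpass(cbf, dt, band)
  bold <- bandpass(bold, dt, band)
  if (fwhm > 0 && length(dim(cbf)) == 4) {
    cbf <- spatial_smooth(cbf, fwhm, acq$voxel_size)
    bold <- spatial_smooth(bold, fwhm, acq$voxel_size)
  }
  structure(list(bold = bold, cbf = cbf, dt = dt, band = band),
            class = "separated_ts")
}
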