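# Quality-control and amplitude metrics: RSFA, DVARS, motion-RMS exclusion.

#' Resting-state fluctuation amplitude (RSFA)
#'
#' Per-voxel temporal standard deviation of the band-passed series
#' (unnormalized: the value carries the units of the input signal). Computed
#' for both the BOLD and the CBF fluctuation series to compare fluctuation
#' amplitudes between groups.
#'
#' @param series 4D array, frames-by-voxels matrix, or vector.
#' @param dt Sampling interval, seconds.
#' @param band Analysis band in Hz (default 0.01-0.071); `NULL` skips the
#'   filter (series already band-limited).
#' @return Per-voxel amplitude map (same spatial shape as the input).
#' @export
rsfa <- function(series, dt, band = c(0.01, 0.071)) {
  m <- as_frame_matrix(series)
  if (nrow(m) < 8) stop("series must have at least 8 frames")
  if (!is.null(band)) m <- fft_filter(m, dt, band[1], band[2], keep_dc = FALSE)
  shape_map(apply(m, 2, sd), m)
}

#' DVARS: RMS of the differentiated timeseries
#'
#' For each consecutive frame pair, the root mean square over mask voxels of
#' the frame-to-frame difference; a summary indicator of motion and
#' artifact. Invariant to adding the same spatial constant to both frames of
#' a pair.
#'
#' @param series 4D array or frames-by-voxels matrix (>= 2 frames).
#' @param mask Logical/binary spatial mask (non-empty); `NULL` uses all
#'   voxels.
#' @return List with `values` (one per frame pair, length `n_frames - 1`)
#'   and `mean` (run average).
#' @export
dvars <- function(series, mask = NULL) {
  m <- as_frame_matrix(series)
  if (nrow(m) < 2) stop("at least 2 frames required")
  if (!is.null(mask)) {
    sel <- as.logical(as.numeric(mask))
    if (!any(sel)) stop("empty mask")
    m <- m[, sel, drop = FALSE]
  }
  d <- diff(m)
  vals <- sqrt(rowMeans(d^2))
  list(values = vals, mean = mean(vals))
}

#' Motion-RMS subject exclusion
#'
#' Summary motion statistic: the root mean square over all frames of the six
#' rigid-body realignment parameters (three translations in mm and three
#' rotations), with rotations converted to mm of displacement on a sphere of
#' radius `rot_radius` (50 mm by convention). A subject is excluded when the
#' RMS strictly exceeds the threshold (default 1.5 mm).
#'
#' @param realignment Numeric matrix with 6 columns: translations (mm) then
#'   rotations (radians), one row per frame.
#' @param threshold Exclusion threshold in mm.
#' @param rot_radius Radius (mm) for the rotation-to-displacement conversion.
#' @return List with `rms` (mm) and logical `excluded`.
#' @export
motion_exclusion <- function(realignment, threshold = 1.5, rot_radius = 50) {
  realignment <- as.matrix(realignment)
  if (ncol(realignment) != 6)
    stop("realignment must have 6 columns (3 translations, 3 rotations)")
  disp <- realignment
  disp[, 4:6] <- disp[, 4:6] * rot_radius
  rms <- sqrt(mean(disp^2))
  list(rms = rms, excluded = rms > threshold)
}

#' Per-subject QC report
#'
#' Bundles RSFA (on both separated series), DVARS of each echo, and the
#' motion-RMS exclusion decision.
#'
#' @param separated A `separated_ts` object (see [separate_run()]).
#' @param run The corresponding `dual_echo_run`.
#' @param realignment Optional 6-column realignment matrix; when `NULL` the
#'   subject is assumed still (rms 0).
#' @param mask Optional spatial mask for DVARS.
#' @param threshold Motion exclusion threshold, mm.
#' @return List with `rsfa_bold`, `rsfa_cbf`, `dvars_echo1`, `dvars_echo2`,
#'   `motion_rms`, `excluded`; class `qc_report`.
#' @export
qc_report <- function(separated, run, realignment = NULL, mask = NULL,
                      threshold = 1.5) {
  mot <- if (is.null(realignment)) list(rms = 0, excluded = FALSE)
         else motion_exclusion(realignment, threshold)
  structure(list(rsfa_bold = rsfa(separated$bold, separated$dt, band = NULL),
                 rsfa_cbf = rsfa(separated$cbf, separated$dt, band = NULL),
                 dvars_echo1 = dvars(run$echo1, mask),
                 dvars_echo2 = dvars(run$echo2, mask),
                 motion_rms = mot$rms, excluded = mot$excluded),
            class = "qc_report")
}
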