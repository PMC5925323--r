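# Baseline perfusion quantification: single-compartment kinetic model for
# background-suppressed pCASL with slice-dependent post-label delay.

#' Temporal means of the control and label volumes
#'
#' @param series 4D interleaved series (or frames-by-voxels matrix).
#' @param tags Character vector "control"/"label" per volume.
#' @return List with maps `si_c` and `si_l` (voxelwise temporal means).
#' @export
temporal_means <- function(series, tags) {
  m <- as_frame_matrix(series)
  if (length(tags) != nrow(m))
    stop("tag vector length does not match the number of volumes")
  if (!all(c("control", "label") %in% tags))
    stop("both control and label volumes are required")
  list(si_c = shape_map(colMeans(m[tags == "control", , drop = FALSE]), m),
       si_l = shape_map(colMeans(m[tags == "label", , drop = FALSE]), m))
}

#' Quantify cerebral blood flow with the single-compartment model
#'
#' \deqn{CBF = \frac{6000\,\lambda\,(SI_C - SI_L)\,e^{PLD/T_{1A}}}
#'   {2\,\alpha\,\alpha_{inv}\,T_{1A}\,M_0\,(1 - e^{-\tau/T_{1A}})}
#'   \quad [\mathrm{ml/100g/min}],}
#' where \eqn{SI_C} and \eqn{SI_L} are the temporal means of the control and
#' label images, \eqn{\lambda} the blood-brain partition coefficient,
#' \eqn{T_{1A}} the longitudinal relaxation time of arterial blood (seconds;
#' the factor 6000 converts ml/g/s to ml/100g/min), \eqn{\alpha} the labeling
#' efficiency, \eqn{\alpha_{inv}} the background-suppression correction,
#' \eqn{\tau} the label duration and PLD the slice-dependent post-label
#' delay (third array axis = slices, ascending).
#'
#' @param si_c,si_l Temporal-mean control and label maps (3D arrays or
#'   vectors of equal shape).
#' @param m0 Equilibrium magnetization map, same shape; voxels with
#'   `m0 <= 0` are masked invalid (CBF 0, `valid_mask` FALSE).
#' @param params A [quant_params()] object; `params$n_slices` must match the
#'   third dimension for 3D input (a scalar `pld` is used for non-array
#'   input via `slice_index`).
#' @param slice_index Optional per-voxel slice index (1-based) for non-3D
#'   input; defaults to slice 1.
#' @return List with `cbf` map (ml/100g/min) and logical `valid_mask`;
#'   class `cbf_map`.
#' @export
quantify_cbf <- function(si_c, si_l, m0, params = quant_params(),
                         slice_index = NULL) {
  if (length(si_c) != length(si_l) || length(si_c) != length(m0))
    stop("si_c, si_l and m0 must have identical shapes")
  if (is.array(si_c) && length(dim(si_c)) == 3) {
    d <- dim(si_c)
    if (d[3] != params$n_slices)
      stop("third dimension (", d[3], ") does not match params$n_slices (",
           params$n_slices, ")")
    slice_index <- rep(seq_len(d[3]), each = d[1] * d[2])
  } else if (is.null(slice_index)) {
    slice_index <- rep(1L, length(si_c))
  }
  kern <- quant_kernel(params, slice_index)
  valid <- as.numeric(m0) > 0
  cbf <- numeric(length(si_c))
  cbf[valid] <- kern[valid] * (as.numeric(si_c)[valid] - as.numeric(si_l)[valid]) /
    as.numeric(m0)[valid]
  out <- if (is.array(si_c)) array(cbf, dim = dim(si_c)) else cbf
  vm <- if (is.array(si_c)) array(valid, dim = dim(si_c)) else valid
  structure(list(cbf = out, valid_mask = vm, params = params),
            class = "cbf_map")
}

#' Quantify CBF directly from a baseline run
#'
#' Convenience wrapper: temporal means of the tagged series, then
#' [quantify_cbf()].
#'
#' @param run List with `series` (4D) and `tags` (see
#'   [assemble_baseline_run()]).
#' @param m0 Equilibrium magnetization map.
#' @param params A [quant_params()] object.
#' @return A `cbf_map` (see [quantify_cbf()]).
#' @export
quantify_baseline_run <- function(run, m0, params = quant_params()) {
  tm <- temporal_means(run$series, run$tags)
  quantify_cbf(tm$si_c, tm$si_l, m0, params)
}
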