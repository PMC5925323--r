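#' Acquisition parameters of a (dual-echo) pCASL run
#'
#' Bundles the sequence timing and geometry needed by the generator and the
#' separation stage. Defaults reproduce a 3T dual-echo pCASL resting-state
#' protocol: TR 3.5 s, TE1/TE2 10/28 ms, 90 interleaved control/label volumes,
#' 64 x 64 x 19 matrix with 3.6 x 3.6 x 5 mm voxels, 1650 ms label duration and
#' 1000 ms first-slice post-label delay.
#'
#' @param tr Repetition time per volume, seconds.
#' @param te1,te2 First and second echo times, seconds (`te2 > te1`). For a
#'   single-echo run set `te2 = NA`.
#' @param n_volumes Total number of volumes (control + label); must be even.
#' @param matrix_size Integer triple `(nx, ny, nz)`.
#' @param voxel_size Numeric triple `(dx, dy, dz)` in mm.
#' @param label_duration Labeling bolus duration, seconds.
#' @param pld_first Post-label delay of the first (most inferior) slice, seconds.
#' @param pld_increment Additional post-label delay per slice, seconds
#'   (ascending 2D acquisition).
#' @param control_first Logical; `TRUE` if the first volume is a control.
#' @return An object of class `acq_params` (a validated list).
#' @export
acq_params <- function(tr = 3.5, te1 = 0.010, te2 = 0.028, n_volumes = 90L,
                       matrix_size = c(64L, 64L, 19L),
                       voxel_size = c(3.6, 3.6, 5),
                       label_duration = 1.65, pld_first = 1.0,
                       pld_increment = 0.05, control_first = TRUE) {
  stopifnot(tr > 0, te1 > 0, length(matrix_size) == 3,
            length(voxel_size) == 3, all(matrix_size >= 1),
            label_duration > 0, pld_first > 0, pld_increment >= 0,
            is.logical(control_first))
  if (!is.na(te2) && te2 <= te1)
    stop("te2 must exceed te1")
  n_volumes <- as.integer(n_volumes)
  if (n_volumes %% 2L != 0L)
    stop("n_volumes must be even (interleaved control/label pairs)")
  structure(list(tr = tr, te1 = te1, te2 = te2, n_volumes = n_volumes,
                 matrix_size = as.integer(matrix_size),
                 voxel_size = as.numeric(voxel_size),
                 label_duration = label_duration, pld_first = pld_first,
                 pld_increment = pld_increment, control_first = control_first),
            class = "acq_params")
}

#' Quantification parameters for the single-compartment perfusion model
#'
#' Constants of the kinetic model used by [quantify_cbf()]. Defaults follow
#' the consensus values for 3T background-suppressed pCASL: blood-brain
#' partition coefficient 0.9 ml/g, arterial blood T1 1650 ms, labeling
#' efficiency 0.85, background-suppression correction 0.83, label duration
#' 1750 ms, and a slice-dependent post-label delay ramping from 1900 ms
#' (slice 1) to 2800 ms (slice 19).
#'
#' @param lambda_bbp Blood-brain partition coefficient, ml/g.
#' @param t1a Longitudinal relaxation time of arterial blood, seconds.
#' @param alpha_label Labeling efficiency, in (0, 1].
#' @param alpha_inv Background-suppression correction factor, in (0, 1].
#'   Use 1 for runs without background suppression.
#' @param label_duration Label duration, seconds.
#' @param pld_first Post-label delay of the first slice, seconds.
#' @param pld_last Post-label delay of the last slice, seconds.
#' @param n_slices Number of slices (ascending order).
#' @return An object of class `quant_params`.
#' @export
quant_params <- function(lambda_bbp = 0.9, t1a = 1.65, alpha_label = 0.85,
                         alpha_inv = 0.83, label_duration = 1.75,
                         pld_first = 1.9, pld_last = 2.8, n_slices = 19L) {
  stopifnot(lambda_bbp > 0, t1a > 0,
            alpha_label > 0, alpha_label <= 1,
            alpha_inv > 0, alpha_inv <= 1,
            label_duration > 0, pld_first > 0, pld_last >= pld_first,
            n_slices >= 1)
  structure(list(lambda_bbp = lambda_bbp, t1a = t1a,
                 alpha_label = alpha_label, alpha_inv = alpha_inv,
                 label_duration = label_duration, pld_first = pld_first,
                 pld_last = pld_last, n_slices = as.integer(n_slices)),
            class = "quant_params")
}

#' Lag grid for the lagged cross-correlation scan
#'
#' Defines the lags at which [lagged_rmax()] evaluates the BOLD-CBF
#' correlation and the temporal resolution of the sinc upsampling. Defaults:
#' lags from -7 s to +7 s in 0.35 s steps, evaluated on a 100 ms grid. The
#' grid is symmetric about zero and always contains the zero lag.
#'
#' @param tau_max Largest absolute lag, seconds.
#' @param step Lag step, seconds.
#' @param upsample_dt Temporal resolution of the sinc-upsampled series, seconds.
#' @return An object of class `lag_grid` with a `lags` vector.
#' @export
lag_grid <- function(tau_max = 7, step = 0.35, upsample_dt = 0.1) {
  stopifnot(tau_max > 0, step > 0, step <= tau_max, upsample_dt > 0)
  k <- floor(tau_max / step + 1e-9)
  lags <- seq(-k, k) * step
  structure(list(tau_min = -k * step, tau_max = k * step, step = step,
                 upsample_dt = upsample_dt, lags = lags),
            class = "lag_grid")
}

#' Slice-dependent post-label delay
#'
#' Linear ramp of the post-label delay across slices of an ascending 2D
#' readout: `pld_first` at slice 1 up to `pld_last` at slice `n_slices`
#' (50 ms per slice with the defaults).
#'
#' @param slice_index 1-based slice index (vectorized).
#' @param params A [quant_params()] object.
#' @return Post-label delay in seconds for each slice.
#' @export
slice_pld <- function(slice_index, params = quant_params()) {
  slice_index <- as.integer(slice_index)
  if (any(slice_index < 1L | slice_index > params$n_slices))
    stop("slice_index out of range 1..", params$n_slices)
  if (params$n_slices == 1L)
    return(rep(params$pld_first, length(slice_index)))
  inc <- (params$pld_last - params$pld_first) / (params$n_slices - 1L)
  params$pld_first + (slice_index - 1L) * inc
}

# run RNG-dependent code with a local, restored seed (bit-reproducible)
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# derive a child seed (kept inside 32-bit integer range)
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483629)
}

# coerce a 4D array / matrix / vector to a frames-by-voxels matrix,
# remembering the original shape so it can be restored
as_frame_matrix <- function(x) {
  if (is.array(x) && length(dim(x)) == 4) {
    d <- dim(x)
    m <- t(matrix(x, nrow = prod(d[1:3]), ncol = d[4]))
    attr(m, "orig_dim") <- d
    m
  } else if (is.matrix(x)) {
    x
  } else {
    m <- matrix(as.numeric(x), ncol = 1)
    attr(m, "orig_vec") <- TRUE
    m
  }
}

restore_shape <- function(m, template) {
  if (!is.null(attr(template, "orig_dim"))) {
    d <- attr(template, "orig_dim")
    d[4] <- nrow(m)
    array(t(m), dim = d)
  } else if (!is.null(attr(template, "orig_vec"))) {
    as.numeric(m[, 1])
  } else {
    m[, , drop = FALSE]
  }
}
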