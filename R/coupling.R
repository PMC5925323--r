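# Voxelwise BOLD-CBF coupling: zero-lag correlation r0 and lag-optimized
# correlation rmax with its optimizing lag tau_star.
#
# The lag scan evaluates, for each lag tau on the grid, the Pearson
# correlation between BOLD advanced by tau and CBF over their truncated
# overlap (no wrap-around), on a sinc-upsampled time grid. Because sinc
# evaluation at shifted times is linear in the original samples, the
# correlation at every lag can be computed exactly from precomputed Gram
# matrices of the interpolation operators, which makes the voxelwise scan
# cheap. At tau = 0 interpolation adds no information, so the native-grid
# correlation r0 is used there; the grid therefore guarantees rmax >= r0.

#' Voxelwise zero-lag Pearson correlation
#'
#' Pearson correlation between paired BOLD and CBF fluctuation series,
#' computed per voxel over time. Voxels with zero variance in either series
#' yield `NA`.
#'
#' @param bold,cbf Series of identical shape: vectors, frames-by-voxels
#'   matrices, or 4D arrays; or a `separated_ts` object passed as `bold`
#'   (then `cbf` is ignored).
#' @return Correlation per voxel: scalar, vector, or 3D array matching the
#'   input spatial shape.
#' @export
pearson_r0 <- function(bold, cbf = NULL) {
  if (inherits(bold, "separated_ts")) { cbf <- bold$cbf; bold <- bold$bold }
  mb <- as_frame_matrix(bold); mc <- as_frame_matrix(cbf)
  if (!all(dim(mb) == dim(mc)))
    stop("bold and cbf series must have identical shapes")
  r <- colwise_cor(mb, mc)
  shape_map(r, mb)
}

# fast column-wise Pearson correlation with zero-variance -> NA
colwise_cor <- function(a, b) {
  n <- nrow(a)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  num <- colSums(ac * bc)
  va <- colSums(ac^2); vb <- colSums(bc^2)
  r <- num / sqrt(va * vb)
  r[va <= 0 | vb <= 0] <- NA_real_
  pmin(1, pmax(-1, r))
}

# reshape a per-voxel statistic back to the input's spatial shape
shape_map <- function(v, template) {
  if (!is.null(attr(template, "orig_dim")))
    array(v, dim = attr(template, "orig_dim")[1:3])
  else if (!is.null(attr(template, "orig_vec"))) v[1]
  else v
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r)`, the variance-stabilizing transform used before group
#' statistics on correlation maps. Values with `|r| >= 1` are clamped to
#' `1 - 1e-7` in magnitude before the transform (documented behavior for
#' degenerate noise-free voxels); `NA` passes through.
#'
#' @param r Correlations (any numeric shape).
#' @return `atanh(r)` with the same shape.
#' @export
fisher_z <- function(r) {
  rc <- pmin(1 - 1e-7, pmax(-(1 - 1e-7), r))
  atanh(rc)
}

# ---- lag-scan kernels --------------------------------------------------

# Gram matrices of the shifted-interpolation operators for one lag grid.
# For lag tau, BOLD(t + tau) is evaluated against CBF(t) at the upsampled
# times t_j within the truncated overlap:
#   A_tau[j, k] = sinc weight of bold sample k at time t_j + tau
#   B_tau[j, k] = sinc weight of cbf sample k at time t_j
# Correlation for series x, y follows from x' (A'A) x, x' (A'B) y, y' (B'B) y
# and the column sums of A and B.
lag_kernels <- function(n, dt_in, grid) {
  key <- paste(n, dt_in, grid$tau_max, grid$step, grid$upsample_dt, sep = "|")
  hit <- .boldcbf_cache[[key]]
  if (!is.null(hit)) return(hit)
  total <- (n - 1) * dt_in
  tu <- seq(0, total, by = grid$upsample_dt)
  kern <- lapply(grid$lags, function(tau) {
    tj <- tu[tu + tau >= -1e-9 & tu + tau <= total + 1e-9]
    if (length(tj) < 10)
      stop("insufficient overlap at lag ", tau, " s")
    a <- sinc_matrix(n, dt_in, tj + tau)
    b <- sinc_matrix(n, dt_in, tj)
    list(m = length(tj),
         gaa = crossprod(a), gbb = crossprod(b), gab = crossprod(a, b),
         sa = colSums(a), sb = colSums(b))
  })
  .boldcbf_cache[[key]] <- kern
  kern
}

#' Lag-optimized BOLD-CBF correlation
#'
#' For each lag `tau` on the grid, computes the Pearson correlation between
#' the BOLD series advanced by `tau` and the CBF series over their
#' overlapping support (truncated overlap, no wrap-around), both evaluated
#' on the sinc-upsampled time grid. Returns the maximum correlation `rmax`
#' and its lag `tau_star`; ties are broken toward the smallest `|tau|`, then
#' the negative lag. The sign convention matches the generator: `tau_star`
#' equals the lag by which BOLD is delayed relative to CBF, so a BOLD signal
#' lagging behind CBF that was generated with a negative `lag` is recovered
#' as a negative `tau_star`. At `tau = 0` the native-resolution correlation
#' is used, so `rmax >= r0` always holds.
#'
#' @param bold,cbf Series of identical shape (vector, frames-by-voxels
#'   matrix, or 4D array), sampled at interval `dt`.
#' @param dt Native sampling interval, seconds (typically `2 TR`).
#' @param grid A [lag_grid()] object.
#' @return List with per-voxel `r0`, `rmax`, `tau_star`, Fisher transforms
#'   `z0` and `zmax`, the lag vector `lags`, and the full correlation-by-lag
#'   matrix `r_by_lag` (lags in rows); class `coupling_map`.
#' @export
lagged_rmax <- function(bold, cbf, dt, grid = lag_grid()) {
  if (inherits(bold, "separated_ts")) {
    dt <- bold$dt; cbf <- bold$cbf; bold <- bold$bold
  }
  mb <- as_frame_matrix(bold); mc <- as_frame_matrix(cbf)
  if (!all(dim(mb) == dim(mc)))
    stop("bold and cbf series must have identical shapes")
  n <- nrow(mb); nv <- ncol(mb)
  if (grid$upsample_dt >= dt)
    stop("upsample_dt must be smaller than the native sampling interval")
  kern <- lag_kernels(n, dt, grid)
  nl <- length(grid$lags)
  rmat <- matrix(NA_real_, nrow = nl, ncol = nv)
  for (k in seq_len(nl)) {
    kk <- kern[[k]]
    sx <- as.numeric(kk$sa %*% mb)           # sums of shifted bold
    sy <- as.numeric(kk$sb %*% mc)
    sxx <- colSums(mb * (kk$gaa %*% mb))
    syy <- colSums(mc * (kk$gbb %*% mc))
    sxy <- colSums(mb * (kk$gab %*% mc))
    vx <- sxx - sx^2 / kk$m
    vy <- syy - sy^2 / kk$m
    r <- (sxy - sx * sy / kk$m) / sqrt(pmax(vx, 0) * pmax(vy, 0))
    r[vx <= 1e-12 * pmax(sxx, 1) | vy <= 1e-12 * pmax(syy, 1)] <- NA_real_
    rmat[k, ] <- pmin(1, pmax(-1, r))
  }
  r0 <- colwise_cor(mb, mc)
  rmat[which(abs(grid$lags) < 1e-12), ] <- r0
  # argmax with tie-break toward smallest |tau|, then negative tau
  ord <- order(abs(grid$lags), grid$lags)
  rmax <- numeric(nv); tau_star <- numeric(nv)
  for (v in seq_len(nv)) {
    rv <- rmat[ord, v]
    if (all(is.na(rv))) { rmax[v] <- NA_real_; tau_star[v] <- NA_real_; next }
    i <- which.max(rv)                       # first max in tie-break order
    rmax[v] <- rv[i]
    tau_star[v] <- grid$lags[ord[i]]
  }
  structure(list(r0 = shape_map(r0, mb), rmax = shape_map(rmax, mb),
                 tau_star = shape_map(tau_star, mb),
                 z0 = shape_map(fisher_z(r0), mb),
                 zmax = shape_map(fisher_z(rmax), mb),
                 lags = grid$lags, r_by_lag = rmat),
            class = "coupling_map")
}
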