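# Voxelwise random-effects group statistics on Fisher-z coupling maps,
# with Benjamini-Hochberg FDR control, plus ROI summaries.

# stack a list of equal-shaped maps into subjects-by-voxels matrix
stack_maps <- function(maps) {
  m <- do.call(rbind, lapply(maps, function(x) as.numeric(x)))
  attr(m, "map_dim") <- if (is.array(maps[[1]])) dim(maps[[1]]) else NULL
  m
}

map_back <- function(v, stacked) {
  d <- attr(stacked, "map_dim")
  if (is.null(d)) v else array(v, dim = d)
}

#' Voxelwise one-sample t-test against zero
#'
#' Random-effects group map: per voxel, a one-sample t on the per-subject
#' values (typically Fisher-z coupling maps) against zero, with
#' `dof = n - 1` and two-sided p-values. Voxels with undefined values in any
#' subject, or zero between-subject variance, are excluded (`NA`) and do not
#' count toward the FDR family.
#'
#' @param maps List of per-subject maps (equal shapes), or a
#'   subjects-by-voxels matrix.
#' @param mask Optional logical map restricting the tested voxels.
#' @param alpha FDR level for the rejection mask.
#' @return List of maps `t`, `p`, `q`, `reject`, plus `dof` and `mask`;
#'   class `group_stat_map`.
#' @export
one_sample_t <- function(maps, mask = NULL, alpha = 0.05) {
  m <- if (is.matrix(maps)) maps else stack_maps(maps)
  n <- nrow(m)
  if (n < 2) stop("at least 2 subjects required")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  t <- mu / (s / sqrt(n))
  t[!is.finite(t) & mu == 0] <- 0           # all-zero voxels: t = 0
  t[s == 0 & mu != 0] <- NA_real_           # degenerate nonzero constant
  p <- 2 * pt(-abs(t), df = n - 1)
  finish_group_stat(t, p, n - 1, m, mask, alpha)
}

#' Voxelwise two-sample unpaired t-test
#'
#' Pooled-variance unpaired t between two groups of per-subject maps,
#' `dof = nA + nB - 2`, two-sided p-values. A Welch variant is available via
#' `var_equal = FALSE`.
#'
#' @param maps_a,maps_b Lists of per-subject maps (or matrices), one per group.
#' @param mask Optional logical map restricting the tested voxels.
#' @param alpha FDR level for the rejection mask.
#' @param var_equal Pooled-variance t when `TRUE` (default), Welch otherwise.
#' @return A `group_stat_map` (see [one_sample_t()]); positive t means
#'   group A > group B.
#' @export
two_sample_t <- function(maps_a, maps_b, mask = NULL, alpha = 0.05,
                         var_equal = TRUE) {
  a <- if (is.matrix(maps_a)) maps_a else stack_maps(maps_a)
  b <- if (is.matrix(maps_b)) maps_b else stack_maps(maps_b)
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 subjects")
  mu_a <- colMeans(a); mu_b <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    dof <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    dof <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mu_a - mu_b) / se
  t[se == 0 & mu_a == mu_b] <- 0
  p <- 2 * pt(-abs(t), df = dof)
  finish_group_stat(t, p, dof, a, mask, alpha)
}

finish_group_stat <- function(t, p, dof, stacked, mask, alpha) {
  keep <- is.finite(p)
  if (!is.null(mask)) keep <- keep & as.logical(as.numeric(mask))
  fdr <- fdr_bh(p[keep], alpha = alpha)
  q <- rep(NA_real_, length(p)); rej <- rep(FALSE, length(p))
  q[keep] <- fdr$q; rej[keep] <- fdr$reject
  structure(list(t = map_back(t, stacked), dof = dof,
                 p = map_back(p, stacked), q = map_back(q, stacked),
                 reject = map_back(rej, stacked),
                 mask = map_back(keep, stacked), alpha = alpha),
            class = "group_stat_map")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with sorted p-values `p(1) <= ... <= p(m)`, all
#' hypotheses with `p <= p(k)` are rejected, where
#' `k = max { i : p(i) <= i * alpha / m }`. The adjusted values `q` are the
#' standard monotone BH-adjusted p-values (computed with
#' [stats::p.adjust()]), so `reject` is equivalent to `q <= alpha`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return List with `q` (adjusted values) and `reject` (logical), in the
#'   input order; empty input gives empty output.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(list(q = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Mean of a map over a gray-matter-restricted ROI
#'
#' Averages a voxel map over the voxels where a binary ROI mask intersects a
#' gray-matter probability map thresholded at `threshold` (default 0.3).
#'
#' @param map Numeric voxel map.
#' @param mask Binary/logical ROI mask of the same shape.
#' @param gm_mask Optional gray-matter probability map of the same shape.
#' @param threshold Gray-matter probability threshold.
#' @return Scalar mean with attribute `n_voxels`.
#' @export
roi_extract <- function(map, mask, gm_mask = NULL, threshold = 0.3) {
  stopifnot(length(map) == length(mask))
  sel <- as.logical(as.numeric(mask))
  if (!is.null(gm_mask)) {
    stopifnot(length(gm_mask) == length(map))
    sel <- sel & (as.numeric(gm_mask) >= threshold)
  }
  sel <- sel & !is.na(as.numeric(map))
  if (!any(sel)) stop("empty ROI: mask and gray-matter support do not intersect")
  structure(mean(as.numeric(map)[sel]), n_voxels = sum(sel))
}

#' Cohen's d for two independent samples
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled standard deviation
#' `s_pooled^2 = ((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2)`.
#'
#' @param a,b Numeric vectors.
#' @return Effect size (scalar).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Group contrast of the lag-correction benefit rmax - r0
#'
#' The per-subject difference `rmax - r0` measures how much the correlation
#' between BOLD and CBF improves when the optimal temporal shift is applied;
#' a larger value indicates a larger temporal mismatch between the two
#' signals. This compares the difference between two groups with an unpaired
#' pooled-variance t-test and reports Cohen's d.
#'
#' @param roi_a,roi_b Data frames (or lists) with per-subject `r0` and
#'   `rmax` values for each group.
#' @return List with per-group means of `r0`, `rmax` and the difference,
#'   `t`, `dof`, `p`, and `cohens_d` (positive when group A's difference is
#'   larger).
#' @export
rmax_minus_r0_contrast <- function(roi_a, roi_b) {
  da <- roi_a$rmax - roi_a$r0
  db <- roi_b$rmax - roi_b$r0
  if (length(da) < 2 || length(db) < 2)
    stop("each group needs at least 2 subjects")
  na <- length(da); nb <- length(db)
  sp2 <- ((na - 1) * var(da) + (nb - 1) * var(db)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- if (se == 0) 0 else (mean(da) - mean(db)) / se
  list(mean_a = c(r0 = mean(roi_a$r0), rmax = mean(roi_a$rmax), diff = mean(da)),
       mean_b = c(r0 = mean(roi_b$r0), rmax = mean(roi_b$rmax), diff = mean(db)),
       t = t, dof = na + nb - 2, p = 2 * pt(-abs(t), df = na + nb - 2),
       cohens_d = cohens_d(da, db))
}
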