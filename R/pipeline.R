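# End-to-end orchestration of the coupling pipeline over a subject roster.

#' Subject record for [run_pipeline()]
#'
#' @param id Unique subject identifier.
#' @param group Group label (e.g. "young", "elderly").
#' @param run A `dual_echo_run`.
#' @param physio Optional `physio_trace` for RETROICOR.
#' @param regressors Optional confound matrix (one row per volume).
#' @param realignment Optional 6-column realignment-parameter matrix for the
#'   motion-RMS exclusion rule.
#' @param baseline Optional baseline ASL run (list `series`, `tags`, `acq`).
#' @param m0 Optional equilibrium magnetization map (required with
#'   `baseline`).
#' @return A `subject_record` list.
#' @export
subject_record <- function(id, group, run, physio = NULL, regressors = NULL,
                           realignment = NULL, baseline = NULL, m0 = NULL) {
  structure(list(id = id, group = group, run = run, physio = physio,
                 regressors = regressors, realignment = realignment,
                 baseline = baseline, m0 = m0),
            class = "subject_record")
}

#' Run the full coupling pipeline on a roster of subjects
#'
#' Per subject: motion-RMS exclusion check, physiological and nuisance
#' regression, BOLD/CBF signal separation with band-pass and optional
#' smoothing, voxelwise r0/rmax/tau_star coupling maps, QC report, and
#' (when a baseline run is supplied) baseline CBF quantification. At the
#' group level: voxelwise one-sample t maps of the Fisher-z coupling per
#' group, the two-group contrast with BH-FDR correction, and ROI summaries
#' including the `rmax - r0` contrast. Excluded subjects are dropped from
#' all group maps. Deterministic: re-running on the same inputs reproduces
#' every numeric output.
#'
#' @param roster List of [subject_record()]s (>= 1).
#' @param band Analysis band, Hz.
#' @param fwhm Spatial smoothing FWHM, mm (0 disables).
#' @param grid A [lag_grid()].
#' @param alpha FDR level for group maps.
#' @param motion_threshold Motion-RMS exclusion threshold, mm.
#' @param quant A [quant_params()] object for baseline quantification.
#' @param analysis_mask Optional logical map: FDR domain and group-test
#'   support; defaults to all voxels.
#' @param rois Optional named list of binary ROI masks.
#' @param gm_mask Optional gray-matter probability map for ROI restriction.
#' @param out_dir Optional directory: coupling and group maps are written as
#'   NIfTI, ROI and QC summaries as TSV.
#' @return Nested result list: `subjects` (per-subject separated series,
#'   coupling maps, QC, CBF), `group` (t/p/q maps per group and contrast),
#'   `roi` (per-subject ROI summary table and contrasts), `excluded` ids.
#' @export
run_pipeline <- function(roster, band = c(0.01, 0.071), fwhm = 0,
                         grid = lag_grid(), alpha = 0.05,
                         motion_threshold = 1.5, quant = quant_params(),
                         analysis_mask = NULL, rois = NULL, gm_mask = NULL,
                         out_dir = NULL) {
  stopifnot(length(roster) >= 1)
  ids <- vapply(roster, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  subjects <- list()
  excluded <- character(0)
  for (rec in roster) {
    mot <- if (is.null(rec$realignment)) list(rms = 0, excluded = FALSE)
           else motion_exclusion(rec$realignment, motion_threshold)
    sep <- separate_run(rec$run, physio = rec$physio,
                        regressors = rec$regressors, band = band, fwhm = fwhm)
    cm <- lagged_rmax(sep$bold, sep$cbf, dt = sep$dt, grid = grid)
    qc <- qc_report(sep, rec$run, rec$realignment,
                    threshold = motion_threshold)
    cbf <- if (!is.null(rec$baseline))
      quantify_baseline_run(rec$baseline, rec$m0, quant) else NULL
    subjects[[rec$id]] <- list(id = rec$id, group = rec$group,
                               separated = sep, coupling = cm, qc = qc,
                               cbf = cbf, excluded = mot$excluded,
                               motion_rms = mot$rms)
    if (mot$excluded) excluded <- c(excluded, rec$id)
    if (!is.null(out_dir) && length(dim(cm$r0)) == 3) {
      for (nm in c("r0", "rmax", "tau_star"))
        write_map(cm[[nm]], file.path(out_dir, paste0(rec$id, "_", nm, ".nii.gz")),
                  voxel_size = rec$run$acq$voxel_size)
    }
  }
  kept <- subjects[setdiff(names(subjects), excluded)]
  groups <- split(kept, vapply(kept, `[[`, "", "group"))
  group_stats <- lapply(groups, function(g) {
    if (length(g) < 2) return(NULL)
    list(z0 = one_sample_t(lapply(g, function(s) s$coupling$z0),
                           mask = analysis_mask, alpha = alpha),
         zmax = one_sample_t(lapply(g, function(s) s$coupling$zmax),
                             mask = analysis_mask, alpha = alpha))
  })
  contrast <- NULL
  if (length(groups) == 2 && all(vapply(groups, length, 0L) >= 2)) {
    ga <- groups[[1]]; gb <- groups[[2]]
    contrast <- list(
      z0 = two_sample_t(lapply(ga, function(s) s$coupling$z0),
                        lapply(gb, function(s) s$coupling$z0),
                        mask = analysis_mask, alpha = alpha),
      zmax = two_sample_t(lapply(ga, function(s) s$coupling$zmax),
                          lapply(gb, function(s) s$coupling$zmax),
                          mask = analysis_mask, alpha = alpha),
      groups = names(groups))
  }
  roi_out <- NULL
  if (!is.null(rois)) {
    rows <- list()
    for (s in kept) for (rn in names(rois)) {
      r0 <- roi_extract(s$coupling$r0, rois[[rn]], gm_mask)
      rm <- roi_extract(s$coupling$rmax, rois[[rn]], gm_mask)
      ts <- roi_extract(s$coupling$tau_star, rois[[rn]], gm_mask)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = s$id, group = s$group, roi = rn,
                   r0 = as.numeric(r0), rmax = as.numeric(rm),
                   rmax_minus_r0 = as.numeric(rm) - as.numeric(r0),
                   tau_star = as.numeric(ts))
    }
    tab <- do.call(rbind, rows)
    contrasts <- NULL
    if (length(groups) == 2) {
      gl <- names(groups)
      contrasts <- lapply(names(rois), function(rn) {
        a <- tab[tab$roi == rn & tab$group == gl[1], ]
        b <- tab[tab$roi == rn & tab$group == gl[2], ]
        if (nrow(a) < 2 || nrow(b) < 2) return(NULL)
        c(list(roi = rn), rmax_minus_r0_contrast(a, b))
      })
      names(contrasts) <- names(rois)
      ps <- vapply(contrasts, function(x) if (is.null(x)) NA_real_ else x$p,
                   numeric(1))
      qs <- rep(NA_real_, length(ps))
      qs[!is.na(ps)] <- fdr_bh(ps[!is.na(ps)], alpha)$q
      for (i in seq_along(contrasts))
        if (!is.null(contrasts[[i]])) contrasts[[i]]$q <- qs[i]
    }
    roi_out <- list(table = tab, contrasts = contrasts)
    if (!is.null(out_dir)) write_tsv(tab, file.path(out_dir, "roi_summary.tsv"))
  }
  if (!is.null(out_dir)) {
    qct <- do.call(rbind, lapply(subjects, function(s)
      data.frame(subject = s$id, group = s$group, motion_rms = s$motion_rms,
                 excluded = s$excluded,
                 dvars_echo1 = s$qc$dvars_echo1$mean,
                 dvars_echo2 = s$qc$dvars_echo2$mean)))
    write_tsv(qct, file.path(out_dir, "qc_summary.tsv"))
  }
  list(subjects = subjects, group = group_stats, contrast = contrast,
       roi = roi_out, excluded = excluded)
}
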