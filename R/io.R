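# Standard-format I/O: 4D NIfTI volumes (one file per echo), JSON sidecars
# carrying acquisition parameters and the control/label tag vector, TSV
# physiological traces and truth/summary tables.

#' Write a dual-echo run to disk
#'
#' One 4D NIfTI per echo (volume order = acquisition order, voxel data stored
#' as double so the round-trip is lossless), plus a JSON sidecar with the
#' acquisition parameters and the control/label tag vector.
#'
#' @param run A `dual_echo_run`.
#' @param prefix Output path prefix; files `<prefix>_echo1.nii.gz`,
#'   `<prefix>_echo2.nii.gz` and `<prefix>.json` are created.
#' @return The sidecar path, invisibly.
#' @export
write_dual_echo_run <- function(run, prefix) {
  vox <- run$acq$voxel_size
  for (e in 1:2) {
    img <- RNifti::asNifti(run[[paste0("echo", e)]],
                           pixdim = c(vox, run$acq$tr), datatype = "double")
    RNifti::writeNifti(img, paste0(prefix, "_echo", e, ".nii.gz"),
                       datatype = "double")
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(list(acq = unclass(run$acq), tags = run$tags),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a dual-echo run written by [write_dual_echo_run()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `dual_echo_run`.
#' @export
read_dual_echo_run <- function(prefix) {
  sidecar <- paste0(prefix, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar: expected tag/parameter file ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  acq <- do.call(acq_params, meta$acq[setdiff(names(meta$acq), character())])
  e1 <- read_map(paste0(prefix, "_echo1.nii.gz"))
  e2 <- read_map(paste0(prefix, "_echo2.nii.gz"))
  structure(list(echo1 = e1, echo2 = e2, tags = meta$tags, acq = acq),
            class = "dual_echo_run")
}

#' Write a voxel map (or 4D series) as NIfTI
#'
#' @param map 3D or 4D numeric array.
#' @param path Output `.nii.gz` path.
#' @param voxel_size mm per voxel.
#' @param dt Time-axis spacing in seconds (stored for 4D data so downstream
#'   tools see the correct sampling interval).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, voxel_size = c(3.6, 3.6, 5), dt = NULL) {
  pd <- c(voxel_size, if (!is.null(dt)) dt)
  img <- RNifti::asNifti(map, pixdim = pd, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI map as a plain array
#'
#' @param path `.nii(.gz)` path.
#' @return Numeric array (attributes dropped).
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Write / read a physiological trace as two-column TSV
#'
#' Columns `cardiac` and `respiratory`, one row per sample at the trace's
#' sampling rate; the duration is `nrow / sampling_rate` seconds.
#'
#' @param physio A `physio_trace`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_physio_tsv <- function(physio, path) {
  write.table(data.frame(cardiac = physio$cardiac,
                         respiratory = physio$respiratory),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_physio_tsv
#' @param sampling_rate Hz of the stored trace.
#' @export
read_physio_tsv <- function(path, sampling_rate = 100) {
  d <- read.delim(path)
  if (!all(c("cardiac", "respiratory") %in% names(d)))
    stop("malformed physio file ", path, ": need columns cardiac, respiratory")
  structure(list(sampling_rate = sampling_rate, cardiac = d$cardiac,
                 respiratory = d$respiratory,
                 duration = nrow(d) / sampling_rate),
            class = "physio_trace")
}

#' Write / read a table as TSV (column types preserved on round-trip)
#'
#' @param table A data frame.
#' @param path TSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)
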