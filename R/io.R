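#' Write a time series as NIfTI files
#'
#' Magnitude (and, if present, phase) written as standard 4D NIfTI-1
#' images with the TR stored in the time pixdim.
#'
#' @param ts an [fmri_ts].
#' @param magnitude_path output path for the magnitude image (.nii/.nii.gz).
#' @param phase_path optional output path for the phase image.
#' @return Invisibly, the written paths.
#' @export
write_ts_nifti <- function(ts, magnitude_path, phase_path = NULL) {
  img <- RNifti::asNifti(ts$magnitude)
  RNifti::pixdim(img) <- c(1, 1, 1, ts$tr_seconds)
  RNifti::writeNifti(img, magnitude_path)
  paths <- magnitude_path
  if (!is.null(phase_path)) {
    if (is.null(ts$phase)) stopf("no phase data to write")
    pimg <- RNifti::asNifti(ts$phase)
    RNifti::pixdim(pimg) <- c(1, 1, 1, ts$tr_seconds)
    RNifti::writeNifti(pimg, phase_path)
    paths <- c(paths, phase_path)
  }
  invisible(paths)
}

#' Read a time series from NIfTI files
#'
#' @param magnitude_path magnitude image path.
#' @param phase_path optional phase image path.
#' @param tr_seconds TR override; taken from the header when NULL.
#' @param n_noise_scans appended noise volumes contained in the file.
#' @return An [fmri_ts].
#' @export
read_ts_nifti <- function(magnitude_path, phase_path = NULL,
                          tr_seconds = NULL, n_noise_scans = 0L) {
  img <- RNifti::readNifti(magnitude_path)
  mag <- array(as.numeric(img), dim = dim(img))
  if (is.null(tr_seconds)) {
    pd <- RNifti::pixdim(img)
    tr_seconds <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  ph <- NULL
  if (!is.null(phase_path)) {
    p <- RNifti::readNifti(phase_path)
    ph <- array(as.numeric(p), dim = dim(p))
  }
  fmri_ts(pmax(mag, 0), ph, tr_seconds, n_noise_scans)
}

#' Write an event design as a BIDS-style events table
#'
#' Tab-separated columns `onset` (seconds), `duration` (seconds),
#' `trial_type`.
#'
#' @param design an [event_design()].
#' @param path output .tsv path.
#' @return Invisibly, the path.
#' @export
write_events_tsv <- function(design, path) {
  tr <- attr(design, "tr_seconds")
  tab <- data.frame(onset = design$onset_volume * tr,
                    duration = attr(design, "duration_seconds"),
                    trial_type = design$condition)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an events table back into an event design
#'
#' @param path .tsv path with `onset`, `duration`, `trial_type` columns.
#' @param tr_seconds repetition time used to convert onsets to volumes.
#' @return An [event_design()].
#' @export
read_events_tsv <- function(path, tr_seconds) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  event_design(tab$trial_type, round(tab$onset / tr_seconds), tr_seconds)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path .yaml path.
#' @return Invisibly the path, or the [sim_config()] when reading.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Write a 3D map as NIfTI
#'
#' @param map 3D numeric array (a vector is accepted with `dim3` given).
#' @param path output path.
#' @param dim3 spatial dimensions when `map` is a vector.
#' @return Invisibly, the path.
#' @export
write_map_nifti <- function(map, path, dim3 = NULL) {
  if (!is.null(dim3)) map <- array(map, dim = dim3)
  RNifti::writeNifti(RNifti::asNifti(map), path)
  invisible(path)
}
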