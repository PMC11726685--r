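#' 4D fMRI time-series container
#'
#' Bundles a magnitude 4D array (x, y, z, t), an optional phase array in
#' radians, the repetition time, and the number of appended no-excitation
#' noise volumes. The last `n_noise_scans` volumes along the 4th dimension
#' are noise scans: acquisitions without radiofrequency excitation that
#' contain only (complex Gaussian) thermal noise and are used to calibrate
#' the absolute noise level.
#'
#' @param magnitude non-negative 4D numeric array.
#' @param phase optional 4D array of phases in radians, same shape.
#' @param tr_seconds repetition time in seconds.
#' @param n_noise_scans number of appended noise volumes (counted within
#'   `dim(magnitude)[4]`).
#' @return An object of class `fmri_ts`.
#' @export
fmri_ts <- function(magnitude, phase = NULL, tr_seconds, n_noise_scans = 0L) {
  if (length(dim(magnitude)) != 4L)
    stopf("`magnitude` must be a 4D array")
  if (!all(is.finite(magnitude)) || any(magnitude < 0))
    stopf("`magnitude` must be finite and non-negative")
  if (!is.null(phase) && !identical(dim(phase), dim(magnitude)))
    stopf("`phase` must have the same shape as `magnitude`")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stopf("`tr_seconds` must be positive")
  n_noise_scans <- as.integer(n_noise_scans)
  if (n_noise_scans < 0 || n_noise_scans >= dim(magnitude)[4])
    stopf("`n_noise_scans` must be in [0, T)")
  structure(list(magnitude = magnitude, phase = phase,
                 tr_seconds = tr_seconds,
                 n_noise_scans = n_noise_scans),
            class = "fmri_ts")
}

#' @export
print.fmri_ts <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("<fmri_ts> %d x %d x %d voxels, %d volumes (%d noise scans), TR %.3g s, phase: %s\n",
              d[1], d[2], d[3], d[4], x$n_noise_scans, x$tr_seconds,
              if (is.null(x$phase)) "absent" else "present"))
  invisible(x)
}

## Complex-valued view: magnitude * exp(i * phase); magnitude-only data are
## returned as real arrays.
ts_values <- function(ts) {
  if (is.null(ts$phase)) ts$magnitude
  else ts$magnitude * exp(1i * ts$phase)
}

n_data_volumes <- function(ts) dim(ts$magnitude)[4] - ts$n_noise_scans

## Index vectors of data vs appended noise volumes.
data_vol_idx <- function(ts) seq_len(n_data_volumes(ts))
noise_vol_idx <- function(ts) {
  if (ts$n_noise_scans == 0L) integer(0)
  else n_data_volumes(ts) + seq_len(ts$n_noise_scans)
}

#' Drop appended noise volumes
#'
#' Removes the trailing noise scans from a time series; the analysis
#' stream (temporal filtering, GLM) operates on data volumes only.
#'
#' @param ts an [fmri_ts].
#' @return An [fmri_ts] with `n_noise_scans = 0`.
#' @export
strip_noise_scans <- function(ts) {
  if (ts$n_noise_scans == 0L) return(ts)
  keep <- data_vol_idx(ts)
  fmri_ts(ts$magnitude[, , , keep, drop = FALSE],
          if (!is.null(ts$phase)) ts$phase[, , , keep, drop = FALSE],
          ts$tr_seconds, 0L)
}

## Flatten to voxels x time matrix and back.
ts_matrix <- function(x) {
  d <- dim(x)
  matrix(x, nrow = prod(d[1:3]), ncol = d[4])
}
matrix_ts <- function(m, dim3) array(m, dim = c(dim3, ncol(m)))

## Rebuild an fmri_ts from complex (or real) voxel values.
values_ts <- function(vals, template) {
  if (is.complex(vals)) {
    fmri_ts(Mod(vals), Arg(vals), template$tr_seconds, template$n_noise_scans)
  } else {
    fmri_ts(pmax(vals, 0), NULL, template$tr_seconds, template$n_noise_scans)
  }
}
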