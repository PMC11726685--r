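#' Canonical two-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking at
#' `peak` seconds (default 5) and an undershoot peaking near 15 s with
#' amplitude ratio 1:`undershoot_ratio`. The sampled kernel is normalized
#' to sum to one, so GLM betas for a unit-scaled design are in
#' percent-signal-change units when fitted to PSC data.
#'
#' @param dt sampling step in seconds (e.g. the TR).
#' @param peak time of the response maximum, seconds.
#' @param undershoot_peak time of the undershoot minimum, seconds.
#' @param undershoot_ratio response:undershoot amplitude ratio.
#' @param duration kernel support in seconds (default 30).
#' @return Numeric vector sampled at `dt`, summing to one.
#' @export
two_gamma_hrf <- function(dt, peak = 5, undershoot_peak = 15,
                          undershoot_ratio = 6, duration = 30) {
  if (dt <= 0) stopf("dt must be positive")
  t <- seq(0, duration, by = dt)
  ## gamma density with unit scale peaks at shape - 1
  h <- stats::dgamma(t, shape = peak + 1) -
    stats::dgamma(t, shape = undershoot_peak + 1) / undershoot_ratio
  h / sum(h)
}

#' Build the single-trial design matrix
#'
#' One predictor per trial — the TR-sampled two-gamma HRF placed at the
#' trial's onset volume — plus a constant: 37 columns for the standard
#' 36-trial run. With a unit-sum HRF and PSC data the trial betas are
#' directly interpretable as percent signal change.
#'
#' @param design an [event_design()].
#' @param n_volumes number of data volumes T.
#' @param hrf optional HRF kernel at TR sampling (defaults to
#'   [two_gamma_hrf()] at the design's TR).
#' @return list of class `design_matrix`: `X` (T x (K+1)), `hrf_kernel`,
#'   `column_labels`, `condition_of_trial`, `tr_seconds`.
#' @export
build_design <- function(design, n_volumes, hrf = NULL) {
  tr <- attr(design, "tr_seconds")
  if (any(design$onset_volume >= n_volumes))
    stopf("trial onset at volume %d is outside the run (T = %d)",
          max(design$onset_volume), n_volumes)
  k <- hrf %||% two_gamma_hrf(tr)
  K <- nrow(design)
  X <- matrix(0, nrow = n_volumes, ncol = K + 1L)
  for (i in seq_len(K)) {
    idx <- design$onset_volume[i] + seq_along(k)  # 0-based onset
    ok <- idx <= n_volumes
    X[idx[ok], i] <- k[ok]
  }
  X[, K + 1L] <- 1
  labels <- c(if (K > 0) paste0("trial", seq_len(K), "_", design$condition),
              "constant")
  colnames(X) <- labels
  structure(list(X = X, hrf_kernel = k, column_labels = labels,
                 condition_of_trial = design$condition, tr_seconds = tr),
            class = "design_matrix")
}

## Apply a function to the magnitude data of an fmri_ts, or to a T x V
## matrix / vector directly; returns the same kind of object.
apply_temporal <- function(x, fun) {
  if (inherits(x, "fmri_ts")) {
    d <- dim(x$magnitude)
    Y <- fun(t(ts_matrix(x$magnitude)))
    x$magnitude <- array(t(Y), dim = d)
    x
  } else if (is.matrix(x)) {
    fun(x)
  } else {
    drop(fun(matrix(x, ncol = 1)))
  }
}

#' Temporal filtering: high-pass then Gaussian smoothing
#'
#' Removes slow drifts by zeroing Fourier components below
#' `highpass_cycles` cycles per run (the mean is preserved), then smooths
#' with a temporal Gaussian of FWHM `smooth_fwhm_points` samples (kernel
#' renormalized at the run edges). Linear; applied to data volumes only —
#' strip appended noise scans first.
#'
#' @param x an [fmri_ts] (without noise scans), a T x V matrix, or a
#'   vector.
#' @param highpass_cycles cutoff in cycles per run (default 7: cycles 1-6
#'   are removed).
#' @param smooth_fwhm_points Gaussian FWHM in samples (default 2).
#' @return Filtered object of the same kind.
#' @export
temporal_filter <- function(x, highpass_cycles = 7, smooth_fwhm_points = 2) {
  if (inherits(x, "fmri_ts") && x$n_noise_scans > 0L)
    stopf("strip appended noise scans before temporal filtering")
  apply_temporal(x, function(Y) {
    T_ <- nrow(Y)
    if (highpass_cycles > 1) {
      F_ <- stats::mvfft(Y)
      lo <- 2:min(highpass_cycles, T_)          # bins for cycles 1..hc-1
      hi <- T_ + 2L - lo
      hi <- hi[hi > max(lo) & hi <= T_]
      F_[c(lo, hi), ] <- 0
      Y <- Re(stats::mvfft(F_, inverse = TRUE)) / T_
    }
    if (smooth_fwhm_points > 0) {
      sd <- smooth_fwhm_points / (2 * sqrt(2 * log(2)))
      rad <- max(1L, ceiling(4 * sd))
      w <- stats::dnorm(-rad:rad, sd = sd)
      K <- matrix(0, T_, T_)
      for (i in seq_len(T_)) {
        j <- max(1L, i - rad):min(T_, i + rad)
        wk <- w[j - i + rad + 1L]
        K[i, j] <- wk / sum(wk)
      }
      Y <- K %*% Y
    }
    Y
  })
}

#' Percent-signal-change normalization
#'
#' `y'(t) = 100 * (y(t) - mean(y)) / mean(y)` per voxel. Voxels whose
#' temporal mean is (near) zero cannot be normalized; they are set to zero
#' and flagged in the `valid` attribute.
#'
#' @param x an [fmri_ts], T x V matrix, or vector.
#' @param eps threshold on `|mean|` below which a voxel is excluded.
#' @return Same kind of object, zero-mean per voxel, with attribute
#'   `valid` (logical per voxel) on the magnitude/matrix.
#' @export
psc_normalize <- function(x, eps = 1e-8) {
  valid_out <- NULL
  out <- apply_temporal(x, function(Y) {
    mu <- colMeans(Y)
    valid <- abs(mu) > eps
    Yn <- sweep(Y, 2, mu, "-")
    Yn <- sweep(Yn, 2, ifelse(valid, mu, 1), "/") * 100
    Yn[, !valid] <- 0
    valid_out <<- valid
    Yn
  })
  if (inherits(out, "fmri_ts")) attr(out$magnitude, "valid") <- valid_out
  else attr(out, "valid") <- valid_out
  out
}

#' Single-trial GLM
#'
#' Ordinary least squares fit of every voxel's PSC time series on the
#' single-trial design matrix. Betas are in percent-signal units.
#'
#' @param y an [fmri_ts] (PSC-normalized magnitude) or T x V matrix.
#' @param design a [build_design()] result.
#' @return list of class `beta_maps`: `betas` (voxel x trial),
#'   `intercept`, `condition_of_trial`, `dim3` (spatial dims when the
#'   input was an [fmri_ts], else NULL).
#' @export
fit_glm <- function(y, design) {
  X <- design$X
  dim3 <- NULL
  if (inherits(y, "fmri_ts")) {
    if (y$n_noise_scans > 0L) stopf("strip noise scans before the GLM")
    dim3 <- dim(y$magnitude)[1:3]
    Y <- t(ts_matrix(y$magnitude))
  } else Y <- y
  if (nrow(Y) != nrow(X)) stopf("time dimension mismatch")
  if (nrow(X) <= ncol(X)) stopf("more design columns than volumes")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, Y)                      # (K+1) x V
  K <- ncol(X) - 1L
  structure(list(betas = t(coefs[seq_len(K), , drop = FALSE]),
                 intercept = as.numeric(coefs[K + 1L, ]),
                 condition_of_trial = design$condition_of_trial,
                 dim3 = dim3),
            class = "beta_maps")
}

#' Across-trial t-statistics
#'
#' One-sample t over single-trial betas: `t = mean / (sd / sqrt(n))` with
#' `dof = n - 1`, using the variability across trials rather than the GLM
#' residuals. Voxels with zero across-trial variance are undefined (NA).
#'
#' @param betas a [fit_glm()] result.
#' @param contrast `"all_sounds"` (every trial) or a condition id.
#' @return list of class `t_map`: `t` (voxel vector, NA where undefined),
#'   `dof`, `contrast`, `dim3`.
#' @export
trial_t <- function(betas, contrast = "all_sounds") {
  sel <- if (identical(contrast, "all_sounds"))
    rep(TRUE, length(betas$condition_of_trial))
  else betas$condition_of_trial == contrast
  if (sum(sel) < 2) stopf("contrast '%s' has fewer than 2 trials", contrast)
  B <- betas$betas[, sel, drop = FALSE]
  n <- ncol(B)
  m <- rowMeans(B)
  s <- sqrt(rowSums((B - m)^2) / (n - 1))
  t <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  structure(list(t = t, dof = n - 1L, contrast = contrast,
                 dim3 = betas$dim3),
            class = "t_map")
}

#' Temporal signal-to-noise ratio
#'
#' Voxelwise mean divided by standard deviation of the magnitude time
#' series (appended noise scans excluded). Zero-variance voxels are NA.
#'
#' @param ts an [fmri_ts] or T x V matrix.
#' @return Numeric vector (or 3D array for [fmri_ts] input) of tSNR
#'   values.
#' @export
tsnr <- function(ts) {
  if (inherits(ts, "fmri_ts")) {
    Y <- t(ts_matrix(ts$magnitude[, , , data_vol_idx(ts), drop = FALSE]))
    d3 <- dim(ts$magnitude)[1:3]
  } else {
    Y <- ts
    d3 <- NULL
  }
  if (nrow(Y) < 2) stopf("need at least 2 volumes")
  m <- colMeans(Y)
  s <- apply(Y, 2, stats::sd)
  v <- ifelse(s > 0, m / s, NA_real_)
  if (!is.null(d3)) array(v, dim = d3) else v
}

#' FDR-thresholded activation mask
#'
#' Two-sided p-values from the t distribution, Benjamini-Hochberg step-up
#' control of the false discovery rate at level `q` (default 0.01).
#'
#' @param tmap a [trial_t()] result.
#' @param q FDR level.
#' @return list: `mask` (logical per voxel, FALSE where t undefined),
#'   `p_threshold` (largest raw p rejected, NA when none), `q`, `n_sig`.
#' @export
fdr_mask <- function(tmap, q = 0.01) {
  ok <- is.finite(tmap$t)
  if (!any(ok)) stopf("no defined t-values")
  p <- rep(NA_real_, length(tmap$t))
  p[ok] <- 2 * stats::pt(-abs(tmap$t[ok]), df = tmap$dof)
  adj <- rep(NA_real_, length(p))
  adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  mask <- !is.na(adj) & adj <= q
  list(mask = mask,
       p_threshold = if (any(mask)) max(p[mask]) else NA_real_,
       q = q, n_sig = sum(mask))
}
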