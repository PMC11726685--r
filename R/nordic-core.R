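#' Patch geometry for locally low-rank denoising
#'
#' The PCA kernel is a cube whose side is chosen so that the number of
#' voxels per patch is about `ratio` times the number of timepoints
#' (default 11:1), clipped to the volume dimensions. The stride defaults to
#' half the kernel so neighbouring patches overlap; boundary patches are
#' shifted inward so every voxel is covered.
#'
#' @param grid_shape integer 3-vector of volume dimensions.
#' @param n_time number of timepoints entering the Casorati matrix.
#' @param ratio target voxels-per-patch / timepoints (default 11).
#' @param kernel optional explicit kernel side lengths (3-vector).
#' @param stride optional explicit strides (3-vector).
#' @return list of class `patch_spec`: `kernel`, `stride`, `starts` (list of
#'   start indices per axis).
#' @export
patch_spec <- function(grid_shape, n_time, ratio = 11,
                       kernel = NULL, stride = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(kernel)) {
    side <- max(1L, round((ratio * n_time)^(1 / 3)))
    kernel <- pmin(rep(side, 3L), grid_shape)
  } else {
    kernel <- as.integer(rep(kernel, length.out = 3L))
  }
  if (any(kernel < 1L) || any(kernel > grid_shape))
    stopf("patch kernel %s exceeds volume dimensions %s",
          paste(kernel, collapse = "x"), paste(grid_shape, collapse = "x"))
  if (is.null(stride)) stride <- pmax(1L, kernel %/% 2L)
  stride <- as.integer(rep(stride, length.out = 3L))
  starts <- lapply(1:3, function(a) {
    last <- grid_shape[a] - kernel[a] + 1L
    unique(c(seq.int(1L, last, by = stride[a]), last))
  })
  structure(list(kernel = kernel, stride = stride, starts = starts,
                 ratio = ratio),
            class = "patch_spec")
}

#' Estimate the g-factor map
#'
#' Spatial map of thermal-noise amplification, normalized to minimum 1.
#' With appended noise scans present the map is proportional to the
#' voxelwise std of the noise-scan values (real and imaginary channels
#' pooled for complex data), spatially smoothed; without noise scans it is
#' estimated from high-frequency temporal residuals (first differences) of
#' the series. The pre-normalization noise level at g = 1 is returned as
#' attribute `sigma0` (per-channel std).
#'
#' @param ts an [fmri_ts] with at least 30 volumes or at least 5 noise
#'   scans.
#' @param smooth_sigma Gaussian smoothing sd in voxels.
#' @return 3D array >= 1 with attributes `sigma0` and `source`.
#' @export
estimate_gfactor_map <- function(ts, smooth_sigma = 1.5) {
  if (all(ts$magnitude == 0)) stopf("all-zero input")
  d <- dim(ts$magnitude)[1:3]
  if (ts$n_noise_scans >= 2L) {
    vals <- ts_values(ts)
    nz <- matrix(vals[, , , noise_vol_idx(ts), drop = FALSE], nrow = prod(d))
    if (is.complex(nz)) {
      ## pooled std of the two channels, per voxel
      s <- sqrt((apply(Re(nz), 1, stats::var) +
                 apply(Im(nz), 1, stats::var)) / 2)
    } else {
      s <- apply(nz, 1, stats::sd)
    }
    src <- "noise_scan"
  } else {
    if (n_data_volumes(ts) < 30L)
      stopf("need >= 30 volumes or >= 2 noise scans to estimate the g-factor")
    vals <- ts_values(ts)
    y <- matrix(vals[, , , data_vol_idx(ts), drop = FALSE], nrow = prod(d))
    dy <- y[, -1, drop = FALSE] - y[, -ncol(y), drop = FALSE]
    if (is.complex(dy)) {
      s <- sqrt((apply(Re(dy), 1, stats::var) +
                 apply(Im(dy), 1, stats::var)) / 4)
    } else {
      s <- apply(dy, 1, stats::sd) / sqrt(2)
    }
    src <- "temporal_residual"
  }
  sm <- smooth3d(array(s, dim = d), smooth_sigma)
  sigma0 <- min(sm)
  if (max(sm) == 0) {
    ## noiseless data: no amplification structure to estimate
    g <- array(1, dim = d)
    sigma0 <- 0
  } else if (sigma0 <= 0) {
    stopf("degenerate noise level estimate")
  } else {
    g <- sm / sigma0
  }
  attr(g, "sigma0") <- sigma0
  attr(g, "source") <- src
  g
}

#' Divide a time series by a g-factor map
#'
#' After division the thermal noise is uniformly distributed across space,
#' the i.i.d. assumption of the patch PCA. Exact inverse of itself with
#' `inverse = TRUE`.
#'
#' @param ts an [fmri_ts].
#' @param g positive 3D array matching the spatial dimensions.
#' @param inverse multiply instead of divide.
#' @return An [fmri_ts].
#' @export
normalize_by_gfactor <- function(ts, g, inverse = FALSE) {
  if (!identical(as.integer(dim(g)), as.integer(dim(ts$magnitude)[1:3])))
    stopf("g-factor map shape mismatch")
  if (any(g <= 0)) stopf("g-factor map must be positive")
  f <- if (inverse) as.numeric(g) else 1 / as.numeric(g)
  ts$magnitude <- ts$magnitude * f   # recycled over the 4th dimension
  ts
}

.mc_cache <- new.env(parent = emptyenv())

#' Monte-Carlo singular-value threshold
#'
#' Mean (over `n_mc` draws) of the largest singular value of an m x n
#' matrix with i.i.d. N(0, sigma^2) entries — the noise bulk edge used as
#' the hard threshold on the Casorati eigenspectrum. Computed at unit
#' sigma and scaled, so `mc_sv_threshold(m, n, 2 * s) ==
#' 2 * mc_sv_threshold(m, n, s)` exactly; results are cached per
#' (m, n, n_mc, seed).
#'
#' @param m,n matrix dimensions (>= 2).
#' @param sigma noise std per entry (>= 0).
#' @param n_mc number of Monte-Carlo draws.
#' @param seed RNG seed for the draws.
#' @return Positive scalar (0 when `sigma = 0`).
#' @export
mc_sv_threshold <- function(m, n, sigma, n_mc = 20L, seed = 1L) {
  if (m < 2 || n < 2) stopf("m and n must be >= 2")
  if (n_mc < 1) stopf("n_mc must be >= 1")
  if (sigma < 0) stopf("sigma must be non-negative")
  if (sigma == 0) return(0)
  key <- paste(m, n, n_mc, seed, sep = "_")
  unit <- .mc_cache[[key]]
  if (is.null(unit)) {
    top_sv <- function(x) {
      if (nrow(x) >= 2 * ncol(x)) {
        sqrt(max(eigen(crossprod(x), symmetric = TRUE,
                       only.values = TRUE)$values))
      } else {
        La.svd(x, nu = 0, nv = 0)$d[1]
      }
    }
    unit <- with_seed(seed, {
      mean(vapply(seq_len(n_mc), function(i) {
        top_sv(matrix(stats::rnorm(m * n), m, n))
      }, numeric(1)))
    })
    .mc_cache[[key]] <- unit
  }
  sigma * unit
}

#' Hard-threshold the singular values of a Casorati matrix
#'
#' SVD of the patch matrix (rows = voxels, columns = timepoints); singular
#' values at or below `sv_cutoff` are zeroed — those components are
#' indistinguishable from zero-mean Gaussian noise — and the matrix is
#' rebuilt from the survivors.
#'
#' @param casorati real or complex M x N matrix.
#' @param sv_cutoff non-negative threshold; 0 keeps everything.
#' @return list `mat` (denoised matrix) and `kept_rank`.
#' @export
denoise_patch <- function(casorati, sv_cutoff) {
  if (!all(is.finite(Re(casorati))))
    stopf("non-finite entries in Casorati matrix")
  if (sv_cutoff < 0) stopf("sv_cutoff must be non-negative")
  if (sv_cutoff == 0)
    return(list(mat = casorati, kept_rank = min(dim(casorati))))
  m <- nrow(casorati)
  n <- ncol(casorati)
  if (m >= 2 * n) {
    ## tall matrix: eigendecomposition of the n x n Gram matrix gives the
    ## same singular values/right vectors at a fraction of the SVD cost
    G <- crossprod(Conj(casorati), casorati)
    e <- eigen(G, symmetric = TRUE)
    d <- sqrt(pmax(Re(e$values), 0))
    k <- sum(d > sv_cutoff)
    if (k == 0) {
      out <- matrix(if (is.complex(casorati)) 0 + 0i else 0, m, n)
    } else {
      Vk <- e$vectors[, seq_len(k), drop = FALSE]
      out <- (casorati %*% Vk) %*% Conj(t(Vk))
    }
    return(list(mat = out, kept_rank = k))
  }
  s <- La.svd(casorati)
  keep <- s$d > sv_cutoff
  k <- sum(keep)
  if (k == 0) {
    out <- matrix(if (is.complex(casorati)) 0 + 0i else 0,
                  nrow(casorati), ncol(casorati))
  } else {
    ki <- seq_len(k)
    out <- s$u[, ki, drop = FALSE] %*% (s$d[ki] * s$vt[ki, , drop = FALSE])
  }
  list(mat = out, kept_rank = k)
}

## Noise level per Casorati entry after g-normalization. For complex data
## this is the per-complex-entry std sqrt(var(Re) + var(Im)), which makes
## the real-entry Monte-Carlo bulk edge match the complex one.
estimate_sigma_entry <- function(values) {
  if (is.complex(values)) {
    sqrt(stats::var(as.numeric(Re(values))) +
         stats::var(as.numeric(Im(values))))
  } else {
    stats::sd(as.numeric(values))
  }
}

#' Locally low-rank denoising of a 4D fMRI time series
#'
#' The full patch-PCA pipeline: optional removal of a low-resolution
#' volume-wise phase estimate ([phase_stabilize()]), g-factor
#' normalization, sliding cubic patches whose Casorati matrices
#' (voxels x timepoints, appended noise scans included) are
#' hard-thresholded at the Monte-Carlo noise bulk edge, overlap-averaged
#' recombination, and re-application of the g-factor.
#'
#' Two threshold modes mirror the two processing strategies commonly used:
#' \describe{
#'   \item{`noise_scan`}{the noise level is estimated empirically from the
#'     appended no-excitation volumes (the default, more aggressive
#'     strategy);}
#'   \item{`gfactor_only`}{no noise scan is used; the level is taken from
#'     high-frequency temporal residuals and the cutoff is scaled by the
#'     constant `1/sqrt(2)`, a deliberately conservative threshold that
#'     compensates for g-factor underestimation.}
#' }
#'
#' With magnitude-only input the Casorati matrices are real; note the
#' magnitude noise distribution is then Rician rather than Gaussian, so
#' thresholds calibrated for Gaussian entries are approximate.
#'
#' @param ts an [fmri_ts]; must contain noise scans when
#'   `mode = "noise_scan"`.
#' @param patch a [patch_spec()]; defaults to the 11:1 cubic kernel.
#' @param mode `"noise_scan"` or `"gfactor_only"`.
#' @param seed seed for the Monte-Carlo threshold.
#' @param n_mc Monte-Carlo draws for the threshold.
#' @param nn_scale cutoff scale applied in `gfactor_only` mode
#'   (default `1/sqrt(2)`).
#' @param sv_cutoff optional explicit cutoff overriding the estimate
#'   (0 gives the exact identity path).
#' @param phase_stabilization apply [phase_stabilize()] first (default:
#'   whenever phase is present).
#' @param g optional precomputed g-factor map.
#' @return list `ts` (denoised [fmri_ts], noise scans still appended) and
#'   `report` (class `denoise_report`: patch count, kept/removed component
#'   summaries, `sigma_hat`, `sv_cutoff`, mode, seed).
#' @export
nordic_denoise <- function(ts, patch = NULL,
                           mode = c("noise_scan", "gfactor_only"),
                           seed = 1L, n_mc = 20L, nn_scale = 1 / sqrt(2),
                           sv_cutoff = NULL,
                           phase_stabilization = !is.null(ts$phase),
                           g = NULL) {
  mode <- match.arg(mode)
  if (mode == "noise_scan" && ts$n_noise_scans == 0L)
    stopf("mode = 'noise_scan' requires appended noise scans")
  if (phase_stabilization) {
    if (is.null(ts$phase)) stopf("phase stabilization requires phase data")
    ts <- phase_stabilize(ts)
  }
  d <- dim(ts$magnitude)[1:3]
  ntot <- dim(ts$magnitude)[4]
  if (is.null(g)) g <- estimate_gfactor_map(ts)
  tsn <- normalize_by_gfactor(ts, g)
  vals <- ts_values(tsn)
  Y <- matrix(vals, nrow = prod(d))                    # voxels x time
  if (is.null(patch)) patch <- patch_spec(d, ntot)
  m <- prod(patch$kernel)
  ## noise level in g-normalized units
  if (mode == "noise_scan") {
    nzi <- noise_vol_idx(ts)
    sigma_hat <- estimate_sigma_entry(
      matrix(vals[, , , nzi, drop = FALSE], nrow = prod(d)))
  } else {
    dy <- Y[, -1, drop = FALSE] - Y[, -ncol(Y), drop = FALSE]
    sigma_hat <- estimate_sigma_entry(dy) / sqrt(2)
  }
  if (is.null(sv_cutoff)) {
    sv_cutoff <- mc_sv_threshold(m, ntot, sigma_hat, n_mc, seed) *
      (if (mode == "gfactor_only") nn_scale else 1)
  }
  acc <- matrix(if (is.complex(Y)) 0 + 0i else 0, prod(d), ntot)
  cnt <- numeric(prod(d))
  lin <- array(seq_len(prod(d)), dim = d)
  kept <- integer(0)
  for (x0 in patch$starts[[1]]) for (y0 in patch$starts[[2]])
    for (z0 in patch$starts[[3]]) {
      vox <- as.integer(lin[x0 + seq_len(patch$kernel[1]) - 1L,
                            y0 + seq_len(patch$kernel[2]) - 1L,
                            z0 + seq_len(patch$kernel[3]) - 1L])
      dn <- denoise_patch(Y[vox, , drop = FALSE], sv_cutoff)
      acc[vox, ] <- acc[vox, ] + dn$mat
      cnt[vox] <- cnt[vox] + 1
      kept <- c(kept, dn$kept_rank)
    }
  if (any(cnt == 0)) stopf("internal error: uncovered voxels")
  out_vals <- array(acc / cnt, dim = c(d, ntot))
  out <- values_ts(out_vals, tsn)
  out <- normalize_by_gfactor(out, g, inverse = TRUE)
  minmn <- min(m, ntot)
  report <- structure(list(n_patches = length(kept),
                           kept_rank = kept,
                           mean_components_kept = mean(kept),
                           mean_components_removed = mean(minmn - kept),
                           min_mn = minmn,
                           sigma_hat = sigma_hat,
                           sv_cutoff = sv_cutoff,
                           mode = mode, seed = seed, n_mc = n_mc,
                           kernel = patch$kernel),
                      class = "denoise_report")
  list(ts = out, report = report)
}

#' @export
print.denoise_report <- function(x, ...) {
  cat(sprintf(paste0("<denoise_report> mode=%s, %d patches (kernel %s), ",
                     "sigma_hat=%.4g, sv_cutoff=%.4g,\n  components kept ",
                     "%.1f / removed %.1f of %d on average\n"),
              x$mode, x$n_patches, paste(x$kernel, collapse = "x"),
              x$sigma_hat, x$sv_cutoff, x$mean_components_kept,
              x$mean_components_removed, x$min_mn))
  invisible(x)
}

#' Remove a low-resolution volume-wise phase estimate
#'
#' For each volume, a low-spatial-frequency phase estimate is obtained by
#' windowing the volume's spatial frequency spectrum with a cosine-tapered
#' (Tukey) low-pass of width `1/tukey_scale` of the spectrum, and the
#' complex data are rotated by the conjugate of that estimate's unit
#' phase. Magnitude is untouched; only the phase is recentred, which makes
#' the signal component of the complex data approximately real before the
#' patch PCA.
#'
#' @param ts an [fmri_ts] with phase present.
#' @param tukey_scale scale factor: the retained low-frequency band spans
#'   `1/tukey_scale` of the spectrum (default 10).
#' @return An [fmri_ts] with stabilized phase.
#' @export
phase_stabilize <- function(ts, tukey_scale = 10) {
  if (is.null(ts$phase)) stopf("phase data required")
  if (tukey_scale <= 0) stopf("tukey_scale must be positive")
  d <- dim(ts$magnitude)[1:3]
  w1 <- lapply(d, function(n) tukey_lowpass(n, 1 / tukey_scale))
  W <- outer(outer(w1[[1]], w1[[2]]), w1[[3]])
  dim(W) <- d
  vals <- ts_values(ts)
  for (t in seq_len(dim(vals)[4])) {
    C <- vals[, , , t]
    L <- stats::fft(stats::fft(C) * W, inverse = TRUE) / length(C)
    u <- L / Mod(L)
    u[!is.finite(u)] <- 1
    vals[, , , t] <- C * Conj(u)
  }
  fmri_ts(ts$magnitude, Arg(vals), ts$tr_seconds, ts$n_noise_scans)
}

## 1D cosine-tapered low-pass window over FFT bin frequencies.
## cutoff is the normalized frequency (0..0.5] below which energy is kept;
## passband |f| <= cutoff/2, taper to zero at |f| = cutoff.
tukey_lowpass <- function(n, cutoff) {
  f <- abs(((seq_len(n) - 1 + n %/% 2) %% n) - n %/% 2) / n
  w <- numeric(n)
  w[f <= cutoff / 2] <- 1
  tap <- f > cutoff / 2 & f <= cutoff
  w[tap] <- 0.5 * (1 + cos(pi * (f[tap] - cutoff / 2) / (cutoff / 2)))
  w
}
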