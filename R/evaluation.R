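#' Spatial correlation of two maps
#'
#' Pearson correlation over the voxels of a mask — the similarity metric
#' used for map-to-map, run-to-run and split-half comparisons.
#'
#' @param map_a,map_b numeric vectors/arrays of equal length.
#' @param mask logical (or 0/1) selector; default all voxels.
#' @return Correlation coefficient; NA when either map has zero variance.
#' @export
spatial_correlation <- function(map_a, map_b, mask = NULL) {
  a <- as.numeric(map_a)
  b <- as.numeric(map_b)
  if (length(a) != length(b)) stopf("map lengths differ")
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    a <- a[keep]
    b <- b[keep]
  }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stopf("fewer than 3 voxels in mask")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

## r clipped away from +-1 so atanh stays finite on identical maps.
clip_r <- function(r, eps = 1e-12) pmin(1 - eps, pmax(-(1 - eps), r))

#' Fisher z-transform
#'
#' `z = atanh(r)`; use [fisher_z_inv()] to map back. Correlations from
#' identical maps should be clipped to `1 - 1e-12` before transforming
#' (done internally by the reliability functions).
#'
#' @param r correlation(s), `|r| < 1`.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stopf("|r| must be < 1 for the Fisher z-transform")
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z value(s).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Repeated split-half reliability
#'
#' For each of `n_repetitions` random splits, the runs are partitioned
#' into two halves (sizes differing by at most one), the per-run maps are
#' averaged within each half, and the two half-maps are correlated within
#' the mask. The per-split correlations are aggregated by a Fisher-z mean.
#'
#' @param run_maps voxel x run matrix (one map per run), or a list of
#'   equal-length vectors.
#' @param n_repetitions number of random splits (default 50).
#' @param seed RNG seed for the split sequence.
#' @param mask optional logical voxel selector.
#' @return list of class `reliability_result`: `r` (per split), `z_mean`,
#'   `r_mean` (= tanh of `z_mean`), `splits` (list of half-one run ids).
#' @export
split_half_reliability <- function(run_maps, n_repetitions = 50L, seed = 1L,
                                   mask = NULL) {
  if (is.list(run_maps)) run_maps <- do.call(cbind, run_maps)
  R <- ncol(run_maps)
  if (R < 2) stopf("split-half reliability needs at least 2 runs")
  with_seed(seed, {
    halves <- lapply(seq_len(n_repetitions),
                     function(i) sample(R, R %/% 2))
    r <- vapply(halves, function(h) {
      spatial_correlation(rowMeans(run_maps[, h, drop = FALSE]),
                          rowMeans(run_maps[, -h, drop = FALSE]), mask)
    }, numeric(1))
    z <- mean(fisher_z(clip_r(r)))
    structure(list(r = r, z_mean = z, r_mean = fisher_z_inv(z),
                   splits = halves),
              class = "reliability_result")
  })
}

#' Leave-one-run-out correlation
#'
#' For each fold, the reference map is the average over all-but-one runs
#' of the *original* (undenoised) data, and the left-out run of the
#' strategy under evaluation is correlated against it — so every strategy
#' is scored against the same reference.
#'
#' @param original_runs voxel x run matrix of reference (original) maps.
#' @param strategy_runs voxel x run matrix of the evaluated strategy
#'   (can be the same matrix for the original strategy itself).
#' @param mask optional logical voxel selector.
#' @return Numeric vector, one correlation per left-out run.
#' @export
loro_correlation <- function(original_runs, strategy_runs, mask = NULL) {
  if (is.list(original_runs)) original_runs <- do.call(cbind, original_runs)
  if (is.list(strategy_runs)) strategy_runs <- do.call(cbind, strategy_runs)
  R <- ncol(original_runs)
  if (R < 3) stopf("leave-one-run-out needs at least 3 runs")
  if (!identical(dim(original_runs), dim(strategy_runs)))
    stopf("run map dimensions differ between strategies")
  vapply(seq_len(R), function(k) {
    ref <- rowMeans(original_runs[, -k, drop = FALSE])
    spatial_correlation(strategy_runs[, k], ref, mask)
  }, numeric(1))
}

#' Exhaustive sign-flip permutation test
#'
#' Exact paired test: all `2^n` sign assignments of the per-subject
#' differences are enumerated and the two-sided p-value is the proportion
#' of assignments whose `|mean|` is at least the observed `|mean|`. The
#' p-value resolution is exactly `1 / 2^n`.
#'
#' @param paired_diffs per-subject paired differences (n <= 20).
#' @return p-value in (0, 1].
#' @export
sign_flip_permutation_test <- function(paired_diffs) {
  d <- as.numeric(paired_diffs)
  n <- length(d)
  if (n == 0) stopf("no differences supplied")
  if (n > 20) stopf("exhaustive enumeration limited to n <= 20")
  ints <- 0:(2^n - 1)
  signs <- vapply(seq_len(n), function(b)
    2 * (bitwAnd(ints, bitwShiftL(1L, b - 1L)) > 0) - 1, numeric(2^n))
  perm_means <- abs(as.numeric(signs %*% d)) / n
  obs <- abs(mean(d))
  mean(perm_means >= obs - 1e-12)
}

#' Bonferroni correction
#'
#' @param p_values raw p-value(s).
#' @param m number of comparisons.
#' @return Adjusted p-values `min(1, p * m)`.
#' @export
bonferroni <- function(p_values, m) {
  if (m < 1) stopf("m must be >= 1")
  pmin(1, p_values * m)
}

## Orthonormalized Helmert contrasts for a p-level within factor.
orthonormal_contrasts <- function(p) {
  M <- stats::contr.helmert(p)
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

## Univariate repeated-measures F for one within-subject effect given the
## n x cells data matrix and an orthonormal cell-contrast matrix.
rm_effect <- function(Y, M, effect) {
  Z <- Y %*% M                                  # n x q contrast scores
  n <- nrow(Z)
  q <- ncol(Z)
  zbar <- colMeans(Z)
  ss_eff <- n * sum(zbar^2)
  ss_err <- sum(sweep(Z, 2, zbar)^2)
  df1 <- q
  df2 <- q * (n - 1)
  F_ <- (ss_eff / df1) / (ss_err / df2)
  S <- stats::cov(Z)
  eps <- if (q == 1) 1 else sum(diag(S))^2 / (q * sum(S * S))
  eps <- min(1, max(eps, 1 / q))
  data.frame(effect = effect, df1 = df1, df2 = df2, F = F_,
             p = stats::pf(F_, df1, df2, lower.tail = FALSE),
             epsilon = eps,
             p_gg = stats::pf(F_, df1 * eps, df2 * eps, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA. With a subjects x levels matrix, tests the
#' single within factor (e.g. processing strategy); with a subjects x A x B
#' array, tests both main effects and their interaction. Each effect's F
#' uses its own subject-by-effect error term; the Greenhouse-Geisser
#' epsilon is computed from the sample covariance of the orthonormalized
#' within-subject contrast scores and the corrected p-value uses
#' epsilon-scaled degrees of freedom. For a two-level factor epsilon is 1
#' and F equals the squared paired t-statistic.
#'
#' @param values subjects x levels matrix or subjects x A x B array;
#'   no missing cells.
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`,
#'   `F`, `p`, `epsilon`, `p_gg`.
#' @export
rm_anova <- function(values) {
  if (any(!is.finite(values))) stopf("missing or non-finite cells")
  dims <- dim(values)
  if (is.matrix(values)) {
    if (dims[2] < 2) stopf("need at least 2 factor levels")
    rm_effect(values, orthonormal_contrasts(dims[2]), "factor")
  } else if (length(dims) == 3) {
    a <- dims[2]; b <- dims[3]
    if (a < 2 || b < 2) stopf("need at least 2 levels per factor")
    Y <- matrix(values, nrow = dims[1])          # cells vary A fastest
    Ca <- orthonormal_contrasts(a)
    Cb <- orthonormal_contrasts(b)
    ones_a <- matrix(1 / sqrt(a), a, 1)
    ones_b <- matrix(1 / sqrt(b), b, 1)
    rbind(rm_effect(Y, kronecker(ones_b, Ca), "A"),
          rm_effect(Y, kronecker(Cb, ones_a), "B"),
          rm_effect(Y, kronecker(Cb, Ca), "A:B"))
  } else stopf("`values` must be a matrix or a 3D array")
}

#' Mean beta change per tSNR bin
#'
#' Bins voxels by tSNR (equal-count bins by default) and returns the mean
#' beta difference per bin — the summary showing that denoising-induced
#' beta changes concentrate in low-tSNR voxels.
#'
#' @param beta_diff per-voxel beta difference (original - denoised).
#' @param tsnr per-voxel tSNR values.
#' @param n_bins number of bins.
#' @param type `"equal_count"` (quantile bins) or `"equal_width"`.
#' @return data.frame: `bin`, `tsnr_mean`, `mean_diff` (NA for empty
#'   bins), `n`.
#' @export
beta_tsnr_bins <- function(beta_diff, tsnr, n_bins = 10L,
                           type = c("equal_count", "equal_width")) {
  type <- match.arg(type)
  beta_diff <- as.numeric(beta_diff)
  tsnr <- as.numeric(tsnr)
  ok <- is.finite(beta_diff) & is.finite(tsnr)
  beta_diff <- beta_diff[ok]
  tsnr <- tsnr[ok]
  breaks <- if (type == "equal_count") {
    unique(stats::quantile(tsnr, probs = seq(0, 1, length.out = n_bins + 1)))
  } else {
    seq(min(tsnr), max(tsnr), length.out = n_bins + 1)
  }
  bin <- cut(tsnr, breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(bin = seq_len(n_bins))
  out$tsnr_mean <- vapply(out$bin, function(b) {
    if (any(bin == b)) mean(tsnr[bin == b]) else NA_real_
  }, numeric(1))
  out$mean_diff <- vapply(out$bin, function(b) {
    if (any(bin == b)) mean(beta_diff[bin == b]) else NA_real_
  }, numeric(1))
  out$n <- vapply(out$bin, function(b) sum(bin == b), integer(1))
  out
}
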