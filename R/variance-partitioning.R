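#' Orthogonalize the original series against the denoised series
#'
#' OLS fit `y_ori = alpha * y_an + b + e`, equivalent to Gram-Schmidt
#' orthogonalization: the residual is the portion of the original time
#' series orthogonal to the denoised one (and to the constant) — the part
#' removed by denoising, up to scaling.
#'
#' @param y_ori original time series.
#' @param y_an time series after denoising (must not be constant).
#' @return list: `alpha`, `intercept`, `residual`.
#' @export
orthogonalize <- function(y_ori, y_an) {
  if (length(y_ori) != length(y_an)) stopf("series lengths differ")
  if (length(y_ori) < 3) stopf("need at least 3 timepoints")
  ca <- y_an - mean(y_an)
  den <- sum(ca^2)
  if (den <= 1e-24 * length(y_an)) stopf("denoised series is constant")
  alpha <- sum((y_ori - mean(y_ori)) * ca) / den
  intercept <- mean(y_ori) - alpha * mean(y_an)
  residual <- y_ori - alpha * y_an - intercept
  list(alpha = alpha, intercept = intercept, residual = residual)
}

#' Sum-of-squares decomposition of the original series
#'
#' With `alpha` and the residual from [orthogonalize()], the total sum of
#' squares of the original series about its mean splits exactly into the
#' alpha-scaled sum of squares of the denoised series and the residual sum
#' of squares: `SS(y_ori) = alpha^2 SS(y_an) + SS(e)`.
#'
#' @param y_ori original series.
#' @param alpha scaling from [orthogonalize()].
#' @param y_an denoised series.
#' @param residual residual from [orthogonalize()].
#' @return list: `ss_total_ori`, `ss_an_scaled`, `ss_resid`.
#' @export
ss_decompose <- function(y_ori, alpha, y_an, residual) {
  ss <- function(x) sum((x - mean(x))^2)
  list(ss_total_ori = ss(y_ori),
       ss_an_scaled = alpha^2 * ss(y_an),
       ss_resid = ss(residual))
}

#' Design-explained sum of squares
#'
#' OLS fit of a series on the single-trial design matrix;
#' `ss_design` is the sum of squares of the fitted values about their
#' mean, `ss_error` the residual sum of squares, and (with the constant in
#' X) they add up to the series' total sum of squares about its mean.
#'
#' @param y time series (vector) or T x V matrix.
#' @param design a [build_design()] result (full rank).
#' @return For a vector: list `ss_design`, `ss_error`. For a matrix: a
#'   data.frame with one row per column of `y`.
#' @export
design_explained_ss <- function(y, design) {
  X <- design$X
  qx <- qr(X)
  if (qx$rank < ncol(X)) stopf("design matrix is rank deficient")
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  if (nrow(Y) != nrow(X)) stopf("series length does not match design")
  fit <- qr.fitted(qx, Y)
  ssd <- colSums(sweep(fit, 2, colMeans(fit))^2)
  sse <- colSums((Y - fit)^2)
  if (is.matrix(y)) data.frame(ss_design = ssd, ss_error = sse)
  else list(ss_design = ssd[[1]], ss_error = sse[[1]])
}

#' Per-voxel variance partition of original vs denoised data
#'
#' For every voxel: orthogonalize the original series against the denoised
#' one, decompose the total sum of squares into retained
#' (`alpha^2 SS(y_an)`) and removed (`SS(e)`) parts, and quantify the
#' design-related variance in the original series, the denoised series and
#' the removed residual by regressing each against the design matrix.
#' `ss_design_resid / ss_total_ori` is the fraction of the original
#' variance that is design-related yet absent from the denoised data —
#' signal removed by denoising.
#'
#' Voxels whose denoised series is (near-)constant are excluded; their
#' count is reported in attribute `n_excluded`.
#'
#' @param Y_ori,Y_an T x V matrices (same preprocessing, e.g. PSC).
#' @param design a [build_design()] result.
#' @return data.frame of class `variance_partition`, one row per retained
#'   voxel: `voxel`, `alpha`, `intercept`, `ss_total_ori`, `ss_an_scaled`,
#'   `ss_resid`, `ss_design_ori`, `ss_design_an`, `ss_design_resid`, plus
#'   ratio columns `frac_design_ori`, `frac_design_an`,
#'   `frac_removed_design`.
#' @export
partition_voxels <- function(Y_ori, Y_an, design) {
  if (!identical(dim(Y_ori), dim(Y_an))) stopf("matrix shapes differ")
  T_ <- nrow(Y_ori)
  co <- sweep(Y_ori, 2, colMeans(Y_ori))
  ca <- sweep(Y_an, 2, colMeans(Y_an))
  den <- colSums(ca^2)
  keep <- den > 1e-24 * T_
  alpha <- numeric(ncol(Y_ori))
  alpha[keep] <- colSums(co[, keep, drop = FALSE] *
                           ca[, keep, drop = FALSE]) / den[keep]
  intercept <- colMeans(Y_ori) - alpha * colMeans(Y_an)
  resid <- co - sweep(ca, 2, alpha, "*")
  ss_total <- colSums(co^2)
  ss_an_scaled <- alpha^2 * den
  ss_resid <- colSums(resid^2)
  d_ori <- design_explained_ss(Y_ori, design)
  d_an <- design_explained_ss(Y_an, design)
  d_res <- design_explained_ss(resid, design)
  out <- data.frame(voxel = which(keep),
                    alpha = alpha[keep],
                    intercept = intercept[keep],
                    ss_total_ori = ss_total[keep],
                    ss_an_scaled = ss_an_scaled[keep],
                    ss_resid = ss_resid[keep],
                    ss_design_ori = d_ori$ss_design[keep],
                    ss_design_an = d_an$ss_design[keep],
                    ss_design_resid = d_res$ss_design[keep])
  out$frac_design_ori <- out$ss_design_ori / out$ss_total_ori
  out$frac_design_an <- d_an$ss_design[keep] / den[keep]
  out$frac_removed_design <- out$ss_design_resid / out$ss_total_ori
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- c("variance_partition", "data.frame")
  out
}

#' Fraction of design-related variance removed by denoising
#'
#' `ss_design_resid / ss_total_ori`: the design-explained sum of squares of
#' the removed residual relative to the total original sum of squares.
#'
#' @param partition one row (or the whole data.frame) from
#'   [partition_voxels()], or any list with `ss_design_resid` and
#'   `ss_total_ori`.
#' @return Numeric fraction(s); NA where the total SS is zero.
#' @export
removed_signal_fraction <- function(partition) {
  ifelse(partition$ss_total_ori > 0,
         partition$ss_design_resid / partition$ss_total_ori, NA_real_)
}
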