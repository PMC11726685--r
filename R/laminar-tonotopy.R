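#' Cortical-depth profile of single-trial betas
#'
#' For each of the 11 depth bins (1 = deep, 11 = superficial): average the
#' single-trial betas over the ROI voxels of that depth, then take the
#' mean and standard deviation across trials. A volumetric stand-in for
#' surface-based equivolume depth sampling: depths come as integer labels.
#'
#' @param betas a [fit_glm()] result.
#' @param depth_labels integer array/vector (0 outside cortex, 1..11
#'   inside), one value per voxel.
#' @param roi logical or 0/1 array/vector selecting the ROI.
#' @param condition `"all_sounds"` or a condition id.
#' @param n_depths number of depth bins (default 11).
#' @return data.frame of class `depth_profile`: `depth`, `mean_beta`,
#'   `trial_variability` (sd across trials), `n_voxels`, `condition`.
#' @export
laminar_profile <- function(betas, depth_labels, roi,
                            condition = "all_sounds", n_depths = 11L) {
  depth <- as.integer(depth_labels)
  roi <- as.logical(roi)
  sel <- if (identical(condition, "all_sounds"))
    rep(TRUE, length(betas$condition_of_trial))
  else betas$condition_of_trial == condition
  if (!any(sel)) stopf("no trials for condition '%s'", condition)
  B <- betas$betas[, sel, drop = FALSE]
  empty <- setdiff(seq_len(n_depths), unique(depth[roi]))
  if (length(empty) > 0)
    stopf("empty depth bin(s) in ROI: %s", paste(empty, collapse = ", "))
  rows <- lapply(seq_len(n_depths), function(dd) {
    vox <- roi & depth == dd
    trial_means <- colMeans(B[vox, , drop = FALSE])
    data.frame(depth = dd,
               mean_beta = mean(trial_means),
               trial_variability = stats::sd(trial_means),
               n_voxels = sum(vox))
  })
  out <- do.call(rbind, rows)
  out$condition <- condition
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Best-frequency (tonotopic) labelling
#'
#' Per-voxel winner between the high- and low-frequency condition betas,
#' restricted to voxels significant in the supplied mask; ties (absolute
#' difference below `tie_eps`) are labelled `"untuned"`.
#'
#' @param beta_high,beta_low per-voxel condition beta maps.
#' @param tmask logical per-voxel significance mask (e.g. from
#'   [fdr_mask()]); default all voxels.
#' @param tie_eps tie threshold on `|beta_high - beta_low|`.
#' @return Character vector per voxel: `"high"`, `"low"`, `"untuned"`, or
#'   NA outside the mask.
#' @export
best_frequency <- function(beta_high, beta_low, tmask = NULL,
                           tie_eps = 1e-9) {
  bh <- as.numeric(beta_high)
  bl <- as.numeric(beta_low)
  if (length(bh) != length(bl)) stopf("map lengths differ")
  if (is.null(tmask)) tmask <- rep(TRUE, length(bh))
  lab <- rep(NA_character_, length(bh))
  d <- bh - bl
  inm <- as.logical(tmask)
  lab[inm] <- ifelse(abs(d[inm]) < tie_eps, "untuned",
                     ifelse(d[inm] > 0, "high", "low"))
  lab
}
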