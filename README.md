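# nordicfmri

Locally low-rank thermal-noise denoising for fMRI time series, with the
full evaluation stack needed to understand what denoising does to
event-related response estimates — built for (and tested on) the hardest
case: slow event-related designs in submillimeter auditory fMRI, where
thermal noise dominates.

## Who this is for

Researchers running high-resolution fMRI who want to (1) apply NORDIC-style
patch-wise PCA denoising with a principled random-matrix threshold, and
(2) quantify the resulting bias–variance tradeoff: how much the
$t$-statistics and reliability improve, how much percent-signal change is
lost, and where in the data (tSNR, cortical depth) that loss concentrates.
Everything runs on synthetic complex-valued data with known ground truth,
so the whole pipeline is verifiable end to end without any acquired
dataset.

## The method

For each cubic patch of $m$ voxels over $n$ timepoints, form the Casorati
matrix $Y \in \mathbb{C}^{m \times n}$ (voxels × time; $m \approx 11n$).
After removing a low-resolution volume-wise phase estimate and dividing by
the g-factor map $g(v)$ (so thermal noise is i.i.d. across voxels), the
singular values of $Y$ are hard-thresholded at the noise bulk edge — the
Monte-Carlo mean of the largest singular value of an $m \times n$ matrix
with i.i.d. $\mathcal{N}(0, \hat\sigma^2)$ entries, asymptotically
$\hat\sigma(\sqrt{m} + \sqrt{n})$ (Marchenko–Pastur). Components at or
below the edge are indistinguishable from noise and removed; patches are
overlap-averaged and the g-factor re-applied. Two threshold calibrations
are provided:

* `noise_scan` — $\hat\sigma$ estimated from appended no-excitation noise
  volumes (aggressive, the default);
* `gfactor_only` — no noise scan; residual-based $\hat\sigma$ with the
  cutoff scaled by $1/\sqrt{2}$ (conservative: removes fewer components).

Downstream, responses are estimated per single trial: a GLM with 36 trial
predictors (two-gamma HRF peaking at 5 s, kernel summing to 1, so betas are
in percent-signal units) plus a constant, after high-pass filtering
(7 cycles/run), temporal Gaussian smoothing (FWHM 2 volumes) and
percent-signal-change normalization. Evaluation covers across-trial
$t$-maps with FDR control, repeated split-half and leave-one-run-out
spatial reliability, exhaustive sign-flip permutation tests,
repeated-measures ANOVA with Greenhouse–Geisser correction, per-voxel
variance partitioning of the original series into denoised-retained and
removed parts (an exact sum-of-squares identity via OLS
orthogonalization), laminar profiles over 11 cortical depths, and
best-frequency (tonotopic) maps.

## Worked example

Simulate one subject at the study conditions (16³ voxels, 230 volumes +
5 noise scans at TR 1.6 s, tSNR ≈ 20, 36 tone-sequence trials), denoise
with the aggressive threshold, and compare single-trial statistics:

```r
library(nordicfmri)

cfg <- sim_config(grid_shape = c(16L, 16L, 16L), seed = 42L)
subject <- simulate_subject(cfg, n_runs = 2L)
run1 <- subject$runs[[1]]
run1
#> <fmri_ts> 16 x 16 x 16 voxels, 235 volumes (5 noise scans), TR 1.6 s, phase: present

dn <- nordic_denoise(run1, mode = "noise_scan", seed = 1L)
dn$report
#> <denoise_report> mode=noise_scan, 8 patches (kernel 14x14x14), sigma_hat=7.849, sv_cutoff=529.9,
#>   components kept 2.4 / removed 232.6 of 235 on average

roi <- subject$truth$roi_labels == 1
summarize <- function(ts, label) {
  tsx <- temporal_filter(strip_noise_scans(ts))
  X <- build_design(subject$designs[[1]], 230L)
  betas <- fit_glm(psc_normalize(tsx), X)
  tmap <- trial_t(betas, "all_sounds")
  cat(sprintf("%-10s mean beta (ROI) %.2f %%  median t (ROI) %.2f  active voxels (qFDR<0.01) %d\n",
              label, mean(rowMeans(betas$betas)[roi]),
              median(tmap$t[roi], na.rm = TRUE),
              fdr_mask(tmap, q = 0.01)$n_sig))
}
summarize(run1, "original")
#> original   mean beta (ROI) 1.43 %  median t (ROI) 0.81  active voxels (qFDR<0.01) 230
summarize(dn$ts, "denoised")
#> denoised   mean beta (ROI) 1.23 %  median t (ROI) 8.50  active voxels (qFDR<0.01) 4088
```

The numbers show the characteristic bias–variance tradeoff of hard
singular-value thresholding at low SNR: the mean response estimate in the
active region shrinks (1.43% → 1.23% — part of the design-related signal is
indistinguishable from noise within one run and is removed), while the
across-trial variability drops far more, so the median $t$ rises an order
of magnitude and many more voxels survive the qFDR < 0.01 threshold.
`partition_voxels()` makes the same statement exactly, splitting each
voxel's total sum of squares into the denoising-retained and removed parts
and measuring the design-explained variance in each.

A full three-strategy comparison (original / `noise_scan` /
`gfactor_only`) with NIfTI outputs and a JSON manifest:

```sh
Rscript scripts/run_pipeline.R --out pipeline_out --runs 2 --seed 7
```

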