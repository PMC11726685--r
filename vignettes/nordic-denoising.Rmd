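---
title: "Locally low-rank thermal-noise denoising for event-related fMRI: model, assumptions, and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally low-rank thermal-noise denoising for event-related fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nordicfmri)
```

## The problem

Submillimeter fMRI trades signal-to-noise ratio for spatial resolution, and
at 0.8 mm voxels the dominant noise source is thermal: zero-mean Gaussian
noise in the complex MR signal, amplified spatially by the parallel-imaging
g-factor and appearing Rician in magnitude images. Auditory cortex is a
particularly hard case — far from the receive coils, next to air cavities,
with smaller percent-signal changes than visual cortex — so slow
event-related auditory designs sit deep in the thermal-noise-dominated
regime.

`nordicfmri` implements NORDIC-style locally low-rank (LLR) denoising for
this setting and, just as importantly, the machinery to *evaluate* what
denoising does to response estimates: single-trial GLMs, split-half and
leave-one-run-out reliability, variance partitioning of the original series
into retained and removed parts, and laminar/tonotopic profiling. All of it
is driven by a synthetic complex-valued generator with known ground truth,
so every stage of the pipeline is testable without any acquired data.

## The denoising model

For a patch of $m$ voxels observed at $n$ timepoints, form the Casorati
matrix $Y \in \mathbb{C}^{m \times n}$ (rows = voxels, columns =
timepoints). The LLR assumption is that the noiseless signal within a patch
is low-rank — neighbouring voxels carry redundant temporal information —
while thermal noise is full-rank with i.i.d. entries. If the noise is
i.i.d. $\mathcal{N}(0, \sigma^2)$, random-matrix theory (the
Marchenko-Pastur law) says the singular values of a pure-noise matrix
concentrate below the bulk edge $\sigma(\sqrt{m} + \sqrt{n})$. Components
at or below that edge are indistinguishable from noise; components above
it carry signal.

The pipeline in `nordic_denoise()` is:

1. **Phase stabilization** (complex data only, `phase_stabilize()`): each
   volume's low-spatial-frequency phase — estimated by windowing the
   volume's 3D spectrum with a cosine-tapered (Tukey) low-pass of width
   1/10 of the spectrum (`tukey_scale = 10`) — is rotated away. Magnitude
   is untouched; the signal becomes approximately real, concentrating it
   into fewer components.
2. **g-factor normalization** (`estimate_gfactor_map()`,
   `normalize_by_gfactor()`): dividing by the spatial noise-amplification
   map makes the noise level uniform across voxels, the i.i.d. assumption
   of the threshold. With appended no-excitation noise scans the map is
   the smoothed voxelwise std of the noise-scan values, normalized to
   minimum 1; without them it falls back to first-difference temporal
   residuals.
3. **Patch-wise hard thresholding** (`denoise_patch()`): cubic patches
   whose voxel count is about 11 times the number of timepoints slide
   across the volume with stride half the kernel; each patch's singular
   values at or below the cutoff are zeroed and the patch is rebuilt.
4. **Overlap-averaged recombination**: every voxel's value is the
   unweighted mean over all patches covering it; boundary patches are
   shifted inward so coverage is complete. With the cutoff forced to 0
   this path is exactly the identity, which the tests use to validate the
   patch bookkeeping.
5. The g-factor is re-applied.

### The two threshold modes

The cutoff is the Monte-Carlo estimate (`mc_sv_threshold()`, default 20
draws) of the *mean largest* singular value of an $m \times n$ i.i.d.
Gaussian matrix at the estimated noise level — the bulk edge plus its
finite-size offset:

* **`noise_scan`** (aggressive, the default processing strategy): $\sigma$
  is estimated empirically from the appended noise scans after g-factor
  normalization, pooled across voxels. Because the g-factor map itself is
  estimated (and tends to be underestimated by up to ~10%), this empirical
  calibration absorbs that error.
* **`gfactor_only`** (conservative): no noise scan is used; $\sigma$ comes
  from high-frequency temporal residuals and the cutoff is scaled by the
  constant $1/\sqrt{2}$. The lower cutoff removes fewer components, so the
  result stays closer to the original data.

For complex data the noise level is parameterized as the per-complex-entry
std $\sqrt{\operatorname{var}(\mathrm{Re}) +
\operatorname{var}(\mathrm{Im})}$, which makes the real-entry Monte-Carlo
bulk edge coincide with the complex-matrix bulk edge. With magnitude-only
input the Casorati entries are real but their noise is Rician, not
Gaussian, so thresholds are approximate — the standard caveat for
magnitude-only LLR denoising.

### Numerical choices

* Hard thresholding (zeroing), not soft shrinkage: components are either
  kept or removed.
* Singular values exactly equal to the cutoff are removed (the keep rule
  is strict `>`); with `sv_cutoff = 0` nothing is removed.
* For tall patches ($m \ge 2n$) the decomposition runs through the
  $n \times n$ Gram matrix (eigenvalues = squared singular values), which
  is algebraically identical to the SVD route and several times faster.
* `mc_sv_threshold()` is computed at unit noise and scaled by $\sigma$, so
  scale equivariance is exact, and results are cached per
  $(m, n, n_\mathrm{mc}, \mathrm{seed})$.
* Noiseless input (all-zero noise scans) yields $\hat\sigma = 0$, cutoff
  0, and the identity path rather than an error.

## The estimation and evaluation stream

After denoising, noise scans are stripped and each strategy's run is
processed identically: temporal filtering (Fourier removal of cycles 1–6
per run with the mean preserved, then temporal Gaussian smoothing of FWHM
2 samples), percent-signal-change normalization, and an ordinary
least-squares GLM with one predictor per trial (36 + constant). Predictors
are the canonical two-gamma HRF — gamma densities with unit scale peaking
at 5 s and 15 s, amplitude ratio 1:6 — sampled at the TR and normalized to
sum to 1, so with a unit-scaled design the betas are in percent-signal
units. Filtering precedes PSC normalization; since the temporal mean is
preserved by both filters the order only matters at the third decimal.

Statistics use the variability *across single trials*, not the GLM
residuals: $t = \bar\beta / (s_\beta / \sqrt{n})$ with $n - 1$ degrees of
freedom. (The one-sample $t$ is the only dimensionally consistent reading
compatible with $t$-distribution FDR thresholds.) Activation maps use
two-sided $p$-values and Benjamini-Hochberg FDR control at $q = 0.01$.

Reliability metrics: repeated split-half (50 random partitions of the runs
into halves differing by at most one run, Pearson correlation of the
half-averaged maps within a mask, aggregated by Fisher-z mean with $r$
clipped to $1 - 10^{-12}$ before `atanh`), run-to-run correlations over
all unordered pairs, and leave-one-run-out correlation where the
reference map always comes from the *original* (undenoised) runs so every
strategy is scored against the same target. Group inference uses
exhaustive sign-flip permutation tests (all $2^n$ assignments, two-sided,
resolution exactly $2^{-n}$) with Bonferroni correction, and fully
within-subject repeated-measures ANOVA with Greenhouse-Geisser correction
(epsilon from the covariance of orthonormalized contrast scores;
Huynh-Feldt is not implemented). Two-sidedness of the permutation test and
the all-pairs convention for run-to-run correlations were open choices;
both are the conservative defaults.

### Variance partitioning

Per voxel, the original series is regressed on the denoised series,
$Y_\mathrm{ori} = \alpha Y_\mathrm{AN} + b + \varepsilon$ — equivalent to
Gram-Schmidt orthogonalization — giving the exact split
$SS(Y_\mathrm{ori}) = \hat\alpha^2 SS(Y_\mathrm{AN}) +
SS(\hat\varepsilon)$ of the total sum of squares (about the mean) into the
part retained by denoising and the part removed. Each of the three series
is then regressed on the design matrix, and
$SS^X(\hat\varepsilon) / SS(Y_\mathrm{ori})$ — design-explained variance
sitting in the removed residual — quantifies signal that denoising
discarded. The decomposition is computed per run (whether to concatenate
runs was unspecified; per-run keeps the $\alpha$ interpretable when the
noise level varies between runs). Voxels whose denoised series is
near-constant are excluded with a logged count rather than fitted.

### Laminar and tonotopic summaries

Depth profiles average single-trial betas over ROI voxels within each of
11 depth bins, then take mean and sd across trials; variability is always
across trials. Depths are integer label volumes supplied by the simulator
— a volumetric stand-in for surface-based equivolume sampling, whose
interpolate-then-average vertex ordering cannot be replicated
volumetrically. Best-frequency maps label each significant voxel by the
larger of the two predictable-condition betas, with ties
($|\Delta\beta| < 10^{-9}$) marked untuned.

## The synthetic generator

`simulate_subject()` emulates one 2D-EPI slow event-related run per call:

* **Design**: 36 trials over six four-tone sequence conditions (two
  predictable conditions 10 trials each, four others 4 each), tone
  sequence duration 1.6 s, inter-trial intervals of 5–7 volumes with mean
  exactly 6, TR 1.6 s (1.65 s reproduces the second acquisition site), 230
  volumes plus 5 appended noise scans. With 36 trials there are 35 gaps,
  so the balanced interval multiset is 12 fives, 11 sixes and 12 sevens; a
  6-volume baseline precedes the first trial and the tail of the run
  stays baseline.
* **Signal**: per-voxel condition amplitudes in percent units against a
  baseline of 100. The ROI amplitude ramps from 1.5% at the deepest to
  3.0% at the most superficial of 11 depth labels — the gradient-echo
  draining-vein profile — and a high/low/high frequency-preference banding
  modulates the condition ending in the preferred frequency by ±30%.
  These sit in the range reported for tone responses in 7T auditory
  cortex.
* **Noise**: complex Gaussian thermal noise with per-channel std
  `sigma_thermal` (default 5, i.e. voxel tSNR near 20 at $g = 1$ — the
  low-SNR regime of submillimeter auditory acquisitions), amplified by a
  smooth g-factor map in `[1, 2]`; structured physiological noise (linear
  drift + 0.3 Hz and 1.0 Hz sinusoids aliased by the TR + AR(1) with
  $\rho = 0.3$, spatially coherent with a smooth amplitude map, default
  0.5% of baseline); a smooth static spatial phase plus a small common
  temporal phase fluctuation. Appended noise scans contain only the
  complex noise term.

What it deliberately does **not** model: k-space sampling, multiband/SENSE
reconstruction, motion, geometric distortion, scanner-sound interactions
with the auditory stimulation, and realistic vascular physiology. Passing
tests therefore show that the algorithms behave as specified under the
stated statistical assumptions — not that every effect size matches
acquired 7T data.

## Operating point and what the tests show

The interesting behaviour of hard singular-value thresholding lives near
the detection edge: a task component whose singular value
$\theta \approx \sigma (mn)^{1/4}$ is on the boundary of separability from
the noise bulk. At the generator's defaults the all-sounds response sits
just at that edge, which is precisely the paper-like regime: the
aggressive noise-scan threshold removes part of the design-related
variance (betas shrink, and the removed residual carries design variance),
while across-trial variability drops much more, so $t$-statistics and
split-half reliability rise. The conservative $1/\sqrt{2}$ threshold
removes less noise *and* less signal, landing between the original and the
aggressive strategy on every metric.

Problem sizes in the test suite were chosen to keep the full run
desk-scale: unit fixtures use $12^3$ grids (a single clipped patch), and
the directional study uses 20 simulated subjects at $16^3$ — eight
overlapping $14^3$ patches, enough for overlap averaging to matter — with
two runs each. The overall direction of all six reproduced effects
(t increase, reliability increase, beta reduction ordered by threshold
aggressiveness, design variance in the removed component ordered the same
way, beta changes concentrated at low tSNR, laminar slope flattening) is
stable across subjects at these sizes.

## Known limitations

* Volumetric depth labels approximate surface-based equivolume sampling.
* Magnitude-only thresholds ignore the Rician noise floor.
* The Monte-Carlo threshold assumes i.i.d. entries after g-normalization;
  residual spatial correlation of the noise (e.g. from reconstruction
  filters, not simulated here) would shift the bulk edge.
* `rm_anova()` implements one- and two-factor fully within-subject
  designs only, and only the Greenhouse-Geisser correction.
* The exhaustive sign-flip test is limited to 20 subjects ($2^{20}$
  assignments); larger cohorts would need a sampled permutation variant.
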