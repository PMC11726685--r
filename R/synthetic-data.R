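#' Tone-sequence condition labels
#'
#' Six four-tone sequence conditions: predictable, mispredicted and
#' unpredictable contexts, each ending in either a high or a low target
#' frequency. Per run the two predictable sequences are presented 10 times
#' each and the other four conditions 4 times each (36 trials total).
#'
#' @return Character vector of the six condition ids, with a `counts`
#'   attribute giving the per-run trial counts.
#' @export
tone_conditions <- function() {
  conds <- c("PredH", "PredL", "MispredH", "MispredL", "UnpredH", "UnpredL")
  attr(conds, "counts") <- c(PredH = 10L, PredL = 10L, MispredH = 4L,
                             MispredL = 4L, UnpredH = 4L, UnpredL = 4L)
  conds
}

## Duration of one four-tone sequence: 4 x 100 ms tones with 400 ms gaps.
TONE_SEQUENCE_SECONDS <- 1.6

#' Simulation configuration
#'
#' Parameters of the synthetic complex-valued fMRI generator. Defaults
#' emulate a 2D-EPI slow event-related auditory run: 230 volumes at
#' TR 1.6 s plus five appended no-excitation noise scans, a baseline
#' image intensity of 100 so that percent-signal-change amplitudes map
#' directly onto image units, thermal noise in the complex domain with
#' per-channel std `sigma_thermal` amplified by a smooth g-factor map,
#' and percent-level structured physiological noise.
#'
#' `sigma_thermal = 5` against baseline 100 yields voxel tSNR near 20 at
#' g = 1, the low-SNR regime typical of submillimeter auditory fMRI.
#'
#' @param grid_shape integer 3-vector, voxels per axis.
#' @param n_volumes data volumes per run (default 230).
#' @param n_noise_scans appended noise volumes (default 5).
#' @param tr_seconds repetition time; 1.6 by default, 1.65 mirrors the
#'   second acquisition site.
#' @param sigma_thermal per-channel std of the complex Gaussian thermal
#'   noise, in image units.
#' @param physio_amplitude std of structured physiological fluctuations in
#'   percent of baseline.
#' @param gfactor_range range (both >= 1) of the smooth noise-amplification
#'   map.
#' @param baseline mean image intensity.
#' @param seed integer seed; the full dataset is reproducible given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(12L, 12L, 12L),
                       n_volumes = 230L,
                       n_noise_scans = 5L,
                       tr_seconds = 1.6,
                       sigma_thermal = 5,
                       physio_amplitude = 0.5,
                       gfactor_range = c(1, 2),
                       baseline = 100,
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stopf("`grid_shape` must be 3 positive integers")
  if (n_volumes < 1L) stopf("`n_volumes` must be positive")
  if (n_noise_scans < 0L) stopf("`n_noise_scans` must be non-negative")
  if (tr_seconds <= 0) stopf("`tr_seconds` must be positive")
  if (sigma_thermal < 0) stopf("`sigma_thermal` must be non-negative")
  if (physio_amplitude < 0) stopf("`physio_amplitude` must be non-negative")
  if (length(gfactor_range) != 2L || gfactor_range[1] < 1 ||
      diff(gfactor_range) < 0)
    stopf("`gfactor_range` must be an increasing pair with minimum >= 1")
  structure(list(grid_shape = grid_shape,
                 n_volumes = as.integer(n_volumes),
                 n_noise_scans = as.integer(n_noise_scans),
                 tr_seconds = tr_seconds,
                 sigma_thermal = sigma_thermal,
                 physio_amplitude = physio_amplitude,
                 gfactor_range = as.numeric(gfactor_range),
                 baseline = baseline,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Event design constructor
#'
#' A light container for an ordered trial list. `generate_design()` builds
#' designs satisfying the full per-run invariants (exact condition counts,
#' inter-trial intervals in 5-7 volumes with mean exactly 6);
#' `event_design()` itself only checks ordering and label validity, so
#' reduced designs can be assembled for short test series.
#'
#' @param condition character vector of condition ids (see
#'   [tone_conditions()]).
#' @param onset_volume 0-based onset volume per trial, strictly increasing.
#' @param tr_seconds repetition time in seconds.
#' @return A data.frame of class `event_design` with columns `condition`,
#'   `onset_volume`; TR and stimulus duration stored as attributes.
#' @export
event_design <- function(condition, onset_volume, tr_seconds = 1.6) {
  if (length(condition) != length(onset_volume))
    stopf("`condition` and `onset_volume` lengths differ")
  if (!all(condition %in% tone_conditions()))
    stopf("unknown condition label(s): %s",
          paste(setdiff(condition, tone_conditions()), collapse = ", "))
  onset_volume <- as.integer(onset_volume)
  if (any(onset_volume < 0) || is.unsorted(onset_volume, strictly = TRUE))
    stopf("`onset_volume` must be non-negative and strictly increasing")
  structure(data.frame(condition = as.character(condition),
                       onset_volume = onset_volume,
                       stringsAsFactors = FALSE),
            tr_seconds = tr_seconds,
            duration_seconds = TONE_SEQUENCE_SECONDS,
            class = c("event_design", "data.frame"))
}

#' Generate a randomized per-run event design
#'
#' Draws a random trial order with exact per-run condition counts
#' (10/10/4/4/4/4 over the six tone-sequence conditions, 36 trials) and
#' inter-trial intervals that are a seeded random permutation of a balanced
#' multiset of \{5, 6, 7\} volumes, so the mean interval is exactly 6.
#' A 6-volume baseline precedes the first trial; volumes after the last
#' trial remain baseline.
#'
#' @param config a [sim_config()].
#' @param lead_in_volumes baseline volumes before the first onset.
#' @return An [event_design()].
#' @export
generate_design <- function(config, lead_in_volumes = 6L) {
  counts <- attr(tone_conditions(), "counts")
  n_trials <- sum(counts)                      # 36
  ## 35 gaps: 12 fives, 11 sixes, 12 sevens -> sum 210, mean exactly 6
  gaps <- c(rep(5L, 12L), rep(6L, 11L), rep(7L, 12L))
  with_seed(sub_seed(config$seed, 11L), {
    order <- sample(rep(names(counts), counts))
    gaps <- sample(gaps)
    onsets <- lead_in_volumes + cumsum(c(0L, gaps))
    needed <- onsets[n_trials] + lead_in_volumes
    if (config$n_volumes < needed)
      stopf("n_volumes = %d cannot accommodate 36 trials (needs >= %d)",
            config$n_volumes, needed)
    event_design(order, onsets, config$tr_seconds)
  })
}

#' Generate a smooth g-factor map
#'
#' Smooth spatial map of parallel-imaging noise amplification: filtered
#' Gaussian noise rescaled into `gfactor_range`. Thermal noise std at a
#' voxel is `g(v) * sigma_thermal` per channel.
#'
#' @param config a [sim_config()].
#' @return 3D array with values in `gfactor_range`, deterministic given the
#'   seed.
#' @export
generate_gfactor <- function(config) {
  rng <- config$gfactor_range
  d <- config$grid_shape
  if (rng[1] == rng[2]) return(array(rng[1], dim = d))
  with_seed(sub_seed(config$seed, 23L), {
    raw <- array(stats::rnorm(prod(d)), dim = d)
    sm <- smooth3d(raw, sigma = max(d) / 6)
    sc <- (sm - min(sm)) / (max(sm) - min(sm))
    array(rng[1] + sc * (rng[2] - rng[1]), dim = d)
  })
}

#' Ground-truth record for a simulated subject
#'
#' Builds the truth the analyses are scored against: a cortical-ribbon
#' stand-in ROI with 11 depth labels, a high/low/high tonotopic preference
#' pattern, per-condition response amplitudes (percent-signal units) that
#' ramp towards the superficial depths (the gradient-echo draining-vein
#' profile), a smooth g-factor map, a baseline image and a smooth static
#' phase field.
#'
#' Amplitudes: at cortical depth d in 1..11 the all-sound response is
#' `1.5 + 1.5 * (d - 1) / 10` percent (1.5 deep to 3.0 superficial); the
#' condition matching a voxel's frequency preference is scaled by 1.3 and
#' the non-preferred one by 0.7.
#'
#' @param config a [sim_config()].
#' @param tuning modulation depth of frequency preference (default 0.3).
#' @return A list of class `ground_truth` with elements `beta_true`
#'   (x,y,z,6 array, percent), `gfactor`, `roi_labels`, `depth_labels`,
#'   `tono_pref`, `baseline`, `phase_static`.
#' @export
make_ground_truth <- function(config, tuning = 0.3) {
  d <- config$grid_shape
  conds <- tone_conditions()
  ## ROI: interior slab (1-voxel shell excluded in x and y); depth runs
  ## along z, binned into 11 depths from deep (1) to superficial (11).
  roi <- array(0L, dim = d)
  xs <- if (d[1] > 2) 2:(d[1] - 1) else seq_len(d[1])
  ys <- if (d[2] > 2) 2:(d[2] - 1) else seq_len(d[2])
  roi[xs, ys, ] <- 1L
  depth <- array(0L, dim = d)
  zidx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  depth[roi == 1L] <- pmax(1L, as.integer(ceiling(11 * zidx[roi == 1L] / d[3])))
  ## tonotopy: high-low-high bands along y
  yb <- ceiling(3 * seq_len(d[2]) / d[2])      # 1,2,3 bands
  pref_high <- array(rep(rep(yb != 2L, each = d[1]), d[3]), dim = d)
  amp <- array(0, dim = d)
  amp[roi == 1L] <- 1.5 + 1.5 * (depth[roi == 1L] - 1) / 10
  beta <- array(0, dim = c(d, length(conds)))
  high_cond <- grepl("H$", conds)
  for (k in seq_along(conds)) {
    match_pref <- if (high_cond[k]) pref_high else !pref_high
    beta[, , , k] <- amp * (1 + tuning * ifelse(match_pref, 1, -1))
  }
  phase_static <- with_seed(sub_seed(config$seed, 37L), {
    p <- smooth3d(array(stats::rnorm(prod(d)), dim = d), sigma = max(d) / 5)
    0.5 * p / max(abs(p))
  })
  structure(list(beta_true = beta,
                 conditions = conds,
                 gfactor = generate_gfactor(config),
                 roi_labels = roi,
                 depth_labels = depth,
                 tono_pref = ifelse(pref_high, "high", "low"),
                 baseline = array(config$baseline, dim = d),
                 phase_static = phase_static),
            class = "ground_truth")
}

## Condition-wise HRF regressors: T x 6 matrix, each column the sum of
## unit-sum HRF kernels at that condition's onsets.
condition_regressors <- function(design, n_volumes, tr_seconds) {
  k <- two_gamma_hrf(tr_seconds)
  conds <- tone_conditions()
  R <- matrix(0, nrow = n_volumes, ncol = length(conds),
              dimnames = list(NULL, conds))
  for (i in seq_len(nrow(design))) {
    j <- match(design$condition[i], conds)
    idx <- design$onset_volume[i] + seq_along(k)   # 0-based onset -> 1-based
    ok <- idx <= n_volumes
    R[idx[ok], j] <- R[idx[ok], j] + k[ok]
  }
  R
}

#' Synthesize one complex-valued fMRI run
#'
#' Composes the complex signal
#' `S(v,t) = baseline(v) * (1 + PSC(v,t)/100 + physio(v,t)/100) * exp(i phi(v,t))
#'  + g(v) * sigma * (xi1 + i xi2)`
#' with `xi` standard normal, where PSC is `beta_true` convolved with the
#' two-gamma HRF at the trial onsets and physio is slow drift + two
#' sinusoids (0.3 and 1.0 Hz, aliased by the TR) + AR(1) noise (rho 0.3),
#' coherent across space with a smooth amplitude map. `n_noise_scans`
#' volumes containing only the complex noise term are appended.
#'
#' @param design an [event_design()].
#' @param truth a [make_ground_truth()] record.
#' @param config a [sim_config()].
#' @param run_seed optional seed for this run's noise realization
#'   (defaults to `config$seed`); the truth record is seed-independent of it.
#' @return An [fmri_ts] (magnitude + phase) with an extra element `clean`:
#'   the noiseless magnitude 4D array (data volumes only).
#' @export
synthesize_run <- function(design, truth, config, run_seed = config$seed) {
  if (config$sigma_thermal < 0) stopf("negative sigma_thermal")
  d <- config$grid_shape
  nv <- config$n_volumes
  V <- prod(d)
  R <- condition_regressors(design, nv, config$tr_seconds)
  B <- matrix(truth$beta_true, nrow = V)               # V x 6
  psc <- B %*% t(R)                                    # V x T, percent units
  with_seed(sub_seed(run_seed, 53L), {
    t_sec <- (seq_len(nv) - 1L) * config$tr_seconds
    drift <- scale(t_sec)[, 1]
    s1 <- sin(2 * pi * 0.3 * t_sec + stats::runif(1, 0, 2 * pi))
    s2 <- sin(2 * pi * 1.0 * t_sec + stats::runif(1, 0, 2 * pi))
    ar <- as.numeric(stats::filter(stats::rnorm(nv), 0.3, "recursive"))
    p <- drift + s1 + s2 + ar / stats::sd(ar)
    p <- p / stats::sd(p)
    w0 <- smooth3d(array(stats::runif(V), dim = d), 2)
    wmap <- 0.5 + (w0 - min(w0)) / (max(w0) - min(w0))   # in [0.5, 1.5]
    physio <- config$physio_amplitude * matrix(wmap, ncol = 1) %*% matrix(p, nrow = 1)
    amp <- as.numeric(truth$baseline) * (1 + (psc + physio) / 100)
    clean <- array(amp, dim = c(d, nv))
    phi <- outer(as.numeric(truth$phase_static), rep(1, nv)) +
      matrix(0.01 * sin(2 * pi * 2 * seq_len(nv) / nv),
             nrow = V, ncol = nv, byrow = TRUE)
    ntot <- nv + config$n_noise_scans
    gsig <- as.numeric(truth$gfactor) * config$sigma_thermal
    noise <- (matrix(stats::rnorm(V * ntot), V) +
              1i * matrix(stats::rnorm(V * ntot), V)) * gsig
    S <- cbind(amp * exp(1i * phi), matrix(0, V, config$n_noise_scans)) + noise
    ts <- fmri_ts(array(Mod(S), dim = c(d, ntot)),
                  array(Arg(S), dim = c(d, ntot)),
                  config$tr_seconds, config$n_noise_scans)
    ts$clean <- clean
    ts
  })
}

#' Simulate a full multi-run subject
#'
#' Convenience wrapper: one truth record, `n_runs` independently randomized
#' designs and noise realizations.
#'
#' @param config a [sim_config()].
#' @param n_runs number of runs.
#' @return list with `truth`, `designs` (list), `runs` (list of [fmri_ts]).
#' @export
simulate_subject <- function(config, n_runs = 2L) {
  truth <- make_ground_truth(config)
  designs <- vector("list", n_runs)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg_r <- config
    cfg_r$seed <- sub_seed(config$seed, 1000L + r)
    designs[[r]] <- generate_design(cfg_r)
    runs[[r]] <- synthesize_run(designs[[r]], truth, config,
                                run_seed = cfg_r$seed)
  }
  list(truth = truth, designs = designs, runs = runs, config = config)
}
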