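# Shared fixtures built in code. Heavier simulations are cached in a local
# environment so several test files can reuse the same realization.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## Small standard run at the low-SNR study conditions (tSNR ~ 20 at g = 1).
tiny_config <- function(seed = 101L, ...) {
  args <- list(grid_shape = c(12L, 12L, 12L), sigma_thermal = 5,
               physio_amplitude = 0.5, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

## One simulated subject (truth + 2 runs) reused across files.
tiny_subject <- function() {
  cached("tiny_subject", simulate_subject(tiny_config(), n_runs = 2L))
}

## Denoised versions of run 1 of the tiny subject, both threshold modes.
tiny_denoised <- function(mode) {
  cached(paste0("tiny_dn_", mode), {
    nordic_denoise(tiny_subject()$runs[[1]], mode = mode, seed = 5L)
  })
}

## A reduced event design for short series (plumbing only; not a full run).
short_design <- function(n_trials = 12L, spacing = 8L, tr = 1.6,
                         lead_in = 4L) {
  conds <- rep(tone_conditions(), length.out = n_trials)
  event_design(conds, lead_in + spacing * (seq_len(n_trials) - 1L), tr)
}

## Noise-only series: known g map, zero signal, zero physio.
noise_only_ts <- function(g, sigma, n_vol, n_noise, seed = 1L, d = dim(g),
                          complex = TRUE) {
  V <- prod(d)
  nt <- n_vol + n_noise
  set.seed(seed)
  z <- (matrix(rnorm(V * nt), V) + 1i * matrix(rnorm(V * nt), V)) *
    as.numeric(g) * sigma
  if (complex) {
    fmri_ts(array(Mod(z), c(d, nt)), array(Arg(z), c(d, nt)), 1.6, n_noise)
  } else {
    fmri_ts(array(Mod(z), c(d, nt)), NULL, 1.6, n_noise)
  }
}

## Fresh scratch directory under the session tempdir.
local_tmpdir <- function() {
  d <- tempfile("nordicfmri_test_")
  dir.create(d)
  d
}
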