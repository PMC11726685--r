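test_that("g-factor estimation recovers homogeneous and ramped noise maps", {
  d <- c(10L, 10L, 10L)
  ## homogeneous noise: estimated map ~ 1 everywhere
  ts1 <- noise_only_ts(array(1, d), sigma = 2, n_vol = 10L, n_noise = 200L,
                       seed = 21L)
  g1 <- estimate_gfactor_map(ts1)
  expect_lt(max(abs(g1 - 1)), 0.1)
  ## ramp 1 -> 3 along x, 500 noise scans: voxelwise ratio in [0.9, 1.1]
  ramp <- array(rep(seq(1, 3, length.out = d[1]), times = prod(d[2:3])),
                dim = d)
  ts2 <- noise_only_ts(ramp, sigma = 1.5, n_vol = 10L, n_noise = 500L,
                       seed = 22L)
  g2 <- estimate_gfactor_map(ts2, smooth_sigma = 0.5)
  ratio <- g2 / (ramp / min(ramp))
  expect_true(all(ratio >= 0.9 & ratio <= 1.1))
  ## determinism
  expect_identical(g2, estimate_gfactor_map(ts2, smooth_sigma = 0.5))
  ## all-zero input errors
  zero <- fmri_ts(array(0, c(d, 40L)), NULL, 1.6, 5L)
  expect_error(estimate_gfactor_map(zero), "all-zero")
})

test_that("g-factor normalization divides, inverts exactly, and validates", {
  ts <- tiny_subject()$runs[[1]]
  d <- dim(ts$magnitude)[1:3]
  expect_equal(normalize_by_gfactor(ts, array(1, d))$magnitude, ts$magnitude)
  half <- normalize_by_gfactor(ts, array(2, d))
  expect_equal(half$magnitude, ts$magnitude / 2)
  g <- tiny_subject()$truth$gfactor
  back <- normalize_by_gfactor(normalize_by_gfactor(ts, g), g, inverse = TRUE)
  expect_equal(back$magnitude, ts$magnitude, tolerance = 1e-12)
  expect_error(normalize_by_gfactor(ts, array(0, d)), "positive")
})

test_that("Monte-Carlo singular-value threshold matches the Marchenko-Pastur edge", {
  expect_equal(mc_sv_threshold(1000, 100, 0), 0)
  thr <- mc_sv_threshold(1000, 100, 1, n_mc = 20, seed = 3)
  edge <- sqrt(1000) + sqrt(100)
  expect_lt(abs(thr - edge) / edge, 0.02)
  ## exact scale equivariance at fixed seed
  expect_identical(mc_sv_threshold(1000, 100, 2, n_mc = 20, seed = 3), 2 * thr)
  expect_error(mc_sv_threshold(1000, 100, -1), "non-negative")
})

test_that("patch hard thresholding keeps strong components and removes weak ones", {
  set.seed(8)
  u <- rnorm(50); v <- rnorm(30)
  m1 <- 10 * (u / sqrt(sum(u^2))) %o% (v / sqrt(sum(v^2)))
  r1 <- denoise_patch(m1, 5)
  expect_equal(r1$mat, m1, tolerance = 1e-10)
  expect_equal(r1$kept_rank, 1L)
  ## pure noise entirely below the cutoff -> zero matrix
  noise <- matrix(rnorm(50 * 30, sd = 0.01), 50, 30)
  top <- La.svd(noise, nu = 0, nv = 0)$d[1]
  r0 <- denoise_patch(noise, top + 1)
  expect_true(all(r0$mat == 0))
  expect_equal(r0$kept_rank, 0L)
  ## Eckart-Young: discarded energy equals the squared dropped singular values
  s <- La.svd(matrix(rnorm(40 * 20), 40, 20))
  d_fixed <- c(20, 8, 3, 2, rep(0.5, 16))
  m2 <- s$u %*% (d_fixed * s$vt)
  r2 <- denoise_patch(m2, 5)
  expect_equal(r2$kept_rank, 2L)
  dropped <- sqrt(sum(d_fixed[d_fixed <= 5]^2))
  expect_equal(norm(m2 - r2$mat, "F"), dropped, tolerance = 1e-10)
})

test_that("forcing the cutoff to zero reproduces the input through the patch machinery", {
  ts <- tiny_subject()$runs[[1]]
  out <- nordic_denoise(ts, mode = "noise_scan", sv_cutoff = 0,
                        phase_stabilization = FALSE)
  expect_equal(out$ts$magnitude, ts$magnitude, tolerance = 1e-10)
  expect_equal(out$ts$phase, ts$phase, tolerance = 1e-6)
  expect_true(all(out$report$kept_rank == out$report$min_mn))
})

test_that("a noiseless run passes through essentially unchanged", {
  cfg <- tiny_config(sigma_thermal = 0, physio_amplitude = 0, seed = 31L)
  sub <- simulate_subject(cfg, n_runs = 1L)
  ts <- sub$runs[[1]]
  out <- nordic_denoise(ts, mode = "noise_scan", phase_stabilization = FALSE)
  rel <- sqrt(mean((out$ts$magnitude - ts$magnitude)^2)) /
    sqrt(mean(ts$magnitude^2))
  expect_lt(rel, 1e-6)
})

test_that("denoising brings a low-SNR run closer to the clean signal", {
  sub <- tiny_subject()
  ts <- sub$runs[[1]]
  dn <- tiny_denoised("noise_scan")
  keep <- seq_len(nordicfmri:::n_data_volumes(ts))
  clean <- ts$clean
  err_in <- apply(ts$magnitude[, , , keep] - clean, 1:3, sd)
  err_out <- apply(dn$ts$magnitude[, , , keep] - clean, 1:3, sd)
  roi <- sub$truth$roi_labels == 1
  expect_gt(mean(err_out[roi] < err_in[roi]), 0.95)
  expect_true(all(is.finite(dn$ts$magnitude)))
})

test_that("the g-factor-only threshold mode is more conservative than the noise-scan mode", {
  dn_ns <- tiny_denoised("noise_scan")
  dn_nn <- tiny_denoised("gfactor_only")
  expect_true(all(dn_nn$report$kept_rank >= dn_ns$report$kept_rank))
  expect_lt(dn_nn$report$sv_cutoff, dn_ns$report$sv_cutoff)
})

test_that("denoising pure noise removes almost all variance", {
  d <- c(10L, 10L, 10L)
  ts <- noise_only_ts(array(1, d), sigma = 3, n_vol = 60L, n_noise = 5L,
                      seed = 44L)
  out <- nordic_denoise(ts, mode = "noise_scan", seed = 2L)
  cvar <- function(x) {
    z <- nordicfmri:::ts_values(x)
    stats::var(Re(as.vector(z))) + stats::var(Im(as.vector(z)))
  }
  expect_lt(cvar(out$ts), 0.1 * cvar(ts))
})

test_that("phase stabilization removes smooth phase and preserves magnitude", {
  d <- c(8L, 8L, 8L)
  set.seed(55)
  mag <- array(runif(prod(d) * 4, 50, 150), c(d, 4L))
  ## spatially constant phase is fully captured by the low-pass estimate
  ts_const <- fmri_ts(mag, array(0.8, c(d, 4L)), 1.6, 0L)
  out <- phase_stabilize(ts_const)
  expect_lt(max(abs(out$phase)), 1e-8)
  expect_equal(out$magnitude, mag)
  ## zero phase input is untouched
  ts_zero <- fmri_ts(mag, array(0, c(d, 4L)), 1.6, 0L)
  out0 <- phase_stabilize(ts_zero)
  expect_lt(max(abs(out0$phase)), 1e-10)
  ## magnitude is preserved voxelwise for arbitrary phase
  ts_rand <- fmri_ts(mag, array(runif(prod(d) * 4, -1, 1), c(d, 4L)), 1.6, 0L)
  outr <- phase_stabilize(ts_rand)
  expect_equal(outr$magnitude, mag, tolerance = 1e-10)
  expect_error(phase_stabilize(fmri_ts(mag, NULL, 1.6, 0L)), "phase")
})

test_that("patch specification respects the 11:1 ratio and covers the volume", {
  ps <- patch_spec(c(64L, 64L, 40L), 230L)
  expect_equal(prod(ps$kernel) / 230, 11, tolerance = 0.25)
  for (a in 1:3) {
    expect_equal(ps$starts[[a]][1], 1L)
    expect_equal(max(ps$starts[[a]]) + ps$kernel[a] - 1L,
                 c(64L, 64L, 40L)[a])
  }
  expect_error(patch_spec(c(8L, 8L, 8L), 230L, kernel = 16L), "exceeds")
})
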