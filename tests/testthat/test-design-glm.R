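test_that("the two-gamma HRF peaks at 5 s, sums to one, and undershoots", {
  k <- two_gamma_hrf(0.05)
  t <- seq(0, 30, by = 0.05)
  expect_equal(t[which.max(k)], 5)
  expect_equal(sum(k), 1, tolerance = 1e-10)
  expect_lt(min(k[t > 5]), 0)                    # undershoot after the peak
  ## TR-sampled kernel keeps the unit sum
  expect_equal(sum(two_gamma_hrf(1.6)), 1, tolerance = 1e-10)
})

test_that("the single-trial design matrix has one column per trial plus a constant", {
  cfg <- sim_config(seed = 2L)
  des <- generate_design(cfg)
  X <- build_design(des, cfg$n_volumes)
  expect_equal(ncol(X$X), 37L)
  expect_equal(X$X[, 37], rep(1, cfg$n_volumes))
  expect_lte(max(X$X[, 1:36]), max(X$hrf_kernel))
  ## empty design -> constant only
  empty <- event_design(character(0), integer(0), 1.6)
  X0 <- build_design(empty, 50L)
  expect_equal(ncol(X0$X), 1L)
  ## two trials 6 TRs apart give shifted copies of the same column
  two <- event_design(c("PredH", "PredL"), c(10L, 16L), 1.6)
  X2 <- build_design(two, 60L)$X
  expect_equal(X2[17:60, 2], X2[11:54, 1])
  expect_error(build_design(two, 12L), "outside the run")
})

test_that("temporal filtering preserves the mean, removes slow cycles, and smooths", {
  T_ <- 230L
  const <- matrix(100, T_, 1)
  expect_equal(temporal_filter(const), const, tolerance = 1e-10)
  slow <- matrix(sin(2 * pi * 3 * (0:(T_ - 1)) / T_), T_, 1)
  out <- temporal_filter(slow)
  expect_lt(max(abs(out)), 0.05 * max(abs(slow)))
  set.seed(12)
  wn <- matrix(rnorm(T_), T_, 1)
  expect_lt(sd(temporal_filter(wn)), sd(wn))
  ts <- tiny_subject()$runs[[1]]
  expect_error(temporal_filter(ts), "strip")
})

test_that("percent-signal-change normalization matches its definition", {
  expect_equal(psc_normalize(c(99, 100, 101)), c(-1, 0, 1),
               ignore_attr = TRUE)
  expect_equal(psc_normalize(rep(5, 10)), rep(0, 10),
               ignore_attr = TRUE)
  set.seed(3)
  y <- 100 + rnorm(50)
  expect_equal(psc_normalize(y), psc_normalize(7 * y), tolerance = 1e-12,
               ignore_attr = TRUE)
  z <- psc_normalize(cbind(rep(0, 50), y))
  expect_false(attr(z, "valid")[1])
  expect_true(attr(z, "valid")[2])
  expect_true(all(z[, 1] == 0))
})

test_that("the GLM recovers noiseless betas and behaves under the null", {
  cfg <- sim_config(seed = 6L)
  des <- generate_design(cfg)
  X <- build_design(des, cfg$n_volumes)
  set.seed(77)
  btrue <- matrix(rnorm(37 * 50), nrow = 37)
  Y <- X$X %*% btrue
  fit <- fit_glm(Y, X)
  expect_equal(t(fit$betas), btrue[1:36, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  ## pure-noise voxels: mean beta ~ 0 within 3 SE (Monte-Carlo null)
  set.seed(78)
  Yn <- matrix(rnorm(cfg$n_volumes * 1000), cfg$n_volumes)
  fn <- fit_glm(Yn, X)
  mb <- mean(fn$betas)
  se <- sd(fn$betas) / sqrt(length(fn$betas))
  expect_lt(abs(mb), 3 * se)
  ## adding a constant moves only the intercept
  f1 <- fit_glm(Yn + 5, X)
  expect_equal(f1$betas, fn$betas, tolerance = 1e-8)
  expect_equal(f1$intercept, fn$intercept + 5, tolerance = 1e-8)
  ## residuals orthogonal to every design column
  resid <- Yn[, 1:5] - X$X %*% rbind(t(fn$betas[1:5, ]), fn$intercept[1:5])
  expect_lt(max(abs(crossprod(X$X, resid))), 1e-8)
  ## duplicated column -> informative rank error
  Xbad <- X
  Xbad$X[, 2] <- Xbad$X[, 1]
  expect_error(fit_glm(Yn, Xbad), "collinear")
})

test_that("across-trial t-statistics match the one-sample t", {
  bm <- structure(list(betas = rbind(c(1, 2, 3), c(2, 2, 2), c(-1, -2, -3)),
                       intercept = rep(0, 3),
                       condition_of_trial = rep("PredH", 3), dim3 = NULL),
                  class = "beta_maps")
  tm <- trial_t(bm, "all_sounds")
  expect_equal(tm$t[1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tm$t[1], 3.464, tolerance = 1e-3)
  expect_true(is.na(tm$t[2]))                    # zero variance masked
  expect_equal(tm$t[3], -tm$t[1])                # sign antisymmetry
  expect_equal(tm$dof, 2L)
  expect_error(trial_t(bm, "UnpredL"), "fewer than 2")
})

test_that("tSNR follows its definition and is scale invariant", {
  set.seed(5)
  y <- matrix(rnorm(200, mean = 100, sd = 10), ncol = 1)
  expect_equal(tsnr(y), mean(y) / sd(y))
  expect_equal(tsnr(3 * y), tsnr(y), tolerance = 1e-12)
})

test_that("FDR masking matches brute-force Benjamini-Hochberg", {
  ## brute force on a printed toy vector
  p <- c(0.001, 0.02, 0.03, 0.5)
  q <- 0.05
  m <- length(p)
  ord <- order(p)
  bh_keep <- rep(FALSE, m)
  kmax <- suppressWarnings(max(which(sort(p) <= q * seq_len(m) / m)))
  if (is.finite(kmax)) bh_keep[ord[seq_len(kmax)]] <- TRUE
  expect_equal(bh_keep, c(TRUE, TRUE, TRUE, FALSE))
  ## package path: construct t-values giving exactly those p-values
  dof <- 10L
  tv <- qt(p / 2, df = dof, lower.tail = FALSE)
  tm <- structure(list(t = tv, dof = dof, contrast = "all_sounds",
                       dim3 = NULL), class = "t_map")
  res <- fdr_mask(tm, q = q)
  expect_equal(res$mask, bh_keep)
  expect_equal(res$p_threshold, 0.03, tolerance = 1e-10)
  ## degenerate levels
  t1 <- structure(list(t = rep(0, 4), dof = dof, contrast = "all_sounds",
                       dim3 = NULL), class = "t_map")
  expect_equal(fdr_mask(t1, q = 0.05)$n_sig, 0L)
  expect_equal(fdr_mask(tm, q = 1)$n_sig, 4L)
})
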