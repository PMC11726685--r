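test_that("spatial correlation behaves on identical, inverted and independent maps", {
  set.seed(14)
  a <- rnorm(1e4)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a), -1)
  b <- rnorm(1e4)
  expect_lt(abs(spatial_correlation(a, b)), 0.05)
  expect_true(is.na(spatial_correlation(a, rep(1, 1e4))))
  expect_error(spatial_correlation(a[1:2], b[1:2]), "fewer than 3")
})

test_that("split-half reliability handles identical runs, noise runs, and is seeded", {
  set.seed(15)
  base <- rnorm(500)
  same <- cbind(base, base, base, base)
  r1 <- split_half_reliability(same, n_repetitions = 10L, seed = 3L)
  expect_true(all(r1$r > 1 - 1e-9))
  noise <- matrix(rnorm(5000 * 6), ncol = 6)
  rn <- split_half_reliability(noise, n_repetitions = 50L, seed = 4L)
  ## splits reuse the same runs, so the per-split r values are dependent:
  ## bound the mean by 3 x their spread rather than 3 x SE
  expect_lt(abs(rn$z_mean), 3 * sd(rn$r))
  r2 <- split_half_reliability(noise, n_repetitions = 50L, seed = 4L)
  expect_identical(rn$r, r2$r)
  expect_identical(rn$splits, r2$splits)
  expect_error(split_half_reliability(noise[, 1, drop = FALSE]),
               "at least 2")
})

test_that("leave-one-run-out correlates each run against the original reference", {
  set.seed(16)
  base <- rnorm(400)
  runs <- sapply(1:4, function(i) base)
  r <- loro_correlation(runs, runs)
  expect_length(r, 4L)
  expect_true(all(r > 1 - 1e-9))
  ## a pure-noise left-out run decorrelates only its own fold
  noisy <- runs
  noisy[, 2] <- rnorm(400)
  r2 <- loro_correlation(runs, noisy)
  expect_lt(abs(r2[2]), 0.2)
  expect_true(all(r2[-2] > 1 - 1e-9))
  expect_error(loro_correlation(runs[, 1:2], runs[, 1:2]), "at least 3")
})

test_that("the Fisher transform matches atanh and inverts exactly", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("the exhaustive sign-flip test enumerates all assignments exactly", {
  ## all-positive differences across 10 subjects: only the two extreme
  ## assignments reach |mean| = 1
  p <- sign_flip_permutation_test(rep(1, 10))
  expect_equal(p, 2 / 1024)
  ## symmetric differences: observed mean 0, every assignment ties
  expect_equal(sign_flip_permutation_test(c(0.4, -0.4, 1.1, -1.1)), 1)
  ## invariance to subject order
  set.seed(17)
  d <- rnorm(8, mean = 0.5)
  expect_equal(sign_flip_permutation_test(d),
               sign_flip_permutation_test(sample(d)))
  ## resolution is 1/2^n and p in (0, 1]
  p8 <- sign_flip_permutation_test(d)
  expect_equal(round(p8 * 2^8), p8 * 2^8, tolerance = 1e-12)
  expect_gt(p8, 0)
  expect_lte(p8, 1)
  expect_error(sign_flip_permutation_test(numeric(0)), "no differences")
})

test_that("two-level repeated-measures ANOVA equals the squared paired t-test", {
  set.seed(18)
  y <- cbind(rnorm(12, 10), rnorm(12, 10.8))
  res <- rm_anova(y)
  tt <- t.test(y[, 1], y[, 2], paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$epsilon, 1)
  ## location invariance
  res2 <- rm_anova(y + 100)
  expect_equal(res2$F, res$F, tolerance = 1e-10)
})

test_that("repeated-measures ANOVA keeps its type-I error near nominal under the null", {
  set.seed(19)
  pvals <- replicate(500, {
    y <- matrix(rnorm(10 * 3), 10, 3)   # no true strategy effect
    rm_anova(y)$p_gg
  })
  rate <- mean(pvals < 0.05)
  ## binomial 3 SE band around 0.05 (GG is slightly conservative)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
  ## p-values roughly uniform: mean near 0.5
  expect_lt(abs(mean(pvals) - 0.5), 0.08)
})

test_that("two-factor repeated-measures ANOVA reports all three effects", {
  set.seed(20)
  n <- 10
  arr <- array(rnorm(n * 3 * 2), c(n, 3, 2))
  arr[, , 2] <- arr[, , 2] + 1          # factor B main effect
  res <- rm_anova(arr)
  expect_equal(res$effect, c("A", "B", "A:B"))
  expect_lt(res$p[res$effect == "B"], 0.01)
  expect_true(all(res$epsilon <= 1 & res$epsilon > 0))
  expect_error(rm_anova(array(c(arr[, , 1] * NA, arr[, , 2]), c(n, 3, 2))),
               "missing")
})

test_that("beta-vs-tSNR binning summarises differences per bin", {
  set.seed(21)
  ts_vals <- runif(2000, 5, 50)
  expect_true(all(beta_tsnr_bins(rep(0, 2000), ts_vals, 10)$mean_diff == 0))
  ## monotone input gives strictly increasing bin means
  res <- beta_tsnr_bins(ts_vals, ts_vals, 10)
  expect_true(all(diff(res$mean_diff) > 0))
  expect_equal(sum(res$n), 2000L)
  ## equal-width variant covers the same data
  resw <- beta_tsnr_bins(ts_vals, ts_vals, 10, type = "equal_width")
  expect_equal(sum(resw$n), 2000L)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_equal(bonferroni(c(0.2, 0.9), 1), c(0.2, 0.9))
  expect_error(bonferroni(0.1, 0), ">= 1")
})
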