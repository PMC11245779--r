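test_that("a uniform group separation produces one full-cycle cluster", {
  set.seed(21)
  YA <- sim_smooth_field(10, 101, 15)
  YB <- sim_smooth_field(10, 101, 15) + 10
  s <- spm_ttest2(YA, YB)
  expect_equal(nrow(s$clusters), 1)
  expect_equal(s$clusters$start_pct, 0)
  expect_equal(s$clusters$end_pct, 100)
  expect_lte(s$clusters$p, s$alpha)
})

test_that("identical paired conditions give no clusters", {
  set.seed(22)
  Y <- sim_smooth_field(8, 101, 12)
  s <- spm_ttest_paired(Y, Y)
  expect_equal(nrow(s$clusters), 0)
})

test_that("a paired localized bump is detected inside its support", {
  set.seed(23)
  YA <- sim_smooth_field(10, 101, 12)
  g <- seq(0, 100)
  bump <- 8 * exp(-(g - 65)^2 / 50)  # confined to early swing
  YB <- YA + matrix(bump, 10, 101, byrow = TRUE) +
    0.2 * sim_smooth_field(10, 101, 12)
  s <- spm_ttest_paired(YB, YA)
  expect_gte(nrow(s$clusters), 1)
  main <- s$clusters[which.max(s$clusters$extent_nodes), ]
  expect_gt(main$start_pct, 40)
  expect_lt(main$end_pct, 90)
  expect_true(main$start_pct <= 65 && main$end_pct >= 65)
})

test_that("RFT threshold behaves in its limits and is monotone in alpha", {
  expect_equal(rft_threshold(20, 101, Inf, 0.05), qt(1 - 0.025, 20))
  expect_equal(rft_threshold(20, 101, 1e9, 0.05), qt(1 - 0.025, 20),
               tolerance = 1e-6)
  expect_gt(rft_threshold(20, 101, 10, 0.01), rft_threshold(20, 101, 10, 0.05))
  expect_gt(rft_threshold(20, 101, 5, 0.05), rft_threshold(20, 101, 20, 0.05))
  expect_error(rft_threshold(20, 101, 0, 0.05))
})

test_that("RFT threshold matches a permutation oracle on smooth fields", {
  set.seed(24)
  u_rft <- rft_threshold(20, 101, 10, 0.05)
  u_perm <- mean(replicate(10, {
    Y <- sim_smooth_field(22, 101, 10)
    spm_permutation(Y[1:11, ], Y[12:22, ], n_perm = 500,
                    seed = sample.int(1e6, 1))$t_critical
  }))
  expect_lt(abs(u_perm - u_rft) / u_rft, 0.05)
})

test_that("the FWHM estimator recovers known smoothness within 15%", {
  set.seed(25)
  for (w in c(5, 10, 20)) {
    est <- mean(replicate(10, {
      Y <- sim_smooth_field(20, 101, w)
      estimate_fwhm(sweep(Y, 2, colMeans(Y)))
    }))
    expect_lt(abs(est - w) / w, 0.15)
  }
})

test_that("the t continuum is invariant to a common constant shift", {
  set.seed(26)
  YA <- sim_smooth_field(8, 101, 10)
  YB <- sim_smooth_field(9, 101, 10)
  s0 <- spm_ttest2(YA, YB)
  s1 <- spm_ttest2(YA + 100, YB + 100)
  expect_equal(s1$t, s0$t, tolerance = 1e-9)
  expect_equal(s1$t_critical, s0$t_critical, tolerance = 1e-9)
})

test_that("clusters are contiguous, sorted and consistent with the threshold", {
  set.seed(27)
  g <- seq(0, 100)
  signal <- 4 * exp(-(g - 25)^2 / 30) - 4 * exp(-(g - 75)^2 / 30)
  YA <- sim_smooth_field(12, 101, 8) + matrix(signal, 12, 101, byrow = TRUE)
  YB <- sim_smooth_field(12, 101, 8)
  s <- spm_ttest2(YA, YB)
  cl <- s$clusters
  expect_gte(nrow(cl), 2)
  expect_true(all(cl$start_pct < cl$end_pct))
  expect_true(all(diff(cl$start_pct) > 0))
  if (nrow(cl) > 1) expect_true(all(cl$start_pct[-1] >= cl$end_pct[-nrow(cl)]))
  expect_true(all(cl$p > 0 & cl$p <= s$alpha))
  # every node strictly inside a cluster exceeds the threshold
  for (i in seq_len(nrow(cl))) {
    inside <- g > cl$start_pct[i] & g < cl$end_pct[i]
    expect_true(all(abs(s$t[inside]) >= s$t_critical))
  }
})

test_that("permutation SPM is deterministic and agrees with RFT on strong signal", {
  set.seed(28)
  g <- seq(0, 100)
  YA <- sim_smooth_field(12, 101, 12) +
    matrix(6 * exp(-(g - 70)^2 / 80), 12, 101, byrow = TRUE)
  YB <- sim_smooth_field(12, 101, 12)
  p1 <- spm_permutation(YA, YB, n_perm = 500, seed = 99)
  p2 <- spm_permutation(YA, YB, n_perm = 500, seed = 99)
  expect_identical(p1$t_critical, p2$t_critical)
  expect_identical(p1$clusters, p2$clusters)
  r <- spm_ttest2(YA, YB)
  expect_equal(nrow(p1$clusters), nrow(r$clusters))
  expect_lt(max(abs(c(p1$clusters$start_pct - r$clusters$start_pct,
                      p1$clusters$end_pct - r$clusters$end_pct))), 3)
  expect_error(spm_permutation(YA, YB, n_perm = 50), "n_perm")
  expect_error(spm_permutation(YA, YB, n_perm = 100, alpha = 0.001), "too few")
})

test_that("node-wise normality checks are calibrated and catch skew", {
  set.seed(29)
  Y <- matrix(rnorm(25 * 101), 25)
  res <- normality_continuum(Y)
  expect_gte(mean(res$p < 0.05), 0)
  expect_lte(mean(res$p < 0.05), 0.12)
  skew <- exp(2 * matrix(rnorm(25 * 101), 25))
  res2 <- normality_continuum(skew)
  expect_gt(mean(res2$p < 0.05), 0.5)
  expect_true(res2$non_normal)
  expect_error(normality_continuum(Y[1:2, ]), "3 curves")
})

test_that("amplitude normalization maps to [0,1] and is affine-invariant", {
  cy <- template_cycle("preferred", center = FALSE)
  sn <- spatial_normalize(cy)
  expect_equal(range(sn$hip), c(0, 1))
  expect_equal(range(sn$knee), c(0, 1))
  cy2 <- cy
  cy2$hip <- 3 * cy$hip + 40
  expect_equal(spatial_normalize(cy2)$hip, sn$hip, tolerance = 1e-12)
  z <- spatial_normalize(cy, "zscore")
  expect_lt(abs(mean(z$hip)), 1e-9)
  expect_equal(sd(z$hip), 1, tolerance = 1e-9)
  flat <- make_cycle(rep(1, 11), seq_len(11))
  expect_error(spatial_normalize(flat), "zero-ROM")
})

test_that("SPM results print, summarize and serialize", {
  set.seed(30)
  YA <- sim_smooth_field(6, 101, 15) + 5
  YB <- sim_smooth_field(6, 101, 15)
  s <- spm_ttest2(YA, YB)
  expect_output(print(s), "SPM\\{t\\}")
  expect_s3_class(summary(s), "summary.spm_t")
  js <- jsonlite::fromJSON(spm_to_json(s))
  expect_equal(js$df, s$df)
  expect_equal(js$t_critical, s$t_critical, tolerance = 1e-9)
})
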