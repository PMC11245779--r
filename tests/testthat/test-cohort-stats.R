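test_that("z-score outlier rule removes exactly the planted value", {
  set.seed(41)
  x <- as.numeric(scale(rnorm(30)))  # exact mean 0, sd 1
  planted <- c(x, 4)
  res <- remove_outliers(planted, normal = TRUE)
  expect_equal(res$removed, 31L)
  expect_equal(res$method, "zscore")
  # idempotent on its own output
  res2 <- remove_outliers(res$values, normal = TRUE)
  expect_length(res2$removed, 0)
})

test_that("identical values are never flagged as outliers", {
  x <- rep(3.14, 10)
  expect_length(remove_outliers(x, normal = TRUE)$removed, 0)
  expect_length(remove_outliers(x, normal = FALSE)$removed, 0)
  expect_error(remove_outliers(1:3), "n >= 4")
})

test_that("Tukey fences on {1..20, 100} remove only the extreme value", {
  # type-7 quartiles of the 21 values: Q1 = 6, Q3 = 16, IQR = 10,
  # upper fence 31, lower fence -9 (computed by hand)
  x <- c(1:20, 100)
  res <- remove_outliers(x, normal = FALSE)
  expect_equal(res$removed, 21L)
  expect_equal(res$method, "tukey")
  expect_equal(res$values, 1:20)
})

test_that("two-group comparison gates on normality and detects real shifts", {
  set.seed(42)
  a <- rnorm(20)
  same <- compare_two_groups(a, a)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_equal(unname(same$statistic), 0, tolerance = 1e-9)

  # power against a 2 SD shift at the study arm size
  rej <- replicate(200, {
    compare_two_groups(rnorm(29), rnorm(29, 2))$p_value < 0.05
  })
  expect_gt(mean(rej), 0.99)

  # log-normal data routes to the nonparametric branch most of the time
  branch <- replicate(200, {
    compare_two_groups(exp(rnorm(29)), exp(rnorm(29)))$normality_gate
  })
  expect_gt(mean(branch == "non-normal"), 0.8)
  expect_error(compare_two_groups(1:2, 1:5), "n >= 3")
  expect_error(compare_two_groups(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("two-group type-I error is calibrated at the study arm size", {
  set.seed(43)
  rej <- replicate(1000, {
    compare_two_groups(rnorm(29), rnorm(29))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("three-condition comparison handles degenerate, strong and ranked data", {
  m0 <- matrix(rep(rnorm(10), 3), ncol = 3,
               dimnames = list(NULL, c("fast", "preferred", "slow")))
  r0 <- compare_three_conditions(m0)
  expect_equal(r0$p_value, 1)
  expect_null(r0$post_hoc)

  # the within-control hip ROM speed gradient: means 41/36/30ish, SD 5
  set.seed(44)
  hits <- replicate(100, {
    base <- rnorm(29, 0, 5)
    m <- cbind(fast = base + rnorm(29, 0, 2) + 41,
               preferred = base + rnorm(29, 0, 2) + 36,
               slow = base + rnorm(29, 0, 2) + 30)
    r <- compare_three_conditions(m)
    !is.null(r$post_hoc) && all(r$post_hoc$p_adjusted < 0.05)
  })
  expect_gt(mean(hits), 0.9)

  # Friedman branch is invariant to monotone transformations
  set.seed(45)
  m <- matrix(exp(rnorm(45, sd = 2)), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  r1 <- compare_three_conditions(m)
  r2 <- compare_three_conditions(m^3)
  expect_equal(r1$test_name, "Friedman")
  expect_equal(r2$test_name, "Friedman")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)

  expect_error(compare_three_conditions(m[, 1:2]), "3 conditions")
  expect_error(compare_three_conditions(m[1:4, ]), "5 complete-case")
})

test_that("post hoc adjusted p-values never fall below the unadjusted ones", {
  set.seed(46)
  base <- rnorm(20, 0, 3)
  m <- cbind(a = base + 5, b = base + rnorm(20), c = base - 4 + rnorm(20))
  r <- compare_three_conditions(m)
  if (!is.null(r$post_hoc)) {
    expect_true(all(r$post_hoc$p_adjusted >= r$post_hoc$p_unadjusted - 1e-12))
  }
  mm <- matrix(exp(rnorm(60, sd = 1.5)), ncol = 3)
  mm[, 1] <- mm[, 1] * 5
  colnames(mm) <- c("a", "b", "c")
  r2 <- compare_three_conditions(mm)
  if (!is.null(r2$post_hoc)) {
    expect_true(all(r2$post_hoc$p_adjusted >= r2$post_hoc$p_unadjusted - 1e-12))
  }
})

test_that("paired comparison uses the exact signed-rank null for small n", {
  on <- c(5.1, 4.8, 5.6, 5.0, 4.9, 5.3, 5.2, 5.4)
  expect_equal(compare_paired(on, on)$p_value, 1)
  # uniformly signed differences (distinct magnitudes, so the exact null
  # applies), n = 8: exact two-sided p = 2 / 2^8
  off <- on - c(0.31, 0.44, 0.52, 0.23, 0.36, 0.58, 0.61, 0.47)
  expect_equal(compare_paired(on, off)$p_value, 2 / 256)
  # antisymmetric differences carry no evidence
  on2 <- c(1, 2, 3, 4, 5, 6)
  off2 <- on2 + c(-3, -2, -1, 1, 2, 3)
  expect_gt(compare_paired(on2, off2)$p_value, 0.9)
  expect_error(compare_paired(1:5, 1:4), "equal length")
  expect_error(compare_paired(1:4, 1:4), "5 pairs")
})

test_that("chi-squared comparison matches hand-computed tables", {
  # balanced gender counts in two study arms: no detectable difference
  r <- compare_categorical(rbind(c(15, 14), c(18, 11)))
  expect_gt(r$p_value, 0.05)
  r0 <- compare_categorical(rbind(c(7, 3), c(7, 3)))
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p_value, 1)
  r2 <- compare_categorical(rbind(c(10, 0), c(0, 10)))
  expect_equal(unname(r2$statistic), 20)
  expect_lt(r2$p_value, 0.01)
  expect_error(compare_categorical(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(compare_categorical(rbind(c(-1, 2), c(1, 2))), "nonnegative")
})
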