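test_that("ROM handles constants, sinusoids and per-cycle averaging", {
  expect_equal(rom(rep(30, 50)), 0)
  t <- seq(0, 1, length.out = 401)
  expect_equal(rom(20 + 15 * sin(2 * pi * t)), 30, tolerance = 1e-6)
  # trial-level ROM is the mean of per-cycle ranges
  ranges <- c(40, 42, 44, 41, 43)
  cycles <- lapply(ranges, function(r)
    make_cycle(r * seq(0, 1, length.out = 11) - r / 2, rep(0, 11),
               centered = TRUE))
  expect_equal(rom(cycles, "hip"), 42)
  expect_error(rom(numeric(1)), "2 samples")
  # positive homogeneity
  x <- rnorm(60)
  expect_equal(rom(3.7 * x), 3.7 * rom(x))
})

test_that("ACC is exactly 1 for identical cycles and bounded in [0, 1]", {
  cy <- template_cycle("preferred")
  expect_identical(acc(rep(list(cy), 10)), 1)
  set.seed(11)
  for (i in 1:25) {
    M <- sample(2:6, 1)
    n <- sample(5:30, 1)
    cycles <- replicate(M, make_cycle(cumsum(rnorm(n)), cumsum(rnorm(n)),
                                      centered = TRUE), simplify = FALSE)
    a <- acc(cycles)
    expect_gte(a, 0)
    expect_lte(a, 1)
  }
})

test_that("ACC of two cycles with orthogonal segment directions is sqrt(2)/2", {
  n <- 21
  a <- make_cycle(seq_len(n), rep(0, n), centered = TRUE)   # directions (1, 0)
  b <- make_cycle(rep(0, n), seq_len(n), centered = TRUE)   # directions (0, 1)
  expect_equal(acc(list(a, b)), sqrt(2) / 2, tolerance = 1e-12)
})

test_that("ACC of many uniformly random directions is near zero", {
  set.seed(12)
  n <- 41
  cycles <- replicate(100, {
    th <- runif(n - 1, 0, 2 * pi)
    make_cycle(cumsum(c(0, cos(th))), cumsum(c(0, sin(th))), centered = TRUE)
  }, simplify = FALSE)
  expect_lt(acc(cycles), 0.15)
})

test_that("ACC agrees with an independent circular-statistics oracle", {
  set.seed(13)
  for (i in 1:20) {
    M <- sample(2:5, 1)
    n <- sample(4:10, 1)
    cycles <- replicate(M, make_cycle(cumsum(rnorm(n)), cumsum(rnorm(n)),
                                      centered = TRUE), simplify = FALSE)
    expect_equal(acc(cycles), acc_oracle(cycles), tolerance = 1e-9)
  }
})

test_that("consecutive-pair ACC variant equals the resultant form for 2 cycles", {
  cy1 <- sine_cycle(10, 20)
  cy2 <- sine_cycle(10, 20, ph = 0.2)
  expect_equal(acc(list(cy1, cy2), "consecutive"),
               acc(list(cy1, cy2), "resultant"))
  expect_error(acc(list(cy1)), "2 cycles")
})

test_that("SSD follows the RMS-distance convention", {
  cy <- template_cycle("preferred")
  expect_equal(ssd(cy, cy), 0)
  # concentric circles of radius 10 and 12, identical parameterization
  # (101 equispaced phases of the full turn, so each circle is exactly centered)
  t <- (0:100) / 101
  c10 <- make_cycle(10 * cos(2 * pi * t), 10 * sin(2 * pi * t), centered = TRUE)
  c12 <- make_cycle(12 * cos(2 * pi * t), 12 * sin(2 * pi * t), centered = TRUE)
  expect_equal(ssd(c10, c12), 2, tolerance = 1e-9)
  expect_equal(ssd(c10, c12, "sum"), sum(rep(4, 101)), tolerance = 1e-9)
  # symmetry and translation invariance through centering
  expect_equal(ssd(c10, c12), ssd(c12, c10))
  shifted <- template_cycle("preferred", center = FALSE)
  shifted$hip <- shifted$hip + 5
  expect_equal(ssd(mean_center(shifted), cy), 0, tolerance = 1e-12)
})

test_that("SSD satisfies the triangle inequality on the grid metric", {
  set.seed(14)
  for (i in 1:10) {
    mk <- function() make_cycle(rnorm(31), rnorm(31), centered = TRUE)
    a <- mk(); b <- mk(); c <- mk()
    expect_lte(ssd(a, c), ssd(a, b) + ssd(b, c) + 1e-12)
  }
})

test_that("trial-level SSD averages consecutive cycle pairs", {
  cys <- list(sine_cycle(10, 20), sine_cycle(11, 22), sine_cycle(12, 24))
  expect_equal(trial_ssd(cys),
               mean(c(ssd(cys[[1]], cys[[2]]), ssd(cys[[2]], cys[[3]]))))
  expect_error(trial_ssd(cys[1]), "2 cycles")
})

test_that("extremal points of a proportional sinusoid pair are analytic", {
  cy <- sine_cycle(10, 20)
  ex <- extremal_points(cy)
  expect_equal(ex$max$location_pct, 25)
  expect_equal(ex$min$location_pct, 75)
  expect_equal(ex$max$magnitude_deg, sqrt(500), tolerance = 1e-9)
  expect_equal(ex$min$magnitude_deg, sqrt(500), tolerance = 1e-9)
  expect_error(extremal_points(make_cycle(rep(0, 11), rep(0, 11),
                                          centered = TRUE)), "degenerate")
})

test_that("normative templates place extrema in late stance and mid-swing", {
  for (sp in c("slow", "preferred", "fast")) {
    ex <- extremal_points(template_cycle(sp))
    expect_lte(abs(ex$min$location_pct - 46), 2)
    expect_lte(abs(ex$max$location_pct - 76), 1)
  }
})

test_that("speed adaptation ratios are correct arithmetic", {
  cy <- template_cycle("preferred")
  m <- trial_metrics(list(cy, cy))
  same <- speed_adaptation_ratio(m, m)
  expect_equal(same$ratio_min, 1)
  expect_equal(same$ratio_max, 1)
  expect_equal(same$ratio_of_ratios, 1)
  a <- m; b <- m
  a$min_mag <- 12; b$min_mag <- 10
  a$max_mag <- 11; b$max_mag <- 10
  r <- speed_adaptation_ratio(a, b)
  expect_equal(r$ratio_of_ratios, 1.2 / 1.1, tolerance = 1e-12)
  # uniform scaling of both joints cancels in the ratio of ratios
  sc <- template_cycle("preferred")
  sc$hip <- 1.3 * sc$hip
  sc$knee <- 1.3 * sc$knee
  ms <- trial_metrics(list(sc, sc))
  rs <- speed_adaptation_ratio(ms, m)
  expect_equal(rs$ratio_min, 1.3, tolerance = 1e-9)
  expect_equal(rs$ratio_of_ratios, 1, tolerance = 1e-9)
  b$min_mag <- 0
  expect_error(speed_adaptation_ratio(a, b), "zero")
})

test_that("a ratio maps to a percent difference as (r - 1) * 100", {
  expect_equal(ratio_percent_difference(1.2), 20)
  expect_equal(ratio_percent_difference(c(1, 2)), c(0, 100))
  expect_error(ratio_percent_difference(-1))
})

test_that("ACC and SSD are invariant to constant joint offsets via centering", {
  tr <- simulate_trial(gait_template("preferred"), effect_config(),
                       n_cycles = 4, seed = 6)
  shifted <- tr
  shifted$hip <- shifted$hip + 40
  shifted$knee <- shifted$knee - 15
  m0 <- trial_metrics(prep_trial(tr))
  m1 <- trial_metrics(prep_trial(shifted))
  expect_equal(m1$acc, m0$acc, tolerance = 1e-12)
  expect_equal(m1$ssd, m0$ssd, tolerance = 1e-12)
})
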