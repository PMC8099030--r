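test_that("region z-scoring is exact, idempotent and reports bad regions", {
  arr <- array(rnorm(4 * 4 * 50), c(4, 4, 50))
  m <- zscore_regions(lattice_movie(arr, 0.1))
  mu <- apply(m$values, c(1, 2), mean)
  sd_pop <- sqrt(apply(m$values, c(1, 2), function(x) mean((x - mean(x))^2)))
  expect_lt(max(abs(mu)), 1e-9)
  expect_lt(max(abs(sd_pop - 1)), 1e-6)
  expect_identical(zscore_regions(m), m)

  # closed form on a single region
  arr1 <- array(rep(c(1, 2, 3), each = 1), c(1, 1, 3))
  z <- zscore_regions(lattice_movie(arr1, 1))
  expect_equal(as.numeric(z$values), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  arr[2, 3, ] <- 7
  expect_error(zscore_regions(lattice_movie(arr, 0.1)), "\\(2, 3\\)")
})

test_that("block averaging halves the lattice and conserves the mean", {
  # constant field stays constant
  m <- lattice_movie(array(2.5, c(4, 4, 3)), 0.1)
  cg <- coarse_grain_step(m)
  expect_true(all(cg$values == 2.5))
  expect_identical(dim(cg$values), c(2L, 2L, 3L))
  expect_identical(cg$level, 1L)

  # worked 2x2 frame (repeated so the movie has two samples)
  fr <- array(rep(c(1, 5, 3, 7), 2), c(2, 2, 2))
  expect_equal(as.numeric(coarse_grain_step(lattice_movie(fr, 1))$values),
               c(4, 4))

  # spatial mean is invariant frame by frame
  arr <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  m8 <- lattice_movie(arr, 0.1)
  cg8 <- coarse_grain_step(m8)
  expect_equal(apply(cg8$values, 3, mean), apply(arr, 3, mean),
               tolerance = 1e-12)

  expect_error(coarse_grain_step(lattice_movie(array(0, c(3, 3, 2)), 1)),
               "even")
})

test_that("a 64-lattice coarse-grains through the full level sequence", {
  m <- lattice_movie(array(rnorm(64 * 64 * 2), c(64, 64, 2)), 0.1)
  hier <- coarse_grain_hierarchy(m)
  expect_identical(vapply(hier, function(x) dim(x$values)[1], integer(1)),
                   c(64L, 32L, 16L, 8L, 4L, 2L))
  expect_identical(vapply(hier, function(x) x$level, integer(1)), 0:5)
})

test_that("time correlation matches analytic forms", {
  # independent white-noise regions decorrelate immediately
  m <- zscore_regions(lattice_movie(array(rnorm(8 * 8 * 500), c(8, 8, 500)), 1))
  prof <- time_correlation(m, max_lag = 10)
  expect_equal(prof$values[1], 1, tolerance = 1e-9)
  expect_lt(max(abs(prof$values[-1])), 3 / sqrt(64 * 500))

  # a cosine over whole periods autocorrelates as a cosine
  tt <- (0:999) * 0.02 * pi
  arr <- array(cos(tt), c(1, 1, 1000))
  mc <- zscore_regions(lattice_movie(arr, 0.02 * pi))
  pc <- time_correlation(mc, max_lag = 200)
  expect_lt(max(abs(pc$values - cos(pc$lags))), 0.05)

  # Ornstein-Uhlenbeck field with timescale 2
  mou <- zscore_regions(ou_lattice(8, 4000, 0.05, tau = 2, seed = 8))
  pou <- time_correlation(mou, max_lag = 80)
  expect_lt(max(abs(pou$values - exp(-pou$lags / 2))), 0.05)

  expect_error(time_correlation(mou, max_lag = 4000), "max_lag")
})

test_that("decay times are located by interpolation and verified by a root finder", {
  lags <- seq(0, 10, 0.01)
  expect_equal(decay_time(list(lags = lags, values = exp(-lags / 2))), 2,
               tolerance = 0.01 / 2)

  # linear profile: 1 - t/2 crosses 1/e at 2 (1 - 1/e)
  lagl <- seq(0, 1.9, 0.001)
  expect_equal(decay_time(list(lags = lagl, values = 1 - lagl / 2)),
               2 * (1 - exp(-1)), tolerance = 1e-3)

  # oscillatory decay against an independent root-finding oracle
  f <- function(t) exp(-t) * cos(0.1 * t)
  lagf <- seq(0, 5, 0.002)
  t_star <- uniroot(function(t) f(t) - f(0) / exp(1), c(0.5, 2), tol = 1e-10)$root
  expect_equal(decay_time(list(lags = lagf, values = f(lagf))), t_star,
               tolerance = 1e-3)

  expect_error(decay_time(list(lags = c(0, 1), values = c(1, 0.9))),
               "never decays")
})

test_that("the critical exponent follows from per-level decay times", {
  # two constructed levels with decay times 1 and 2 give z = 1
  m0 <- ou_lattice(8, 6000, 0.05, tau = 1, seed = 1)
  m1 <- ou_lattice(8, 6000, 0.05, tau = 2, seed = 2)
  m1$level <- 1L
  est <- estimate_z_correlation(list(m0, m1))
  expect_equal(est$z, 1, tolerance = 0.1)
  expect_identical(est$method, "correlation")
  expect_length(est$per_level_decay_times, 2)

  # identical statistics at both levels: z = 0
  m1b <- ou_lattice(8, 6000, 0.05, tau = 1, seed = 3)
  m1b$level <- 1L
  expect_lt(abs(estimate_z_correlation(list(m0, m1b))$z), 0.1)

  expect_error(estimate_z_correlation(list(m0)), "two levels")
})
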