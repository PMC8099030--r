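test_that("trajectory rescaling matches closed forms", {
  tt <- seq(0, 60, 0.01)
  tr <- timeseries(rbind(cos(tt), sin(tt)), dt = 0.01)

  # identity scale
  id <- scale_trajectory(tr, scale_params(b = 1, alpha = -1.5))
  expect_equal(id$values, tr$values, tolerance = 1e-9)

  # circular orbit, b = 4, alpha = -3/2: amplitude x4, period x8
  sc <- scale_trajectory(tr, scale_params(b = 4, alpha = -1.5))
  expect_equal(sc$values[1, ], 4 * cos(tt / 8), tolerance = 1e-6)
  expect_equal(sc$values[2, ], 4 * sin(tt / 8), tolerance = 1e-6)
})

test_that("a rescaled Kepler orbit still satisfies the equation of motion", {
  # simulate a two-body ellipse and rescale the cartesian trajectory;
  # the finite-difference residual of the inverse-square law must vanish
  # at alpha = -3/2 and only there
  G <- 1; M <- 1e5
  a_th <- 1.25
  T_th <- 2 * pi * sqrt(a_th^3 / (G * M))
  # perihelion r = 1 of an a = 1.25, e = 0.2 ellipse: v^2 = GM (1 + e) / r
  sys <- orbit_system(c(M, 1), rbind(c(0, 0), c(1, 0)),
                      rbind(c(0, 0), c(0, sqrt(G * M * 1.2))), G = G)
  run <- simulate_nbody(sys, duration = 3 * T_th, dt = T_th / 20000,
                        record_every = 10L)
  xy <- timeseries(rbind(run$positions[2, 1, ], run$positions[2, 2, ]), run$dt)

  newton_residual <- function(traj) {
    v <- traj$values; h <- traj$dt
    n <- ncol(v)
    acc <- (v[, 3:n] - 2 * v[, 2:(n - 1)] + v[, 1:(n - 2)]) / h^2
    pos <- v[, 2:(n - 1)]
    r3 <- colSums(pos^2)^1.5
    force <- -G * M * sweep(pos, 2, r3, "/")
    max(abs(acc - force)) / max(abs(force))
  }
  expect_lt(newton_residual(xy), 1e-3)

  res <- vapply(c(-2.5, -2, -1.5, -1, -0.5), function(a) {
    newton_residual(scale_trajectory(xy, scale_params(b = 2, alpha = a)))
  }, numeric(1))
  expect_lt(res[3], 1e-3)                       # alpha = -3/2
  expect_identical(which.min(res), 3L)          # and only there
  expect_true(all(res[-3] > 0.05))
})

test_that("input rescaling shifts timing but not amplitude", {
  dt <- 0.01
  # all-zero inputs stay zero
  z <- input_series(matrix(0, 1, 500), dt)
  expect_true(all(scale_inputs(z, scale_params(2, -1))$values == 0))

  # a bump at t = 2 moves to t = 4 under b = 2, alpha = -1
  tt <- (0:999) * dt
  bump <- exp(-(tt - 2)^2 / (2 * 0.05^2))
  v <- scale_inputs(input_series(rbind(bump), dt), scale_params(2, -1))
  expect_equal(tt[which.max(v$values)], 4, tolerance = 2 * dt)
  expect_equal(max(v$values), 1, tolerance = 1e-6)

  # sinusoid frequency maps to b^alpha * f (spectral peak oracle)
  f0 <- 5
  sine <- sin(2 * pi * f0 * tt)
  v2 <- scale_inputs(input_series(rbind(sine), dt), scale_params(2, -1))
  spec <- stats::spec.pgram(as.numeric(v2$values), plot = FALSE, taper = 0)
  f_peak <- spec$freq[which.max(spec$spec)] / dt
  expect_equal(f_peak, f0 / 2, tolerance = 0.1)
})

test_that("connectivity rescaling follows the uniform and per-node laws", {
  A <- matrix(c(-1, 0.2, 0.5, -1), 2)
  C <- matrix(c(1, 0), 2, 1)

  id <- scale_connectivity(A, C, scale_params(1, -1.5))
  expect_equal(id$A, A)
  expect_equal(id$C, C)

  sc <- scale_connectivity(A, C, scale_params(4, -1.5))
  expect_equal(sc$A, matrix(c(-0.125, 0.025, 0.0625, -0.125), 2))
  expect_equal(sc$C, 4^(-0.5) * C)

  # per-node factors all equal reduce exactly to the uniform law
  set.seed(1)
  A3 <- matrix(rnorm(9), 3)
  C3 <- matrix(rnorm(9), 3)
  pn <- scale_connectivity(A3, C3, scale_params(2, -1, b_per_node = c(2, 2, 2)))
  un <- scale_connectivity(A3, C3, scale_params(2, -1))
  expect_equal(pn$A, un$A, tolerance = 1e-12)
  expect_equal(pn$C, un$C, tolerance = 1e-12)

  expect_error(scale_connectivity(A, C, scale_params(2, -1, b_per_node = c(1, 2, 3))),
               "one entry per node")
})

test_that("scaling operations compose multiplicatively", {
  tt <- seq(0, 40, 0.01)
  tr <- timeseries(rbind(cos(tt) * exp(-tt / 30)), dt = 0.01)
  p1 <- scale_params(1.5, -1); p2 <- scale_params(2, -1)
  both <- scale_trajectory(scale_trajectory(tr, p1), p2)
  once <- scale_trajectory(tr, scale_params(3, -1))
  expect_equal(both$values, once$values, tolerance = 1e-6)

  A <- matrix(c(-1, 0.2, 0.5, -1), 2)
  s_both <- scale_connectivity(scale_connectivity(A, NULL, p1)$A, NULL, p2)
  s_once <- scale_connectivity(A, NULL, scale_params(3, -1))
  expect_equal(s_both$A, s_once$A, tolerance = 1e-12)
})

test_that("the rescaled model reproduces the rescaled solution", {
  # integrating (b^alpha A, b^(alpha+1) C) with time-rescaled inputs from
  # b * x0 must equal the rescaled original solution
  A <- matrix(c(-1, 0.3, -0.2, -0.8), 2)
  C <- matrix(c(0.8, 0.1), 2, 1)
  dt <- 0.05; Tn <- 400
  p <- scale_params(2, -1)

  # autonomous case: exact up to interpolation
  y0 <- integrate_model(dcm_model(A), x0 = c(0.5, -0.2), n_samples = Tn, dt = dt)
  y_s <- integrate_model(dcm_model(scale_connectivity(A, NULL, p)$A),
                         x0 = c(0.5, -0.2) * 2, n_samples = Tn, dt = dt)
  expect_lt(max(abs(y_s$values - scale_trajectory(y0, p)$values)), 1e-6)

  # driven case: piecewise-constant input discretisation bounds the error
  u <- matrix(sin((0:(Tn - 1)) * dt), 1)
  inp <- input_series(u, dt)
  v_s <- scale_inputs(inp, p)
  y0d <- integrate_model(dcm_model(A, C), x0 = c(0.5, -0.2), inputs = inp,
                         n_samples = Tn, dt = dt)
  sc <- scale_connectivity(A, C, p)
  y_sd <- integrate_model(dcm_model(sc$A, sc$C), x0 = c(0.5, -0.2) * 2,
                          inputs = v_s, n_samples = ncol(v_s$values), dt = dt)
  ref <- scale_trajectory(y0d, p)
  n <- min(ncol(y_sd$values), ncol(ref$values))
  expect_lt(max(abs(y_sd$values[, 1:n] - ref$values[, 1:n])), 0.02)
})

test_that("exponent conversions and the Kepler exponent are exact", {
  expect_identical(kepler_alpha(), -1.5)
  for (b in c(2, 10)) expect_equal(b^(2 * kepler_alpha() + 3), 1)

  expect_identical(alpha_from_z(1.5), -1.5)
  expect_identical(alpha_from_z(0), 0)
  set.seed(3)
  z <- runif(100, -3, 3)
  expect_identical(z_from_alpha(alpha_from_z(z[1])), z[1])
  expect_equal(vapply(z, function(zz) z_from_alpha(alpha_from_z(zz)), numeric(1)), z)
})

test_that("time rescaling truncates rather than extrapolates", {
  tr <- timeseries(rbind(sin(seq(0, 10, 0.01))), dt = 0.01)
  expect_warning(out <- scale_trajectory(tr, scale_params(2, 0.5)), "truncated")
  expect_lt(ncol(out$values), ncol(tr$values))
})
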