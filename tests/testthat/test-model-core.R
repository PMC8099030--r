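test_that("noiseless integration matches closed forms and an ODE oracle", {
  # zero generator: identity flow
  y <- integrate_model(dcm_model(matrix(0)), x0 = 1, n_samples = 20, dt = 0.3)
  expect_equal(as.numeric(y$values), rep(1, 20))

  # scalar exponential decay
  y <- integrate_model(dcm_model(matrix(-1)), x0 = 1, n_samples = 101, dt = 0.01)
  expect_equal(y$values[1, 101], exp(-1), tolerance = 1e-10)

  # one-step propagation equals the matrix exponential exactly
  A <- matrix(c(-1, 0.2, 0.5, -1), 2)
  y2 <- integrate_model(dcm_model(A), x0 = c(1, 0), n_samples = 2, dt = 0.13)
  expect_equal(y2$values[, 2],
               as.numeric(Matrix::expm(Matrix::Matrix(A * 0.13)) %*% c(1, 0)),
               tolerance = 1e-12)

  # full trajectory against an independent adaptive-step ODE integration
  dt <- 0.01
  y3 <- integrate_model(dcm_model(A), x0 = c(1, 0),
                        n_samples = 501, dt = dt)
  sol <- deSolve::ode(y = c(1, 0), times = seq(0, 5, dt),
                      func = function(t, x, p) list(as.numeric(A %*% x)),
                      parms = NULL, rtol = 1e-12, atol = 1e-12)
  expect_lt(max(abs(t(sol[, 2:3]) - y3$values)), 1e-6)
})

test_that("stochastic integration is reproducible and respects smoothness", {
  m <- dcm_model(matrix(-1), noise_sd = 0.3, noise_smoothness = 0.2)
  a <- integrate_model(m, 0, n_samples = 200, dt = 0.05, seed = 4)
  b <- integrate_model(m, 0, n_samples = 200, dt = 0.05, seed = 4)
  d <- integrate_model(m, 0, n_samples = 200, dt = 0.05, seed = 5)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, d$values))
  # smoothed noise decorrelates more slowly than white noise
  mw <- dcm_model(matrix(-1), noise_sd = 0.3)
  w <- integrate_model(mw, 0, n_samples = 2000, dt = 0.05, seed = 4)
  s <- integrate_model(m, 0, n_samples = 2000, dt = 0.05, seed = 4)
  ac1 <- function(x) cor(x[-length(x)], x[-1])
  expect_gt(ac1(s$values[1, ]), ac1(w$values[1, ]))
})

test_that("integration validates dimensions and inputs", {
  expect_error(integrate_model(dcm_model(matrix(-1)), x0 = c(1, 2),
                               n_samples = 10, dt = 0.1), "length")
  m <- dcm_model(matrix(-1), C = matrix(1))
  expect_error(integrate_model(m, 0, n_samples = 10, dt = 0.1),
               "none were supplied")
})

test_that("variational Laplace reproduces the conjugate Gaussian posterior", {
  # linear forward model with known noise precision: the Laplace scheme
  # must agree with the closed-form Bayesian linear regression, and its
  # free energy with the exact log evidence
  for (p in c(1L, 2L)) {
    set.seed(p)
    n <- 60
    X <- matrix(rnorm(n * p), n, p)
    b <- rnorm(p)
    tau <- 16
    y <- X %*% b + rnorm(n, sd = 1 / sqrt(tau))
    m0 <- rep(0.2, p); S0 <- diag(0.7, p)
    fit <- variational_laplace(y, function(th) as.numeric(X %*% th),
                               m0, S0, noise_precision = tau)
    S_post <- solve(tau * crossprod(X) + solve(S0))
    m_post <- S_post %*% (tau * crossprod(X, y) + solve(S0) %*% m0)
    Sy <- X %*% S0 %*% t(X) + diag(1 / tau, n)
    log_ev <- -0.5 * (n * log(2 * pi) +
                        as.numeric(determinant(Sy)$modulus) +
                        as.numeric(t(y - X %*% m0) %*% solve(Sy, y - X %*% m0)))
    expect_lt(max(abs(fit$mean - m_post)), 1e-6)
    expect_lt(max(abs(fit$cov - S_post)), 1e-6)
    expect_lt(abs(fit$F - log_ev), 1e-3)
    expect_true(fit$converged)
  }
})

test_that("model inversion recovers generating parameters", {
  # noiseless scalar decay
  y <- integrate_model(dcm_model(matrix(-1)), x0 = 1, n_samples = 500, dt = 0.05)
  post <- invert_model(y, priors = prior_spec(1))
  expect_lt(abs(post$mean_A[1, 1] + 1), 0.05)
  expect_true(post$converged)
  # free energy is monotone over accepted iterations
  expect_true(all(diff(post$F_trace) >= -1e-9))
})

test_that("delta priors pin the posterior at the prior mean", {
  y <- integrate_model(dcm_model(matrix(-2)), x0 = 1, n_samples = 50, dt = 0.1)
  pri <- prior_spec(1, var_A = matrix(0, 1, 1), mean_A = matrix(-0.7))
  post <- invert_model(y, priors = pri)
  expect_identical(post$mean_A, matrix(-0.7))
})

test_that("parameter recovery holds across random stable systems", {
  # 2x2 systems, diagonal -1, off-diagonals in [-0.5, 0.5], state noise
  # sd 0.05, 1000 samples; root-mean-square error over replicates < 0.1
  errs <- c()
  f_monotone <- TRUE
  for (rep in 1:20) {
    set.seed(rep)
    A <- matrix(c(-1, runif(1, -0.5, 0.5), runif(1, -0.5, 0.5), -1), 2)
    if (any(Re(eigen(A, only.values = TRUE)$values) >= 0)) next
    y <- integrate_model(dcm_model(A, noise_sd = 0.05), x0 = c(1, -1),
                         n_samples = 1000, dt = 0.5, seed = rep)
    post <- invert_model(y, priors = prior_spec(2))
    errs <- c(errs, as.numeric(post$mean_A - A))
    f_monotone <- f_monotone && all(diff(post$F_trace) >= -1e-9)
  }
  expect_lt(sqrt(mean(errs^2)), 0.1)
  expect_true(f_monotone)
})

test_that("inversion signals unusable designs", {
  y <- timeseries(matrix(rnorm(4), 2, 2), dt = 0.1)
  expect_error(invert_model(y, priors = prior_spec(2)),
               "at least as many observations")
  expect_error(invert_model(y, priors = prior_spec(3)), "disagree")
})

test_that("Bayesian model averaging combines moments under softmax weights", {
  A <- matrix(c(-1, 0.1, -0.2, -1), 2)
  P <- synthetic_posterior(A, sd = 0.05, F = -10)
  # idempotence
  avg <- bayesian_model_average(list(P, P, P))
  expect_equal(avg$mean_A, P$mean_A)
  expect_equal(avg$cov, P$cov, tolerance = 1e-12)
  expect_equal(avg$F, P$F, tolerance = 1e-12)

  # equal evidence: plain average of the means
  P1 <- synthetic_posterior(matrix(-1), F = 3)
  P2 <- synthetic_posterior(matrix(-3), F = 3)
  expect_equal(bayesian_model_average(list(P1, P2))$mean_A[1, 1], -2)

  # 20 nats of evidence difference: the winner takes all
  P2$F <- P1$F - 20
  expect_lt(abs(bayesian_model_average(list(P1, P2))$mean_A[1, 1] + 1), 1e-6)

  expect_error(bayesian_model_average(list()), "empty")
  expect_error(bayesian_model_average(list(P, P1)), "inconsistent")
})

test_that("input coupling is estimable when its prior is free", {
  set.seed(2)
  A <- matrix(c(-1, 0.3, -0.2, -0.8), 2)
  C <- matrix(c(0.8, 0.1), 2, 1)
  u <- matrix(sin(seq(0, 20, length.out = 400)), 1)
  inp <- input_series(u, 0.05)
  y <- integrate_model(dcm_model(A, C, noise_sd = 0.02), x0 = c(0.5, -0.2),
                       inputs = inp, n_samples = 400, dt = 0.05, seed = 5)
  pri <- prior_spec(2, n_inputs = 1, var_C = matrix(1, 2, 1))
  post <- invert_model(y, inp, pri)
  expect_lt(max(abs(post$mean_C - C)), 0.15)
  expect_lt(max(abs(post$mean_A - A)), 0.2)
})
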