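# priors that fix the input matrix at the identity (used when inverting
# the perturbation-driven scalable families)
identity_input_priors <- function(N) {
  prior_spec(N, n_inputs = N, mean_C = diag(N), var_C = matrix(0, N, N))
}

# hand-built posterior with tight marginals, for evidence-module tests
synthetic_posterior <- function(A, sd = 0.01, F = 0) {
  N <- nrow(A)
  structure(list(
    mean_A = A, mean_C = NULL, cov = diag(sd^2, N * N),
    free_A = seq_len(N * N), free_C = integer(0),
    F = F, lambda = 0, converged = TRUE, n_iter = 1L,
    F_trace = numeric(0), n_states = N), class = "dcm_posterior")
}

# small independent-OU lattice movie (every region an AR(1) with the same
# timescale), handy for correlation tests
ou_lattice <- function(L, n_samples, dt, tau, seed) {
  set.seed(seed)
  phi <- exp(-dt / tau)
  arr <- array(0, c(L, L, n_samples))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    x <- numeric(n_samples)
    x[1] <- rnorm(1)
    innov <- rnorm(n_samples - 1, sd = sqrt(1 - phi^2))
    for (t in seq_len(n_samples - 1)) x[t + 1] <- phi * x[t] + innov[t]
    arr[i, j, ] <- x
  }
  lattice_movie(arr, dt)
}

# orbital period from the unwrapped polar angle of a body (independent of
# the radial-distance machinery under test)
period_from_angle <- function(run, body = 2L, centre = 1L) {
  px <- run$positions[body, 1, ] - run$positions[centre, 1, ]
  py <- run$positions[body, 2, ] - run$positions[centre, 2, ]
  th <- atan2(py, px)
  thu <- th + 2 * pi * cumsum(c(0, diff(th) < -pi)) -
    2 * pi * cumsum(c(0, diff(th) > pi))
  tt <- run$times
  2 * pi / unname(coef(lm(thu ~ tt))[2])
}
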