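#' Linear stochastic state-space (DCM) model
#'
#' The generative model is the linear stochastic differential equation
#' \deqn{dx/dt = A x(t) + C v(t) + \omega(t),}
#' where `A` is the intrinsic coupling matrix (units 1/time), `C` couples
#' `m` exogenous inputs into the states, and `\omega` is a random
#' fluctuation term. Models intended to generate decaying activity should
#' have eigenvalues of `A` with non-positive real part; the constructor
#' warns otherwise.
#'
#' @param A numeric `N x N` intrinsic coupling matrix.
#' @param C numeric `N x m` extrinsic coupling matrix, or `NULL` for an
#'   autonomous system.
#' @param noise_sd standard deviation of the state fluctuations (signal
#'   units per sqrt(time)); 0 gives deterministic dynamics.
#' @param noise_smoothness temporal correlation length of the fluctuations
#'   (time units); 0 means white noise. Non-zero values give the smooth,
#'   non-Markovian fluctuations appropriate for biological timeseries.
#' @return An object of class `dcm_model`.
#' @export
dcm_model <- function(A, C = NULL, noise_sd = 0, noise_smoothness = 0) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (!all(is.finite(A))) stop("A must be finite")
  if (!is.null(C)) {
    C <- as.matrix(C)
    if (nrow(C) != nrow(A)) stop("C must have as many rows as A")
    if (!all(is.finite(C))) stop("C must be finite")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_smoothness < 0) stop("noise_smoothness must be >= 0")
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) > 1e-12))
    warning("A has eigenvalues with positive real part; trajectories will grow")
  structure(list(A = A, C = C, noise_sd = noise_sd,
                 noise_smoothness = noise_smoothness),
            class = "dcm_model")
}

#' @export
print.dcm_model <- function(x, ...) {
  cat(sprintf("<dcm_model> %d state(s), %d input(s), noise_sd = %g\n",
              nrow(x$A), if (is.null(x$C)) 0L else ncol(x$C), x$noise_sd))
  invisible(x)
}

#' Prior specification for model inversion
#'
#' Element-wise Gaussian priors over `A` and `C`. A prior variance of 0
#' fixes the corresponding parameter at its prior mean. The default prior
#' used throughout the package puts mean -1 on the diagonal of `A`
#' (self-inhibition, guaranteeing decay a priori), 0 off the diagonal, and
#' variance 1 everywhere.
#'
#' @param n_states number of states `N`.
#' @param n_inputs number of inputs `m` (0 for autonomous models).
#' @param mean_A,var_A `N x N` matrices of prior means / variances.
#' @param mean_C,var_C `N x m` matrices; default variance 0 fixes `C`
#'   (used for neural data where inputs have been regressed out).
#' @return An object of class `dcm_priors`.
#' @export
prior_spec <- function(n_states,
                       n_inputs = 0L,
                       mean_A = NULL, var_A = NULL,
                       mean_C = NULL, var_C = NULL) {
  N <- as.integer(n_states)
  m <- as.integer(n_inputs)
  if (is.null(mean_A)) mean_A <- diag(-1, N)
  if (is.null(var_A)) var_A <- matrix(1, N, N)
  mean_A <- as.matrix(mean_A); var_A <- as.matrix(var_A)
  stopifnot(all(dim(mean_A) == c(N, N)), all(dim(var_A) == c(N, N)))
  if (any(var_A < 0)) stop("prior variances must be >= 0")
  if (m > 0L) {
    if (is.null(mean_C)) mean_C <- matrix(0, N, m)
    if (is.null(var_C)) var_C <- matrix(0, N, m)
    mean_C <- as.matrix(mean_C); var_C <- as.matrix(var_C)
    stopifnot(all(dim(mean_C) == c(N, m)), all(dim(var_C) == c(N, m)))
    if (any(var_C < 0)) stop("prior variances must be >= 0")
  } else {
    mean_C <- NULL; var_C <- NULL
  }
  structure(list(n_states = N, n_inputs = m,
                 mean_A = mean_A, var_A = var_A,
                 mean_C = mean_C, var_C = var_C),
            class = "dcm_priors")
}

# exact discrete-time propagator over one step of length dt for
# dx/dt = A x + C v with v held constant over the step:
#   x[t+1] = Ad x[t] + Bd v[t]
# computed from the exponential of the augmented matrix [[A, C], [0, 0]].
.propagator <- function(A, C, dt) {
  N <- nrow(A)
  if (is.null(C) || ncol(C) == 0L) {
    Ad <- as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
    return(list(Ad = Ad, Bd = NULL))
  }
  m <- ncol(C)
  aug <- rbind(cbind(A, C), matrix(0, m, N + m))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(aug * dt)))
  list(Ad = E[seq_len(N), seq_len(N), drop = FALSE],
       Bd = E[seq_len(N), N + seq_len(m), drop = FALSE])
}

# Gaussian-kernel smoothing of white noise rows; kernel normalized to unit
# l2 norm so the marginal variance of the noise is preserved.
.smooth_noise <- function(W, width_samples) {
  if (width_samples <= 0) return(W)
  half <- max(1L, ceiling(3 * width_samples))
  k <- stats::dnorm(seq(-half, half), sd = width_samples)
  k <- k / sqrt(sum(k^2))
  t(apply(W, 1L, function(w) {
    stats::filter(c(rev(w[seq_len(half)]), w, rev(w[length(w) - seq_len(half) + 1L])),
                  k, sides = 2L)[half + seq_along(w)]
  }))
}

#' Integrate the linear state-space model
#'
#' Propagates `dx/dt = A x + C v (+ noise)` from an initial state.
#' The deterministic part uses the exact matrix-exponential propagator per
#' sample step (no discretisation error for piecewise-constant inputs).
#' When `noise_sd > 0` and a seed is given, stochastic integration uses
#' Euler-Maruyama on a grid refined by `substeps`, with the fluctuation
#' term optionally smoothed in time (non-Markovian noise), then subsampled
#' back to `dt`.
#'
#' @param model a [dcm_model()].
#' @param x0 initial state vector, length `N`.
#' @param inputs a [input_series()] with at least `n_samples` columns, or
#'   `NULL` for autonomous dynamics.
#' @param n_samples number of samples to return (including the initial
#'   state).
#' @param dt sampling interval.
#' @param seed integer RNG seed; required when `noise_sd > 0`.
#' @param substeps Euler-Maruyama refinement for the stochastic path.
#' @return A [timeseries()] with `n_samples` columns.
#' @examples
#' m <- dcm_model(A = matrix(-1))
#' y <- integrate_model(m, x0 = 1, n_samples = 11, dt = 0.1)
#' y$values[11]             # e^(-1)
#' @export
integrate_model <- function(model, x0, inputs = NULL, n_samples, dt,
                            seed = NULL, substeps = 10L) {
  stopifnot(inherits(model, "dcm_model"))
  N <- nrow(model$A)
  x0 <- as.numeric(x0)
  if (length(x0) != N) stop("x0 must have length ", N)
  if (n_samples < 2L) stop("n_samples must be >= 2")
  if (dt <= 0) stop("dt must be positive")
  m <- if (is.null(model$C)) 0L else ncol(model$C)
  V <- NULL
  if (m > 0L) {
    if (is.null(inputs)) stop("model has inputs but none were supplied")
    stopifnot(inherits(inputs, "dcm_inputs"))
    if (nrow(inputs$values) != m) stop("inputs must have ", m, " rows")
    if (ncol(inputs$values) < n_samples)
      stop("inputs must cover at least n_samples samples")
    V <- inputs$values
  }

  stochastic <- model$noise_sd > 0 && !is.null(seed)
  X <- matrix(0, N, n_samples)
  X[, 1L] <- x0

  if (!stochastic) {
    pr <- .propagator(model$A, model$C, dt)
    for (t in seq_len(n_samples - 1L)) {
      X[, t + 1L] <- pr$Ad %*% X[, t]
      if (m > 0L) X[, t + 1L] <- X[, t + 1L] + pr$Bd %*% V[, t]
    }
  } else {
    set.seed(as.integer(seed))
    h <- dt / substeps
    n_fine <- (n_samples - 1L) * substeps
    W <- matrix(stats::rnorm(N * n_fine), N, n_fine)
    W <- .smooth_noise(W, model$noise_smoothness / h)
    x <- x0
    for (t in seq_len(n_fine)) {
      drift <- model$A %*% x
      if (m > 0L) {
        vi <- V[, min(((t - 1L) %/% substeps) + 1L, ncol(V)), drop = FALSE]
        drift <- drift + model$C %*% vi
      }
      x <- x + h * drift + model$noise_sd * sqrt(h) * W[, t]
      if (t %% substeps == 0L) X[, t %/% substeps + 1L] <- x
    }
  }
  timeseries(X, dt)
}
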