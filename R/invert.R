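#' Variational Laplace for a Gaussian-noise forward model
#'
#' Maximises a variational free-energy bound on the log evidence of the
#' model `y = f(theta) + e`, `e ~ N(0, exp(-lambda) I)`, under a Gaussian
#' prior on `theta`, using Gauss-Newton ascent with step halving. The log
#' noise precision `lambda` is either fixed (known-precision regression)
#' or updated to its conditional mode under a flat hyperprior.
#'
#' The returned free energy is the Laplace approximation to the log model
#' evidence,
#' \deqn{F = \log p(y | \theta^*) + \log p(\theta^*) +
#'       \tfrac{1}{2}\log|2\pi\Sigma_{post}| (+ \lambda\ term),}
#' which is exact for models linear in `theta` with known precision.
#' `F` never decreases across accepted iterations.
#'
#' @param y numeric vector of observations.
#' @param f forward function `theta -> predicted y`.
#' @param prior_mean,prior_cov Gaussian prior over `theta` (`prior_cov`
#'   may be a vector of variances, taken as diagonal).
#' @param noise_precision if not `NULL`, the known residual precision;
#'   otherwise the precision is estimated.
#' @param max_iter,tol iteration cap and relative free-energy convergence
#'   tolerance.
#' @param jac_step finite-difference step for the Jacobian.
#' @return list with `mean`, `cov`, `F`, `lambda`, `converged`, `n_iter`,
#'   `F_trace`.
#' @export
variational_laplace <- function(y, f, prior_mean, prior_cov,
                                noise_precision = NULL,
                                max_iter = 128L, tol = 1e-6,
                                jac_step = 1e-6) {
  y <- as.numeric(y)
  n <- length(y)
  p <- length(prior_mean)
  if (is.vector(prior_cov) && !is.matrix(prior_cov)) prior_cov <- diag(prior_cov, p)
  if (any(diag(prior_cov) <= 0)) stop("prior variances must be > 0 for free parameters")
  P0 <- solve(prior_cov)
  ldP0 <- determinant(P0, logarithm = TRUE)$modulus
  est_lambda <- is.null(noise_precision)

  jacobian <- function(theta) {
    J <- matrix(0, n, p)
    for (j in seq_len(p)) {
      hp <- theta; hm <- theta
      hp[j] <- hp[j] + jac_step
      hm[j] <- hm[j] - jac_step
      J[, j] <- (f(hp) - f(hm)) / (2 * jac_step)
    }
    J
  }

  free_energy <- function(theta, lambda, J) {
    e <- y - f(theta)
    sse <- sum(e^2)
    tau <- exp(lambda)
    H <- tau * crossprod(J) + P0
    ldH <- determinant(H, logarithm = TRUE)$modulus
    dth <- theta - prior_mean
    Fv <- -0.5 * tau * sse + 0.5 * n * lambda - 0.5 * n * log(2 * pi) -
      0.5 * drop(t(dth) %*% P0 %*% dth) + 0.5 * ldP0 - 0.5 * ldH
    if (est_lambda) {
      # Laplace term for the noise hyperparameter (flat prior on lambda);
      # curvature of the log likelihood wrt lambda at its mode is sse*tau/2
      Fv <- Fv + 0.5 * log(2 * pi) - 0.5 * log(pmax(0.5 * tau * sse, 1e-300))
    }
    as.numeric(Fv)
  }

  lambda_mode <- function(theta) {
    sse <- sum((y - f(theta))^2)
    min(log(n / max(sse, 1e-12)), 27)  # cap precision at ~5e11
  }

  theta <- as.numeric(prior_mean)
  lambda <- if (est_lambda) lambda_mode(theta) else log(noise_precision)
  J <- jacobian(theta)
  Fcur <- free_energy(theta, lambda, J)
  F_trace <- Fcur
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    tau <- exp(lambda)
    e <- y - f(theta)
    g <- tau * crossprod(J, e) - P0 %*% (theta - prior_mean)
    H <- tau * crossprod(J) + P0
    step <- tryCatch(solve(H, g),
                     error = function(err) stop("singular curvature in variational_laplace"))
    accepted <- FALSE
    for (k in 0:8) {
      th_new <- theta + as.numeric(step) / 2^k
      lam_new <- if (est_lambda) lambda_mode(th_new) else lambda
      J_new <- jacobian(th_new)
      Fnew <- free_energy(th_new, lam_new, J_new)
      if (is.finite(Fnew) && Fnew > Fcur) { accepted <- TRUE; break }
    }
    if (!accepted) { converged <- TRUE; break }
    dF <- Fnew - Fcur
    theta <- th_new; lambda <- lam_new; J <- J_new; Fcur <- Fnew
    F_trace <- c(F_trace, Fcur)
    if (dF < tol * max(abs(Fcur), 1)) { converged <- TRUE; break }
  }

  tau <- exp(lambda)
  H <- tau * crossprod(J) + P0
  Sigma <- solve(H)
  Sigma <- (Sigma + t(Sigma)) / 2
  list(mean = theta, cov = Sigma, F = Fcur, lambda = lambda,
       converged = converged, n_iter = iter, F_trace = F_trace)
}

# index bookkeeping for the free parameters of a prior spec
.free_index <- function(priors) {
  iA <- which(priors$var_A > 0)
  iC <- if (!is.null(priors$var_C)) which(priors$var_C > 0) else integer(0)
  list(iA = iA, iC = iC, p = length(iA) + length(iC))
}

# assemble (A, C) matrices from prior means with free elements replaced
.theta_to_mats <- function(theta, priors, idx) {
  A <- priors$mean_A
  if (length(idx$iA)) A[idx$iA] <- theta[seq_along(idx$iA)]
  C <- priors$mean_C
  if (length(idx$iC)) C[idx$iC] <- theta[length(idx$iA) + seq_along(idx$iC)]
  list(A = A, C = C)
}

#' Invert the DCM recovery model on observed timeseries
#'
#' Fits the linear state-space model by variational Laplace on the exact
#' one-step discrete map `x[t+1] = e^{A dt} x[t] + drive`, estimating the
#' free elements of `A` (and of `C` where the prior variance is positive)
#' together with a single log noise-precision hyperparameter. Returns a
#' Laplace-approximate posterior and the free energy `F`, a lower bound on
#' the log model evidence balancing accuracy against complexity.
#'
#' @param data a [timeseries()] of observed signals.
#' @param inputs optional [input_series()] (required if `C` has free or
#'   non-zero elements).
#' @param priors a [prior_spec()]; variance 0 fixes a parameter.
#' @param settings list of optional controls: `max_iter` (128), `tol`
#'   (1e-6), `noise_precision` (fix the residual precision instead of
#'   estimating it).
#' @return An object of class `dcm_posterior` with fields `mean_A`,
#'   `mean_C`, `cov` (over free parameters), `free_A`/`free_C` (indices),
#'   `F`, `lambda`, `converged`, `n_iter`, `F_trace`, `n_states`.
#' @export
invert_model <- function(data, inputs = NULL, priors, settings = list()) {
  stopifnot(inherits(data, "dcm_timeseries"), inherits(priors, "dcm_priors"))
  N <- nrow(data$values)
  if (N != priors$n_states) stop("priors and data disagree on the number of states")
  Tn <- ncol(data$values)
  idx <- .free_index(priors)
  if (idx$p == 0L) {
    # delta priors everywhere: the posterior is the prior
    return(structure(list(
      mean_A = priors$mean_A, mean_C = priors$mean_C,
      cov = matrix(0, 0, 0), free_A = integer(0), free_C = integer(0),
      F = NA_real_, lambda = NA_real_, converged = TRUE, n_iter = 0L,
      F_trace = numeric(0), n_states = N), class = "dcm_posterior"))
  }
  n_obs <- N * (Tn - 1L)
  if (n_obs < idx$p) stop("need at least as many observations as free parameters")
  m <- priors$n_inputs
  needs_inputs <- m > 0L && (length(idx$iC) > 0L || any(priors$mean_C != 0))
  V <- NULL
  if (needs_inputs) {
    if (is.null(inputs)) stop("priors include input coupling but no inputs given")
    V <- inputs$values[, seq_len(Tn - 1L), drop = FALSE]
  }

  X0 <- data$values[, seq_len(Tn - 1L), drop = FALSE]
  X1 <- data$values[, -1L, drop = FALSE]
  dt <- data$dt

  fwd <- function(theta) {
    mats <- .theta_to_mats(theta, priors, idx)
    pr <- .propagator(mats$A, if (needs_inputs) mats$C else NULL, dt)
    P <- pr$Ad %*% X0
    if (needs_inputs) P <- P + pr$Bd %*% V
    as.numeric(P)
  }

  prior_mean <- c(priors$mean_A[idx$iA], priors$mean_C[idx$iC])
  prior_var <- c(priors$var_A[idx$iA], priors$var_C[idx$iC])

  fit <- variational_laplace(
    y = as.numeric(X1), f = fwd,
    prior_mean = prior_mean, prior_cov = prior_var,
    noise_precision = settings$noise_precision,
    max_iter = settings$max_iter %||% 128L,
    tol = settings$tol %||% 1e-6
  )

  mats <- .theta_to_mats(fit$mean, priors, idx)
  structure(list(
    mean_A = mats$A, mean_C = mats$C, cov = fit$cov,
    free_A = idx$iA, free_C = idx$iC,
    F = fit$F, lambda = fit$lambda, converged = fit$converged,
    n_iter = fit$n_iter, F_trace = fit$F_trace, n_states = N),
    class = "dcm_posterior")
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf("<dcm_posterior> %d state(s), F = %.3f, %s after %d iteration(s)\n",
              x$n_states, x$F,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("posterior mean A:\n"); print(round(x$mean_A, 4))
  invisible(x)
}

# marginal posterior variance of a free A element (by index into A)
.marginal_var_A <- function(post, i) {
  k <- match(i, post$free_A)
  if (is.na(k)) return(0)
  post$cov[k, k]
}

#' Fixed-effects Bayesian model averaging of posteriors
#'
#' Combines posteriors from several fitted models into one representative
#' posterior, weighting the first two moments by the softmax of the free
#' energies (models with higher evidence dominate). Averaging identical
#' posteriors is the identity.
#'
#' @param posteriors list of `dcm_posterior` objects with identical
#'   parameter dimensions.
#' @return A `dcm_posterior` whose `F` is the log of the average model
#'   evidence.
#' @export
bayesian_model_average <- function(posteriors) {
  if (length(posteriors) == 0L) stop("empty posterior list")
  if (length(posteriors) == 1L) return(posteriors[[1L]])
  dims <- vapply(posteriors, function(p) p$n_states, integer(1))
  if (length(unique(dims)) != 1L) stop("posteriors have inconsistent dimensions")
  frees <- lapply(posteriors, function(p) p$free_A)
  if (!all(vapply(frees, identical, logical(1), y = frees[[1L]])))
    stop("posteriors have inconsistent free-parameter sets")
  Fs <- vapply(posteriors, function(p) p$F, numeric(1))
  w <- exp(Fs - max(Fs)); w <- w / sum(w)

  th <- vapply(posteriors,
               function(p) c(p$mean_A[p$free_A], p$mean_C[p$free_C]),
               numeric(length(frees[[1L]]) + length(posteriors[[1L]]$free_C)))
  th <- matrix(th, ncol = length(posteriors))
  m_bar <- as.numeric(th %*% w)
  p <- nrow(th)
  M2 <- matrix(0, p, p)
  for (k in seq_along(posteriors))
    M2 <- M2 + w[k] * (posteriors[[k]]$cov + tcrossprod(th[, k]))
  cov_bar <- M2 - tcrossprod(m_bar)
  cov_bar <- (cov_bar + t(cov_bar)) / 2

  out <- posteriors[[1L]]
  mats <- list(A = out$mean_A, C = out$mean_C)
  mats$A[out$free_A] <- m_bar[seq_along(out$free_A)]
  if (length(out$free_C))
    mats$C[out$free_C] <- m_bar[length(out$free_A) + seq_along(out$free_C)]
  out$mean_A <- mats$A; out$mean_C <- mats$C; out$cov <- cov_bar
  out$F <- max(Fs) + log(sum(exp(Fs - max(Fs)))) - log(length(Fs))
  out$F_trace <- numeric(0)
  out
}

#' Bayesian model reduction for a univariate Gaussian parameter
#'
#' Computes the change in log model evidence obtained by replacing the
#' prior `N(mu0, v0)` used during inversion with a reduced prior
#' `N(mu0r, v0r)`, given the corresponding posterior marginal `N(mu, v)`.
#' This closed form lets scaling hypotheses about connectivity be scored
#' against an existing posterior without refitting the model.
#'
#' @param mu,v posterior marginal mean and variance.
#' @param mu0,v0 original prior mean and variance.
#' @param mu0r,v0r reduced prior mean and variance.
#' @return list with `dF` (log-evidence change) and the reduced posterior
#'   `mean` and `var`.
#' @export
bmr_gaussian <- function(mu, v, mu0, v0, mu0r, v0r) {
  pi_p <- 1 / v; pi_0 <- 1 / v0; pi_0r <- 1 / v0r
  pi_r <- pi_p + pi_0r - pi_0
  if (pi_r <= 0) stop("reduced posterior precision is not positive")
  mu_r <- (pi_p * mu + pi_0r * mu0r - pi_0 * mu0) / pi_r
  dF <- 0.5 * (log(pi_p) - log(pi_r) + log(pi_0r) - log(pi_0)) -
    0.5 * (mu0r^2 * pi_0r - mu0^2 * pi_0 + mu^2 * pi_p - mu_r^2 * pi_r)
  list(dF = as.numeric(dF), mean = as.numeric(mu_r), var = 1 / pi_r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
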