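#' Scale-transformation parameters
#'
#' Bundles the scale factor `b`, the temporal rescaling exponent `alpha`
#' and the amplitude exponent `beta` of the scaling transformation
#' \deqn{r(t) \to b^\beta\, b\, r(b^\alpha t).}
#' For z-scored signals the amplitude exponent is redundant and must be 0.
#' An optional per-node vector of factors supports scaling each node of a
#' networked system by a different amount.
#'
#' @param b global scale factor, > 0.
#' @param alpha temporal rescaling exponent (dimensionless).
#' @param beta amplitude exponent; must be 0 for z-scored data.
#' @param b_per_node optional positive vector of per-node scale factors.
#' @return An object of class `scale_params`.
#' @export
scale_params <- function(b, alpha, beta = 0, b_per_node = NULL) {
  if (!is.numeric(b) || length(b) != 1L || b <= 0) stop("b must be a positive scalar")
  if (!is.finite(alpha)) stop("alpha must be finite")
  if (!is.finite(beta)) stop("beta must be finite")
  if (!is.null(b_per_node) && any(b_per_node <= 0))
    stop("all per-node factors must be > 0")
  structure(list(b = b, alpha = alpha, beta = beta, b_per_node = b_per_node),
            class = "scale_params")
}

# cubic-spline row-wise evaluation of a series at new times; times outside
# the sampled span are reported via the "keep" mask (no extrapolation)
.resample_rows <- function(values, dt, t_new) {
  t_old <- (seq_len(ncol(values)) - 1L) * dt
  keep <- t_new >= t_old[1L] - 1e-12 & t_new <= t_old[length(t_old)] + 1e-12
  out <- matrix(NA_real_, nrow(values), sum(keep))
  for (i in seq_len(nrow(values))) {
    sf <- stats::splinefun(t_old, values[i, ], method = "fmm")
    out[i, ] <- sf(t_new[keep])
  }
  list(values = out, keep = keep)
}

#' Rescale a trajectory in amplitude and time
#'
#' Applies `r(t) -> b^beta * b * r(b^alpha t)`, evaluated on the original
#' sampling grid by cubic interpolation. Samples whose rescaled time falls
#' outside the recorded span are truncated (with a warning) rather than
#' extrapolated.
#'
#' @param traj a [timeseries()] on a uniform grid.
#' @param p a [scale_params()].
#' @return A [timeseries()]; shorter than the input if truncation occurred.
#' @examples
#' tr <- timeseries(rbind(cos(seq(0, 20, 0.01))), dt = 0.01)
#' sc <- scale_trajectory(tr, scale_params(b = 4, alpha = -1.5))
#' # period is multiplied by 4^1.5 = 8, amplitude by 4
#' @export
scale_trajectory <- function(traj, p) {
  stopifnot(inherits(traj, "dcm_timeseries"), inherits(p, "scale_params"))
  if (traj$zscored && p$beta != 0)
    stop("beta must be 0 for z-scored trajectories")
  t_new <- time_axis(traj) * p$b^p$alpha
  rs <- .resample_rows(traj$values, traj$dt, t_new)
  if (!all(rs$keep))
    warning(sprintf("rescaled time exceeds the sampled span; truncated to %d samples",
                    sum(rs$keep)))
  if (sum(rs$keep) < 2L) stop("fewer than two samples remain after truncation")
  amp <- p$b^(p$beta + 1)
  timeseries(amp * rs$values, traj$dt, labels = traj$labels)
}

#' Rescale an input series in time
#'
#' Inputs transform as `v(t) -> v(b^alpha t)`: only the timing of
#' perturbations changes, not their amplitude.
#'
#' @param inputs an [input_series()].
#' @param p a [scale_params()].
#' @return An [input_series()], truncated where the rescaled time exceeds
#'   the recorded span.
#' @export
scale_inputs <- function(inputs, p) {
  stopifnot(inherits(inputs, "dcm_inputs"), inherits(p, "scale_params"))
  t_new <- (seq_len(ncol(inputs$values)) - 1L) * inputs$dt * p$b^p$alpha
  rs <- .resample_rows(inputs$values, inputs$dt, t_new)
  if (!all(rs$keep))
    warning(sprintf("rescaled time exceeds the sampled span; truncated to %d samples",
                    sum(rs$keep)))
  if (sum(rs$keep) < 2L) stop("fewer than two samples remain after truncation")
  input_series(rs$values, inputs$dt)
}

#' Rescale connectivity matrices
#'
#' Under the uniform transformation all nodes share the scale factor `b`
#' and the coupling matrices transform as
#' \deqn{A \to b^\alpha A, \qquad C \to b^{\alpha+1} C.}
#' With per-node factors `b_i` the element-wise law is
#' \deqn{a_{ij} \to b_i^{\alpha+1} a_{ij} / b_j, \qquad
#'       c_{ij} \to b_i^{\alpha+2} c_{ij} / b_j,}
#' which reduces exactly to the uniform case when all `b_i = b`.
#'
#' @param A intrinsic coupling matrix.
#' @param C extrinsic coupling matrix or `NULL`.
#' @param p a [scale_params()]; if `b_per_node` is set the element-wise
#'   law is applied (its length must be `nrow(A)`, and `ncol(C)` must
#'   equal `nrow(A)` so each input is tied to a node).
#' @return list with rescaled `A` and `C`.
#' @export
scale_connectivity <- function(A, C = NULL, p) {
  stopifnot(inherits(p, "scale_params"))
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (is.null(p$b_per_node)) {
    A_s <- p$b^p$alpha * A
    C_s <- if (is.null(C)) NULL else p$b^(p$alpha + 1) * as.matrix(C)
  } else {
    bi <- p$b_per_node
    if (length(bi) != nrow(A)) stop("b_per_node must have one entry per node")
    A_s <- outer(bi^(p$alpha + 1), 1 / bi) * A
    if (is.null(C)) {
      C_s <- NULL
    } else {
      C <- as.matrix(C)
      if (ncol(C) != nrow(A))
        stop("per-node scaling of C requires one input per node")
      C_s <- outer(bi^(p$alpha + 2), 1 / bi) * C
    }
  }
  list(A = A_s, C = C_s)
}

#' Convert between the temporal rescaling exponent and the dynamical
#' critical exponent
#'
#' Coarse graining a scale-free system stretches characteristic decay
#' times as `t_b = b^z t_r`, while the scaling transformation compresses
#' time as `b^alpha`; the two exponents are related by `alpha = -z`.
#'
#' @param z,alpha exponent value.
#' @return The corresponding exponent (`alpha_from_z` returns `-z`;
#'   `z_from_alpha` returns `-alpha`). The two functions are mutual
#'   inverses.
#' @export
alpha_from_z <- function(z) {
  stopifnot(is.finite(z))
  -z
}

#' @rdname alpha_from_z
#' @export
z_from_alpha <- function(alpha) {
  stopifnot(is.finite(alpha))
  -alpha
}

#' The Kepler temporal-rescaling exponent
#'
#' Rescaling a gravitational orbit by `b` multiplies the right-hand side
#' of Newton's law by a residual factor `b^(2*alpha + 3)`; the orbit
#' family is mechanically similar only when that exponent vanishes. The
#' root of `2*alpha + 3 = 0` is `alpha = -3/2`, equivalent to Kepler's
#' third law (period^2 proportional to semi-major axis^3).
#'
#' @return -1.5, the unique root of the residual exponent.
#' @export
kepler_alpha <- function() {
  # root of the linear residual exponent 2*alpha + 3
  -3 / 2
}
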