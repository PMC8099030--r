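#' Lattice movie
#'
#' An `L x L x T` array of region timecourses on a square lattice, as
#' produced by wide-field imaging after cropping to a power-of-two window.
#' `level` counts coarse-graining steps applied so far, so the effective
#' block factor relative to level 0 is `b = 2^level`.
#'
#' @param values numeric `L x L x T` array.
#' @param dt sampling interval.
#' @param level coarse-graining level, >= 0.
#' @param zscored logical; `TRUE` after [zscore_regions()].
#' @return An object of class `lattice_movie`.
#' @export
lattice_movie <- function(values, dt, level = 0L, zscored = FALSE) {
  if (length(dim(values)) != 3L) stop("values must be an L x L x T array")
  d <- dim(values)
  if (d[1L] != d[2L]) stop("lattice must be square")
  if (d[3L] < 2L) stop("need at least two samples")
  if (dt <= 0) stop("dt must be positive")
  if (level < 0) stop("level must be >= 0")
  if (!all(is.finite(values))) stop("values must be finite")
  structure(list(values = values, dt = dt, level = as.integer(level),
                 zscored = isTRUE(zscored)),
            class = "lattice_movie")
}

#' @export
print.lattice_movie <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<lattice_movie> %dx%d regions x %d samples, dt = %g, level %d%s\n",
              d[1L], d[2L], d[3L], x$dt, x$level,
              if (x$zscored) ", z-scored" else ""))
  invisible(x)
}

#' Z-score every region of a lattice movie
#'
#' Subtracts the temporal mean and divides by the population standard
#' deviation of each region's timecourse. A zero-variance region is an
#' error and is reported with its lattice coordinates.
#'
#' @param movie a [lattice_movie()].
#' @return The z-scored movie (flag set). Already z-scored input is
#'   returned unchanged.
#' @export
zscore_regions <- function(movie) {
  stopifnot(inherits(movie, "lattice_movie"))
  if (movie$zscored) return(movie)
  d <- dim(movie$values)
  v <- movie$values
  m <- apply(v, c(1L, 2L), mean)
  s <- sqrt(apply(v, c(1L, 2L), function(x) mean((x - mean(x))^2)))
  if (any(s == 0)) {
    bad <- which(s == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("region (%d, %d) has zero variance and cannot be z-scored",
                 bad[1L], bad[2L]))
  }
  v <- sweep(sweep(v, c(1L, 2L), m), c(1L, 2L), s, "/")
  lattice_movie(v, movie$dt, movie$level, zscored = TRUE)
}

#' One coarse-graining step (2 x 2 block averaging)
#'
#' Replaces each aligned, non-overlapping 2 x 2 neighbourhood of regions
#' by its arithmetic-mean timecourse, halving the lattice side and
#' incrementing the level. The output is deliberately NOT re-z-scored
#' (block averaging shrinks variance); callers restore unit variance with
#' [zscore_regions()] before correlation or model fitting.
#'
#' @param movie a [lattice_movie()] with even side >= 2.
#' @return A [lattice_movie()] of side `L/2`.
#' @export
coarse_grain_step <- function(movie) {
  stopifnot(inherits(movie, "lattice_movie"))
  L <- dim(movie$values)[1L]
  if (L < 2L || L %% 2L != 0L) stop("lattice side must be even and >= 2")
  v <- movie$values
  odd <- seq(1L, L, 2L); even <- odd + 1L
  out <- (v[odd, odd, , drop = FALSE] + v[even, odd, , drop = FALSE] +
            v[odd, even, , drop = FALSE] + v[even, even, , drop = FALSE]) / 4
  lattice_movie(out, movie$dt, movie$level + 1L, zscored = FALSE)
}

#' Average time-correlation function of a lattice movie
#'
#' Computes `C(t) = (1/N) sum_i <x_i(t0 + t) x_i(t0)>` with the ensemble
#' average taken over time origins `t0` (stationarity assumed), averaged
#' over all regions of the lattice.
#'
#' @param movie a z-scored [lattice_movie()].
#' @param max_lag largest lag in samples, < T.
#' @return An object of class `correlation_profile`: `lags` (time units),
#'   `values`, `n_series`, `dt`.
#' @export
time_correlation <- function(movie, max_lag) {
  stopifnot(inherits(movie, "lattice_movie"))
  if (!movie$zscored) stop("z-score the movie before computing correlations")
  d <- dim(movie$values)
  Tn <- d[3L]
  if (max_lag >= Tn) stop("max_lag must be smaller than the number of samples")
  X <- matrix(aperm(movie$values, c(3L, 1L, 2L)), nrow = Tn)  # T x N
  vals <- vapply(0:max_lag, function(lag) {
    i1 <- seq_len(Tn - lag)
    mean(colSums(X[i1, , drop = FALSE] * X[i1 + lag, , drop = FALSE]) / (Tn - lag))
  }, numeric(1))
  structure(list(lags = (0:max_lag) * movie$dt, values = vals,
                 n_series = d[1L] * d[2L], dt = movie$dt),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("<correlation_profile> %d lag(s), C(0) = %.3f, %d series\n",
              length(x$lags), x$values[1L], x$n_series))
  invisible(x)
}

#' Characteristic decay time of a correlation profile
#'
#' The first time at which the correlation function falls to `1/e` of its
#' value at lag zero, located by linear interpolation between the
#' bracketing samples. If the profile never reaches the threshold within
#' the computed lags an error is raised rather than a fabricated value.
#'
#' @param profile a `correlation_profile` (or a list with `lags` and
#'   `values`).
#' @return The decay time, in the profile's time units.
#' @export
decay_time <- function(profile) {
  lags <- profile$lags; v <- profile$values
  if (v[1L] <= 0) stop("C(0) must be positive")
  thr <- v[1L] / exp(1)
  below <- which(v < thr)
  if (length(below) == 0L)
    stop("correlation never decays to 1/e within the computed lags")
  j <- below[1L]
  if (j == 1L) stop("profile starts below threshold")
  # linear interpolation between samples j-1 and j
  frac <- (v[j - 1L] - thr) / (v[j - 1L] - v[j])
  lags[j - 1L] + frac * (lags[j] - lags[j - 1L])
}

#' Estimate the dynamical critical exponent from decay times
#'
#' Coarse graining a scale-free system stretches characteristic decay
#' times as `t_b = b^z t_r`. With block factor 2 per level, `z` is the
#' least-squares slope of `log2(decay time)` against level, using every
#' supplied level; the two-level case reduces to `z = log2(t_b / t_r)`.
#'
#' @param movies list of [lattice_movie()] across consecutive levels
#'   (finest first); movies are z-scored internally if needed.
#' @param max_lag_frac largest correlation lag as a fraction of T.
#' @return An object of class `exponent_estimate`: `z`, `method`
#'   (`"correlation"`), `per_level_decay_times`, `levels`, `b_base` (2).
#' @export
estimate_z_correlation <- function(movies, max_lag_frac = 0.5) {
  if (length(movies) < 2L) stop("need at least two levels")
  lv <- vapply(movies, function(m) m$level, integer(1))
  td <- vapply(movies, function(m) {
    m <- zscore_regions(m)
    prof <- time_correlation(m, max_lag = floor(dim(m$values)[3L] * max_lag_frac))
    decay_time(prof)
  }, numeric(1))
  fit <- stats::lm(log2(td) ~ lv)
  structure(list(z = unname(stats::coef(fit)[2L]), method = "correlation",
                 per_level_decay_times = td, levels = lv, b_base = 2),
            class = "exponent_estimate")
}

#' @export
print.exponent_estimate <- function(x, ...) {
  cat(sprintf("<exponent_estimate> z = %.3f (%s, %d levels)\n",
              x$z, x$method, length(x$levels)))
  invisible(x)
}

#' Build the full coarse-graining hierarchy of a movie
#'
#' Repeatedly applies [coarse_grain_step()] from the movie's level down to
#' lattices of side `min_side`, returning every level including the input.
#'
#' @param movie a [lattice_movie()] with power-of-two side.
#' @param min_side coarsest lattice side to keep (default 2).
#' @return list of movies, finest first.
#' @export
coarse_grain_hierarchy <- function(movie, min_side = 2L) {
  L <- dim(movie$values)[1L]
  if (bitwAnd(L, L - 1L) != 0L) stop("lattice side must be a power of 2")
  out <- list(movie)
  while (dim(out[[length(out)]]$values)[1L] > min_side)
    out[[length(out) + 1L]] <- coarse_grain_step(out[[length(out)]])
  out
}
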