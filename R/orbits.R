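#' Gravitational N-body system
#'
#' A planar system of point masses under pairwise inverse-square gravity.
#' The default study system is one sun and two planets with a sun/planet
#' mass ratio of 1e5, heavy enough that the sun's wobble about the centre
#' of mass is negligible.
#'
#' @param masses positive numeric vector; index 1 is conventionally the
#'   sun.
#' @param positions `k x 2` matrix of initial positions (length units).
#' @param velocities `k x 2` matrix of initial velocities.
#' @param G gravitational constant in consistent units.
#' @return An object of class `orbit_system`.
#' @export
orbit_system <- function(masses, positions, velocities, G = 1) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  k <- length(masses)
  if (any(masses <= 0)) stop("masses must be positive")
  if (!all(dim(positions) == c(k, 2L)) || !all(dim(velocities) == c(k, 2L)))
    stop("positions and velocities must be k x 2 matrices")
  d <- as.matrix(stats::dist(positions))
  if (any(d[upper.tri(d)] == 0)) stop("two bodies are coincident")
  structure(list(masses = as.numeric(masses), positions = positions,
                 velocities = velocities, G = G),
            class = "orbit_system")
}

#' Default three-body study system
#'
#' One sun (mass `1e5`) at the origin and two planets (mass 1) started at
#' perihelion on near-circular orbits whose semi-major axes differ by
#' 10%. The planets start at different orbital phases so their radial
#' oscillations are not phase locked. The default eccentricity is small:
#' with a 10% axis spacing and this mass ratio, more eccentric orbits
#' would approach within a few Hill radii of each other and perturb each
#' other's periods at the percent level.
#'
#' @param a1 semi-major axis of the inner planet's orbit.
#' @param axis_ratio ratio between the two semi-major axes.
#' @param eccentricity orbital eccentricity of both planets.
#' @param mass_ratio sun mass over planet mass.
#' @param G gravitational constant.
#' @param phase2 initial orientation offset of planet 2's orbit (radians).
#' @return An [orbit_system()].
#' @export
three_body_system <- function(a1 = 1, axis_ratio = 1.1, eccentricity = 0.02,
                              mass_ratio = 1e5, G = 1, phase2 = pi / 2) {
  M <- mass_ratio
  e <- eccentricity
  # perihelion of a Kepler orbit with semi-major axis a: r = a (1 - e),
  # where the speed is v^2 = G M (1 + e) / r
  peri <- function(a) a * (1 - e)
  vper <- function(a) sqrt(G * M * (1 + e) / peri(a))
  a2 <- a1 * axis_ratio
  rot <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                           sin(th) * v[1] + cos(th) * v[2])
  p1 <- c(peri(a1), 0);               v1 <- c(0, vper(a1))
  p2 <- rot(c(peri(a2), 0), phase2);  v2 <- rot(c(0, vper(a2)), phase2)
  orbit_system(masses = c(M, 1, 1),
               positions = rbind(c(0, 0), p1, p2),
               velocities = rbind(c(0, 0), v1, v2),
               G = G)
}

# pairwise gravitational acceleration for a k x 2 position matrix
.nbody_accel <- function(pos, masses, G) {
  k <- nrow(pos)
  acc <- matrix(0, k, 2L)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      dvec <- pos[j, ] - pos[i, ]
      r2 <- sum(dvec^2)
      inv_r3 <- 1 / (r2 * sqrt(r2))
      acc[i, ] <- acc[i, ] + G * masses[j] * dvec * inv_r3
      acc[j, ] <- acc[j, ] - G * masses[i] * dvec * inv_r3
    }
  }
  acc
}

.nbody_energy <- function(pos, vel, masses, G) {
  ke <- 0.5 * sum(masses * rowSums(vel^2))
  pe <- 0
  k <- nrow(pos)
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      pe <- pe - G * masses[i] * masses[j] / sqrt(sum((pos[j, ] - pos[i, ])^2))
  ke + pe
}

#' Simulate an N-body system with a symplectic integrator
#'
#' Velocity-Verlet integration of pairwise inverse-square gravity. Energy
#' and linear momentum conservation are checked over the run: a relative
#' energy drift beyond `energy_tol` signals a step-size failure (e.g., a
#' close encounter) and raises an error rather than silently returning a
#' corrupted trajectory.
#'
#' @param system an [orbit_system()].
#' @param duration total simulated time.
#' @param dt integration step.
#' @param record_every record state every this many steps.
#' @param energy_tol maximum tolerated relative energy drift.
#' @param min_separation pairwise distance below which the run aborts.
#' @return list of class `nbody_run` with `times` (recorded instants),
#'   `positions` (`k x 2 x n_rec` array), `velocities` (final), `energy`
#'   (per recorded instant), `energy_drift`, `momentum_drift`, `system`,
#'   `dt`.
#' @export
simulate_nbody <- function(system, duration, dt, record_every = 1L,
                           energy_tol = 1e-6, min_separation = 1e-6) {
  stopifnot(inherits(system, "orbit_system"))
  if (dt <= 0 || duration <= dt) stop("need duration > dt > 0")
  n_steps <- floor(duration / dt)
  n_rec <- n_steps %/% record_every + 1L
  k <- length(system$masses)
  pos <- system$positions; vel <- system$velocities
  G <- system$G; masses <- system$masses
  P <- array(NA_real_, c(k, 2L, n_rec))
  En <- numeric(n_rec)
  P[, , 1L] <- pos
  En[1L] <- .nbody_energy(pos, vel, masses, G)
  times <- numeric(n_rec); ri <- 1L
  acc <- .nbody_accel(pos, masses, G)
  p0 <- colSums(masses * vel)
  for (s in seq_len(n_steps)) {
    pos <- pos + vel * dt + 0.5 * acc * dt^2
    acc_new <- .nbody_accel(pos, masses, G)
    vel <- vel + 0.5 * (acc + acc_new) * dt
    acc <- acc_new
    if (s %% record_every == 0L) {
      ri <- ri + 1L
      P[, , ri] <- pos
      En[ri] <- .nbody_energy(pos, vel, masses, G)
      times[ri] <- s * dt
      d <- as.matrix(stats::dist(pos))
      if (any(d[upper.tri(d)] < min_separation))
        stop("close encounter: bodies closer than min_separation; reduce dt")
    }
  }
  P <- P[, , seq_len(ri), drop = FALSE]
  En <- En[seq_len(ri)]; times <- times[seq_len(ri)]
  drift <- max(abs(En - En[1L])) / abs(En[1L])
  if (drift > energy_tol)
    stop(sprintf("energy drift %.3g exceeds tolerance %.3g; reduce dt",
                 drift, energy_tol))
  mom <- colSums(masses * vel)
  structure(list(times = times, positions = P, velocities = vel,
                 energy = En, energy_drift = drift,
                 momentum_drift = max(abs(mom - p0)) /
                   max(sum(abs(masses * vel)), 1e-300),
                 system = system, dt = dt * record_every),
            class = "nbody_run")
}

#' Radial distances from the centre of mass
#'
#' @param run an `nbody_run`.
#' @param bodies indices of the bodies to extract (default: all but the
#'   first, i.e., the planets).
#' @return A [timeseries()], one row per requested body.
#' @export
radial_distance <- function(run, bodies = NULL) {
  stopifnot(inherits(run, "nbody_run"))
  masses <- run$system$masses
  if (is.null(bodies)) bodies <- seq_along(masses)[-1L]
  n_rec <- dim(run$positions)[3L]
  com <- apply(run$positions, c(2L, 3L), function(p) sum(p * masses) / sum(masses))
  vals <- matrix(0, length(bodies), n_rec)
  for (bi in seq_along(bodies)) {
    dx <- run$positions[bodies[bi], 1L, ] - com[1L, ]
    dy <- run$positions[bodies[bi], 2L, ] - com[2L, ]
    vals[bi, ] <- sqrt(dx^2 + dy^2)
  }
  timeseries(vals, run$dt, labels = paste0("body", bodies))
}

#' Simulate a family of orbit systems at increasing scales
#'
#' Rebuilds and simulates the base system with all positions multiplied by
#' `(1 + increment)^(s-1)` and velocities by the inverse square root of
#' that factor (preserving orbital shape), for `n_scales` scales. Each run
#' covers `periods` orbital periods of the outer planet and records the
#' planets' radial distance from the centre of mass.
#'
#' @param base an [orbit_system()] (sun first).
#' @param n_scales number of scales, >= 2 unless `n_scales = 1`.
#' @param increment fractional size increase per scale (0.10 in the study
#'   design).
#' @param periods simulated duration in outer-planet periods (per scale,
#'   so larger orbits are watched for proportionally longer).
#' @param steps_per_period integration steps per inner-planet period.
#' @param obs_per_period recorded samples per inner-planet period at the
#'   base scale; the same sampling clock is used for every scale, as for
#'   a camera with a fixed frame rate.
#' @return An object of class `orbit_family`: `scales` (vector of `b_s`),
#'   `trajectories` (list of 2-row radial-distance [timeseries()], raw
#'   units), `semi_major_axes` and `periods` (matrices scale x planet,
#'   measured from the simulated output by [measure_orbit()]),
#'   `energy_drift` (per scale).
#' @export
make_orbit_family <- function(base, n_scales = 10L, increment = 0.10,
                              periods = 5, steps_per_period = 6000L,
                              obs_per_period = 80L) {
  stopifnot(inherits(base, "orbit_system"))
  if (n_scales < 1L) stop("n_scales must be >= 1")
  scales <- (1 + increment)^(seq_len(n_scales) - 1L)
  G <- base$G; M <- sum(base$masses)
  # apsidal radii of the planets give their semi-major axes up to shape;
  # use the largest initial distance as the reference length
  r_ref <- max(sqrt(rowSums(base$positions^2)))
  trajectories <- vector("list", n_scales)
  drift <- numeric(n_scales)
  n_planets <- length(base$masses) - 1L
  a_mat <- matrix(NA_real_, n_scales, n_planets)
  T_mat <- matrix(NA_real_, n_scales, n_planets)
  r_min <- min(sqrt(rowSums(base$positions[-1L, , drop = FALSE]^2)))
  # fixed observation clock, set by the base-scale inner planet
  dt_obs <- 2 * pi * sqrt(r_min^3 / (G * M)) / obs_per_period
  for (s in seq_len(n_scales)) {
    f <- scales[s]
    sys_s <- orbit_system(base$masses,
                          base$positions * f,
                          base$velocities / sqrt(f),
                          G = G)
    # conservative period bound from the largest apsidal distance
    T_outer <- 2 * pi * sqrt((r_ref * f)^3 / (G * M))
    T_inner <- 2 * pi * sqrt((r_min * f)^3 / (G * M))
    dt_sim <- T_inner / steps_per_period
    dur <- periods * T_outer
    rec <- max(1L, round(dt_obs / dt_sim))
    run <- simulate_nbody(sys_s, dur, dt_sim, record_every = rec)
    tr <- radial_distance(run)
    trajectories[[s]] <- tr
    drift[s] <- run$energy_drift
    for (pl in seq_len(n_planets)) {
      mo <- measure_orbit(timeseries(tr$values[pl, , drop = FALSE], tr$dt), tr$dt)
      a_mat[s, pl] <- mo$semi_major_axis
      T_mat[s, pl] <- mo$period
    }
  }
  structure(list(scales = scales, trajectories = trajectories,
                 semi_major_axes = a_mat, periods = T_mat,
                 energy_drift = drift, increment = increment),
            class = "orbit_family")
}

#' @export
print.orbit_family <- function(x, ...) {
  cat(sprintf("<orbit_family> %d scale(s), b = %s\n", length(x$scales),
              paste(round(x$scales, 3), collapse = ", ")))
  invisible(x)
}

#' Measure semi-major axis and period from a radial-distance series
#'
#' The semi-major axis is the mean of the apsidal (max and min radial)
#' distances; the period is located at the dominant non-zero peak of the
#' radial-distance autocorrelation, refined by parabolic interpolation.
#' At least two full orbital cycles must be present.
#'
#' @param traj single-row radial-distance [timeseries()].
#' @param dt sampling interval (defaults to `traj$dt`).
#' @return list with `semi_major_axis` and `period`.
#' @export
measure_orbit <- function(traj, dt = traj$dt) {
  stopifnot(inherits(traj, "dcm_timeseries"), nrow(traj$values) == 1L)
  r <- as.numeric(traj$values)
  a <- (max(r) + min(r)) / 2
  x <- r - mean(r)
  if (stats::sd(x) == 0) stop("constant radial distance: period undefined")
  n <- length(x)
  # Hann-taper the series and normalise by the window's own
  # autocorrelation: edge terms of the raw finite-series autocorrelation
  # ripple at twice the orbital frequency, in phase at every multiple of
  # the period, and would otherwise shift the peaks systematically
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / (n - 1L)))
  lag_max <- n %/% 2L
  ac <- stats::acf(x * w, lag.max = lag_max, plot = FALSE,
                   demean = FALSE)$acf[, 1L, 1L]
  wac <- stats::acf(w, lag.max = lag_max, plot = FALSE,
                    demean = FALSE)$acf[, 1L, 1L]
  keep <- wac > 0.02
  ac <- (ac / wac)[keep]
  lag_max <- sum(keep) - 1L
  # local maxima of the autocorrelation, excluding lag 0
  loc <- which(diff(sign(diff(ac))) == -2) + 1L
  loc <- loc[ac[loc] > 0]
  if (length(loc) == 0L)
    stop("no autocorrelation peak found: need at least two orbital cycles")
  pk <- loc[which.max(ac[loc])]
  # keep the FIRST peak of comparable height (harmonics of the period)
  cand <- loc[ac[loc] > 0.9 * ac[pk]]
  pk <- min(cand)
  refine <- function(idx) {
    # parabolic interpolation of the peak position (in lag units)
    if (idx > 1L && idx < length(ac)) {
      y1 <- ac[idx - 1L]; y2 <- ac[idx]; y3 <- ac[idx + 1L]
      denom <- (y1 - 2 * y2 + y3)
      delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
      idx - 1L + max(min(delta, 0.5), -0.5)
    } else idx - 1
  }
  p1 <- refine(pk)
  # edge ripple shifts a single peak by O(1/n); average over the visible
  # multiples of the period to suppress it
  ms <- integer(0); lag_m <- numeric(0)
  for (m in seq_len(max(1L, floor(lag_max / p1)))) {
    ctr <- round(m * p1)
    lo <- max(2L, ctr - max(2L, round(0.2 * p1)))
    hi <- min(length(ac) - 1L, ctr + max(2L, round(0.2 * p1)))
    if (hi <= lo + 1L) next
    im <- lo - 1L + which.max(ac[lo:hi])
    if (im <= lo || im >= hi) next       # peak not interior to the window
    ms <- c(ms, m); lag_m <- c(lag_m, refine(im))
  }
  period <- if (length(ms) > 0L) sum(ms * lag_m) / sum(ms^2) * dt else p1 * dt
  if (n * dt < 2 * period)
    stop("series shorter than two orbital cycles")
  list(semi_major_axis = a, period = period)
}

#' Kepler's third-law slope across an orbit family
#'
#' Regresses `log(period)` on `log(semi-major axis)` over all scales and
#' planets of a family. For inverse-square gravity the slope is 3/2.
#'
#' @param family an [make_orbit_family()] result.
#' @return list with `slope`, `intercept` and the per-orbit `log_a`,
#'   `log_T` used in the fit.
#' @export
kepler_slope <- function(family) {
  stopifnot(inherits(family, "orbit_family"))
  log_a <- log(as.numeric(family$semi_major_axes))
  log_T <- log(as.numeric(family$periods))
  fit <- stats::lm(log_T ~ log_a)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       log_a = log_a, log_T = log_T)
}
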