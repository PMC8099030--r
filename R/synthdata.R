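#' Specification for a synthetic dataset
#'
#' Describes either a family of scalable multichannel series with a known
#' temporal rescaling exponent, or a scale-free lattice movie hierarchy
#' with a known dynamical critical exponent. All generation is seeded and
#' fully reproducible.
#'
#' @param kind `"scalable_series"` or `"scalefree_lattice"`.
#' @param seed integer RNG seed (mandatory).
#' @param n_samples samples per series.
#' @param dt sampling interval (default 0.05, i.e., 20 Hz).
#' @param L lattice side for lattices; power of 2.
#' @param z_true dynamical critical exponent of a lattice.
#' @param alpha_true temporal rescaling exponent of a scalable family.
#' @param base_timescale characteristic time `tau0` of the finest level /
#'   base scale; must exceed `dt`.
#' @param noise_sd observation noise standard deviation.
#' @param n_scales,increment scalable-family scale ladder (defaults match
#'   the ten-scale, +10% study design).
#' @param n_states state dimension of scalable-series models.
#' @param parent_weight fraction of each lattice region's variance
#'   inherited from its parent block signal.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(kind = c("scalable_series", "scalefree_lattice"),
                       seed,
                       n_samples = 2000L, dt = 0.05,
                       L = 16L, z_true = 0.5, alpha_true = -1.5,
                       base_timescale = 0.4, noise_sd = NULL,
                       n_scales = 10L, increment = 0.10,
                       n_states = 2L, parent_weight = 0.35) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("a seed is mandatory for synthetic generation")
  if (base_timescale <= dt) stop("base_timescale must exceed dt")
  if (kind == "scalefree_lattice" && bitwAnd(L, L - 1L) != 0L)
    stop("L must be a power of 2")
  if (parent_weight <= 0 || parent_weight >= 1)
    stop("parent_weight must be in (0, 1)")
  # observation-noise default differs by kind: one-step fits of the
  # scalable families are attenuation-sensitive to regressor noise
  if (is.null(noise_sd))
    noise_sd <- if (kind == "scalefree_lattice") 0.05 else 0.01
  structure(list(kind = kind, seed = as.integer(seed),
                 n_samples = as.integer(n_samples), dt = dt, L = as.integer(L),
                 z_true = z_true, alpha_true = alpha_true,
                 base_timescale = base_timescale, noise_sd = noise_sd,
                 n_scales = as.integer(n_scales), increment = increment,
                 n_states = as.integer(n_states),
                 parent_weight = parent_weight),
            class = "synth_spec")
}

# draw a stable intrinsic matrix: diagonal -1/tau0, off-diagonals small;
# redrawn (bounded retries) if any eigenvalue has non-negative real part
.draw_stable_A <- function(n_states, tau0, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    A <- matrix(stats::rnorm(n_states^2, sd = 0.3 / tau0), n_states, n_states)
    diag(A) <- -1 / tau0
    if (all(Re(eigen(A, only.values = TRUE)$values) < -1e-6)) return(A)
  }
  stop("failed to draw a stable intrinsic matrix")
}

#' Generate a scalable family of timeseries with known exponent
#'
#' Draws a base stable intrinsic matrix `A` (diagonal `-1/tau0`), then for
#' each scale factor `b_s` integrates the model with connectivity
#' `A_s = b_s^alpha A`, driven by unit perturbations delivered through an
#' identity input matrix every five relaxation times of that scale (as in
#' a trial-based relaxation experiment). The perturbation directions
#' cycle through the state basis so the relaxation segments span the
#' whole state space; the input timing is rescaled with the dynamics, so
#' the family satisfies the scaling relations for both connectivity and
#' inputs. White observation noise of standard deviation `noise_sd`
#' (relative to the unit perturbation) is added to the emitted signals.
#' The noise must stay small: a one-step-ahead fit attenuates the
#' estimated coupling additively by (noise/signal variance ratio) / dt,
#' which distorts the recovered exponent once it reaches a few percent of
#' the couplings; the default of 0.01 keeps the distortion an order of
#' magnitude below the recovery tolerance.
#'
#' @param spec a [synth_spec()] with `kind = "scalable_series"`.
#' @return list with `scales`, `base_A`, and per scale an entry holding
#'   `b`, `series` (a [timeseries()]), `inputs` (the perturbation train,
#'   an [input_series()]) and `model` (the generating [dcm_model()],
#'   whose `C` is the identity).
#' @export
generate_scalable_series <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$kind == "scalable_series")
  set.seed(spec$seed)
  A <- .draw_stable_A(spec$n_states, spec$base_timescale)
  scales <- (1 + spec$increment)^(seq_len(spec$n_scales) - 1L)
  # perturbation directions cycle through the standard basis so that the
  # relaxation segments span the whole state space (a single repeated
  # direction leaves the coupling matrix unidentified); the slowest scale
  # must relax within the recording window at least once
  slowest <- spec$base_timescale * max(scales)^(-spec$alpha_true)
  if (3 * slowest > spec$n_samples * spec$dt)
    warning("recording window shorter than 3 relaxation times of the slowest scale")
  entries <- vector("list", length(scales))
  N <- spec$n_states
  for (s in seq_along(scales)) {
    A_s <- scales[s]^spec$alpha_true * A
    model <- dcm_model(A_s, C = diag(N), noise_sd = spec$noise_sd)
    tau_s <- spec$base_timescale * scales[s]^(-spec$alpha_true)
    kick_every <- max(2L, round(5 * tau_s / spec$dt))
    # impulse train: unit perturbations as one-step inputs of area 1
    V <- matrix(0, N, spec$n_samples)
    kick_t <- seq(kick_every, spec$n_samples - 2L, by = kick_every)
    for (ki in seq_along(kick_t))
      V[(ki %% N) + 1L, kick_t[ki]] <- 1 / spec$dt
    inp <- input_series(V, spec$dt)
    x0 <- c(1, numeric(N - 1L))
    ts_s <- integrate_model(model, x0 = x0, inputs = inp,
                            n_samples = spec$n_samples, dt = spec$dt)
    vals <- ts_s$values + matrix(stats::rnorm(length(ts_s$values),
                                              sd = spec$noise_sd), N)
    entries[[s]] <- list(b = scales[s],
                         series = timeseries(vals, spec$dt),
                         inputs = inp,
                         model = model)
  }
  list(scales = scales, entries = entries, base_A = A)
}

# exact-discretisation OU draw: AR(1) with coefficient exp(-dt/tau),
# stationary initial condition; n independent rows
.ou_rows <- function(n, n_samples, dt, tau) {
  phi <- exp(-dt / tau)
  innov_sd <- sqrt(1 - phi^2)
  X <- matrix(0, n, n_samples)
  X[, 1L] <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * (n_samples - 1L), sd = innov_sd), n)
  for (t in seq_len(n_samples - 1L)) X[, t + 1L] <- phi * X[, t] + eps[, t]
  X
}

#' Generate a scale-free lattice hierarchy with known exponent
#'
#' Builds the hierarchy coarsest-first: the root block carries a signal
#' with the longest timescales, and each level is disaggregated into
#' 2 x 2 children that mix the parent signal with independent faster
#' Ornstein-Uhlenbeck innovations (timescale `tau0 * 2^(z k)` at level
#' `k`). The innovations of the four siblings are centred so their block
#' average reproduces the parent exactly, which makes the intended decay
#' time of every level hold by construction. The root signal is itself
#' built from a chain of three virtual ancestor levels, so that every
#' analysed level sees the same geometric stack of slower timescales and
#' the level-`k` correlation function is (up to sampling noise) an exact
#' time-rescaled copy of the level-0 one. White observation noise is
#' added at the finest level, all levels are returned z-scored.
#'
#' @param spec a [synth_spec()] with `kind = "scalefree_lattice"`.
#' @return list of [lattice_movie()]s, level 0 (finest, side `L`) first,
#'   down to side 2.
#' @export
generate_scalefree_lattice <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$kind == "scalefree_lattice")
  k_max <- as.integer(log2(spec$L)) - 1L   # coarsest analysed level: side 2
  tau_at <- function(k) spec$base_timescale * 2^(spec$z_true * k)
  if (tau_at(k_max) >= spec$n_samples * spec$dt)
    stop("decay time at the coarsest level exceeds the recording length")
  set.seed(spec$seed)
  Tn <- spec$n_samples
  w <- spec$parent_weight
  # root: a single signal at the level above the coarsest analysed one,
  # itself carrying a chain of virtual slower ancestors so the timescale
  # stack seen from every analysed level is self-similar
  k_root <- k_max + 1L
  n_ancestors <- 3L
  root <- .ou_rows(1L, Tn, spec$dt, tau_at(k_root + n_ancestors))
  for (k in seq(k_root + n_ancestors - 1L, k_root))
    root <- sqrt(w) * root + sqrt(1 - w) * .ou_rows(1L, Tn, spec$dt, tau_at(k))
  # restore unit variance (the mixture is unit-variance in expectation)
  parent <- array(root, c(1L, 1L, Tn))
  for (k in seq(k_root - 1L, 0L)) {
    Lk <- spec$L / 2^k
    child <- array(0, c(Lk, Lk, Tn))
    tau_k <- tau_at(k)
    po <- dim(parent)[1L]
    for (I in seq_len(po)) for (J in seq_len(po)) {
      eta <- .ou_rows(4L, Tn, spec$dt, tau_k)
      eta <- sweep(eta, 2L, colMeans(eta))          # siblings sum to zero
      eta <- eta * sqrt(4 / 3)                      # restore unit variance
      mix <- sqrt(w) * matrix(parent[I, J, ], 4L, Tn, byrow = TRUE) +
        sqrt(1 - w) * eta
      child[2L * I - 1L, 2L * J - 1L, ] <- mix[1L, ]
      child[2L * I, 2L * J - 1L, ] <- mix[2L, ]
      child[2L * I - 1L, 2L * J, ] <- mix[3L, ]
      child[2L * I, 2L * J, ] <- mix[4L, ]
    }
    parent <- child
  }
  if (spec$noise_sd > 0)
    parent <- parent + array(stats::rnorm(length(parent), sd = spec$noise_sd),
                             dim(parent))
  finest <- zscore_regions(lattice_movie(parent, spec$dt, level = 0L))
  lapply(coarse_grain_hierarchy(finest, min_side = 2L), zscore_regions)
}

#' Write a set of synthetic fixtures with a manifest
#'
#' Generates each spec and writes it in the package's plain-text formats
#' (CSV per series; one CSV per lattice level with regions in rows),
#' together with a JSON manifest holding the specs, seeds and MD5
#' checksums. Regenerating from the same specs is byte-identical.
#'
#' @param specs list of [synth_spec()] objects.
#' @param directory writable output directory (created if missing).
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
write_fixture_set <- function(specs, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    stopifnot(inherits(spec, "synth_spec"))
    tag <- sprintf("%s_%02d_seed%d", spec$kind, si, spec$seed)
    files <- character(0)
    if (spec$kind == "scalable_series") {
      fam <- generate_scalable_series(spec)
      for (s in seq_along(fam$entries)) {
        f <- file.path(directory, sprintf("%s_scale%02d.csv", tag, s))
        write_timeseries_csv(fam$entries[[s]]$series, f)
        files <- c(files, f)
      }
    } else {
      movies <- generate_scalefree_lattice(spec)
      for (k in seq_along(movies)) {
        f <- file.path(directory, sprintf("%s_level%d.csv", tag, k - 1L))
        write_movie_csv(movies[[k]], f)
        files <- c(files, f)
      }
    }
    entries[[tag]] <- list(spec = unclass(spec),
                           files = basename(files),
                           md5 = unname(tools::md5sum(files)))
  }
  manifest <- list(entries = entries)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
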