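#' Read / write lattice movies
#'
#' CSV is the package's portable plain-text movie format: one row per
#' region with its lattice coordinates `i, j` followed by one column per
#' sample, the header carrying the actual sample times (so the sampling
#' interval round-trips). HDF5 (dataset `movie`, attributes `dt` and
#' `level`) is supported when the `rhdf5` package is installed. TIFF
#' stacks (one `L x L` frame per sample, values in `[0, 1]`) can be read
#' with an explicit `dt`.
#'
#' @param movie a [lattice_movie()].
#' @param path file path.
#' @return Writers return `path` invisibly; readers a [lattice_movie()].
#' @export
write_movie_csv <- function(movie, path) {
  stopifnot(inherits(movie, "lattice_movie"))
  d <- dim(movie$values)
  idx <- expand.grid(i = seq_len(d[1L]), j = seq_len(d[2L]))
  flat <- t(apply(idx, 1L, function(ij) movie$values[ij[1L], ij[2L], ]))
  df <- data.frame(idx, flat)
  names(df) <- c("i", "j", sprintf("t%.10g", (seq_len(d[3L]) - 1L) * movie$dt))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_movie_csv
#' @param level coarse-graining level to record on the loaded movie.
#' @export
read_movie_csv <- function(path, level = 0L) {
  df <- utils::read.csv(path, check.names = FALSE)
  tcols <- grep("^t", names(df), value = TRUE)
  tt <- as.numeric(sub("^t", "", tcols))
  if (length(tt) < 2L) stop("need at least two samples in ", path)
  L <- max(df$i)
  if (max(df$j) != L || nrow(df) != L^2)
    stop("malformed movie CSV (expected a square lattice): ", path)
  arr <- array(0, c(L, L, length(tt)))
  for (r in seq_len(nrow(df)))
    arr[df$i[r], df$j[r], ] <- as.numeric(df[r, tcols])
  lattice_movie(arr, dt = tt[2L] - tt[1L], level = level)
}

#' @rdname write_movie_csv
#' @export
write_movie_h5 <- function(movie, path) {
  stopifnot(inherits(movie, "lattice_movie"))
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("HDF5 support requires the 'rhdf5' package")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(movie$values, path, "movie")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "movie")
  rhdf5::h5writeAttribute(movie$dt, did, "dt")
  rhdf5::h5writeAttribute(movie$level, did, "level")
  rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_movie_csv
#' @export
read_movie_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("HDF5 support requires the 'rhdf5' package")
  vals <- rhdf5::h5read(path, "movie")
  at <- rhdf5::h5readAttributes(path, "movie")
  lattice_movie(vals, dt = as.numeric(at$dt),
                level = as.integer(at$level %||% 0L))
}

#' @rdname write_movie_csv
#' @param dt sampling interval of the TIFF stack (not stored in TIFF).
#' @export
read_movie_tiff <- function(path, dt, level = 0L) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF support requires the 'tiff' package")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims != dims[, 1L]))
    stop("inconsistent frame sizes in TIFF stack: ", path)
  arr <- array(0, c(dims[1L, 1L], dims[2L, 1L], length(frames)))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (length(dim(f)) == 3L) f <- f[, , 1L]   # first channel
    arr[, , k] <- f
  }
  lattice_movie(arr, dt = dt, level = level)
}

#' Load a lattice movie, guessing the format from the extension
#'
#' @param path input file (`.csv`, `.h5`/`.hdf5`, `.tif`/`.tiff`).
#' @param dt sampling interval, required for TIFF input.
#' @param level coarse-graining level for formats that do not store it.
#' @return A [lattice_movie()].
#' @export
load_movie <- function(path, dt = NULL, level = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = read_movie_csv(path, level = level),
         h5 = ,
         hdf5 = read_movie_h5(path),
         tif = ,
         tiff = {
           if (is.null(dt)) stop("dt must be given for TIFF input")
           read_movie_tiff(path, dt = dt, level = level)
         },
         stop("unsupported movie format: .", ext))
}

#' Pipeline configuration
#'
#' Validated bag of settings for the two reference workflows. Every
#' stochastic stage draws from the single `seed`, so a rerun with the same
#' configuration reproduces all outputs exactly.
#'
#' @param workflow `"kepler"` or `"coarse_grain"`.
#' @param seed integer seed (mandatory).
#' @param grid candidate exponent grid: alpha values for the Kepler
#'   workflow, z values for coarse graining.
#' @param n_trials,noise_sd noise trials of the second-level scan.
#' @param n_scales,increment,periods,eccentricity,steps_per_period,obs_per_period
#'   orbit-family settings (Kepler workflow).
#' @param block_subsample_fraction fraction of blocks fitted at the three
#'   finest levels (coarse-grain workflow).
#' @param re_zscore_levels re-z-score block signals at every level before
#'   fitting (recommended: block averaging shrinks variance).
#' @param state_mode `"two"` fits a 2-state model per 2 x 2 block (the two
#'   diagonal-pair averages); `"four"` fits all four regions.
#' @param output_dir optional directory for [write_report()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(workflow = c("kepler", "coarse_grain"),
                            seed,
                            grid = NULL,
                            n_trials = 100L, noise_sd = 0.01,
                            n_scales = 10L, increment = 0.10,
                            periods = 5, eccentricity = 0.02,
                            steps_per_period = 6000L, obs_per_period = 80L,
                            block_subsample_fraction = 0.25,
                            re_zscore_levels = TRUE,
                            state_mode = c("two", "four"),
                            output_dir = NULL) {
  workflow <- match.arg(workflow)
  state_mode <- match.arg(state_mode)
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(grid))
    grid <- if (workflow == "kepler") seq(-3, 0, 0.05) else seq(0, 3, 0.05)
  if (block_subsample_fraction <= 0 || block_subsample_fraction > 1)
    stop("block_subsample_fraction must be in (0, 1]")
  structure(list(workflow = workflow, seed = as.integer(seed), grid = grid,
                 n_trials = as.integer(n_trials), noise_sd = noise_sd,
                 n_scales = as.integer(n_scales), increment = increment,
                 periods = periods, eccentricity = eccentricity,
                 steps_per_period = as.integer(steps_per_period),
                 obs_per_period = as.integer(obs_per_period),
                 block_subsample_fraction = block_subsample_fraction,
                 re_zscore_levels = isTRUE(re_zscore_levels),
                 state_mode = state_mode, output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Kepler-exponent recovery workflow
#'
#' Simulates the three-body orbit family across scales, fits a two-node
#' DCM to the z-scored planetary radial distances at every scale
#' (expressed in natural time units of the base orbit, so couplings are
#' order one), and scans candidate temporal rescaling exponents by
#' Bayesian model reduction with noise trials. For inverse-square gravity
#' the evidence peaks near `alpha = -3/2`.
#'
#' @param config a [pipeline_config()] with `workflow = "kepler"`.
#' @return list with `curve` (an `evidence_curve`), `summary`
#'   ([summarize_peaks()]), `family`, `posteriors`, `series`,
#'   `kepler_slope`, `config`.
#' @export
run_kepler_workflow <- function(config) {
  stopifnot(inherits(config, "pipeline_config"), config$workflow == "kepler")
  sys <- three_body_system(eccentricity = config$eccentricity)
  fam <- make_orbit_family(sys, n_scales = config$n_scales,
                           increment = config$increment,
                           periods = config$periods,
                           steps_per_period = config$steps_per_period,
                           obs_per_period = config$obs_per_period)
  if (config$increment == 0)
    warning("increment = 0: all scales are identical and the evidence curve will be flat")
  # natural time unit: inverse angular frequency of the base inner orbit
  r_min <- min(sqrt(rowSums(sys$positions[-1L, , drop = FALSE]^2)))
  omega1 <- sqrt(sys$G * sum(sys$masses) / r_min^3)
  posts <- vector("list", length(fam$scales))
  for (s in seq_along(fam$scales)) {
    dat <- zscore_timeseries(fam$trajectories[[s]])
    dat$dt <- dat$dt * omega1
    posts[[s]] <- invert_model(dat, priors = prior_spec(2L))
  }
  ser <- scale_series(fam$scales, posts, base_index = 1L)
  curve <- scan_exponent(ser, config$grid, n_trials = config$n_trials,
                         noise_sd = config$noise_sd, seed = config$seed)
  res <- list(curve = curve, summary = summarize_peaks(curve),
              family = fam, posteriors = posts, series = ser,
              kepler_slope = kepler_slope(fam)$slope, config = config)
  if (!is.null(config$output_dir)) write_report(res, config$output_dir)
  res
}

# state timecourses of one 2 x 2 block: either the two diagonal-pair
# averages ("two") or all four regions ("four")
.block_states <- function(vals, bi, bj, state_mode) {
  i0 <- 2L * bi - 1L; j0 <- 2L * bj - 1L
  tl <- vals[i0, j0, ]; br <- vals[i0 + 1L, j0 + 1L, ]
  tr <- vals[i0 + 1L, j0, ]; bl <- vals[i0, j0 + 1L, ]
  if (state_mode == "two") rbind((tl + br) / 2, (tr + bl) / 2)
  else rbind(tl, tr, bl, br)
}

# fit first-level DCMs to a (sampled) set of 2 x 2 blocks and average them
.fit_level_blocks <- function(movie, fraction, state_mode, seed) {
  L <- dim(movie$values)[1L]
  nb <- L %/% 2L
  blocks <- expand.grid(bi = seq_len(nb), bj = seq_len(nb))
  if (fraction < 1) {
    set.seed(seed)
    keep <- sample(nrow(blocks), max(1L, round(fraction * nrow(blocks))))
    blocks <- blocks[keep, , drop = FALSE]
  }
  n_states <- if (state_mode == "two") 2L else 4L
  priors <- prior_spec(n_states)
  posts <- list(); skipped <- list()
  for (r in seq_len(nrow(blocks))) {
    sig <- .block_states(movie$values, blocks$bi[r], blocks$bj[r], state_mode)
    fit <- tryCatch({
      dat <- zscore_timeseries(timeseries(sig, movie$dt))
      invert_model(dat, priors = priors)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      skipped[[length(skipped) + 1L]] <-
        list(block = c(blocks$bi[r], blocks$bj[r]), reason = conditionMessage(fit))
    } else posts[[length(posts) + 1L]] <- fit
  }
  if (length(posts) == 0L) stop("no block produced a usable model fit at this level")
  # blocks hold different data, so their evidences are not comparable in
  # the model-selection sense: evidence-weighted (softmax) averaging would
  # simply select the most predictable block and bias the level estimate.
  # Combine moments with equal weights instead; the level evidence is the
  # sum of the block evidences.
  F_total <- sum(vapply(posts, function(p) p$F, numeric(1)))
  flat <- lapply(posts, function(p) { p$F <- 0; p })
  avg <- bayesian_model_average(flat)
  avg$F <- F_total
  list(posterior = avg,
       n_fit = length(posts), skipped = skipped,
       blocks = blocks)
}

#' Coarse-graining workflow: estimate the dynamical critical exponent
#'
#' Per coarse-graining level of the movie: z-scores the regions,
#' partitions them into 2 x 2 blocks, fits a first-level DCM per
#' (randomly sampled) block with the default priors (diagonal -1,
#' off-diagonal 0, variance 1; the input matrix is fixed at zero), and
#' averages the block posteriors into one intrinsic matrix per level
#' (equal-weight moment averaging: the blocks hold different data, so
#' softmax evidence weighting would degenerate into selecting a single
#' block). The per-level matrices are then compared with the
#' finest-level matrix under the scale-free transformation
#' `A_level = (2^level)^(-z) A_0`, and candidate `z` values are scored by
#' the summed reduction free energy.
#'
#' @param config a [pipeline_config()] with `workflow = "coarse_grain"`
#'   (`grid` is interpreted as candidate `z` values).
#' @param movie a [lattice_movie()] with power-of-two side.
#' @return list with `curve` (an `evidence_curve` over `z`), `summary`,
#'   `per_level` (fit metadata including the BMA intrinsic matrix per
#'   level), `series`, `config`.
#' @export
run_coarse_grain_workflow <- function(config, movie) {
  stopifnot(inherits(config, "pipeline_config"),
            config$workflow == "coarse_grain",
            inherits(movie, "lattice_movie"))
  L <- dim(movie$values)[1L]
  if (bitwAnd(L, L - 1L) != 0L) stop("movie side must be a power of 2")
  hier <- coarse_grain_hierarchy(movie, min_side = 2L)
  per_level <- list()
  posts <- list()
  for (k in seq_along(hier)) {
    mk <- hier[[k]]
    mk <- if (config$re_zscore_levels || mk$level == 0L) zscore_regions(mk) else mk
    frac <- if (mk$level <= 2L) config$block_subsample_fraction else 1
    lv <- .fit_level_blocks(mk, frac, config$state_mode,
                            seed = config$seed + mk$level)
    posts[[k]] <- lv$posterior
    per_level[[k]] <- list(level = mk$level, side = dim(mk$values)[1L],
                           n_blocks_fit = lv$n_fit, skipped = lv$skipped,
                           A = lv$posterior$mean_A)
  }
  b_levels <- 2^vapply(hier, function(m) m$level, integer(1))
  ser <- scale_series(b_levels, posts, base_index = 1L)
  # scan z through alpha = -z (the evidence engine works in alpha)
  z_grid <- config$grid
  alpha_grid <- rev(-z_grid)
  curve_a <- scan_exponent(ser, alpha_grid, n_trials = config$n_trials,
                           noise_sd = config$noise_sd, seed = config$seed)
  curve <- curve_a
  curve$grid <- z_grid
  curve$F <- curve_a$F[, rev(seq_along(alpha_grid)), drop = FALSE]
  curve$element_F <- curve_a$element_F[, rev(seq_along(alpha_grid)), drop = FALSE]
  curve$peak_per_trial <- -curve_a$peak_per_trial
  res <- list(curve = curve, summary = summarize_peaks(curve),
              per_level = per_level, series = ser, config = config)
  if (!is.null(config$output_dir)) write_report(res, config$output_dir)
  res
}

#' Write a JSON report (and evidence-curve plot) for a workflow result
#'
#' @param results list returned by [run_kepler_workflow()] or
#'   [run_coarse_grain_workflow()].
#' @param directory output directory, created if needed.
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(results, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  curve <- results$curve
  report <- list(
    workflow = results$config$workflow,
    seed = results$config$seed,
    grid = curve$grid,
    F_total = colSums(curve$F),
    F_trials = curve$F,
    peak_per_trial = curve$peak_per_trial,
    mode = results$summary$mode,
    spread = results$summary$spread,
    per_element_modes = results$summary$per_element_modes
  )
  if (!is.null(results$kepler_slope)) report$kepler_slope <- results$kepler_slope
  if (!is.null(results$per_level))
    report$per_level_A <- lapply(results$per_level,
                                 function(l) list(level = l$level, A = l$A))
  json_path <- file.path(directory, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  png_path <- file.path(directory, "evidence_curve.png")
  grDevices::png(png_path, width = 800, height = 500)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::matplot(curve$grid, t(curve$F), type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    xlab = "exponent", ylab = "free energy (nats)",
                    main = sprintf("%s evidence scan", results$config$workflow))
  graphics::abline(v = results$summary$mode, col = "red", lty = 2)
  invisible(c(json_path, png_path))
}

#' Serialise / restore a posterior as JSON
#'
#' Deterministic field ordering and explicit matrix shapes, for diffing
#' and archiving first-level results.
#'
#' @param post a `dcm_posterior`.
#' @param path output / input path.
#' @return `write_posterior_json` returns `path` invisibly;
#'   `read_posterior_json` a `dcm_posterior`.
#' @export
write_posterior_json <- function(post, path) {
  stopifnot(inherits(post, "dcm_posterior"))
  obj <- list(
    n_states = post$n_states,
    mean_A = post$mean_A,
    mean_C = post$mean_C,
    cov = post$cov,
    free_A = post$free_A,
    free_C = post$free_C,
    F = post$F,
    lambda = post$lambda,
    converged = post$converged,
    n_iter = post$n_iter
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname write_posterior_json
#' @export
read_posterior_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    mean_A = matrix(obj$mean_A, obj$n_states, byrow = FALSE),
    mean_C = if (!is.null(obj$mean_C)) as.matrix(obj$mean_C) else NULL,
    cov = as.matrix(obj$cov),
    free_A = as.integer(obj$free_A),
    free_C = as.integer(obj$free_C %||% integer(0)),
    F = obj$F, lambda = obj$lambda, converged = obj$converged,
    n_iter = obj$n_iter, F_trace = numeric(0), n_states = obj$n_states),
    class = "dcm_posterior")
}
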