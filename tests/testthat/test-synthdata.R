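test_that("synthetic generation is deterministic given spec and seed", {
  sp <- synth_spec("scalefree_lattice", seed = 5, L = 4, n_samples = 300)
  a <- generate_scalefree_lattice(sp)
  b <- generate_scalefree_lattice(sp)
  expect_identical(lapply(a, `[[`, "values"), lapply(b, `[[`, "values"))

  ss <- synth_spec("scalable_series", seed = 5, n_scales = 3, n_samples = 400)
  fa <- generate_scalable_series(ss)
  fb <- generate_scalable_series(ss)
  expect_identical(lapply(fa$entries, function(e) e$series$values),
                   lapply(fb$entries, function(e) e$series$values))
})

test_that("spec validation catches impossible requests", {
  expect_error(synth_spec("scalefree_lattice", seed = 1, L = 12), "power of 2")
  expect_error(synth_spec("scalable_series", seed = 1, base_timescale = 0.01),
               "exceed dt")
  expect_error(synth_spec("scalable_series"), "seed")
  expect_error(generate_scalefree_lattice(
    synth_spec("scalefree_lattice", seed = 1, L = 16, z_true = 3,
               n_samples = 200)), "exceeds the recording length")
})

test_that("alpha = 0 families share one generating model across scales", {
  sp <- synth_spec("scalable_series", seed = 2, alpha_true = 0,
                   n_scales = 4, n_samples = 300)
  fam <- generate_scalable_series(sp)
  for (s in 2:4) {
    expect_identical(fam$entries[[s]]$model$A, fam$entries[[1]]$model$A)
    expect_identical(fam$entries[[s]]$inputs$values, fam$entries[[1]]$inputs$values)
  }
})

test_that("scalar noiseless families stretch decay times exactly with b", {
  sp <- synth_spec("scalable_series", seed = 3, alpha_true = -1,
                   n_scales = 2, increment = 1, n_states = 1,
                   noise_sd = 0, n_samples = 400)
  fam <- generate_scalable_series(sp)
  expect_equal(fam$entries[[2]]$model$A, fam$entries[[1]]$model$A / 2)
  # scale-2 trajectory at 2t equals the base trajectory at t over the
  # first relaxation segment (before the first re-perturbation)
  x1 <- fam$entries[[1]]$series$values[1, ]
  x2 <- fam$entries[[2]]$series$values[1, ]
  k <- 1:19   # within the first relaxation segment of both scales
  expect_equal(x2[2 * k - 1], x1[k], tolerance = 1e-10)
})

test_that("lattice construction satisfies its design identities", {
  sp <- synth_spec("scalefree_lattice", seed = 7, L = 8, n_samples = 600)
  movies <- generate_scalefree_lattice(sp)
  expect_identical(vapply(movies, function(m) dim(m$values)[1], integer(1)),
                   c(8L, 4L, 2L))
  expect_true(all(vapply(movies, function(m) m$zscored, logical(1))))

  # coarse graining the finest level reproduces the next level up to the
  # per-region normalisation
  cg <- zscore_regions(coarse_grain_step(movies[[1]]))
  for (i in 1:4) for (j in 1:4) {
    expect_gt(cor(cg$values[i, j, ], movies[[2]]$values[i, j, ]), 0.99)
  }
})

test_that("z = 0 lattices have level-independent decay times", {
  sp <- synth_spec("scalefree_lattice", seed = 11, L = 8, z_true = 0,
                   n_samples = 1500)
  est <- estimate_z_correlation(generate_scalefree_lattice(sp))
  td <- est$per_level_decay_times
  expect_lt(max(td) / min(td) - 1, 0.1)
})

test_that("the OU discretisation is exact", {
  # lag-h autocorrelation of the AR(1) surrogate equals exp(-h dt / tau)
  m <- ou_lattice(6, 6000, 0.05, tau = 0.8, seed = 13)
  z <- zscore_regions(m)
  prof <- time_correlation(z, max_lag = 40)
  expect_lt(max(abs(prof$values - exp(-prof$lags / 0.8))), 0.05)
})

test_that("fixture sets are reproducible byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()

  # empty spec list: a manifest and nothing else
  man0 <- write_fixture_set(list(), d1)
  expect_length(man0$entries, 0)
  expect_identical(list.files(d1), "manifest.json")

  sp <- synth_spec("scalefree_lattice", seed = 4, L = 4, n_samples = 120)
  ss <- synth_spec("scalable_series", seed = 4, n_scales = 2, n_samples = 150)
  m1 <- write_fixture_set(list(sp, ss), d1)
  m2 <- write_fixture_set(list(sp, ss), d2)
  expect_identical(unname(m1$entries[[1]]$md5), unname(m2$entries[[1]]$md5))
  expect_identical(unname(m1$entries[[2]]$md5), unname(m2$entries[[2]]$md5))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # the written movie loads back as a valid lattice
  f <- file.path(d1, m1$entries[[1]]$files[1])
  mv <- read_movie_csv(f)
  expect_identical(dim(mv$values), c(4L, 4L, 120L))
})
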