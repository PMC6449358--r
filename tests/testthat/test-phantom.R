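test_that("rendered sphere voxel counts match brute-force enumeration", {
  spec <- sphere_phantom_spec(
    shape = c(30, 28, 16),
    spheres = data.frame(x = 10, y = 12, z = 8, r = 6, intensity = 100))
  ph <- render_phantom(spec)
  expect_equal(length(ph$gt$ids), 1L)
  expect_equal(ph$gt$volumes,
               ref_sphere_count(c(10, 12, 8), 6, c(30, 28, 16)))
  # within 5% of the continuous sphere volume for r >= 5
  expect_lt(abs(ph$gt$volumes - 4 / 3 * pi * 6^3), 0.05 * 4 / 3 * pi * 6^3)
  expect_true(all(ph$volume[ph$gt$labels == 1] == 100))
  expect_true(all(ph$volume[ph$gt$labels == 0] == 10))
})

test_that("default layout produces six spheres with near-ideal volumes", {
  ph <- render_phantom(sphere_phantom_spec())
  expect_equal(length(ph$gt$ids), 6L)
  ideal <- 4 / 3 * pi * c(7, 9, 7, 9, 7, 7)^3
  expect_true(all(abs(ph$gt$volumes - ideal) / ideal < 0.05))
})

test_that("empty sphere list gives a uniform background volume", {
  spec <- sphere_phantom_spec(
    shape = c(10, 10, 5),
    spheres = data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                         r = numeric(0), intensity = numeric(0)))
  ph <- render_phantom(spec)
  expect_true(all(ph$volume == spec$background_level))
  expect_equal(length(ph$gt$ids), 0L)
})

test_that("touching spheres resolve to distinct labels by nearest centre", {
  spec <- sphere_phantom_spec(
    shape = c(40, 24, 16),
    spheres = data.frame(x = c(12, 22), y = c(12, 12), z = c(8, 8),
                         r = c(7, 7), intensity = 100))
  ph <- render_phantom(spec)
  expect_equal(length(ph$gt$ids), 2L)
  # exhaustive nearest-centre oracle
  lab_ref <- array(0L, dim = spec$shape)
  for (x in 0:39) for (y in 0:23) for (z in 0:15) {
    d1 <- (x - 12)^2 + (y - 12)^2 + (z - 8)^2
    d2 <- (x - 22)^2 + (y - 12)^2 + (z - 8)^2
    if (d1 <= 49 && d1 <= d2) lab_ref[x + 1, y + 1, z + 1] <- 1L
    else if (d2 <= 49) lab_ref[x + 1, y + 1, z + 1] <- 2L
  }
  expect_identical(ph$gt$labels, lab_ref)
  expect_equal(sum(ph$gt$labels == 1 & ph$gt$labels == 2), 0L)
})

test_that("spheres entirely outside the volume are rejected", {
  expect_error(
    render_phantom(sphere_phantom_spec(
      shape = c(20, 20, 10),
      spheres = data.frame(x = 19.5, y = 19.5, z = 9, r = 2,
                           intensity = 50))),
    NA)  # centre inside -> fine
  expect_error(sphere_phantom_spec(
    shape = c(20, 20, 10),
    spheres = data.frame(x = 40, y = 10, z = 5, r = 2, intensity = 50)),
    "inside")
})

test_that("measure_snr implements 20 log10(mean fg / sd bg)", {
  spec <- small_phantom_spec()
  ph <- render_phantom(spec)
  vol <- ph$volume
  # craft foreground mean 100 and background sd 50 around its mean
  set.seed(7)
  bg <- which(ph$gt$labels == 0)
  vol[bg] <- rnorm(length(bg), 0, 50)
  vol[ph$gt$labels > 0] <- 100
  s <- sd(vol[bg])
  expect_equal(measure_snr(vol, ph$gt), 20 * log10(100 / s))
  # fg mean == bg sd -> 0 dB
  vol[ph$gt$labels > 0] <- s
  expect_equal(measure_snr(vol, ph$gt), 0, tolerance = 1e-12)
  # constant background -> undefined
  vol[bg] <- 3
  expect_error(measure_snr(vol, ph$gt), "variance")
})

test_that("calibration matches the closed form when Poisson is negligible", {
  # the full-size phantom keeps finite-sample bias of the measured SNR small
  ph <- render_phantom(sphere_phantom_spec())
  # huge poisson_scaling -> shot noise vanishes; sigma ~ mu * 10^(-snr/20)
  ns <- calibrate_noise(ph$volume, ph$gt, target_snr_db = -7,
                        poisson_scaling = 1e6, seed = 3)
  expect_equal(ns$gaussian_sigma, 100 * 10^(7 / 20), tolerance = 0.05)
  ns0 <- calibrate_noise(ph$volume, ph$gt, target_snr_db = 0,
                         poisson_scaling = 1e6, seed = 3)
  expect_equal(ns0$gaussian_sigma, 100, tolerance = 0.05)
})

test_that("unreachable targets fail with the achievable SNR in the message", {
  spec <- small_phantom_spec()
  ph <- render_phantom(spec)
  expect_error(calibrate_noise(ph$volume, ph$gt, target_snr_db = 60,
                               poisson_scaling = 0.01, seed = 1),
               "unreachable")
})

test_that("apply_noise is reproducible and noiseless in the limit", {
  spec <- small_phantom_spec()
  ph <- render_phantom(spec)
  ns <- noise_spec(gaussian_sigma = 30, poisson_scaling = 1, seed = 11)
  a <- apply_noise(ph$volume, ns)
  b <- apply_noise(ph$volume, ns)
  expect_identical(a, b)
  quiet <- noise_spec(gaussian_sigma = 0, poisson_scaling = 1e9, seed = 1)
  expect_equal(apply_noise(ph$volume, quiet), ph$volume, tolerance = 1e-3)
})

test_that("the benchmark suite hits its SNR targets within 0.5 dB", {
  suite <- make_benchmark_suite(seed = 5)
  expect_length(suite, 4L)
  targets <- c(2, -1, -5, -7)
  for (k in seq_along(suite)) {
    expect_equal(dim(suite[[k]]$volume), c(100, 100, 20))
    expect_lt(abs(suite[[k]]$snr_measured - targets[k]), 0.5)
    # noise never alters the ground truth
    expect_identical(suite[[k]]$gt$labels, suite[[1]]$gt$labels)
  }
  # determinism: same seed, same volumes
  suite2 <- make_benchmark_suite(seed = 5, snr_db = 2)
  expect_identical(suite2[[1]]$volume, suite[[1]]$volume)
})
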