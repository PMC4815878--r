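test_that("zero fluence gives an all-zero pattern; masked pixels carry NA", {
  geom <- small_geometry()
  geom$mask[1:3, 1:3] <- FALSE
  p <- simulate_pattern(test_sphere(), geom, fluence_scale = 0)
  expect_true(all(p$counts == 0, na.rm = TRUE))
  expect_true(all(is.na(p$counts[1:3, 1:3])))
})

test_that("expected count at forward scattering equals the fluence scale", {
  # beam center placed exactly on a pixel so that pixel has q = 0
  geom <- detector_geometry(n_fast = 9, n_slow = 9, center = c(4, 4))
  for (model in list(test_sphere(), test_dumbbell())) {
    set.seed(1)
    p <- simulate_pattern(model, geom,
                          orientation = random_orientation(1)[1, ],
                          fluence_scale = 3333, poisson = FALSE)
    expect_equal(p$counts[5, 5], 3333, tolerance = 1e-9)
  }
})

test_that("orientation enters only through the rotated model", {
  # exact equivariance: passing an orientation equals pre-rotating the model
  geom <- small_geometry()
  sph <- test_sphere()
  set.seed(11)
  quat <- random_orientation(1)[1, ]
  rot <- quat_to_matrix(quat)
  pre <- bead_model(sph$centers %*% t(rot), sph$bead_radius, sph$weights)
  p1 <- simulate_pattern(sph, geom, orientation = quat,
                         fluence_scale = 1e4, poisson = FALSE)
  p2 <- simulate_pattern(pre, geom, fluence_scale = 1e4, poisson = FALSE)
  expect_equal(p1$counts, p2$counts, tolerance = 1e-9)
})

test_that("noiseless sphere intensity is orientation invariant", {
  # a single spherical bead is exactly isotropic: any orientation gives the
  # identical pattern to machine precision
  geom <- small_geometry()
  ball <- bead_model(matrix(0, 1, 3), bead_radius = 45)
  set.seed(11)
  p1 <- simulate_pattern(ball, geom, random_orientation(1)[1, ],
                         fluence_scale = 1e4, poisson = FALSE)
  p2 <- simulate_pattern(ball, geom, random_orientation(1)[1, ],
                         fluence_scale = 1e4, poisson = FALSE)
  pick <- cbind(sample(48, 20), sample(48, 20))
  expect_equal(p1$counts[pick], p2$counts[pick], tolerance = 1e-9)
  # a lattice-discretized sphere is isotropic up to discretization; the
  # anisotropy is O((q * spacing)^2), so patterns agree closely at low q
  sph <- test_sphere()
  q1 <- simulate_pattern(sph, geom, random_orientation(1)[1, ],
                         fluence_scale = 1e4, poisson = FALSE)
  q2 <- simulate_pattern(sph, geom, random_orientation(1)[1, ],
                         fluence_scale = 1e4, poisson = FALSE)
  qmag <- matrix(pixel_q_vectors(geom)$qmag, geom$n_slow, geom$n_fast)
  live <- qmag * 5 <= 0.3 & q1$counts > 1   # spacing = 5 nm
  expect_lt(max(abs(q1$counts[live] / q2$counts[live] - 1)), 0.02)
})

test_that("Poisson sampling conserves intensity in expectation", {
  geom <- detector_geometry(n_fast = 12, n_slow = 12, center = c(5.5, 5.5))
  m <- test_dumbbell()
  truth <- simulate_pattern(m, geom, fluence_scale = 200, poisson = FALSE)
  set.seed(99)
  n_rep <- 400
  acc <- matrix(0, 12, 12)
  for (k in seq_len(n_rep))
    acc <- acc + simulate_pattern(m, geom, fluence_scale = 200)$counts
  mu <- acc / n_rep
  se <- sqrt(truth$counts / n_rep)
  live <- truth$counts > 1
  expect_true(all(abs(mu[live] - truth$counts[live]) < 4 * se[live] + 1e-9))
})

test_that("false-positive injection follows the requested rate", {
  geom <- detector_geometry(n_fast = 8, n_slow = 8)
  m <- bead_model(matrix(rnorm(9), 3, 3), 0.5, label = "tiny")
  fp <- bead_model(matrix(rnorm(9) * 3, 3, 3), 0.5, label = "junk")
  ds0 <- simulate_dataset(m, geom, n_patterns = 50, fluence_scale = 10,
                          false_positive_rate = 0, seed = 4)
  expect_false(any(ds0$manifest$false_positive))
  ds <- simulate_dataset(m, geom, n_patterns = 1000, fluence_scale = 10,
                         false_positive_rate = 0.1, false_positive_model = fp,
                         seed = 5)
  n_fp <- sum(ds$manifest$false_positive)
  # binomial(1000, 0.1) central 99% interval
  expect_gte(n_fp, 73)
  expect_lte(n_fp, 128)
  expect_error(simulate_dataset(m, geom, n_patterns = 0), "positive")
  expect_error(simulate_dataset(m, geom, 5, false_positive_rate = 1),
               "false_positive_rate")
})

test_that("pattern stacks round-trip through the on-disk format", {
  geom <- detector_geometry(n_fast = 10, n_slow = 10)
  geom$mask[2, 7] <- FALSE
  m <- test_dumbbell()
  ds <- simulate_dataset(m, geom, n_patterns = 6, fluence_scale = 50,
                         center_jitter_px = 1.5, seed = 21)
  dir <- file.path(tempdir(), "stack_rt")
  write_patterns(ds, dir)
  back <- read_patterns(dir)
  expect_equal(length(back$patterns), 6L)
  for (k in 1:6)
    expect_identical(back$patterns[[k]]$counts, ds$patterns[[k]]$counts)
  expect_equal(back$manifest, ds$manifest, tolerance = 0)
  expect_identical(back$geometry$mask, geom$mask)
  expect_equal(back$geometry$center, geom$center)
})

test_that("noiseless patterns of centrosymmetric models obey Friedel symmetry", {
  # isotropic scatterer: intensity depends on |q| only, so reflection through
  # an on-grid beam center maps the pattern exactly onto itself
  geom <- detector_geometry(n_fast = 21, n_slow = 21, center = c(10, 10))
  p <- simulate_pattern(test_sphere(), geom, fluence_scale = 1e4,
                        poisson = FALSE)
  flipped <- p$counts[21:1, 21:1]
  expect_equal(p$counts, flipped, tolerance = 1e-9)
})
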