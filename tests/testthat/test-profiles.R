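test_that("azimuthal integration reproduces per-pixel bin means", {
  geom <- small_geometry()
  qv <- pixel_q_vectors(geom)
  # synthetic pattern whose counts are a pure function of |q|
  f <- function(q) 100 * exp(-8 * q) + 5
  counts <- matrix(f(qv$qmag), geom$n_slow, geom$n_fast)
  p <- scattering_pattern(counts, geom)
  q_bins <- default_q_bins(geom, n_bins = 60)
  prof <- azimuthal_integrate(p, q_bins = q_bins)
  # brute-force oracle: assign pixels to bins and average directly
  bin <- findInterval(qv$qmag, q_bins)
  for (k in which(prof$n_pix > 0)) {
    expect_equal(prof$I[k], mean(counts[bin == k]), tolerance = 1e-12,
                 label = paste("bin", k))
  }
  # uniform pattern: every non-empty bin reports the constant
  pu <- scattering_pattern(matrix(7, geom$n_slow, geom$n_fast), geom)
  pru <- azimuthal_integrate(pu, q_bins = q_bins)
  expect_true(all(pru$I[pru$n_pix > 0] == 7))
})

test_that("total counts are conserved across binning", {
  geom <- small_geometry()
  geom$mask[5:9, 2:4] <- FALSE
  set.seed(3)
  p <- simulate_pattern(test_sphere(), geom, fluence_scale = 500)
  prof <- azimuthal_integrate(p)
  expect_equal(sum(prof$I * prof$n_pix, na.rm = TRUE),
               sum(p$counts, na.rm = TRUE), tolerance = 1e-9)
})

test_that("fully masked bins are flagged and excluded", {
  geom <- detector_geometry(n_fast = 16, n_slow = 16)
  # mask an annulus so one q bin is empty
  qv <- pixel_q_vectors(geom)
  qm <- matrix(qv$qmag, 16, 16)
  edges <- seq(0, max(qm) * 1.001, length.out = 9)
  geom$mask[qm >= edges[4] & qm < edges[5]] <- FALSE
  p <- simulate_pattern(test_dumbbell(), geom, fluence_scale = 100)
  prof <- azimuthal_integrate(p, q_bins = edges)
  expect_equal(prof$n_pix[4], 0)
  expect_true(is.na(prof$I[4]))
  # all-masked pattern errors
  geom$mask[] <- FALSE
  pm <- scattering_pattern(matrix(NA_real_, 16, 16), geom)
  expect_error(azimuthal_integrate(pm, q_bins = edges), "masked")
})

test_that("merging sums intensities with quadrature uncertainties", {
  q <- 1:10
  single <- saxs_profile(q, I = q * 2, sigma = rep(1, 10),
                         n_pix = rep(4, 10))
  merged <- accumulate_profiles(replicate(5, single, simplify = FALSE))
  expect_equal(merged$I, single$I * 5)
  expect_equal(merged$sigma, rep(sqrt(5), 10))
  expect_equal(merged$n_patterns, 5L)
  # associativity
  set.seed(8)
  ps <- lapply(1:3, function(k)
    saxs_profile(q, I = runif(10), sigma = runif(10), n_pix = rep(2, 10)))
  ab_c <- accumulate_profiles(list(accumulate_profiles(ps[1:2]), ps[[3]]))
  a_bc <- accumulate_profiles(list(ps[[1]], accumulate_profiles(ps[2:3])))
  expect_equal(ab_c$I, a_bc$I, tolerance = 1e-12)
  expect_equal(ab_c$sigma, a_bc$sigma, tolerance = 1e-12)
  # grid mismatch is refused
  other <- saxs_profile(q + 0.5, I = q)
  expect_error(accumulate_profiles(list(single, other)), "grid mismatch")
})

test_that("Pearson correlation is affine invariant and matches a hand case", {
  q <- 1:4
  a <- saxs_profile(q, c(1, 2, 3, 4))
  b <- saxs_profile(q, c(1, 2, 3, 5))
  expect_equal(pearson_correlation(a, a), 1.0)
  a3 <- saxs_profile(q, 3 * a$I + 7)
  expect_equal(pearson_correlation(a, a3), 1.0)
  # hand evaluation: r = 6.5 / sqrt(5 * 8.75) = 0.9827
  expect_equal(pearson_correlation(a, b), 0.9827, tolerance = 1e-4)
  tiny <- saxs_profile(1:2, c(1, 2))
  expect_error(pearson_correlation(tiny, tiny), "insufficient")
})

test_that("convergence trace ends at exactly 1 against the full-set reference", {
  geom <- small_geometry()
  set.seed(31)
  ds <- simulate_dataset(test_sphere(), geom, n_patterns = 30,
                         fluence_scale = 300, seed = 31)
  profs <- lapply(ds$patterns, azimuthal_integrate)
  tr <- convergence_trace(profs, stride = 7)
  expect_equal(tail(tr$n_included, 1), 30L)
  expect_equal(tail(tr$r_p, 1), 1.0, tolerance = 1e-12)
  expect_true(all(diff(tr$n_included) > 0))
  expect_true(all(tr$r_p >= -1 & tr$r_p <= 1))
})

test_that("split-half agreement is perfect for identical inputs and reproducible", {
  q <- seq(0.1, 2, length.out = 20)
  single <- saxs_profile(q, exp(-q), sigma = rep(0.01, 20))
  copies <- replicate(10, single, simplify = FALSE)
  sh <- split_half_consistency(copies, seed = 5)
  expect_equal(sh$r_p, 1.0, tolerance = 1e-12)
  sh2 <- split_half_consistency(copies, seed = 5)
  expect_identical(sh$assignment, sh2$assignment)
  expect_error(split_half_consistency(copies[1]), "at least 2")
})

test_that("merged random-orientation profiles converge to the Debye profile", {
  # the central premise: summed single-particle intensity profiles form a
  # SAXS profile. 2000 noiseless orientations keep the Monte-Carlo error
  # near the first minimum below the 2% band.
  m <- make_shape("prolate", semi_axes = c(67.5, 34), spacing = 9)
  geom <- small_geometry()
  ds <- simulate_dataset(m, geom, n_patterns = 2000, fluence_scale = 2e4,
                         seed = 5, poisson = FALSE)
  q_bins <- default_q_bins(geom, n_bins = 120)
  profs <- lapply(ds$patterns, azimuthal_integrate, q_bins = q_bins)
  merged <- accumulate_profiles(profs)
  ok <- merged$n_pix > 0
  # oracle on the same binning: per-pixel Debye evaluation, then bin means
  qv <- pixel_q_vectors(geom)
  deb_pix <- debye_profile(m, qv$qmag)
  bin <- findInterval(qv$qmag, q_bins)
  binned <- tapply(deb_pix, bin, mean)[as.character(which(ok))]
  mI <- merged$I[ok]
  sc <- sum(mI * binned) / sum(binned^2)
  rel <- mI / (sc * binned) - 1
  qfm <- first_minimum(merged$q[ok], binned)
  expect_lt(max(abs(rel[merged$q[ok] < qfm])), 0.02)
})

test_that("profile .dat files round-trip and tolerate 2-column input", {
  q <- seq(0.05, 1, length.out = 12)
  prof <- saxs_profile(q, exp(-q) * 100, sigma = sqrt(exp(-q) * 100))
  path <- file.path(tempdir(), "prof.dat")
  write_profile_dat(prof, path, comment = "round trip")
  back <- read_profile_dat(path)
  expect_equal(back$q, prof$q, tolerance = 1e-7)
  expect_equal(back$I, prof$I, tolerance = 1e-7)
  expect_equal(back$sigma, prof$sigma, tolerance = 1e-7)
  # 2-column variant
  writeLines(c("# no sigma", "0.1 10", "0.2 5", "0.3 2"), path)
  two <- read_profile_dat(path)
  expect_equal(two$I, c(10, 5, 2))
  expect_true(all(is.na(two$sigma)))
})
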