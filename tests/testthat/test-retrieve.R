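retrieve_db <- function() fixture("small_db", function()
  build_database(canonical_shape_set(10), s_max = 50, n_s = 512))

test_that("chi score closed forms: perfect fits and a hand-computed case", {
  q <- 1:3
  e1 <- saxs_profile(q, c(2, 4, 6), sigma = rep(1, 3))
  fit <- chi_score(e1, c(2, 4, 6))
  expect_equal(fit$c, 1)
  expect_equal(fit$chi, 0)
  # least-squares c absorbs a pure scale
  e2 <- saxs_profile(q, 2 * c(2, 4, 6), sigma = rep(1, 3))
  fit2 <- chi_score(e2, c(2, 4, 6))
  expect_equal(fit2$c, 2)
  expect_equal(fit2$chi, 0, tolerance = 1e-12)
  # hand case: I_e = (1,2,3), I_m = (1,1,1), sigma = 1:
  # c = 6/3 = 2, chi = sqrt(((1-2)^2 + 0 + 1^2)/3) = sqrt(2/3)
  e3 <- saxs_profile(q, c(1, 2, 3), sigma = rep(1, 3))
  fit3 <- chi_score(e3, c(1, 1, 1))
  expect_equal(fit3$c, 2)
  expect_equal(fit3$chi, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(fit3$n_points, 3L)
  expect_error(chi_score(e3, c(0, 0, 0)), "degenerate")
})

test_that("free scale never fits worse than c fixed at one", {
  set.seed(2)
  q <- seq(0.1, 1, length.out = 30)
  for (k in 1:20) {
    Ie <- exp(-q * runif(1, 0.5, 3)) * runif(1, 0.5, 50)
    Im <- exp(-q * runif(1, 0.5, 3))
    sg <- rep(runif(1, 0.01, 1), 30)
    prof <- saxs_profile(q, Ie, sigma = sg)
    free <- chi_score(prof, Im)
    fixed <- sqrt(mean(((Ie - Im) / sg)^2))
    expect_lte(free$chi, fixed + 1e-12)
  }
})

test_that("golden-section search contracts by the golden ratio to the minimum", {
  gs <- golden_section_minimize(function(r) (r - 1)^2, 0.8, 1.25, 0.01)
  expect_equal(gs$x_star, 1.0, tolerance = 0.01)
  # iteration count follows the contraction arithmetic: width shrinks by
  # (sqrt(5)-1)/2 each pass, so 0.45 r0 -> 0.01 r0 takes 8 iterations
  r0 <- 90
  gs2 <- golden_section_minimize(function(r) (r - 95)^2,
                                 0.8 * r0, 1.25 * r0, 0.01 * r0)
  expect_equal(gs2$n_iterations, 8L)
  expect_lte(gs2$n_iterations, 10L)
  phi <- (sqrt(5) - 1) / 2
  expect_equal(diff(gs2$bracket), 0.45 * r0 * phi^8, tolerance = 1e-9)
  expect_lte(diff(gs2$bracket), 0.01 * r0)
  # monotone increasing objective: minimum at the lower end
  gs3 <- golden_section_minimize(identity, 2, 3, 0.005)
  expect_lt(gs3$x_star, 2 + 0.005)
})

test_that("a stored profile retrieves itself with vanishing chi", {
  db <- retrieve_db()
  id <- names(db$entries)[2]
  q <- db$s[db$s > 0 & db$s < 30]
  query <- saxs_profile(q, model_profile_at_radius(db, id, 1, q),
                        sigma = rep(1, length(q)))
  res <- shape_search(db, query, r0 = 1, tol = 1e-8, K = 4,
                      sigma_mode = "relative", compute_maps = FALSE)
  expect_equal(res$ranking$model_id[1], id)
  expect_lt(res$ranking$chi[1], 1e-6)
  expect_equal(res$r_star, 1, tolerance = 1e-6)
})

test_that("duplicated models tie and break lexicographically", {
  models <- canonical_shape_set(10)[1:2]
  dup <- models[[1]]
  dup$label <- paste0("zz_", dup$label)
  db <- build_database(c(models, list(dup)), n_s = 256)
  q <- db$s[db$s > 0 & db$s < 20]
  query <- saxs_profile(q, model_profile_at_radius(db, models[[1]]$label,
                                                   1, q))
  res <- shape_search(db, query, r0 = 1, K = 3, sigma_mode = "relative",
                      compute_maps = FALSE)
  tab <- res$ranking
  a <- tab[tab$model_id == models[[1]]$label, ]
  b <- tab[tab$model_id == dup$label, ]
  expect_equal(a$chi, b$chi, tolerance = 1e-12)
  expect_lt(a$rank, b$rank)   # lexicographic tie break, stable
})

test_that("ranking and optimal radius are invariant to the profile scale", {
  db <- retrieve_db()
  set.seed(77)
  m <- make_shape("dumbbell", radius = 30, separation = 60, spacing = 4)
  q <- seq(0.01, 0.4, length.out = 150)
  I <- debye_profile(m, q)
  sg <- 0.01 * (I + 0.001 * I[1])   # relative errors with a floor at minima
  prof1 <- saxs_profile(q, I, sigma = sg)
  prof2 <- saxs_profile(q, 1e6 * I, sigma = 1e6 * sg)
  r1 <- shape_search(db, prof1, r0 = 55, compute_maps = FALSE)
  r2 <- shape_search(db, prof2, r0 = 55, compute_maps = FALSE)
  expect_equal(r1$ranking$model_id, r2$ranking$model_id)
  expect_equal(r1$r_star, r2$r_star, tolerance = 1e-12)
  expect_equal(r1$ranking$chi, r2$ranking$chi, tolerance = 1e-9)
  expect_equal(r2$ranking$c / r1$ranking$c, rep(1e6, 4), tolerance = 1e-9)
  # the query is a touching dumbbell; the database's dumbbell entry wins
  expect_equal(r1$ranking$model_id[1], "dumbbell_R10_d20")
})

test_that("per-model mode reports each model's own optimal radius", {
  db <- retrieve_db()
  m <- make_shape("sphere", radius = 25, spacing = 25 / 8)
  q <- seq(0.01, 0.5, length.out = 120)
  I <- debye_profile(m, q)
  res <- shape_search(db, saxs_profile(q, I, sigma = 0.01 * I), r0 = 22,
                      mode = "per_model", K = 4, compute_maps = FALSE)
  expect_equal(res$ranking$model_id[1], "sphere_R10")
  # radii are bounding-sphere radii: the query model's own nominal radius
  expect_equal(res$ranking$r[1], nominal_radius(m), tolerance = 0.02)
  expect_gt(length(unique(res$ranking$r)), 1L)
})

test_that("clustering separates the dumbbell family from blob and split spheres", {
  # constructed top set: 8 near-identical dumbbells, 1 fused blob (sphere),
  # 1 pair of well-separated spheres
  mk <- function(model) model_to_voxels(model, voxel_size = 1.2)
  maps <- c(
    lapply(1:8, function(k)
      mk(make_shape("dumbbell", radius = 10,
                    separation = 20 + 0.3 * (k - 4), spacing = 1.6))),
    list(mk(make_shape("sphere", radius = 12.6, spacing = 1.6))),
    list(mk(make_shape("dumbbell", radius = 10, separation = 45,
                       spacing = 1.6))))
  cl <- cluster_top_models(maps, overlap_threshold = 0.75)
  expect_length(unique(cl), 3L)
  expect_equal(cl[1:8], rep(1L, 8))   # largest class holds the best ranks
  expect_true(cl[9] != 1L && cl[10] != 1L && cl[9] != cl[10])
  # threshold limits
  expect_equal(length(unique(cluster_top_models(maps, 0))), 1L)
  expect_equal(length(unique(cluster_top_models(maps, 1 + 1e-9))),
               length(maps))
  # identical maps collapse to one class
  same <- replicate(4, maps[[1]], simplify = FALSE)
  expect_equal(unique(cluster_top_models(same, 0.75)), 1L)
})

test_that("averaging undoes rigid rotations of the same shape", {
  m <- make_shape("prolate", semi_axes = c(12, 6), spacing = 1.2)
  rot <- quat_to_matrix(c(cos(pi / 4), 0, 0, sin(pi / 4)))  # 90 deg about z
  m_rot <- bead_model(m$centers %*% t(rot), m$bead_radius, m$weights)
  map <- model_to_voxels(m, voxel_size = 1)
  map_rot <- model_to_voxels(m_rot, voxel_size = 1)
  avg <- average_models(list(map, map_rot))
  solo <- average_models(list(map))
  expect_identical(dim(avg$values), dim(solo$values))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  aligned_sim <- cosine(avg$values, solo$values)
  # without alignment the 90-degree rotation leaves little overlap
  pad <- function(mp) {
    big <- array(0, dim = dim(avg$values))
    d <- dim(mp$values)
    big[1:d[1], 1:d[2], 1:d[3]] <- mp$values
    big
  }
  raw_sim <- cosine(pad(map), pad(map_rot))
  expect_gt(aligned_sim, 0.9)      # equal up to resampling smoothing
  expect_gt(aligned_sim, raw_sim + 0.2)
  expect_equal(sum(avg$values), sum(map$values), tolerance = 0.05)
})
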