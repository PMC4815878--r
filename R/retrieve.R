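#' Chi score with analytic least-squares scale
#'
#' Goodness of fit between an experimental profile and a model profile on the
#' same q grid. The multiplicative scale `c` is obtained in closed form by
#' least squares, `c = sum(I_e I_m / sigma^2) / sum(I_m^2 / sigma^2)`, and the
#' score is the reduced residual
#' `chi = sqrt( (1/N) sum(((I_e - c I_m) / sigma)^2) )`. Bins that are empty
#' in the experiment or `NA` in the model are excluded and N reduced
#' accordingly.
#'
#' @param exp_profile a `saxs_profile`.
#' @param model_I model intensities on `exp_profile$q` (`NA` allowed).
#' @param sigma_mode `"sigma"` uses the experimental uncertainties (falling
#'   back to relative residuals where sigma is missing or zero);
#'   `"relative"` uses `sigma_i = I_e(q_i)` throughout (unweighted relative
#'   residuals).
#' @return an object of class `chi_fit`: `c`, `chi`, `n_points`.
#' @export
chi_score <- function(exp_profile, model_I,
                      sigma_mode = c("sigma", "relative")) {
  sigma_mode <- match.arg(sigma_mode)
  if (length(model_I) != length(exp_profile$q))
    stop("model_I must be on the experimental q grid")
  use <- exp_profile$n_pix > 0 & is.finite(exp_profile$I) & is.finite(model_I)
  # bins with no usable uncertainty (sigma and the relative-residual fallback
  # |I_e| both non-positive) carry no weightable information and are dropped;
  # exclusion, unlike an absolute fallback, keeps the fit scale invariant
  if (sigma_mode == "sigma") {
    sg_all <- exp_profile$sigma
    bad <- !is.finite(sg_all) | sg_all <= 0
    sg_all[bad] <- abs(exp_profile$I[bad])
  } else {
    sg_all <- abs(exp_profile$I)
  }
  use <- use & is.finite(sg_all) & sg_all > 0
  if (sum(use) < 3L) stop("insufficient data: fewer than 3 shared points")
  Ie <- exp_profile$I[use]
  Im <- model_I[use]
  if (all(Im == 0)) stop("degenerate model: all-zero profile")
  sg <- sg_all[use]
  w <- 1 / sg^2
  cc <- sum(w * Ie * Im) / sum(w * Im * Im)
  cc <- max(cc, 0)
  chi <- sqrt(mean(((Ie - cc * Im) / sg)^2))
  structure(list(c = cc, chi = chi, n_points = sum(use)), class = "chi_fit")
}

#' Golden-section minimization
#'
#' Derivative-free 1D minimization: the bracket shrinks by the golden ratio
#' `(sqrt(5) - 1) / 2` each iteration until its width is at most `tol`; the
#' midpoint of the final bracket is returned. With the retrieval defaults
#' (bracket `[0.8 r0, 1.25 r0]`, `tol = 0.01 r0`) this takes 8 iterations.
#'
#' @param f scalar function of one variable.
#' @param lower,upper bracket ends (`lower < upper`).
#' @param tol absolute bracket-width tolerance (> 0).
#' @return list: `x_star`, `f_star = f(x_star)`, `n_iterations`, `bracket`
#'   (final), `evaluations` (data.frame x, fx of every f call).
#' @export
golden_section_minimize <- function(f, lower, upper, tol) {
  stopifnot(lower < upper, tol > 0)
  phi <- (sqrt(5) - 1) / 2
  log_x <- numeric(0); log_f <- numeric(0)
  fx <- function(x) {
    v <- f(x)
    log_x <<- c(log_x, x); log_f <<- c(log_f, v)
    v
  }
  a <- lower; b <- upper
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- fx(x1); f2 <- fx(x2)
  it <- 0L
  while ((b - a) > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- fx(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- fx(x2)
    }
    it <- it + 1L
  }
  x_star <- (a + b) / 2
  list(x_star = x_star, f_star = fx(x_star), n_iterations = it,
       bracket = c(a, b),
       evaluations = data.frame(x = log_x, fx = log_f))
}

# Chi of every database model at one trial radius; returns the chi vector
# (named by model id) and the matching scale factors.
chi_at_radius <- function(db, exp_profile, r, sigma_mode = "sigma",
                          ids = NULL) {
  if (is.null(ids)) ids <- names(db$entries)
  chi <- numeric(length(ids)); cc <- numeric(length(ids))
  for (k in seq_along(ids)) {
    mi <- model_profile_at_radius(db, ids[k], r, exp_profile$q)
    fit <- chi_score(exp_profile, mi, sigma_mode = sigma_mode)
    chi[k] <- fit$chi; cc[k] <- fit$c
  }
  names(chi) <- ids; names(cc) <- ids
  list(chi = chi, c = cc)
}

#' Retrieve shape models matching a SAXS profile
#'
#' Searches the database for the models whose rescaled profiles best fit the
#' experimental profile under the chi score, optimizing the model radius by
#' golden-section search.
#'
#' Two modes: `"global"` minimizes `J(r) = min over models of chi(r)` over the
#' radius bracket and ranks all models at the optimum `r_star` (all database
#' models scaled to the same radius); `"per_model"` runs an independent
#' golden-section per model (the top 50 candidates at `r0` when the database
#' is larger) and ranks models by their own minimal chi, each reporting its
#' own radius.
#'
#' @param db a `shape_database`.
#' @param exp_profile the experimental `saxs_profile`.
#' @param r0 user-supplied radius guess (nm). When NULL it is estimated from a
#'   Guinier fit as the sphere-equivalent radius `Rg * sqrt(5/3)` (reported in
#'   the result).
#' @param mode `"global"` (default) or `"per_model"`.
#' @param K number of models to return (default 10).
#' @param bracket radius search range; default `c(0.8, 1.25) * r0`.
#' @param tol golden-section radius tolerance; default `0.01 * r0`.
#' @param sigma_mode passed to `chi_score`.
#' @param q_max optional upper q cut applied before fitting.
#' @param overlap_threshold passed to `cluster_top_models`.
#' @param voxel_size voxel edge for the rendered maps; default `r_star / 16`.
#' @param compute_maps set FALSE to skip map rendering and clustering.
#' @return an object of class `retrieval_result`: `ranking` (data.frame
#'   model_id, chi, c, r, rank, class), `r_star`, `r0`, `n_iterations`,
#'   `q_range`, `maps` (aligned top-K `voxel_map`s), `class_maps` (per-class
#'   averages), `average_map` (mean of all top-K), `mode`.
#' @export
shape_search <- function(db, exp_profile, r0 = NULL,
                         mode = c("global", "per_model"), K = 10,
                         bracket = NULL, tol = NULL,
                         sigma_mode = c("sigma", "relative"), q_max = NULL,
                         overlap_threshold = 0.75, voxel_size = NULL,
                         compute_maps = TRUE) {
  mode <- match.arg(mode)
  sigma_mode <- match.arg(sigma_mode)
  if (!length(db$entries)) stop("empty database")
  prof <- exp_profile
  if (!is.null(q_max)) {
    keep <- prof$q <= q_max
    prof <- saxs_profile(prof$q[keep], prof$I[keep], prof$sigma[keep],
                         n_patterns = prof$n_patterns,
                         n_pix = prof$n_pix[keep])
  }
  r0_estimated <- FALSE
  if (is.null(r0)) {
    g <- guinier_radius(prof)
    r0 <- g$Rg * sqrt(5 / 3)
    r0_estimated <- TRUE
    message(sprintf("r0 not supplied; Guinier estimate r0 = %.4g nm (Rg = %.4g nm)",
                    r0, g$Rg))
  }
  stopifnot(r0 > 0)
  if (is.null(bracket)) bracket <- c(0.8, 1.25) * r0
  if (is.null(tol)) tol <- 0.01 * r0
  usable <- prof$n_pix > 0 & is.finite(prof$I)
  if (mean(prof$q[usable] * max(bracket) > max(db$s)) > 0.5)
    stop("range error: q*r exceeds the database s_max over more than half ",
         "of the profile; rebuild the database with a larger s_max")
  K <- min(K, length(db$entries))
  ids <- names(db$entries)

  if (mode == "global") {
    gs <- golden_section_minimize(
      function(r) min(chi_at_radius(db, prof, r, sigma_mode)$chi),
      bracket[1], bracket[2], tol)
    r_star <- gs$x_star
    at <- chi_at_radius(db, prof, r_star, sigma_mode)
    ord <- order(at$chi, ids)
    top <- ids[ord[seq_len(K)]]
    ranking <- data.frame(
      model_id = top, chi = at$chi[top], c = at$c[top],
      r = rep(r_star, K), rank = seq_len(K), row.names = NULL)
    n_iter <- gs$n_iterations
  } else {
    cand <- ids
    if (length(ids) > 50) {
      at0 <- chi_at_radius(db, prof, r0, sigma_mode)
      cand <- ids[order(at0$chi, ids)][1:50]
    }
    rows <- lapply(cand, function(id) {
      gs <- golden_section_minimize(
        function(r) chi_at_radius(db, prof, r, sigma_mode, ids = id)$chi,
        bracket[1], bracket[2], tol)
      at <- chi_at_radius(db, prof, gs$x_star, sigma_mode, ids = id)
      data.frame(model_id = id, chi = at$chi[[1]], c = at$c[[1]],
                 r = gs$x_star, n_iter = gs$n_iterations)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$chi, tab$model_id), ]
    ranking <- data.frame(tab[seq_len(K), c("model_id", "chi", "c", "r")],
                          rank = seq_len(K), row.names = NULL)
    r_star <- ranking$r[1]
    n_iter <- max(tab$n_iter)
  }

  qr <- range(prof$q[usable])
  res <- list(ranking = ranking, r_star = r_star, r0 = r0,
              r0_estimated = r0_estimated, n_iterations = n_iter,
              q_range = qr, mode = mode, sigma_mode = sigma_mode)
  if (compute_maps) {
    if (is.null(voxel_size)) voxel_size <- r_star / 16
    maps <- lapply(seq_len(K), function(k)
      model_to_voxels(db_model_at_radius(db, ranking$model_id[k],
                                         ranking$r[k]),
                      voxel_size = voxel_size))
    names(maps) <- ranking$model_id
    cl <- cluster_top_models(maps, overlap_threshold = overlap_threshold)
    res$ranking$class <- cl
    res$maps <- maps
    res$class_maps <- lapply(sort(unique(cl)), function(g)
      average_models(maps[cl == g]))
    names(res$class_maps) <- paste0("class_", sort(unique(cl)))
    res$average_map <- average_models(maps)
  }
  class(res) <- "retrieval_result"
  res
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf(
    "<retrieval_result: %d models, mode '%s', r* = %.4g nm (r0 = %.4g), %d golden-section iterations>\n",
    nrow(x$ranking), x$mode, x$r_star, x$r0, x$n_iterations))
  print(x$ranking, digits = 4)
  invisible(x)
}

# --- map alignment helpers ------------------------------------------------

# Weighted centroid (nm) of a voxel map.
map_centroid <- function(map) {
  d <- dim(map$values)
  w <- as.vector(map$values)
  tot <- sum(w)
  if (tot <= 0) return(map$origin + (d - 1) / 2 * map$voxel_size)
  ax <- function(k) map$origin[k] + (seq_len(d[k]) - 1) * map$voxel_size
  gx <- rep(ax(1), times = d[2] * d[3])
  gy <- rep(rep(ax(2), each = d[1]), times = d[3])
  gz <- rep(ax(3), each = d[1] * d[2])
  c(sum(w * gx), sum(w * gy), sum(w * gz)) / tot
}

# Deterministic canonical frame: principal axes of the occupancy-weighted
# covariance, eigenvalues decreasing; the sign of each axis is fixed by
# requiring a non-negative third central moment along it (near-zero moments
# leave the axis as returned by eigen); a final flip of the axis with the
# smallest |moment| restores det = +1 if needed.
map_principal_frame <- function(map) {
  d <- dim(map$values)
  w <- as.vector(map$values)
  ctr <- map_centroid(map)
  ax <- function(k) map$origin[k] + (seq_len(d[k]) - 1) * map$voxel_size
  gx <- rep(ax(1), times = d[2] * d[3]) - ctr[1]
  gy <- rep(rep(ax(2), each = d[1]), times = d[3]) - ctr[2]
  gz <- rep(ax(3), each = d[1] * d[2]) - ctr[3]
  X <- cbind(gx, gy, gz)
  tot <- sum(w)
  cov <- crossprod(X * sqrt(pmax(w, 0) / max(tot, .Machine$double.eps)))
  eg <- eigen(cov, symmetric = TRUE)
  V <- eg$vectors
  proj <- X %*% V
  m3 <- colSums(w * proj^3) / max(tot, .Machine$double.eps)
  sdv <- sqrt(colSums(w * proj^2) / max(tot, .Machine$double.eps))
  rel <- ifelse(sdv > 0, m3 / sdv^3, 0)  # dimensionless skewness per axis
  for (k in 1:3) if (rel[k] < -1e-8) V[, k] <- -V[, k]
  if (det(V) < 0) {
    k <- which.min(abs(rel))
    V[, k] <- -V[, k]
  }
  list(center = ctr, axes = V)
}

# Trilinear sample of a map at arbitrary points (n x 3, nm); 0 outside.
trilinear_sample <- function(map, pts) {
  d <- dim(map$values)
  t <- sweep(pts, 2L, map$origin) / map$voxel_size   # 0-based voxel coords
  i0 <- floor(t)
  fr <- t - i0
  out <- numeric(nrow(pts))
  getv <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
    v <- numeric(length(ix))
    if (any(ok))
      v[ok] <- map$values[cbind(ix[ok] + 1L, iy[ok] + 1L, iz[ok] + 1L)]
    v
  }
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    wgt <- (ifelse(cx == 1, fr[, 1], 1 - fr[, 1]) *
            ifelse(cy == 1, fr[, 2], 1 - fr[, 2]) *
            ifelse(cz == 1, fr[, 3], 1 - fr[, 3]))
    out <- out + wgt * getv(i0[, 1] + cx, i0[, 2] + cy, i0[, 3] + cz)
  }
  out
}

# Resample a map into its canonical (centroid + principal axes) frame on a
# symmetric grid: half-extent he, voxel size vs.
align_map_to_frame <- function(map, he, vs) {
  fr <- map_principal_frame(map)
  n <- 2L * as.integer(ceiling(he / vs)) + 1L
  axis <- (seq_len(n) - (n + 1) / 2) * vs
  gx <- rep(axis, times = n * n)
  gy <- rep(rep(axis, each = n), times = n)
  gz <- rep(axis, each = n * n)
  Y <- cbind(gx, gy, gz)                 # canonical coordinates
  X <- Y %*% t(fr$axes)                  # back to original frame
  X <- sweep(X, 2L, fr$center, "+")
  vals <- trilinear_sample(map, X)
  voxel_map(array(vals, dim = c(n, n, n)), vs, origin = rep(axis[1], 3))
}

# Shared canonical grid parameters for a set of maps.
common_frame_params <- function(maps) {
  he <- 0; vs <- Inf
  for (m in maps) {
    d <- dim(m$values)
    ctr <- map_centroid(m)
    ax <- function(k) m$origin[k] + (seq_len(d[k]) - 1) * m$voxel_size
    corners <- as.matrix(expand.grid(range(ax(1)), range(ax(2)),
                                     range(ax(3))))
    he <- max(he, max(sqrt(rowSums(sweep(corners, 2L, ctr)^2))))
    vs <- min(vs, m$voxel_size)
  }
  list(he = he, vs = vs)
}

#' Cluster the top retrieved models by real-space similarity
#'
#' Each map is aligned to its canonical frame (centroid plus principal axes
#' with deterministic sign), resampled to a shared grid, and compared pairwise
#' by normalized voxel overlap (cosine similarity of the occupancy vectors).
#' Single-linkage clustering joins models with overlap at or above the
#' threshold; classes are numbered in rank order of their best-ranked member.
#'
#' @param maps named list of `voxel_map` in rank order.
#' @param overlap_threshold similarity threshold in [0, 1] (default 0.75).
#' @return integer class labels, parallel to `maps`.
#' @export
cluster_top_models <- function(maps, overlap_threshold = 0.75) {
  K <- length(maps)
  if (K == 1L) return(1L)
  fp <- common_frame_params(maps)
  aligned <- lapply(maps, align_map_to_frame, he = fp$he, vs = fp$vs)
  vecs <- vapply(aligned, function(m) as.vector(m$values),
                 numeric(length(aligned[[1]]$values)))
  nrm <- sqrt(colSums(vecs^2))
  sim <- crossprod(vecs) / outer(nrm, nrm)
  # single linkage via union-find
  parent <- seq_len(K)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (a in 1:(K - 1)) for (b in (a + 1):K)
    if (sim[a, b] >= overlap_threshold) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  roots <- vapply(seq_len(K), find, integer(1))
  # classes in rank order of best member (maps arrive rank-ordered)
  uniq <- unique(roots)
  match(roots, uniq)
}

#' Average a set of voxel maps
#'
#' Aligns every member to its canonical frame (so rigid rotations and
#' translations are undone), resamples all members to one shared symmetric
#' grid covering the union of their bounding boxes, and returns the voxel-wise
#' mean.
#'
#' @param maps list of `voxel_map` (>= 1).
#' @return a `voxel_map` on the shared grid.
#' @export
average_models <- function(maps) {
  if (!length(maps)) stop("need at least one map")
  fp <- common_frame_params(maps)
  aligned <- lapply(maps, align_map_to_frame, he = fp$he, vs = fp$vs)
  acc <- aligned[[1]]$values
  if (length(aligned) > 1)
    for (k in 2:length(aligned)) acc <- acc + aligned[[k]]$values
  voxel_map(acc / length(aligned), aligned[[1]]$voxel_size,
            aligned[[1]]$origin)
}
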