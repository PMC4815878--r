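#' Bead models
#'
#' A bead model represents a three-dimensional shape as a set of identical
#' small spheres ("beads") with optional per-bead scattering weights. It is
#' the real-space representation used throughout: the simulator scatters from
#' it coherently, the Debye formula turns it into a 1D SAXS profile, and the
#' shape database stores a unit-radius copy of its coordinates.
#'
#' @param centers numeric matrix (n x 3) of bead centers in nm.
#' @param bead_radius radius of every bead in nm (single positive number).
#' @param weights per-bead scattering weights; default 1 for every bead.
#' @param label text identifier.
#' @return an object of class `bead_model` with elements `centers`,
#'   `bead_radius`, `weights`, `label`.
#' @export
bead_model <- function(centers, bead_radius, weights = NULL, label = "model") {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L || nrow(centers) < 1L)
    stop("bead model needs an n x 3 coordinate matrix with at least one bead")
  if (!is.numeric(bead_radius) || length(bead_radius) != 1L || bead_radius <= 0)
    stop("bead_radius must be a single positive number")
  if (is.null(weights)) weights <- rep(1, nrow(centers))
  if (length(weights) != nrow(centers) || any(weights <= 0))
    stop("weights must be positive and match the number of beads")
  storage.mode(centers) <- "double"
  structure(
    list(centers = unname(centers), bead_radius = bead_radius,
         weights = as.numeric(weights), label = as.character(label)),
    class = "bead_model"
  )
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model '%s': %d beads, bead radius %.3g nm, R = %.4g nm>\n",
              x$label, nrow(x$centers), x$bead_radius, nominal_radius(x)))
  invisible(x)
}

#' @rdname bead_model
#' @param model a `bead_model`.
#' @return `n_beads()`: integer bead count.
#' @export
n_beads <- function(model) nrow(model$centers)

#' Recenter a bead model at its weighted centroid
#'
#' @param model a `bead_model`.
#' @return the model translated so the weight-averaged bead center is at the
#'   origin.
#' @export
recenter_model <- function(model) {
  w <- model$weights / sum(model$weights)
  ctr <- colSums(model$centers * w)
  model$centers <- sweep(model$centers, 2L, ctr)
  model
}

#' Nominal radius of a bead model
#'
#' The radius of the bounding sphere about the weighted centroid: the maximum
#' distance from the centroid to any bead center plus the bead radius. This is
#' the size handle used when database models are rescaled during retrieval.
#'
#' @param model a `bead_model`.
#' @return radius in nm.
#' @export
nominal_radius <- function(model) {
  w <- model$weights / sum(model$weights)
  ctr <- colSums(model$centers * w)
  d <- sweep(model$centers, 2L, ctr)
  max(sqrt(rowSums(d * d))) + model$bead_radius
}

#' Volume-equivalent sphere radius of a bead model
#'
#' Lattice bead models occupy a volume of `n_beads * spacing^3` with
#' `spacing = 2 * bead_radius`. This returns the radius of the sphere (or of
#' each of `n_bodies` equal spheres) holding that volume — the size measure
#' that is robust to the surface fattening of lattice discretization.
#'
#' @param model a `bead_model` built on a cubic lattice.
#' @param n_bodies number of equal bodies the model consists of (2 for a
#'   dumbbell).
#' @return radius in nm.
#' @export
volume_sphere_radius <- function(model, n_bodies = 1) {
  spacing <- 2 * model$bead_radius
  (3 * n_beads(model) * spacing^3 / (4 * pi * n_bodies))^(1 / 3)
}

#' Generate canonical bead shapes
#'
#' Fills a requested solid with beads on a cubic lattice and recenters the
#' result at its centroid. Available shapes: a solid sphere, a prolate
#' spheroid with semi-axes (a, b, b), a dumbbell of two equal spheres, and a
#' cube.
#'
#' @param kind one of `"sphere"`, `"prolate"`, `"dumbbell"`, `"cube"`.
#' @param radius sphere/dumbbell sphere radius in nm (also the cube
#'   half-edge).
#' @param semi_axes for `"prolate"`: numeric `c(a, b)` with `a >= b`, the long
#'   and short semi-axes in nm.
#' @param separation for `"dumbbell"`: distance between the two sphere
#'   centers in nm.
#' @param spacing cubic lattice spacing in nm (bead-center spacing). The bead
#'   radius is set to `spacing / 2` so neighboring beads touch.
#' @param label optional identifier; a descriptive default is derived from the
#'   parameters.
#' @return a `bead_model`.
#' @examples
#' sph <- make_shape("sphere", radius = 10, spacing = 2)
#' nominal_radius(sph)
#' @export
make_shape <- function(kind = c("sphere", "prolate", "dumbbell", "cube"),
                       radius = NULL, semi_axes = NULL, separation = NULL,
                       spacing = 1, label = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(spacing) || spacing <= 0)
    stop("spacing must be positive")
  lattice <- function(half_extent) {
    # symmetric lattice through the origin covering [-h, h] per axis
    ax <- lapply(half_extent, function(h) {
      n <- floor(h / spacing)
      seq(-n, n) * spacing
    })
    as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  }
  if (kind == "sphere") {
    if (is.null(radius) || radius <= 0) stop("sphere needs a positive radius")
    g <- lattice(rep(radius, 3))
    keep <- rowSums(g * g) <= radius^2
    centers <- g[keep, , drop = FALSE]
    if (is.null(label)) label <- sprintf("sphere_R%g", radius)
  } else if (kind == "cube") {
    if (is.null(radius) || radius <= 0) stop("cube needs a positive half-edge (radius)")
    g <- lattice(rep(radius, 3))
    centers <- g  # the lattice itself fills the cube
    if (is.null(label)) label <- sprintf("cube_h%g", radius)
  } else if (kind == "prolate") {
    if (is.null(semi_axes) || length(semi_axes) != 2L || any(semi_axes <= 0))
      stop("prolate needs semi_axes = c(a, b) with positive entries")
    a <- semi_axes[1]; b <- semi_axes[2]
    if (a < b) stop("prolate requires a >= b")
    g <- lattice(c(a, b, b))
    keep <- (g[, 1] / a)^2 + (g[, 2] / b)^2 + (g[, 3] / b)^2 <= 1
    centers <- g[keep, , drop = FALSE]
    if (is.null(label)) label <- sprintf("prolate_a%g_b%g", a, b)
  } else { # dumbbell
    if (is.null(radius) || radius <= 0) stop("dumbbell needs a positive sphere radius")
    if (is.null(separation) || separation <= 0)
      stop("dumbbell needs a positive center separation")
    if (separation > 20 * radius)
      warning("dumbbell separation exceeds 20 sphere radii; spheres are far apart")
    g <- lattice(c(separation / 2 + radius, radius, radius))
    d1 <- (g[, 1] - separation / 2)^2 + g[, 2]^2 + g[, 3]^2
    d2 <- (g[, 1] + separation / 2)^2 + g[, 2]^2 + g[, 3]^2
    keep <- d1 <= radius^2 | d2 <= radius^2
    centers <- g[keep, , drop = FALSE]
    if (is.null(label)) label <- sprintf("dumbbell_R%g_d%g", radius, separation)
  }
  if (nrow(centers) == 0L)
    stop("no lattice point falls inside the requested solid; decrease spacing")
  recenter_model(bead_model(centers, bead_radius = spacing / 2, label = label))
}

#' Read bead centers from a PDB file
#'
#' Atom coordinates become bead centers (converted from Angstrom to nm).
#' Optionally coarse-grains to one bead per residue (the CA atom, or the
#' residue's coordinate mean when no CA is present).
#'
#' @param path PDB file path.
#' @param bead_radius bead radius in nm assigned to the model.
#' @param per_residue if TRUE, one bead per residue instead of one per atom.
#' @return a `bead_model` labelled with the file name.
#' @export
read_bead_pdb <- function(path, bead_radius = 0.25, per_residue = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (per_residue) {
    key <- paste(at$chain, at$resno, sep = "_")
    ca <- at$elety == "CA"
    pick <- function(k) {
      rows <- which(key == k)
      cak <- rows[ca[rows]]
      if (length(cak)) {
        as.numeric(at[cak[1], c("x", "y", "z")])
      } else {
        colMeans(at[rows, c("x", "y", "z")])
      }
    }
    centers <- t(vapply(unique(key), pick, numeric(3)))
  } else {
    centers <- as.matrix(at[, c("x", "y", "z")])
  }
  bead_model(centers / 10, bead_radius = bead_radius,
             label = sub("\\.pdb$", "", basename(path), ignore.case = TRUE))
}
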