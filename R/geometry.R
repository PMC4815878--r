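#' Detector geometry
#'
#' Flat area detector downstream of the sample, normal to the beam. Pixel
#' coordinates are 0-based with the pixel center at integer coordinates; the
#' beam center may be fractional. The wavenumber k = 2*pi/lambda is derived,
#' never stored.
#'
#' @param wavelength_nm X-ray wavelength in nm.
#' @param distance_mm sample-to-detector distance in mm.
#' @param pixel_mm pixel pitch in mm.
#' @param n_fast,n_slow pixel counts along the fast (x) and slow (y) axes.
#' @param center beam center `c(cx, cy)` in fractional pixels; defaults to the
#'   detector middle.
#' @param mask logical matrix (`n_slow` x `n_fast`), TRUE = usable pixel.
#' @return an object of class `detector_geometry`.
#' @export
detector_geometry <- function(wavelength_nm = 2, distance_mm = 500,
                              pixel_mm = 1.5, n_fast = 64, n_slow = 64,
                              center = NULL, mask = NULL) {
  stopifnot(wavelength_nm > 0, distance_mm > 0, pixel_mm > 0,
            n_fast >= 2, n_slow >= 2)
  if (is.null(center)) center <- c((n_fast - 1) / 2, (n_slow - 1) / 2)
  if (center[1] < 0 || center[1] >= n_fast || center[2] < 0 || center[2] >= n_slow)
    stop("beam center must lie inside the detector")
  if (is.null(mask)) mask <- matrix(TRUE, n_slow, n_fast)
  if (!identical(dim(mask), c(as.integer(n_slow), as.integer(n_fast))))
    stop("mask must be an n_slow x n_fast logical matrix")
  structure(
    list(wavelength_nm = wavelength_nm, distance_mm = distance_mm,
         pixel_mm = pixel_mm, n_fast = as.integer(n_fast),
         n_slow = as.integer(n_slow), center = as.numeric(center),
         mask = mask),
    class = "detector_geometry"
  )
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector %dx%d px, %.3g mm pitch, D = %.4g mm, lambda = %.3g nm, center (%.2f, %.2f)>\n",
    x$n_fast, x$n_slow, x$pixel_mm, x$distance_mm, x$wavelength_nm,
    x$center[1], x$center[2]))
  invisible(x)
}

# Pixel index grids as vectors of length n_slow * n_fast in column-major
# (R matrix) order: row index j (slow), column index i (fast), both 0-based.
pixel_index_grid <- function(geometry) {
  i <- rep(0:(geometry$n_fast - 1L), each = geometry$n_slow)
  j <- rep(0:(geometry$n_slow - 1L), times = geometry$n_fast)
  list(i = i, j = j)
}

#' Scattering vectors of detector pixels
#'
#' Maps pixel indices to reciprocal-space vectors on the Ewald sphere:
#' q = k (s_hat - z_hat) with k = 2*pi/lambda and s_hat the unit vector from
#' the sample to the pixel center. The magnitude is |q| = (4*pi/lambda)
#' sin(alpha/2) with alpha the full scattering angle.
#'
#' @param geometry a `detector_geometry`.
#' @param i,j 0-based pixel indices along the fast and slow axes (vectors of
#'   equal length). Default: every pixel, in R matrix (column-major) order.
#' @param center beam center override `c(cx, cy)`; defaults to the geometry's.
#' @return list with `q` (n x 3 matrix, nm^-1), `qmag` (|q|), and `alpha`
#'   (full scattering angle, rad).
#' @export
pixel_q_vectors <- function(geometry, i = NULL, j = NULL, center = NULL) {
  if (is.null(i) || is.null(j)) {
    g <- pixel_index_grid(geometry)
    i <- g$i; j <- g$j
  }
  if (is.null(center)) center <- geometry$center
  k <- 2 * pi / geometry$wavelength_nm
  x <- (i - center[1]) * geometry$pixel_mm
  y <- (j - center[2]) * geometry$pixel_mm
  D <- geometry$distance_mm
  s <- sqrt(x * x + y * y + D * D)
  qx <- k * x / s
  qy <- k * y / s
  qz <- k * (D / s - 1)
  alpha <- atan2(sqrt(x * x + y * y), D)
  list(q = cbind(qx, qy, qz), qmag = sqrt(qx^2 + qy^2 + qz^2), alpha = alpha)
}

#' Flat-region cutoff angle
#'
#' Near the origin of reciprocal space the Ewald sphere is approximately flat.
#' The flat region is defined by the fractional departure of the sphere from
#' its tangent plane: pixels with 1 - cos(alpha) <= flat_tol, alpha being the
#' full scattering angle. The corresponding half-angle cutoff is
#' arccos(1 - flat_tol) / 2; at the default 1% tolerance it is about 0.07 rad.
#'
#' @param flat_tol fractional Ewald-sphere departure tolerance in (0, 1].
#' @return the cutoff half-angle alpha/2 in rad.
#' @export
flat_cutoff_angle <- function(flat_tol = 0.01) {
  stopifnot(flat_tol > 0, flat_tol <= 1)
  acos(1 - flat_tol) / 2
}

#' Flat-region pixel mask
#'
#' @param geometry a `detector_geometry`.
#' @param flat_tol fractional Ewald-sphere departure tolerance (default 0.01).
#' @param center beam center override.
#' @return logical `n_slow` x `n_fast` matrix: TRUE where the pixel is inside
#'   the flat region and unmasked in the geometry.
#' @export
flat_region_mask <- function(geometry, flat_tol = 0.01, center = NULL) {
  stopifnot(flat_tol > 0)
  qv <- pixel_q_vectors(geometry, center = center)
  flat <- (1 - cos(qv$alpha)) <= flat_tol
  matrix(flat, geometry$n_slow, geometry$n_fast) & geometry$mask
}
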