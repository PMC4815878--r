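#' Normalized uniform-sphere amplitude
#'
#' `Phi(x) = 3 (sin x - x cos x) / x^3`, the scattering amplitude of a uniform
#' sphere of radius a evaluated at x = q a, normalized so `Phi(0) = 1`. A
#' series expansion is used near 0 for numerical stability.
#'
#' @param x numeric vector (q times sphere radius).
#' @return amplitude values.
#' @export
sphere_amplitude <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-3
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' SAXS profile of a bead model by the Debye formula
#'
#' Orientation-averaged intensity of a bead model:
#' `I(q) = Phi^2(q a) * sum_i sum_j w_i w_j sinc(q r_ij)` with `a` the bead
#' radius, `r_ij` pairwise bead-center distances and `sinc(x) = sin(x)/x`
#' (1 at x = 0). At q = 0 this equals `(sum w)^2`. Exact O(n^2) pair sums are
#' used up to `histogram_threshold` beads; above it, pair distances are binned
#' into `n_hist_bins` histogram bins (agreeing with the exact sum to well
#' under 1%).
#'
#' @param model a `bead_model`.
#' @param q scattering-vector magnitudes (nm^-1, >= 0).
#' @param histogram_threshold bead count above which the distance histogram is
#'   used (default 2000).
#' @param n_hist_bins number of distance-histogram bins (default 1000).
#' @return intensity vector, same length as `q`.
#' @export
debye_profile <- function(model, q, histogram_threshold = 2000,
                          n_hist_bins = 1000) {
  if (!inherits(model, "bead_model") || n_beads(model) < 1L)
    stop("model must be a non-empty bead_model")
  if (any(q < 0)) stop("q must be non-negative")
  w <- model$weights
  self_term <- sum(w * w)
  if (n_beads(model) == 1L) {
    pair_sum <- numeric(length(q))
  } else if (n_beads(model) > histogram_threshold) {
    # bounding-sphere diameter bounds every pair distance
    ctr <- colSums(model$centers * (w / sum(w)))
    d <- sweep(model$centers, 2L, ctr)
    dmax <- 2 * max(sqrt(rowSums(d * d))) * (1 + 1e-12)
    hist <- .debye_hist_cpp(model$centers, w, as.integer(n_hist_bins), dmax)
    centers <- (seq_len(n_hist_bins) - 0.5) * dmax / n_hist_bins
    keep <- hist$h > 0
    pair_sum <- .debye_pairs_cpp(as.numeric(q), centers[keep], hist$h[keep])
  } else {
    pd <- .pair_dists_cpp(model$centers, w)
    pair_sum <- .debye_pairs_cpp(as.numeric(q), pd$d, pd$w2)
  }
  phi2 <- sphere_amplitude(q * model$bead_radius)^2
  # the exact quantity is a spherical average of |F|^2, hence non-negative;
  # clip the tiny negative excursions of the histogram approximation
  pmax(phi2 * (self_term + pair_sum), 0)
}

#' Brute-force orientation average of the bead-sum intensity
#'
#' Independent cross-check of `debye_profile`: averages the coherent bead-sum
#' intensity `|sum_j w_j exp(i q u . x_j)|^2` over near-uniform unit
#' directions `u` on a Fibonacci sphere, multiplied by the squared bead form
#' factor. Converges to the Debye profile as the number of orientations
#' grows.
#'
#' @param model a `bead_model`.
#' @param q scattering-vector magnitudes (nm^-1).
#' @param n_orientations number of quadrature directions (>= 100).
#' @return intensity vector, same scale as `debye_profile`.
#' @export
spherical_average_oracle <- function(model, q, n_orientations = 500) {
  stopifnot(n_orientations >= 100)
  dirs <- fibonacci_sphere(n_orientations)
  raw <- .spherical_average_cpp(as.numeric(q), dirs, model$centers,
                                model$weights)
  raw * sphere_amplitude(q * model$bead_radius)^2
}

#' Guinier fit: radius of gyration
#'
#' Iterative Guinier analysis: fits `ln I` against `q^2` by least squares on
#' the low-q region, restricts the range to `q * Rg <= qrg_max` using the
#' current Rg estimate, and repeats to convergence. `Rg = sqrt(-3 * slope)`.
#' When the restricted range holds at least 8 points, a `q^4` term is included
#' in the fit (and the slope read from the `q^2` coefficient), which removes
#' most of the systematic bias the pure Guinier form picks up towards
#' `q Rg ~ 1.3`.
#'
#' @param profile a `saxs_profile` (positive intensities required in the fit
#'   range).
#' @param q_max_fit initial upper q limit for the fit; default: the full
#'   profile.
#' @param qrg_max Guinier-validity bound on q*Rg (default 1.3).
#' @return list: `Rg` (nm), `I0` (extrapolated intensity), `n_points`,
#'   `q_range` actually fitted.
#' @export
guinier_radius <- function(profile, q_max_fit = NULL, qrg_max = 1.3) {
  ok <- profile$n_pix > 0 & is.finite(profile$I) & profile$q > 0
  q <- profile$q[ok]; I <- profile$I[ok]
  if (is.null(q_max_fit)) q_max_fit <- max(q)
  use <- q <= q_max_fit
  q <- q[use]; I <- I[use]
  # the Guinier region ends before the first zero: keep the leading
  # positive run so deep minima cannot poison the initial fit
  pos_run <- cumprod(I > 0) > 0
  if (sum(pos_run) >= 5L) { q <- q[pos_run]; I <- I[pos_run] }
  fit_once <- function(q, I) {
    if (length(q) < 5L) stop("Guinier fit needs at least 5 points")
    if (any(I <= 0)) stop("non-positive intensities in the Guinier fit range")
    f <- if (length(q) >= 8L) lm(log(I) ~ I(q^2) + I(q^4))
         else lm(log(I) ~ I(q^2))
    slope <- coef(f)[[2]]
    if (!is.finite(slope) || slope >= 0)
      stop("no Guinier region: non-negative slope")
    list(Rg = sqrt(-3 * slope), I0 = exp(coef(f)[[1]]))
  }
  cur <- fit_once(q, I)
  for (it in 1:20) {
    keep <- q * cur$Rg <= qrg_max
    if (sum(keep) < 5L) keep <- seq_len(min(5L, length(q)))
    nxt <- fit_once(q[keep], I[keep])
    if (abs(nxt$Rg - cur$Rg) < 1e-6 * cur$Rg) { cur <- nxt; break }
    cur <- nxt
  }
  keep <- q * cur$Rg <= qrg_max
  list(Rg = cur$Rg, I0 = cur$I0, n_points = sum(keep),
       q_range = range(q[keep]))
}

#' First local minimum of a sampled curve
#'
#' Position of the first strict local minimum of I(q), refined by a parabolic
#' fit through the minimum and its neighbors. Used e.g. to locate the first
#' sphere-profile minimum at q R = 4.4934.
#'
#' @param q abscissa (strictly increasing).
#' @param I ordinate.
#' @return the refined q position, or NA when no interior minimum exists.
#' @export
first_minimum <- function(q, I) {
  n <- length(I)
  for (k in 2:(n - 1)) {
    if (I[k] < I[k - 1] && I[k] <= I[k + 1]) {
      # a run of tied values (e.g. a clipped-to-zero trough) is one minimum
      # located at its midpoint
      j <- k
      while (j < n && I[j + 1] == I[k]) j <- j + 1
      if (j > k) {
        if (j == n || I[j + 1] > I[k]) return((q[k] + q[j]) / 2)
        next
      }
      x <- q[(k - 1):(k + 1)]; y <- I[(k - 1):(k + 1)]
      denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
      a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
              x[1] * (y[3] - y[2])) / denom
      b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
              x[1]^2 * (y[2] - y[3])) / denom
      if (a > 0) return(-b / (2 * a))
      return(q[k])
    }
  }
  NA_real_
}

#' Principal-axis extents of a bead model
#'
#' Full surface-to-surface extents of the bead cloud along its principal
#' axes (eigenvectors of the weighted second-moment tensor), sorted in
#' decreasing order. For a prolate spheroid these are the long and short
#' diameters.
#'
#' @param model a `bead_model`.
#' @return numeric length-3: extents in nm, decreasing.
#' @export
principal_extents <- function(model) {
  m <- recenter_model(model)
  w <- m$weights / sum(m$weights)
  cov <- crossprod(m$centers * sqrt(w))
  ev <- eigen(cov, symmetric = TRUE)$vectors
  proj <- m$centers %*% ev
  ext <- apply(proj, 2, function(p) diff(range(p))) + 2 * m$bead_radius
  sort(ext, decreasing = TRUE)
}
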