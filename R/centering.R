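#' Beam-center search specification
#'
#' Grid-search settings for Friedel-pair center refinement: the search covers
#' `initial_center + (-half_width .. half_width)` in steps of `step` pixels on
#' both axes, scored inside the flat region of the Ewald sphere.
#'
#' @param initial_center `c(cx, cy)` fractional-pixel starting center.
#' @param half_width grid half-width in pixels.
#' @param step grid step in pixels (> 0, <= half_width).
#' @param flat_tol fractional Ewald-sphere departure defining the flat region
#'   (default 0.01).
#' @param refine if TRUE, a second grid pass at `step / 4` around the first
#'   minimum.
#' @return an object of class `center_search_spec`.
#' @export
center_search_spec <- function(initial_center, half_width = 5, step = 1,
                               flat_tol = 0.01, refine = FALSE) {
  stopifnot(step > 0, half_width >= step, flat_tol > 0, flat_tol < 1,
            length(initial_center) == 2L)
  structure(list(initial_center = as.numeric(initial_center),
                 half_width = half_width, step = step, flat_tol = flat_tol,
                 refine = isTRUE(refine)),
            class = "center_search_spec")
}

#' Friedel-pair asymmetry score
#'
#' For a trial beam center, each flat-region pixel p is paired with its
#' Friedel partner p' (the reflection of p through the center, rounded to the
#' nearest pixel). For a real scattering density I(q) = I(-q), so at the true
#' center paired intensities agree up to noise. The score is the mean over
#' valid pairs of `(I(p) - I(p'))^2 / max(I(p) + I(p'), 1)` — a
#' Poisson-variance-aware squared difference; the floor of 1 in the
#' denominator keeps empty pairs finite. Pairs with either pixel masked or
#' off-detector are skipped.
#'
#' @param pattern a `scattering_pattern`.
#' @param trial_center `c(cx, cy)` in fractional pixels, inside the detector.
#' @param flat_mask logical matrix from `flat_region_mask`; computed at the
#'   trial center when NULL.
#' @param min_pairs minimum number of valid pairs (default 50).
#' @return non-negative score (smaller = more centrosymmetric).
#' @export
friedel_score <- function(pattern, trial_center, flat_mask = NULL,
                          min_pairs = 50) {
  geom <- pattern$geometry
  if (trial_center[1] < 0 || trial_center[1] >= geom$n_fast ||
      trial_center[2] < 0 || trial_center[2] >= geom$n_slow)
    stop("trial center outside detector")
  if (is.null(flat_mask))
    flat_mask <- flat_region_mask(geom, center = trial_center)
  counts <- pattern$counts
  idx <- which(flat_mask & !is.na(counts))
  if (!length(idx)) stop("no usable flat-region pixels")
  # 0-based pixel coordinates of the flat-region pixels
  j <- (idx - 1L) %% geom$n_slow          # slow (row)
  i <- (idx - 1L) %/% geom$n_slow         # fast (column)
  # Friedel partner: reflection through the trial center, nearest pixel
  ip <- as.integer(round(2 * trial_center[1] - i))
  jp <- as.integer(round(2 * trial_center[2] - j))
  ok <- ip >= 0L & ip < geom$n_fast & jp >= 0L & jp < geom$n_slow
  if (!any(ok)) stop("insufficient Friedel pairs: none on the detector")
  pidx <- jp[ok] + 1L + ip[ok] * geom$n_slow
  a <- counts[idx[ok]]
  b <- counts[pidx]
  use <- !is.na(b)
  a <- a[use]; b <- b[use]
  if (length(a) < min_pairs)
    stop("insufficient Friedel pairs: ", length(a), " < ", min_pairs)
  mean((a - b)^2 / pmax(a + b, 1))
}

#' Optimize the beam center by Friedel symmetry
#'
#' Exhaustive grid search around the initial center minimizing
#' `friedel_score` in the flat region. Ties are broken by smallest Euclidean
#' distance to the initial center, then lexicographically by (cx, cy). With
#' `spec$refine` a second pass at a quarter of the step runs around the first
#' minimum.
#'
#' @param pattern a `scattering_pattern`.
#' @param spec a `center_search_spec`; default builds one from the geometry's
#'   nominal center.
#' @return list with `center` (refined `c(cx, cy)`), `score`, and `surface`
#'   (data.frame cx, cy, score over the full grid).
#' @export
optimize_center <- function(pattern, spec = NULL) {
  geom <- pattern$geometry
  if (is.null(spec)) spec <- center_search_spec(geom$center)
  # Flat mask held fixed at the initial center: the flat region is much wider
  # than the search box, so membership changes at the box scale are second
  # order and a fixed mask keeps scores comparable across trial centers.
  flat0 <- flat_region_mask(geom, spec$flat_tol, center = spec$initial_center)
  grid_pass <- function(center0, half_width, step) {
    offs <- seq(-half_width, half_width, by = step)
    grid <- expand.grid(dx = offs, dy = offs)
    cx <- center0[1] + grid$dx
    cy <- center0[2] + grid$dy
    sc <- mapply(function(x, y)
      friedel_score(pattern, c(x, y), flat_mask = flat0), cx, cy)
    data.frame(cx = cx, cy = cy, score = sc)
  }
  surface <- grid_pass(spec$initial_center, spec$half_width, spec$step)
  pick <- function(surf) {
    d2 <- (surf$cx - spec$initial_center[1])^2 +
          (surf$cy - spec$initial_center[2])^2
    ord <- order(surf$score, d2, surf$cx, surf$cy)
    surf[ord[1], ]
  }
  best <- pick(surface)
  if (spec$refine) {
    fine <- grid_pass(c(best$cx, best$cy), spec$step, spec$step / 4)
    surface <- rbind(surface, fine)
    best <- pick(surface)
  }
  list(center = c(best$cx, best$cy), score = best$score, surface = surface)
}

#' Refine beam centers for a whole pattern stack
#'
#' @param patterns list of `scattering_pattern`.
#' @param spec a `center_search_spec` shared by all patterns; default from the
#'   first pattern's geometry.
#' @return data.frame: pattern_index, cx, cy, score.
#' @export
optimize_centers <- function(patterns, spec = NULL) {
  if (is.null(spec))
    spec <- center_search_spec(patterns[[1]]$geometry$center)
  res <- lapply(seq_along(patterns), function(t) {
    r <- optimize_center(patterns[[t]], spec)
    data.frame(pattern_index = t, cx = r$center[1], cy = r$center[2],
               score = r$score)
  })
  do.call(rbind, res)
}
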