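#' SAXS profile container
#'
#' A 1D scattering profile on a fixed q grid: bin-center magnitudes `q`
#' (nm^-1), intensities `I`, Poisson uncertainties `sigma`, the number of
#' merged patterns, and per-bin contributing-pixel counts `n_pix`. Bins with
#' `n_pix == 0` are empty: their `I` is `NA` and they are excluded from fits
#' and correlations.
#'
#' @param q strictly increasing bin centers (nm^-1).
#' @param I intensities (arbitrary units).
#' @param sigma per-bin uncertainties (>= 0); `NA` allowed on empty bins.
#' @param n_patterns number of patterns merged into the profile.
#' @param n_pix per-bin contributing-pixel counts; default 1 where `I` is
#'   finite.
#' @return an object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, I, sigma = NULL, n_patterns = 1L, n_pix = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop("q and I lengths differ")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (is.null(sigma)) sigma <- rep(NA_real_, length(q))
  if (is.null(n_pix)) n_pix <- ifelse(is.finite(I), 1L, 0L)
  if (length(sigma) != length(q) || length(n_pix) != length(q))
    stop("sigma and n_pix must match q in length")
  if (any(sigma < 0, na.rm = TRUE)) stop("sigma must be non-negative")
  structure(list(q = q, I = I, sigma = as.numeric(sigma),
                 n_patterns = as.integer(n_patterns),
                 n_pix = as.numeric(n_pix)),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf(
    "<saxs_profile: %d bins (%d non-empty), q in [%.4g, %.4g] nm^-1, %d pattern(s)>\n",
    length(x$q), sum(x$n_pix > 0), min(x$q), max(x$q), x$n_patterns))
  invisible(x)
}

#' Default q-bin edges for a detector
#'
#' Linear, half-open bins `[e_k, e_{k+1})` from 0 to the largest |q| reached
#' by an unmasked pixel (the detector corner when nothing is masked).
#'
#' @param geometry a `detector_geometry`.
#' @param n_bins number of bins (default 200).
#' @return numeric vector of `n_bins + 1` edges.
#' @export
default_q_bins <- function(geometry, n_bins = 200) {
  qv <- pixel_q_vectors(geometry)
  qmax <- max(qv$qmag[as.vector(geometry$mask)])
  seq(0, qmax * (1 + 1e-9), length.out = n_bins + 1)
}

#' Azimuthal integration of a pattern
#'
#' Converts a centered pattern to a radial "intensity profile": each unmasked
#' pixel is assigned to the half-open bin `[e_k, e_{k+1})` containing its |q|;
#' the bin intensity is the MEAN of its counts (the standard estimator of the
#' azimuthally averaged intensity, comparable across detector coverage) and
#' `sigma = sqrt(sum counts) / n_pix` from Poisson statistics.
#'
#' @param pattern a `scattering_pattern`.
#' @param center beam center used for the q mapping; defaults to the refined
#'   or nominal geometry center.
#' @param q_bins bin edges (strictly increasing); default
#'   `default_q_bins(geometry)`.
#' @return a `saxs_profile` with `n_patterns = 1`.
#' @export
azimuthal_integrate <- function(pattern, center = NULL, q_bins = NULL) {
  geom <- pattern$geometry
  if (is.null(center)) center <- geom$center
  if (is.null(q_bins)) q_bins <- default_q_bins(geom)
  if (any(diff(q_bins) <= 0)) stop("q_bins must be strictly increasing")
  counts <- as.vector(pattern$counts)
  ok <- !is.na(counts)
  if (!any(ok)) stop("empty profile: all pixels masked")
  qmag <- pixel_q_vectors(geom, center = center)$qmag[ok]
  cnt <- counts[ok]
  nb <- length(q_bins) - 1L
  bin <- findInterval(qmag, q_bins, rightmost.closed = FALSE,
                      left.open = FALSE)
  inside <- bin >= 1L & bin <= nb
  bin <- bin[inside]; cnt <- cnt[inside]
  n_pix <- tabulate(bin, nbins = nb)
  tot <- numeric(nb)
  if (length(bin)) {
    agg <- rowsum(cnt, bin)
    tot[as.integer(rownames(agg))] <- agg[, 1]
  }
  I <- ifelse(n_pix > 0, tot / n_pix, NA_real_)
  sigma <- ifelse(n_pix > 0, sqrt(pmax(tot, 0)) / n_pix, NA_real_)
  qc <- (head(q_bins, -1) + tail(q_bins, -1)) / 2
  saxs_profile(qc, I, sigma, n_patterns = 1L, n_pix = n_pix)
}

#' Merge intensity profiles into a cumulative (virtual SAXS) profile
#'
#' Per-bin sum of the input intensities over the profiles where the bin is
#' non-empty, with uncertainties combined in quadrature. Summing N identical
#' profiles therefore gives N times the intensity and sqrt(N) times the
#' sigma. The operation is associative, so cumulative profiles can be merged
#' further.
#'
#' @param profiles list of `saxs_profile` on identical q grids.
#' @return a `saxs_profile` with `n_patterns` equal to the total merged count.
#' @export
accumulate_profiles <- function(profiles) {
  if (!length(profiles)) stop("no profiles to accumulate")
  q <- profiles[[1]]$q
  nb <- length(q)
  I <- numeric(nb); v <- numeric(nb); npx <- numeric(nb)
  any_data <- logical(nb)
  n_pat <- 0L
  for (p in profiles) {
    if (length(p$q) != nb || max(abs(p$q - q)) > 1e-9 * max(abs(q), 1))
      stop("grid mismatch: profiles must share one q grid")
    has <- p$n_pix > 0 & is.finite(p$I)
    I[has] <- I[has] + p$I[has]
    sg <- p$sigma
    sg[!is.finite(sg)] <- 0
    v[has] <- v[has] + sg[has]^2
    npx <- npx + ifelse(has, p$n_pix, 0)
    any_data <- any_data | has
    n_pat <- n_pat + p$n_patterns
  }
  I[!any_data] <- NA_real_
  sigma <- ifelse(any_data, sqrt(v), NA_real_)
  saxs_profile(q, I, sigma, n_patterns = n_pat, n_pix = npx)
}

#' Pearson correlation between two profiles
#'
#' Standard Pearson coefficient over the bins that are non-empty in both
#' profiles (optionally restricted to a q range). Affine-invariant, so
#' profiles on different intensity scales compare directly.
#'
#' @param a,b `saxs_profile`s on a common q grid.
#' @param q_range optional `c(qmin, qmax)` restriction.
#' @param scale `"linear"` correlates intensities as they are; `"log"`
#'   correlates log-intensities over the bins positive in both profiles,
#'   which weights the fringe structure instead of the forward peak.
#' @return correlation in [-1, 1].
#' @export
pearson_correlation <- function(a, b, q_range = NULL,
                                scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (length(a$q) != length(b$q) ||
      max(abs(a$q - b$q)) > 1e-9 * max(abs(a$q), 1))
    stop("grid mismatch between profiles")
  use <- a$n_pix > 0 & b$n_pix > 0 & is.finite(a$I) & is.finite(b$I)
  if (!is.null(q_range))
    use <- use & a$q >= q_range[1] & a$q <= q_range[2]
  if (scale == "log") use <- use & a$I > 0 & b$I > 0
  if (sum(use) < 3L)
    stop("insufficient data: fewer than 3 shared non-empty bins")
  if (scale == "log") cor(log(a$I[use]), log(b$I[use]))
  else cor(a$I[use], b$I[use])
}

#' Convergence trace of the cumulative profile
#'
#' Merges the profiles in order and records, after every `stride` additions
#' (and always after the last), the Pearson correlation of the cumulative
#' profile with a reference profile — typically the merge of the whole data
#' set, in which case the trace ends at exactly 1.
#'
#' @param profiles ordered list of `saxs_profile`.
#' @param reference reference `saxs_profile`; default: merge of all inputs.
#' @param stride record every `stride` patterns (>= 1).
#' @param q_range optional q restriction passed to `pearson_correlation`.
#' @param scale correlation scale (see `pearson_correlation`); the default
#'   `"log"` makes the trace sensitive to the fringe structure rather than
#'   the forward peak, which otherwise saturates the correlation.
#' @return data.frame of class `convergence_trace`: `n_included`, `r_p`.
#' @export
convergence_trace <- function(profiles, reference = NULL, stride = 1,
                              q_range = NULL, scale = "log") {
  stopifnot(stride >= 1)
  if (is.null(reference)) reference <- accumulate_profiles(profiles)
  n <- length(profiles)
  marks <- unique(c(seq(stride, n, by = stride), n))
  q <- profiles[[1]]$q
  nb <- length(q)
  I <- numeric(nb); v <- numeric(nb); npx <- numeric(nb)
  any_data <- logical(nb)
  out_n <- integer(0); out_r <- numeric(0)
  k <- 1L
  for (t in seq_len(n)) {
    p <- profiles[[t]]
    has <- p$n_pix > 0 & is.finite(p$I)
    I[has] <- I[has] + p$I[has]
    sg <- p$sigma; sg[!is.finite(sg)] <- 0
    v[has] <- v[has] + sg[has]^2
    npx <- npx + ifelse(has, p$n_pix, 0)
    any_data <- any_data | has
    if (k <= length(marks) && t == marks[k]) {
      cum <- saxs_profile(q, ifelse(any_data, I, NA_real_),
                          ifelse(any_data, sqrt(v), NA_real_),
                          n_patterns = t, n_pix = npx)
      out_n <- c(out_n, t)
      out_r <- c(out_r, pearson_correlation(cum, reference, q_range, scale))
      k <- k + 1L
    }
  }
  structure(data.frame(n_included = out_n, r_p = out_r),
            class = c("convergence_trace", "data.frame"))
}

#' Split-half consistency check
#'
#' Randomly partitions the profiles into two halves (sizes differing by at
#' most 1), merges each half, and reports the Pearson correlation between the
#' two cumulative profiles — a self-consistency measure of the merged data.
#'
#' @param profiles list of at least 2 `saxs_profile`.
#' @param seed optional integer seed for the partition.
#' @param q_range optional q restriction for the correlation.
#' @return list: `profile_a`, `profile_b` (merged halves), `r_p`,
#'   `assignment` (logical: TRUE = first half).
#' @export
split_half_consistency <- function(profiles, seed = NULL, q_range = NULL) {
  n <- length(profiles)
  if (n < 2L) stop("need at least 2 profiles")
  if (!is.null(seed)) set.seed(seed)
  first <- sample(n, floor(n / 2))
  in_a <- seq_len(n) %in% first
  a <- accumulate_profiles(profiles[in_a])
  b <- accumulate_profiles(profiles[!in_a])
  list(profile_a = a, profile_b = b,
       r_p = pearson_correlation(a, b, q_range), assignment = in_a)
}

#' Read / write 3-column ASCII SAXS profiles
#'
#' The `.dat` convention: whitespace-separated columns q (nm^-1), I, sigma,
#' with `#`-prefixed header lines. The reader tolerates 2-column files
#' (sigma absent).
#'
#' @param profile a `saxs_profile` (empty bins are skipped on write).
#' @param path file path.
#' @param comment header line(s) written after `#`.
#' @return `read_profile_dat`: a `saxs_profile`; `write_profile_dat`: `path`,
#'   invisibly.
#' @export
write_profile_dat <- function(profile, path, comment = NULL) {
  keep <- profile$n_pix > 0 & is.finite(profile$I)
  hdr <- c(sprintf("# vsaxs profile: %d patterns merged", profile$n_patterns),
           if (!is.null(comment)) paste("#", comment),
           "# q[nm^-1]  I  sigma")
  body <- sprintf("%.8g %.8g %.8g", profile$q[keep], profile$I[keep],
                  ifelse(is.finite(profile$sigma[keep]),
                         profile$sigma[keep], 0))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_profile_dat
#' @export
read_profile_dat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (!length(ln)) stop("no data rows in ", path)
  fields <- strsplit(trimws(ln), "\\s+")
  ncol <- length(fields[[1]])
  if (ncol < 2L) stop("profile file needs at least 2 columns")
  m <- t(vapply(fields, function(f) as.numeric(f[seq_len(ncol)]),
                numeric(ncol)))
  sigma <- if (ncol >= 3L) m[, 3] else NULL
  saxs_profile(m[, 1], m[, 2], sigma)
}
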