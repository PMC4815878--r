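#' Scattering pattern
#'
#' One detector frame of photon counts tied to a geometry. Masked pixels carry
#' `NA` and are excluded from every downstream statistic.
#'
#' @param counts numeric matrix (`n_slow` x `n_fast`) of non-negative counts;
#'   `NA` at masked pixels.
#' @param geometry a `detector_geometry`.
#' @param true_orientation optional unit quaternion (synthetic metadata).
#' @param is_false_positive logical flag (synthetic metadata).
#' @param true_center optional true beam center used to generate the frame.
#' @return an object of class `scattering_pattern`.
#' @export
scattering_pattern <- function(counts, geometry, true_orientation = NULL,
                               is_false_positive = FALSE, true_center = NULL) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(geometry$n_slow, geometry$n_fast)))
    stop("counts shape must equal (n_slow, n_fast)")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  structure(
    list(counts = counts, geometry = geometry,
         true_orientation = true_orientation,
         is_false_positive = isTRUE(is_false_positive),
         true_center = true_center),
    class = "scattering_pattern"
  )
}

#' @export
print.scattering_pattern <- function(x, ...) {
  cat(sprintf("<scattering_pattern %dx%d, %.0f photons%s>\n",
              x$geometry$n_fast, x$geometry$n_slow,
              sum(x$counts, na.rm = TRUE),
              if (x$is_false_positive) ", false positive" else ""))
  invisible(x)
}

#' Simulate one single-particle scattering pattern
#'
#' Coherent scattering from a bead model at a given orientation, sampled on
#' the Ewald sphere at each pixel: the noiseless intensity is
#' `fluence_scale * Phi^2(|q| a) |sum_j w_j exp(i q . R x_j)|^2 / (sum_j w_j)^2`
#' with `Phi` the normalized uniform-sphere amplitude of one bead (radius a),
#' so the expected count at forward scattering (q = 0) equals `fluence_scale`
#' exactly and the orientation average of the intensity follows the Debye
#' profile of the model. Counts are Poisson-sampled unless `poisson = FALSE`.
#'
#' @param model a `bead_model`.
#' @param geometry a `detector_geometry`.
#' @param orientation unit quaternion (w, x, y, z); default identity.
#' @param fluence_scale expected photons at forward scattering (>= 0).
#' @param center true beam center used to generate the frame; defaults to the
#'   geometry's nominal center (use to emulate beam-center jitter).
#' @param poisson if FALSE, return the noiseless expected intensity instead of
#'   Poisson counts.
#' @return a `scattering_pattern`.
#' @export
simulate_pattern <- function(model, geometry, orientation = c(1, 0, 0, 0),
                             fluence_scale = 1e4, center = NULL,
                             poisson = TRUE) {
  if (!inherits(model, "bead_model") || n_beads(model) < 1L)
    stop("model must be a non-empty bead_model")
  stopifnot(fluence_scale >= 0)
  if (is.null(center)) center <- geometry$center
  R <- quat_to_matrix(orientation)
  coords <- model$centers %*% t(R)
  qv <- pixel_q_vectors(geometry, center = center)
  amp2 <- .bead_intensity_cpp(qv$q, coords, model$weights)
  phi2 <- sphere_amplitude(qv$qmag * model$bead_radius)^2
  intensity <- fluence_scale * phi2 * amp2 / sum(model$weights)^2
  m <- matrix(intensity, geometry$n_slow, geometry$n_fast)
  if (poisson) {
    m[] <- rpois(length(m), m)
  }
  m[!geometry$mask] <- NA_real_
  scattering_pattern(m, geometry, true_orientation = orientation,
                     true_center = center)
}

#' Simulate a dataset of single-particle patterns
#'
#' Each pattern gets a fresh uniform random orientation; with probability
#' `false_positive_rate` the frame is generated from `false_positive_model`
#' instead of `model` and flagged in the manifest. Per-pattern beam-center
#' jitter is drawn uniformly in +/- `center_jitter_px` on both axes; the
#' geometry's nominal center stays unchanged so downstream centering has
#' something to recover.
#'
#' @param model particle `bead_model`.
#' @param geometry a `detector_geometry`.
#' @param n_patterns number of frames (> 0).
#' @param fluence_scale expected forward-scattering photons per frame.
#' @param center_jitter_px half-width of the uniform beam-center jitter, in
#'   pixels (0 = no jitter).
#' @param false_positive_rate probability in [0, 1) that a frame is a false
#'   positive.
#' @param false_positive_model `bead_model` used for false-positive frames;
#'   required when the rate is positive.
#' @param false_positive_fluence expected forward-scattering photons of a
#'   false-positive frame. Non-sample scatterers (water droplets, aggregates)
#'   are larger and brighter than the particle of interest; the default is
#'   ten times `fluence_scale`.
#' @param seed optional integer seed (applied with `set.seed`).
#' @param poisson passed through to `simulate_pattern`.
#' @return list with `patterns` (list of `scattering_pattern`) and `manifest`
#'   (data.frame: index, false_positive, center_dx, center_dy, qw, qx, qy,
#'   qz).
#' @export
simulate_dataset <- function(model, geometry, n_patterns, fluence_scale = 1e4,
                             center_jitter_px = 0, false_positive_rate = 0,
                             false_positive_model = NULL,
                             false_positive_fluence = 10 * fluence_scale,
                             seed = NULL, poisson = TRUE) {
  if (n_patterns <= 0) stop("n_patterns must be positive")
  if (false_positive_rate < 0 || false_positive_rate >= 1)
    stop("false_positive_rate must be in [0, 1)")
  if (false_positive_rate > 0 && is.null(false_positive_model))
    stop("a false_positive_model is required when false_positive_rate > 0")
  if (!is.null(seed)) set.seed(seed)
  quats <- random_orientation(n_patterns)
  is_fp <- runif(n_patterns) < false_positive_rate
  dx <- runif(n_patterns, -center_jitter_px, center_jitter_px)
  dy <- runif(n_patterns, -center_jitter_px, center_jitter_px)
  if (center_jitter_px == 0) { dx[] <- 0; dy[] <- 0 }
  patterns <- vector("list", n_patterns)
  for (t in seq_len(n_patterns)) {
    src <- if (is_fp[t]) false_positive_model else model
    patterns[[t]] <- simulate_pattern(
      src, geometry, orientation = quats[t, ],
      fluence_scale = if (is_fp[t]) false_positive_fluence else fluence_scale,
      center = geometry$center + c(dx[t], dy[t]),
      poisson = poisson)
    patterns[[t]]$is_false_positive <- is_fp[t]
  }
  manifest <- data.frame(
    index = seq_len(n_patterns), false_positive = is_fp,
    center_dx = dx, center_dy = dy,
    qw = quats[, 1], qx = quats[, 2], qy = quats[, 3], qz = quats[, 4])
  list(patterns = patterns, manifest = manifest)
}

#' Irregular aggregate model for false-positive frames
#'
#' A bent chain of four overlapping spheres — a stand-in for the non-sample
#' scatterers (water droplets, aggregates) behind false-positive hits. Unlike
#' a single sphere it is strongly anisotropic, so each false-positive frame
#' (fresh random orientation) differs from the last, which is what makes
#' false positives visible as fluctuations in the convergence trace.
#'
#' @param scale overall size factor; 1 gives lobes of 55 nm radius spread
#'   over roughly 300 nm.
#' @return a `bead_model` labelled "aggregate".
#' @export
junk_aggregate_model <- function(scale = 1) {
  lobe <- make_shape("sphere", radius = 55 * scale, spacing = 14 * scale)
  offs <- rbind(c(-80, 0, 0), c(20, 0, 0), c(90, 70, 0), c(60, -85, 40)) *
    scale
  centers <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
    sweep(lobe$centers, 2L, offs[k, ], "+")))
  recenter_model(bead_model(centers, bead_radius = 7 * scale,
                            label = "aggregate"))
}

#' Write / read a pattern stack
#'
#' Plain-text on-disk layout: a directory holding `geometry.json` (wavelength,
#' distance, pitch, pixel counts, beam center), `mask.txt` (0/1 matrix),
#' `counts.tsv` (one row per pattern, pixels flattened in column-major order,
#' `NA` at masked pixels) and `truth.csv` (the simulation manifest, when
#' present).
#'
#' @param dataset list with `patterns` and optionally `manifest`, as returned
#'   by `simulate_dataset`.
#' @param dir directory to create/overwrite.
#' @return `write_patterns`: `dir`, invisibly. `read_patterns`: a dataset list
#'   with `patterns`, `geometry` and `manifest` (NULL when absent).
#' @export
write_patterns <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- dataset$patterns[[1]]$geometry
  jsonlite::write_json(
    list(wavelength_nm = geom$wavelength_nm, distance_mm = geom$distance_mm,
         pixel_mm = geom$pixel_mm, n_fast = geom$n_fast, n_slow = geom$n_slow,
         center = geom$center),
    file.path(dir, "geometry.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(geom$mask * 1L, file.path(dir, "mask.txt"),
                     row.names = FALSE, col.names = FALSE)
  counts <- do.call(rbind, lapply(dataset$patterns,
                                  function(p) as.vector(p$counts)))
  data.table::fwrite(data.table::as.data.table(counts),
                     file.path(dir, "counts.tsv"), sep = "\t",
                     col.names = FALSE)
  if (!is.null(dataset$manifest)) {
    mf <- dataset$manifest
    # %.17g keeps doubles bit-exact through the text round trip
    for (cl in names(mf))
      if (is.double(mf[[cl]])) mf[[cl]] <- sprintf("%.17g", mf[[cl]])
    data.table::fwrite(mf, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(dir) {
  if (!file.exists(file.path(dir, "geometry.json")))
    stop("no such file: ", file.path(dir, "geometry.json"))
  gj <- jsonlite::read_json(file.path(dir, "geometry.json"),
                            simplifyVector = TRUE)
  mask <- as.matrix(utils::read.table(file.path(dir, "mask.txt"))) == 1
  dimnames(mask) <- NULL
  geom <- detector_geometry(gj$wavelength_nm, gj$distance_mm, gj$pixel_mm,
                            gj$n_fast, gj$n_slow, center = gj$center,
                            mask = mask)
  counts <- as.matrix(data.table::fread(file.path(dir, "counts.tsv"),
                                        header = FALSE, sep = "\t"))
  manifest <- NULL
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf))
    manifest <- as.data.frame(data.table::fread(tf))
  patterns <- lapply(seq_len(nrow(counts)), function(t) {
    m <- matrix(as.numeric(counts[t, ]), geom$n_slow, geom$n_fast)
    p <- scattering_pattern(m, geom)
    if (!is.null(manifest)) {
      p$is_false_positive <- isTRUE(manifest$false_positive[t])
      p$true_center <- geom$center +
        c(manifest$center_dx[t], manifest$center_dy[t])
      p$true_orientation <- as.numeric(manifest[t, c("qw", "qx", "qy", "qz")])
    }
    p
  })
  list(patterns = patterns, geometry = geom, manifest = manifest)
}
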