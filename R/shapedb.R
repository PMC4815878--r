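#' Build a size-rescalable shape database
#'
#' Every model is recentered, scaled to nominal (bounding-sphere) radius 1 and
#' stored as a dimensionless reference profile `I_ref(s)` on a shared grid of
#' `s = q * R`, normalized to `I_ref(0) = 1`. Because a uniform rescaling of a
#' model by a factor t turns its profile into `I(q) = I_ref(q * t * R)`,
#' evaluating a database model at any trial radius is a pure argument
#' rescaling — no profile is ever recomputed during the search.
#'
#' @param models list of `bead_model` with unique labels.
#' @param s_max upper end of the dimensionless grid (default 50, well past the
#'   fifth minimum of a solid sphere at qR = 4.49, 7.73, ...).
#' @param n_s number of grid points (>= 64; default 512). The grid is equally
#'   spaced with `s[1] = 0`.
#' @return an object of class `shape_database`: `s` (grid), `entries` (named
#'   list of reference profiles with unit-radius geometry), `build_params`.
#' @export
build_database <- function(models, s_max = 50, n_s = 512) {
  stopifnot(s_max > 0, n_s >= 64)
  if (!length(models)) stop("empty model collection")
  ids <- vapply(models, function(m) m$label, character(1))
  if (anyDuplicated(ids)) stop("duplicate model ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  s <- seq(0, s_max, length.out = n_s)
  entries <- lapply(models, function(m) {
    m <- recenter_model(m)
    R <- nominal_radius(m)
    unit <- bead_model(m$centers / R, bead_radius = m$bead_radius / R,
                       weights = m$weights, label = m$label)
    I <- debye_profile(unit, s)
    list(model_id = m$label, I_ref = I / I[1], R_ref = 1,
         geometry = list(centers = unit$centers,
                         bead_radius = unit$bead_radius,
                         weights = unit$weights))
  })
  names(entries) <- ids
  structure(list(s = s, entries = entries,
                 build_params = list(s_max = s_max, n_s = n_s,
                                     n_models = length(models))),
            class = "shape_database")
}

#' @export
print.shape_database <- function(x, ...) {
  cat(sprintf("<shape_database: %d models, s grid [0, %g] x %d>\n",
              length(x$entries), max(x$s), length(x$s)))
  invisible(x)
}

#' Evaluate a database model at a trial radius
#'
#' Returns the model's profile at radius `r` on the experimental q grid by
#' rescaling the stored dimensionless profile: `I(q; r) = I_ref(q * r)`.
#' Interpolation is linear in (s, log I) to preserve deep minima; stretches
#' containing non-positive stored values fall back to linear interpolation.
#' q points with `q * r` beyond the stored grid are returned as `NA` (callers
#' drop them from fits).
#'
#' @param db a `shape_database`.
#' @param model_id entry identifier.
#' @param r trial radius in nm (> 0).
#' @param q experimental q grid (nm^-1).
#' @return intensity vector on `q`, normalized like `I_ref` (the retrieval
#'   scale factor c absorbs normalization); `NA` outside the stored range.
#' @export
model_profile_at_radius <- function(db, model_id, r, q) {
  entry <- db$entries[[model_id]]
  if (is.null(entry)) stop("no such model in database: ", model_id)
  stopifnot(r > 0)
  s_eval <- q * r
  inside <- s_eval <= max(db$s)
  if (!any(inside))
    stop("range error: the whole q range falls beyond s_max = ", max(db$s),
         "; rebuild the database with a larger s_max")
  out <- rep(NA_real_, length(q))
  I <- entry$I_ref
  if (all(I > 0)) {
    out[inside] <- exp(approx(db$s, log(I), xout = s_eval[inside],
                              rule = 2)$y)
  } else {
    out[inside] <- approx(db$s, I, xout = s_eval[inside], rule = 2)$y
  }
  out
}

#' Save / load a shape database
#'
#' Single-file JSON serialization (grid, build parameters, per-model
#' reference profiles and unit-radius bead geometry). Rebuilding from the
#' same inputs and saving again yields a byte-identical file.
#'
#' @param db a `shape_database`.
#' @param path file path (conventionally `.json`).
#' @return `write_shapedb`: `path`, invisibly; `read_shapedb`: a
#'   `shape_database`.
#' @export
write_shapedb <- function(db, path) {
  payload <- list(
    s = db$s, build_params = db$build_params,
    entries = unname(lapply(db$entries, function(e) list(
      model_id = e$model_id, I_ref = e$I_ref, R_ref = e$R_ref,
      centers = as.vector(t(e$geometry$centers)),
      bead_radius = e$geometry$bead_radius,
      weights = e$geometry$weights))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shapedb
#' @export
read_shapedb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(seq_along(p$entries$model_id), function(k) {
    list(model_id = p$entries$model_id[k],
         I_ref = p$entries$I_ref[[k]], R_ref = p$entries$R_ref[k],
         geometry = list(
           centers = matrix(p$entries$centers[[k]], ncol = 3, byrow = TRUE),
           bead_radius = p$entries$bead_radius[k],
           weights = p$entries$weights[[k]]))
  })
  names(entries) <- p$entries$model_id
  structure(list(s = p$s, entries = entries,
                 build_params = as.list(p$build_params)),
            class = "shape_database")
}

#' Bead model of a database entry at a given radius
#'
#' @param db a `shape_database`.
#' @param model_id entry identifier.
#' @param r radius in nm.
#' @return a `bead_model` with the entry's unit-radius geometry scaled by `r`.
#' @export
db_model_at_radius <- function(db, model_id, r) {
  e <- db$entries[[model_id]]
  if (is.null(e)) stop("no such model in database: ", model_id)
  bead_model(e$geometry$centers * r, bead_radius = e$geometry$bead_radius * r,
             weights = e$geometry$weights, label = e$model_id)
}
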