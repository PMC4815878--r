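#' Voxel density map
#'
#' Cubic-voxel occupancy map on a regular grid. `values` is a 3D array
#' indexed `[x, y, z]`; the center of voxel (1,1,1) sits at `origin` (nm) and
#' voxel centers advance by `voxel_size` along each axis.
#'
#' @param values numeric 3D array of non-negative occupancies.
#' @param voxel_size voxel edge length in nm (> 0).
#' @param origin length-3 position (nm) of the first voxel center.
#' @return an object of class `voxel_map`.
#' @export
voxel_map <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (any(!is.finite(values))) stop("map values must be finite")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_map %dx%dx%d, voxel %.3g nm, total %.4g>\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$values)))
  invisible(x)
}

#' Rasterize a bead model onto a voxel grid
#'
#' Each bead's weight is distributed uniformly over the voxels whose centers
#' fall within one bead radius of the bead center (the containing voxel when
#' none does), so the total map occupancy equals the total model weight.
#'
#' @param model a `bead_model`.
#' @param voxel_size voxel edge in nm; default `nominal_radius(model) / 20`.
#' @param pad extra margin around the model, in bead radii (default 1).
#' @return a `voxel_map`.
#' @export
model_to_voxels <- function(model, voxel_size = NULL, pad = 1) {
  if (is.null(voxel_size)) voxel_size <- nominal_radius(model) / 20
  stopifnot(voxel_size > 0)
  rb <- model$bead_radius
  lo <- apply(model$centers, 2, min) - rb * (1 + pad)
  hi <- apply(model$centers, 2, max) + rb * (1 + pad)
  n <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  origin <- lo
  vals <- array(0, dim = n)
  reach <- ceiling(rb / voxel_size)
  off <- as.matrix(expand.grid(dx = -reach:reach, dy = -reach:reach,
                               dz = -reach:reach))
  for (b in seq_len(n_beads(model))) {
    ctr <- model$centers[b, ]
    base <- round((ctr - origin) / voxel_size)  # 0-based index of nearest voxel
    cand <- sweep(off, 2L, base, "+")
    inside <- cand[, 1] >= 0 & cand[, 1] < n[1] &
              cand[, 2] >= 0 & cand[, 2] < n[2] &
              cand[, 3] >= 0 & cand[, 3] < n[3]
    cand <- cand[inside, , drop = FALSE]
    cc <- sweep(cand * voxel_size, 2L, origin, "+")
    d2 <- rowSums(sweep(cc, 2L, ctr)^2)
    sel <- d2 <= rb^2
    if (!any(sel)) sel <- which.min(d2)
    hitidx <- cand[sel, , drop = FALSE] + 1L
    share <- model$weights[b] / nrow(hitidx)
    vals[hitidx] <- vals[hitidx] + share  # rows unique within one bead
  }
  voxel_map(vals, voxel_size, origin)
}

#' Write / read CCP4 density maps
#'
#' Standard single-precision (mode 2) CCP4/MRC maps with a 1024-byte header:
#' grid dimensions, cell lengths in Angstrom (nm x 10, orthogonal cell), axis
#' order X,Y,Z, min/max/mean statistics and the map origin in the ORIGIN
#' header words. A write -> read round trip reproduces values at float32
#' precision.
#'
#' @param map a `voxel_map`.
#' @param path output file.
#' @return `write_ccp4`: `path`, invisibly; `read_ccp4`: a `voxel_map`.
#' @export
write_ccp4 <- function(map, path) {
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(d)                         # NC, NR, NS
  wi(2L)                        # MODE 2 = float32
  wi(c(0L, 0L, 0L))             # NCSTART/NRSTART/NSSTART
  wi(d)                         # MX, MY, MZ sampling intervals
  wf(d * map$voxel_size * 10)   # cell a, b, c in Angstrom
  wf(c(90, 90, 90))             # cell angles
  wi(c(1L, 2L, 3L))             # MAPC, MAPR, MAPS
  v <- map$values
  wf(c(min(v), max(v), mean(v)))
  wi(1L)                        # ISPG
  wi(0L)                        # NSYMBT
  wi(rep(0L, 25))               # EXTRA (words 26-49, incl. skew fields)
  wf(map$origin * 10)           # ORIGIN x, y, z (Angstrom), words 50-52
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(v)))   # ARMS
  wi(0L)                        # NLABL
  writeBin(raw(800), con)       # 10 empty 80-char labels
  wf(as.vector(v))              # section-major = column-major for X,Y,Z order
  invisible(path)
}

#' @rdname write_ccp4
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("unsupported CCP4 mode: ", mode)
  ri(3)             # start offsets
  mx <- ri(3)       # sampling
  cell <- rf(3)
  rf(3)             # angles
  maporder <- ri(3)
  if (!identical(maporder, c(1L, 2L, 3L)))
    stop("only X,Y,Z axis order is supported")
  rf(3)             # stats
  ri(2)             # ISPG, NSYMBT
  ri(25)            # EXTRA
  origin <- rf(3) / 10
  seek(con, 1024)
  vals <- rf(prod(d))
  voxel <- cell[1] / 10 / mx[1]
  voxel_map(array(vals, dim = d), voxel, origin)
}
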