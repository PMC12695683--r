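#' Construct a dose grid
#'
#' A `dose_grid` is a 3-D scalar dose field on a regular lattice in the DICOM
#' patient coordinate system. Values are absorbed dose in Gy; geometry is in mm.
#' The value array is indexed `[x, y, z]` (x fastest), matching the linear
#' ordering of DICOM dose pixel data (columns within rows within frames).
#'
#' @param values numeric 3-D array of doses in Gy; all finite and `>= 0`.
#' @param origin numeric length-3, patient coordinates (mm) of the center of
#'   voxel `[1, 1, 1]`.
#' @param spacing numeric length-3, voxel size (mm) along x, y, z; all `> 0`.
#' @param orientation direction cosines of the row and column axes
#'   (length 6). Only the identity orientation `c(1,0,0, 0,1,0)` (axes aligned
#'   with the patient system) is supported.
#' @param frame_ref frame-of-reference identifier string; grids, structure sets
#'   and masks may only be combined when these match.
#'
#' @return An object of class `dose_grid` with fields `values`, `origin`,
#'   `spacing`, `shape`, `orientation`, `frame_ref`.
#' @export
dose_grid <- function(values, origin, spacing,
                      orientation = c(1, 0, 0, 0, 1, 0),
                      frame_ref = "FOR.1") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop("dose values must all be finite", call. = FALSE)
  }
  if (any(values < 0)) stop("dose values must be >= 0", call. = FALSE)
  origin <- as.double(origin); spacing <- as.double(spacing)
  stopifnot(length(origin) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("spacings must be strictly positive", call. = FALSE)
  orientation <- as.double(orientation)
  if (length(orientation) != 6L ||
      max(abs(orientation - c(1, 0, 0, 0, 1, 0))) > 1e-6) {
    stop("only identity orientation (1,0,0,0,1,0) is supported", call. = FALSE)
  }
  structure(
    list(values = values, origin = origin, spacing = spacing,
         shape = dim(values), orientation = c(1, 0, 0, 0, 1, 0),
         frame_ref = as.character(frame_ref)),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm; dose range [%.4g, %.4g] Gy; frame %s\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values), x$frame_ref))
  invisible(x)
}

#' Voxel-center coordinates along one axis
#'
#' @param grid a `dose_grid`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of voxel-center coordinates in mm.
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + grid$spacing[axis] * (seq_len(grid$shape[axis]) - 1)
}

#' Voxel volume of a grid in mm^3
#' @param grid a `dose_grid`.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

same_lattice <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol
}

#' Resample a dose grid onto another grid's lattice
#'
#' Trilinear interpolation of `grid` at the voxel centers of `target`.
#' Target voxels whose centers fall outside the source extent (beyond the
#' outermost voxel centers) receive 0 Gy. A constant field is reproduced
#' exactly and any trilinear field is reproduced to machine precision.
#'
#' @param grid source `dose_grid`.
#' @param target `dose_grid` (its values are ignored) defining the output
#'   lattice.
#' @return a `dose_grid` on the lattice of `target`, carrying `grid`'s
#'   frame of reference.
#' @export
resample_to <- function(grid, target) {
  stopifnot(inherits(grid, "dose_grid"), inherits(target, "dose_grid"))
  if (same_lattice(grid, target)) {
    out <- grid
    out$origin <- target$origin  # identical within tolerance
    return(out)
  }
  # continuous (0-based) source index of each target center, per axis
  idx <- lapply(1:3, function(ax) {
    (grid_axis(target, ax) - grid$origin[ax]) / grid$spacing[ax]
  })
  n <- grid$shape
  inside1 <- function(u, nax) u >= 0 & u <= nax - 1
  ok <- list(inside1(idx[[1]], n[1]), inside1(idx[[2]], n[2]),
             inside1(idx[[3]], n[3]))
  if (!any(ok[[1]]) || !any(ok[[2]]) || !any(ok[[3]])) {
    warning("source and target extents do not overlap; returning all-zero grid")
  }
  lo <- lapply(1:3, function(ax) pmin(pmax(floor(idx[[ax]]), 0), n[ax] - 1))
  fr <- lapply(1:3, function(ax) idx[[ax]] - lo[[ax]])
  hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1, n[ax] - 1))

  ts <- target$shape
  ax_x <- list(lo = lo[[1]] + 1, hi = hi[[1]] + 1, f = fr[[1]], ok = ok[[1]])
  ax_y <- list(lo = lo[[2]] + 1, hi = hi[[2]] + 1, f = fr[[2]], ok = ok[[2]])
  ax_z <- list(lo = lo[[3]] + 1, hi = hi[[3]] + 1, f = fr[[3]], ok = ok[[3]])

  out <- array(0, dim = ts)
  v <- grid$values
  # interpolate slab by slab in z to bound memory
  for (k in seq_len(ts[3])) {
    if (!ax_z$ok[k]) next
    z0 <- ax_z$lo[k]; z1 <- ax_z$hi[k]; fz <- ax_z$f[k]
    # bilinear in (x, y) on the two bounding z-planes, then blend
    plane <- function(zi) {
      p00 <- v[ax_x$lo, ax_y$lo, zi, drop = FALSE]
      p10 <- v[ax_x$hi, ax_y$lo, zi, drop = FALSE]
      p01 <- v[ax_x$lo, ax_y$hi, zi, drop = FALSE]
      p11 <- v[ax_x$hi, ax_y$hi, zi, drop = FALSE]
      dim(p00) <- dim(p10) <- dim(p01) <- dim(p11) <- c(ts[1], ts[2])
      fx <- ax_x$f; fy <- rep(ax_y$f, each = ts[1])
      (p00 * (1 - fx) + p10 * fx) * (1 - fy) +
        (p01 * (1 - fx) + p11 * fx) * fy
    }
    sl <- plane(z0)
    if (fz > 0) sl <- sl * (1 - fz) + plane(z1) * fz
    sl[!ax_x$ok, ] <- 0
    sl[, !ax_y$ok] <- 0
    out[, , k] <- sl
  }
  dose_grid(out, target$origin, target$spacing, frame_ref = grid$frame_ref)
}

#' Accumulate treatment and per-fraction imaging dose over a course
#'
#' Total course dose is
#' `treatment + (mu_per_fraction / reference_mu) * imaging_per_fraction * n_fractions`.
#' Imaging dose is assumed proportional to the monitor units (MU) of the
#' acquisition, so one per-fraction imaging grid exported at a reference MU
#' setting serves any protocol. Pass a zero `treatment` grid (or `NULL`) for
#' imaging-only accumulation, mirroring plans whose beam doses are zeroed to
#' isolate the imaging contribution.
#'
#' @param treatment `dose_grid` of the full-course treatment dose, or `NULL`
#'   for imaging-only mode.
#' @param imaging_per_fraction `dose_grid` of one imaging acquisition at
#'   `reference_mu` monitor units.
#' @param protocol a [protocol_spec()].
#' @param reference_mu MU setting at which `imaging_per_fraction` was computed.
#' @return `dose_grid` of total course dose on the shared lattice.
#' @export
accumulate_course <- function(treatment, imaging_per_fraction, protocol,
                              reference_mu = 5) {
  stopifnot(inherits(imaging_per_fraction, "dose_grid"),
            inherits(protocol, "protocol_spec"), reference_mu > 0)
  scale <- protocol$mu_per_fraction / reference_mu * protocol$n_fractions
  img <- imaging_per_fraction$values * scale
  if (is.null(treatment)) {
    return(dose_grid(img, imaging_per_fraction$origin,
                     imaging_per_fraction$spacing,
                     frame_ref = imaging_per_fraction$frame_ref))
  }
  stopifnot(inherits(treatment, "dose_grid"))
  if (!identical(treatment$frame_ref, imaging_per_fraction$frame_ref)) {
    stop("frame-of-reference mismatch between treatment and imaging grids",
         call. = FALSE)
  }
  if (!same_lattice(treatment, imaging_per_fraction)) {
    stop("dose grids are not on the same lattice; resample_to() first",
         call. = FALSE)
  }
  dose_grid(treatment$values + img, treatment$origin, treatment$spacing,
            frame_ref = treatment$frame_ref)
}

#' Define an imaging protocol
#'
#' @param label protocol name, e.g. `"5MU"`.
#' @param mu_per_fraction monitor units delivered per daily CBCT acquisition.
#' @param n_fractions number of treatment fractions (one acquisition each).
#' @param gantry_arc acquisition arc in degrees, stored as metadata only.
#' @return a `protocol_spec` object.
#' @export
protocol_spec <- function(label, mu_per_fraction, n_fractions,
                          gantry_arc = c(260, 100)) {
  stopifnot(is.numeric(mu_per_fraction), mu_per_fraction > 0,
            n_fractions >= 1)
  structure(
    list(label = as.character(label),
         mu_per_fraction = as.double(mu_per_fraction),
         n_fractions = as.integer(n_fractions),
         gantry_arc = as.double(gantry_arc)),
    class = "protocol_spec"
  )
}
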