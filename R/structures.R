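#' Construct a structure set
#'
#' Named planar contours in the patient coordinate system. Each ROI holds a
#' list of closed planar polygons; each polygon is an n x 3 matrix of (x, y, z)
#' vertices in mm with constant z (within tolerance). Polygons with fewer than
#' three vertices are dropped with a warning.
#'
#' @param rois named list; each element a list of n x 3 vertex matrices.
#' @param frame_ref frame-of-reference identifier.
#' @param z_tol tolerance (mm) on within-contour z variation.
#' @return a `structure_set` object.
#' @export
structure_set <- function(rois, frame_ref = "FOR.1", z_tol = 1e-3) {
  stopifnot(is.list(rois))
  if (length(rois) && (is.null(names(rois)) || anyDuplicated(names(rois)))) {
    stop("ROI names must be present and unique", call. = FALSE)
  }
  rois <- lapply(rois, function(contours) {
    keep <- vapply(contours, function(p) {
      p <- as.matrix(p)
      nrow(p) >= 3L && ncol(p) == 3L
    }, logical(1))
    if (any(!keep)) warning("skipping malformed contour(s) with < 3 points")
    contours <- lapply(contours[keep], function(p) {
      p <- as.matrix(p); storage.mode(p) <- "double"
      if (diff(range(p[, 3])) > z_tol) {
        stop("contour is not planar: z varies by more than z_tol", call. = FALSE)
      }
      unname(p)
    })
    contours
  })
  structure(list(rois = rois, frame_ref = as.character(frame_ref)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROI(s), frame %s\n", length(x$rois), x$frame_ref))
  for (nm in names(x$rois)) {
    cat(sprintf("  %-16s %d contour(s)\n", nm, length(x$rois[[nm]])))
  }
  invisible(x)
}

#' Apply a nomenclature map and merge duplicate canonical names
#'
#' @param structure a `structure_set`.
#' @param name_map named character vector, raw name -> canonical name. ROIs
#'   absent from the map keep their raw names. Several raw ROIs mapping to one
#'   canonical name are merged (their contour lists concatenated).
#' @return a `structure_set` with canonical ROI names.
#' @export
map_roi_names <- function(structure, name_map = character()) {
  stopifnot(inherits(structure, "structure_set"))
  if (!length(name_map)) return(structure)
  raw <- names(structure$rois)
  canonical <- ifelse(raw %in% names(name_map), name_map[raw], raw)
  merged <- split(structure$rois, canonical)
  merged <- lapply(merged, function(lst) do.call(c, unname(lst)))
  structure_set(merged, frame_ref = structure$frame_ref)
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
# Points within `eps` (mm) of a polygon edge count as inside.
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xe[i]; y2 <- ye[i]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
    # distance from point to segment for the boundary rule
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    }
    on_edge <- on_edge | d2 <= eps^2
  }
  inside | on_edge
}

#' Rasterize a contoured ROI onto a dose grid's lattice
#'
#' A voxel belongs to the ROI when its center lies inside the ROI's contour(s)
#' on the grid slice the contour is assigned to. Each contour is assigned to
#' the slice whose z-center is nearest, provided the offset is at most half the
#' slice spacing; contours farther from any slice are rejected with an error.
#' Multiple contours on one slice combine under the even-odd rule, so nested
#' contours make holes. Points within 1e-9 mm of a contour edge count inside.
#'
#' @param structure a `structure_set`.
#' @param roi ROI name to rasterize.
#' @param grid a `dose_grid` supplying the target lattice.
#' @return an `roi_mask`: logical array matching `grid$shape` plus metadata.
#' @export
rasterize <- function(structure, roi, grid) {
  stopifnot(inherits(structure, "structure_set"), inherits(grid, "dose_grid"))
  if (!identical(structure$frame_ref, grid$frame_ref)) {
    stop("frame-of-reference mismatch between structure set and grid",
         call. = FALSE)
  }
  if (!roi %in% names(structure$rois)) {
    stop(sprintf("ROI '%s' not found in structure set", roi), call. = FALSE)
  }
  contours <- structure$rois[[roi]]
  zc <- grid_axis(grid, 3)
  xc <- grid_axis(grid, 1)
  yc <- grid_axis(grid, 2)
  nx <- grid$shape[1]; ny <- grid$shape[2]
  px <- rep(xc, times = ny)
  py <- rep(yc, each = nx)
  inside <- array(FALSE, dim = grid$shape)

  for (poly in contours) {
    z <- mean(poly[, 3])
    k <- which.min(abs(zc - z))
    if (abs(zc[k] - z) > grid$spacing[3] / 2 + 1e-9) {
      stop(sprintf(
        "contour at z = %.3f mm is farther than half a slice spacing from any grid slice",
        z), call. = FALSE)
    }
    # restrict the test to the polygon's bounding box (padded) for speed
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    sel <- px >= xr[1] - 1e-6 & px <= xr[2] + 1e-6 &
           py >= yr[1] - 1e-6 & py <= yr[2] + 1e-6
    if (!any(sel)) next
    hit <- points_in_polygon(px[sel], py[sel], poly[, 1:2, drop = FALSE])
    slice <- inside[, , k]
    slice[sel] <- xor(slice[sel], hit)  # even-odd across contours
    inside[, , k] <- slice
  }
  if (!any(inside)) {
    stop(sprintf("rasterization of ROI '%s' produced an empty mask", roi),
         call. = FALSE)
  }
  structure(
    list(inside = inside, roi_name = roi,
         grid_ref = grid[c("origin", "spacing", "shape", "frame_ref")],
         voxel_volume = voxel_volume(grid)),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels (%.2f cm^3)\n", x$roi_name,
              sum(x$inside), sum(x$inside) * x$voxel_volume / 1000))
  invisible(x)
}

mask_matches_grid <- function(mask, grid) {
  identical(mask$grid_ref$shape, grid$shape) &&
    max(abs(mask$grid_ref$origin - grid$origin)) <= 1e-6 &&
    max(abs(mask$grid_ref$spacing - grid$spacing)) <= 1e-6
}
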