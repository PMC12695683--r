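# Independent brute-force oracles used across the suites. These deliberately
# re-derive results from first principles (scalar loops, closed forms) and
# never call the package's vectorized implementations.

# Scalar even-odd ray-casting test for a single point; edges handled with the
# half-open [y1, y2) convention. Only used on points in general position.
brute_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > y) != (yj > y)) {
      xcross <- xi + (y - yi) * (xj - xi) / (yj - yi)
      if (x < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

brute_mask <- function(poly, xc, yc) {
  m <- matrix(FALSE, length(xc), length(yc))
  for (i in seq_along(xc)) {
    for (j in seq_along(yc)) {
      m[i, j] <- brute_point_in_polygon(xc[i], yc[j], poly)
    }
  }
  m
}

# random convex polygon (convex hull of random points), centered near `center`
random_convex_polygon <- function(center = c(0, 0), radius = 10, n_pts = 12) {
  pts <- cbind(center[1] + stats::runif(n_pts, -radius, radius),
               center[2] + stats::runif(n_pts, -radius, radius))
  hull <- grDevices::chull(pts)
  pts[hull, , drop = FALSE]
}

# textbook two-tailed paired t-test, written independently of stats::t.test
brute_paired_t <- function(a, b) {
  d <- b - a
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# random differential DVH over a modest number of occupied bins
random_ddvh <- function(max_dose = 40, n_levels = 25, bin_width = 0.05) {
  levels <- sort(stats::runif(n_levels, 0, max_dose))
  frac <- stats::runif(n_levels)
  frac <- frac / sum(frac)
  ddvh_from_levels(levels, frac, bin_width = bin_width)
}

# small random dose grid + random-box mask pair used by DVH oracle tests
random_grid_and_mask <- function(n = 32, max_dose = 10) {
  vals <- array(stats::runif(n^3, 0, max_dose), dim = c(n, n, n))
  g <- dose_grid(vals, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                 frame_ref = "FOR.T")
  inside <- array(FALSE, dim = c(n, n, n))
  lo <- sort(sample(seq_len(n), 2))
  inside[lo[1]:lo[2], lo[1]:lo[2], lo[1]:lo[2]] <- TRUE
  mask <- structure(
    list(inside = inside, roi_name = "box",
         grid_ref = g[c("origin", "spacing", "shape", "frame_ref")],
         voxel_volume = voxel_volume(g)),
    class = "roi_mask")
  list(grid = g, mask = mask)
}

# a tiny fully-written synthetic patient for cohort tests (cached per session)
local_breast_cohort <- function(n = 4, seed = 11, noise = 0.08,
                                dir = tempfile("cohort")) {
  spec <- cohort_spec("breast", n_patients = n, seed = seed, noise = noise)
  list(spec = spec, manifest = generate_cohort(spec, dir), dir = dir)
}
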