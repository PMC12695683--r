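test_that("RTDOSE round-trip preserves geometry exactly and dose to the quantization step", {
  set.seed(42)
  vals <- array(runif(10 * 9 * 8, 0, 60), dim = c(10, 9, 8))
  g <- dose_grid(vals, origin = c(-20, -15, -10), spacing = c(2, 2.5, 3),
                 frame_ref = "FOR.RT")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(g, path)
  g2 <- read_rtdose(path)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)
  expect_identical(g2$shape, g$shape)
  expect_identical(g2$frame_ref, "FOR.RT")
  quant_step <- max(vals) / 2^30
  expect_lt(max(abs(g2$values - g$values)), quant_step)
})

test_that("uniform RTDOSE round-trips as a constant", {
  g <- dose_grid(array(2, dim = c(6, 6, 4)), origin = c(0, 0, 0),
                 spacing = c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(g, path)
  expect_equal(read_rtdose(path)$values, g$values, tolerance = 1e-9)
})

test_that("read_rtdose agrees with an independent tag-by-tag parse (pydicom)", {
  set.seed(7)
  vals <- array(runif(5 * 4 * 3, 0, 12), dim = c(5, 4, 3))
  g <- dose_grid(vals, origin = c(1.5, -2.25, 3), spacing = c(2, 3, 4),
                 frame_ref = "FOR.PD")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(g, path)
  script <- paste(
    "import pydicom, json, sys, numpy as np",
    "d = pydicom.dcmread(sys.argv[1])",
    "arr = (d.pixel_array.astype('float64') * float(d.DoseGridScaling))",
    "print(json.dumps({'modality': d.Modality,",
    " 'ipp': [float(v) for v in d.ImagePositionPatient],",
    " 'pixel_spacing': [float(v) for v in d.PixelSpacing],",
    " 'shape': list(arr.shape),",
    " 'mean': float(arr.mean()), 'max': float(arr.max())}))",
    sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2("python", c(sf, path), stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_identical(ref$modality, "RTDOSE")
  expect_equal(ref$ipp, g$origin)
  expect_equal(ref$pixel_spacing, g$spacing[c(2, 1)])
  expect_equal(ref$shape, c(3, 4, 5))  # frames, rows, cols
  expect_equal(ref$mean, mean(g$values), tolerance = 1e-7)
  expect_equal(ref$max, max(g$values), tolerance = 1e-7)
})

test_that("malformed dose files raise format/type errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(1:64), path)
  expect_error(read_rtdose(path), "DICM")
  g <- dose_grid(array(1, dim = c(2, 2, 2)), c(0, 0, 0), c(1, 1, 1))
  full <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(g, full)
  trunc <- withr::local_tempfile(fileext = ".dcm")
  bytes <- readBin(full, raw(), file.size(full))
  writeBin(bytes[1:(length(bytes) - 20)], trunc)
  expect_error(read_rtdose(trunc), "end of file|shorter")
  ct <- withr::local_tempfile(fileext = ".dcm")
  write_ct_geometry(g, ct)
  expect_error(read_rtdose(ct), "not an RTDOSE")
})

test_that("RTSTRUCT round-trip preserves contours; name_map renames and merges", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  circ <- function(r, z, cx = 0) cbind(cx + r * cos(th), r * sin(th), z)
  ss <- structure_set(
    list(Lung_ipsi = list(circ(30, -4), circ(32, 0), circ(28, 4)),
         heartA = list(circ(20, 0, cx = 60)),
         heartB = list(circ(18, 4, cx = 60))),
    frame_ref = "FOR.S")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(ss, path)

  plain <- read_rtstruct(path)
  expect_setequal(names(plain$rois), c("Lung_ipsi", "heartA", "heartB"))
  err <- max(mapply(function(a, b) max(abs(a - b)),
                    ss$rois$Lung_ipsi, plain$rois$Lung_ipsi))
  expect_lt(err, 1e-6)

  mapped <- read_rtstruct(path, name_map = c(Lung_ipsi = "Lung_IPSI",
                                             heartA = "Heart",
                                             heartB = "Heart"))
  expect_setequal(names(mapped$rois), c("Lung_IPSI", "Heart"))
  expect_length(mapped$rois$Heart, 2)  # merged contour lists
  expect_identical(mapped$frame_ref, "FOR.S")
})

test_that("degenerate structure inputs are handled with warnings", {
  # malformed contour (< 3 points) skipped at construction
  expect_warning(
    ss <- structure_set(list(A = list(cbind(c(0, 1), c(0, 1), c(0, 0)),
                                      cbind(c(0, 5, 5, 0), c(0, 0, 5, 5),
                                            c(0, 0, 0, 0))))),
    "malformed")
  expect_length(ss$rois$A, 1)
})

test_that("rasterize matches the worked 10 mm square example", {
  # 1 mm grid with centers at 0.5..19.5; square [5, 15] x [5, 15] on z = 0
  g <- dose_grid(array(1, dim = c(20, 20, 3)), origin = c(0.5, 0.5, -1),
                 spacing = c(1, 1, 1), frame_ref = "FOR.G")
  sq <- cbind(c(5, 15, 15, 5), c(5, 5, 15, 15), c(0, 0, 0, 0))
  ss <- structure_set(list(SQ = list(sq)), frame_ref = "FOR.G")
  m <- rasterize(ss, "SQ", g)
  expect_identical(sum(m$inside), 100L)
  expect_identical(sum(m$inside[, , 2]), 100L)  # only the z = 0 slice
})

test_that("rasterize equals brute-force point-in-polygon on random convex polygons", {
  set.seed(101)
  g <- dose_grid(array(1, dim = c(24, 24, 1)), origin = c(-11.5, -11.5, 0),
                 spacing = c(1, 1, 1), frame_ref = "FOR.G")
  xc <- grid_axis(g, 1); yc <- grid_axis(g, 2)
  for (trial in 1:50) {
    poly <- random_convex_polygon(center = runif(2, -2, 2), radius = 9)
    ss <- structure_set(list(P = list(cbind(poly, 0))), frame_ref = "FOR.G")
    ref <- brute_mask(poly, xc, yc)
    if (!any(ref)) next
    m <- rasterize(ss, "P", g)
    expect_identical(m$inside[, , 1], ref)
  }
})

test_that("rasterize enforces frame, lookup, slice-assignment and empty-mask errors", {
  g <- dose_grid(array(1, dim = c(10, 10, 4)), origin = c(0.5, 0.5, 0),
                 spacing = c(1, 1, 2), frame_ref = "FOR.A")
  sq <- function(z) cbind(c(2, 8, 8, 2), c(2, 2, 8, 8), rep(z, 4))
  ss_other <- structure_set(list(A = list(sq(0))), frame_ref = "FOR.B")
  expect_error(rasterize(ss_other, "A", g), "frame")
  ss <- structure_set(list(A = list(sq(0))), frame_ref = "FOR.A")
  expect_error(rasterize(ss, "B", g), "not found")
  # contour farther than half a slice spacing from any slice center
  ss_far <- structure_set(list(A = list(sq(20))), frame_ref = "FOR.A")
  expect_error(rasterize(ss_far, "A", g), "slice")
  # contour entirely outside the in-plane grid extent
  out_sq <- cbind(c(50, 60, 60, 50), c(50, 50, 60, 60), rep(0, 4))
  ss_out <- structure_set(list(A = list(out_sq)), frame_ref = "FOR.A")
  expect_error(rasterize(ss_out, "A", g), "empty mask")
})

test_that("nested contours on one slice carve holes (even-odd rule)", {
  g <- dose_grid(array(1, dim = c(30, 30, 1)), origin = c(0.5, 0.5, 0),
                 spacing = c(1, 1, 1), frame_ref = "FOR.A")
  outer_sq <- cbind(c(2, 28, 28, 2), c(2, 2, 28, 28), rep(0, 4))
  inner_sq <- cbind(c(10, 20, 20, 10), c(10, 10, 20, 20), rep(0, 4))
  ss <- structure_set(list(ring = list(outer_sq, inner_sq)),
                      frame_ref = "FOR.A")
  m <- rasterize(ss, "ring", g)
  expect_false(m$inside[15, 15, 1])   # inside the hole
  expect_true(m$inside[5, 5, 1])      # in the ring
})

test_that("resample_to is exact for identity, constants and trilinear fields", {
  set.seed(3)
  vals <- array(runif(12^3), dim = c(12, 12, 12))
  g <- dose_grid(vals, origin = c(0, 0, 0), spacing = c(2, 2, 2))
  expect_identical(resample_to(g, g)$values, g$values)

  const <- dose_grid(array(3, dim = c(12, 12, 12)), c(0, 0, 0), c(2, 2, 2))
  target <- dose_grid(array(0, dim = c(5, 5, 5)), c(3.1, 4.7, 2.9),
                      c(1.3, 1.7, 2.1))
  expect_equal(resample_to(const, target)$values,
               array(3, dim = c(5, 5, 5)))

  lin <- function(x, y, z) 0.5 + 0.25 * x + 0.1 * y + 0.05 * z
  ax <- function(gr, k) grid_axis(gr, k)
  src <- dose_grid(array(0, dim = c(12, 12, 12)), c(0, 0, 0), c(2, 2, 2))
  src$values <- outer(outer(0.25 * ax(src, 1), 0.1 * ax(src, 2), "+"),
                      0.05 * ax(src, 3), "+") + 0.5
  res <- resample_to(src, target)
  expected <- outer(outer(0.25 * ax(target, 1), 0.1 * ax(target, 2), "+"),
                    0.05 * ax(target, 3), "+") + 0.5
  expect_equal(res$values, expected, tolerance = 1e-12)
})

test_that("resample_to zero-fills outside the source and warns on disjoint extents", {
  src <- dose_grid(array(5, dim = c(4, 4, 4)), c(0, 0, 0), c(1, 1, 1))
  target <- dose_grid(array(0, dim = c(4, 4, 4)), c(100, 100, 100), c(1, 1, 1))
  expect_warning(res <- resample_to(src, target), "overlap")
  expect_true(all(res$values == 0))
})

test_that("accumulate_course follows the MU/fraction arithmetic and is linear", {
  img <- dose_grid(array(0.03, dim = c(6, 6, 6)), c(0, 0, 0), c(2, 2, 2),
                   frame_ref = "FOR.C")
  p25 <- protocol_spec("5MU", 5, 25)
  out <- accumulate_course(NULL, img, p25, reference_mu = 5)
  expect_equal(out$values, array(0.75, dim = c(6, 6, 6)))
  p10 <- protocol_spec("10MU", 10, 25)
  out2 <- accumulate_course(NULL, img, p10, reference_mu = 5)
  expect_equal(out2$values, 2 * out$values)

  treat <- dose_grid(array(40, dim = c(6, 6, 6)), c(0, 0, 0), c(2, 2, 2),
                     frame_ref = "FOR.C")
  img28 <- dose_grid(array(0.02, dim = c(6, 6, 6)), c(0, 0, 0), c(2, 2, 2),
                     frame_ref = "FOR.C")
  tot <- accumulate_course(treat, img28, protocol_spec("x", 5, 28),
                           reference_mu = 5)
  expect_equal(tot$values, array(40.56, dim = c(6, 6, 6)))

  # linearity in n_fractions and mu_per_fraction
  set.seed(5)
  imgr <- dose_grid(array(runif(216, 0, 0.05), dim = c(6, 6, 6)),
                    c(0, 0, 0), c(2, 2, 2), frame_ref = "FOR.C")
  a <- accumulate_course(NULL, imgr, protocol_spec("a", 5, 10))
  b <- accumulate_course(NULL, imgr, protocol_spec("b", 5, 20))
  c3 <- accumulate_course(NULL, imgr, protocol_spec("c", 15, 10))
  expect_equal(b$values, 2 * a$values, tolerance = 1e-12)
  expect_equal(c3$values, 3 * a$values, tolerance = 1e-12)

  # lattice / frame mismatches are consistency errors
  shifted <- dose_grid(array(1, dim = c(6, 6, 6)), c(1, 0, 0), c(2, 2, 2),
                       frame_ref = "FOR.C")
  expect_error(accumulate_course(treat, shifted, p25), "lattice")
  other <- dose_grid(array(1, dim = c(6, 6, 6)), c(0, 0, 0), c(2, 2, 2),
                     frame_ref = "FOR.OTHER")
  expect_error(accumulate_course(treat, other, p25), "frame")
})

test_that("CT geometry stub round-trips the lattice", {
  g <- dose_grid(array(0, dim = c(8, 7, 6)), c(-4, -3.5, -3), c(1, 1.5, 2),
                 frame_ref = "FOR.CT")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_ct_geometry(g, path)
  g2 <- read_ct_geometry(path)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)
  expect_identical(g2$shape, g$shape)
  expect_true(all(g2$values == 0))
})
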