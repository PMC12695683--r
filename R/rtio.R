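#' Write a dose grid as a DICOM RTDOSE file
#'
#' Dose is quantized to 32-bit integers with a per-file `DoseGridScaling`
#' chosen so the maximum dose maps near full range (2^30), i.e. the
#' quantization step is about `max(dose) / 2^30` Gy. Pixel data are stored
#' frame by frame (z), row by row (y), column-fastest (x), matching the
#' in-memory `[x, y, z]` array layout.
#'
#' @param grid a `dose_grid`.
#' @param path output file path.
#' @param sop_instance_uid SOP instance UID; supply a deterministic value for
#'   reproducible byte-identical output (the default is a fixed UID).
#' @param dose_summation_type `"PLAN"` or `"FRACTION"` (per-fraction imaging
#'   grids use `"FRACTION"`); metadata only.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(grid, path,
                         sop_instance_uid = paste0(UID_ROOT, ".2.1"),
                         dose_summation_type = "PLAN") {
  stopifnot(inherits(grid, "dose_grid"))
  mx <- max(grid$values)
  # round the scaling to 8 significant digits so its DS string is exact and
  # the round-trip error is bounded by the quantization step (~ mx / 2^30)
  scaling <- if (mx > 0) signif(mx / 2^30, 8) else 1.0
  stored <- as.integer(round(grid$values / scaling))
  nz <- grid$shape[3]
  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_SOP_RTDOSE),
    dcm_str(0x0008, 0x0018, "UI", sop_instance_uid),
    dcm_str(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_num_str(0x0020, 0x0032, "DS", grid$origin),
    dcm_num_str(0x0020, 0x0037, "DS", grid$orientation),
    dcm_str(0x0020, 0x0052, "UI", grid$frame_ref),
    dcm_us(0x0028, 0x0002, 1),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_str(0x0028, 0x0008, "IS", as.character(nz)),
    dcm_at(0x0028, 0x0009, 0x3004, 0x000C),
    dcm_us(0x0028, 0x0010, grid$shape[2]),          # Rows (y)
    dcm_us(0x0028, 0x0011, grid$shape[1]),          # Columns (x)
    dcm_num_str(0x0028, 0x0030, "DS", grid$spacing[c(2, 1)]),  # row\col
    dcm_us(0x0028, 0x0100, 32), dcm_us(0x0028, 0x0101, 32),
    dcm_us(0x0028, 0x0102, 31), dcm_us(0x0028, 0x0103, 0),
    dcm_str(0x3004, 0x0002, "CS", "GY"),
    dcm_str(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_str(0x3004, 0x000A, "CS", dose_summation_type),
    dcm_num_str(0x3004, 0x000C, "DS", grid$spacing[3] * (seq_len(nz) - 1)),
    dcm_num_str(0x3004, 0x000E, "DS", scaling, digits = 9),
    dcm_int_pixels(stored)
  )
  write_dicom_file(path, UID_SOP_RTDOSE, sop_instance_uid, ds)
}

#' Read a DICOM RTDOSE file into a dose grid
#'
#' Applies `DoseGridScaling` so the returned values are in Gy. Requires an
#' axis-aligned orientation and a uniform `GridFrameOffsetVector`.
#'
#' @param path RTDOSE file path.
#' @return a `dose_grid`.
#' @export
read_rtdose <- function(path) {
  ds <- read_dicom_dataset(path)
  modality <- ds[["00080060"]]
  if (is.null(modality) || !identical(toupper(modality$value), "RTDOSE")) {
    stop(sprintf("not an RTDOSE object (Modality = '%s')",
                 if (is.null(modality)) "?" else modality$value), call. = FALSE)
  }
  origin <- ds_required(ds, "00200032", "ImagePositionPatient")
  pixsp <- ds_required(ds, "00280030", "PixelSpacing")
  rows <- ds_required(ds, "00280010", "Rows")
  cols <- ds_required(ds, "00280011", "Columns")
  nframes <- ds_required(ds, "00280008", "NumberOfFrames")
  offsets <- ds_required(ds, "3004000C", "GridFrameOffsetVector")
  scaling <- ds_required(ds, "3004000E", "DoseGridScaling")
  pix <- ds_required(ds, "7FE00010", "PixelData")
  bits <- ds_required(ds, "00280100", "BitsAllocated")
  if (bits != 32) stop("only 32-bit dose pixel data supported", call. = FALSE)
  frame_ref <- if (!is.null(ds[["00200052"]])) ds[["00200052"]]$value else "FOR.UNKNOWN"
  orient <- if (!is.null(ds[["00200037"]])) ds[["00200037"]]$value else c(1, 0, 0, 0, 1, 0)

  dz <- if (length(offsets) > 1) {
    steps <- diff(offsets)
    if (diff(range(steps)) > 1e-6) {
      stop("non-uniform GridFrameOffsetVector not supported", call. = FALSE)
    }
    steps[1]
  } else 1.0
  n <- as.integer(cols) * as.integer(rows) * as.integer(nframes)
  stored <- readBin(pix, "integer", n = n, size = 4, endian = "little")
  if (length(stored) < n) {
    stop("DICOM format error: pixel data shorter than Rows*Columns*Frames",
         call. = FALSE)
  }
  vals <- array(stored * scaling, dim = c(cols, rows, nframes))
  dose_grid(vals, origin = origin, spacing = c(pixsp[2], pixsp[1], dz),
            orientation = orient, frame_ref = frame_ref)
}

#' Write a structure set as a DICOM RTSTRUCT file
#'
#' @param structure a `structure_set`.
#' @param path output file path.
#' @param label structure-set label.
#' @param sop_instance_uid SOP instance UID (fixed default for reproducible
#'   bytes).
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(structure, path, label = "rtimagerisk",
                           sop_instance_uid = paste0(UID_ROOT, ".3.1")) {
  stopifnot(inherits(structure, "structure_set"))
  roi_names <- names(structure$rois)
  roi_items <- lapply(seq_along(roi_names), function(i) {
    c(dcm_str(0x3006, 0x0022, "IS", as.character(i)),
      dcm_str(0x3006, 0x0024, "UI", structure$frame_ref),
      dcm_str(0x3006, 0x0026, "LO", roi_names[i]),
      dcm_str(0x3006, 0x0036, "CS", "AUTOMATIC"))
  })
  contour_items <- lapply(seq_along(roi_names), function(i) {
    contours <- structure$rois[[roi_names[i]]]
    citems <- lapply(contours, function(p) {
      c(dcm_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_str(0x3006, 0x0046, "IS", as.character(nrow(p))),
        dcm_num_str(0x3006, 0x0050, "DS", as.vector(t(p))))
    })
    c(dcm_sq(0x3006, 0x0040, citems),
      dcm_str(0x3006, 0x0084, "IS", as.character(i)))
  })
  frame_item <- list(dcm_str(0x0020, 0x0052, "UI", structure$frame_ref))
  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_SOP_RTSTRUCT),
    dcm_str(0x0008, 0x0018, "UI", sop_instance_uid),
    dcm_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_str(0x3006, 0x0002, "SH", label),
    dcm_sq(0x3006, 0x0010, frame_item),
    dcm_sq(0x3006, 0x0020, roi_items),
    dcm_sq(0x3006, 0x0039, contour_items)
  )
  write_dicom_file(path, UID_SOP_RTSTRUCT, sop_instance_uid, ds)
}

#' Read a DICOM RTSTRUCT file into a structure set
#'
#' Contours are grouped per ROI; an optional nomenclature map renames raw ROI
#' names to canonical ones and merges duplicates (see [map_roi_names()]). ROIs
#' absent from the map keep their raw names. Contours with fewer than three
#' points are skipped with a warning; a file without contour data yields an
#' empty structure set with a warning.
#'
#' @param path RTSTRUCT file path.
#' @param name_map named character vector, raw -> canonical ROI names.
#' @return a `structure_set`.
#' @export
read_rtstruct <- function(path, name_map = character()) {
  ds <- read_dicom_dataset(path)
  modality <- ds[["00080060"]]
  if (is.null(modality) || !identical(toupper(modality$value), "RTSTRUCT")) {
    stop(sprintf("not an RTSTRUCT object (Modality = '%s')",
                 if (is.null(modality)) "?" else modality$value), call. = FALSE)
  }
  frame_ref <- "FOR.UNKNOWN"
  if (!is.null(ds[["30060010"]]) && length(ds[["30060010"]]$value)) {
    it <- ds[["30060010"]]$value[[1]]
    if (!is.null(it[["00200052"]])) frame_ref <- it[["00200052"]]$value
  }
  roi_seq <- ds[["30060020"]]
  con_seq <- ds[["30060039"]]
  if (is.null(roi_seq) || is.null(con_seq) || !length(con_seq$value)) {
    warning("structure set contains no contour data; returning empty set")
    return(structure_set(stats::setNames(list(), character(0)),
                         frame_ref = frame_ref))
  }
  number_to_name <- list()
  for (it in roi_seq$value) {
    num <- as.character(it[["30060022"]]$value)
    number_to_name[[num]] <- it[["30060026"]]$value
  }
  rois <- list()
  for (it in con_seq$value) {
    num <- as.character(it[["30060084"]]$value)
    nm <- number_to_name[[num]]
    if (is.null(nm)) nm <- paste0("ROI_", num)
    contours <- list()
    cs <- it[["30060040"]]
    if (!is.null(cs)) {
      for (cit in cs$value) {
        pts <- cit[["30060050"]]$value
        if (is.null(pts) || length(pts) < 9) {
          warning("skipping malformed contour with < 3 points")
          next
        }
        contours[[length(contours) + 1L]] <-
          matrix(pts, ncol = 3, byrow = TRUE)
      }
    }
    rois[[nm]] <- c(rois[[nm]], contours)
  }
  if (!length(rois)) {
    warning("structure set contains no usable contours; returning empty set")
    return(structure_set(stats::setNames(list(), character(0)),
                         frame_ref = frame_ref))
  }
  map_roi_names(structure_set(rois, frame_ref = frame_ref), name_map)
}

#' Write a CT geometry stub
#'
#' A single multi-frame CT object carrying only lattice geometry (constant
#' pixel data), used to pin the planning lattice of a synthetic patient;
#' readers ignore the image content.
#'
#' @param grid a `dose_grid` whose lattice is to be recorded (values ignored).
#' @param path output path.
#' @param sop_instance_uid SOP instance UID.
#' @return `path`, invisibly.
#' @export
write_ct_geometry <- function(grid, path,
                              sop_instance_uid = paste0(UID_ROOT, ".4.1")) {
  stopifnot(inherits(grid, "dose_grid"))
  nz <- grid$shape[3]
  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_SOP_CT),
    dcm_str(0x0008, 0x0018, "UI", sop_instance_uid),
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_num_str(0x0020, 0x0032, "DS", grid$origin),
    dcm_num_str(0x0020, 0x0037, "DS", grid$orientation),
    dcm_str(0x0020, 0x0052, "UI", grid$frame_ref),
    dcm_str(0x0028, 0x0008, "IS", as.character(nz)),
    dcm_us(0x0028, 0x0010, grid$shape[2]),
    dcm_us(0x0028, 0x0011, grid$shape[1]),
    dcm_num_str(0x0028, 0x0030, "DS", grid$spacing[c(2, 1)]),
    dcm_num_str(0x3004, 0x000C, "DS", grid$spacing[3] * (seq_len(nz) - 1))
  )
  write_dicom_file(path, UID_SOP_CT, sop_instance_uid, ds)
}

#' Read lattice geometry from a CT geometry stub
#'
#' @param path CT stub path written by [write_ct_geometry()].
#' @return a `dose_grid` of zeros on the recorded lattice.
#' @export
read_ct_geometry <- function(path) {
  ds <- read_dicom_dataset(path)
  origin <- ds_required(ds, "00200032", "ImagePositionPatient")
  pixsp <- ds_required(ds, "00280030", "PixelSpacing")
  rows <- ds_required(ds, "00280010", "Rows")
  cols <- ds_required(ds, "00280011", "Columns")
  nframes <- ds_required(ds, "00280008", "NumberOfFrames")
  offsets <- ds_required(ds, "3004000C", "GridFrameOffsetVector")
  frame_ref <- if (!is.null(ds[["00200052"]])) ds[["00200052"]]$value else "FOR.UNKNOWN"
  dz <- if (length(offsets) > 1) diff(offsets)[1] else 1.0
  dose_grid(array(0, dim = c(cols, rows, nframes)), origin = origin,
            spacing = c(pixsp[2], pixsp[1], dz), frame_ref = frame_ref)
}
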