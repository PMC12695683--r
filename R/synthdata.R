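#' Site template for the synthetic phantom cohort
#'
#' Defines, per treatment site, the phantom lattice, the organ-at-risk
#' geometry (spheres / cylinders / ellipsoids in the patient coordinate
#' system), the analytic treatment field (a sigmoid distance falloff from the
#' target, whose range/width were calibrated once so course-total organ mean
#' doses land in the magnitude ranges reported for clinical cohorts), the
#' site-default fraction count (25 breast / 28 pelvic / 35 head & neck) and
#' the intended per-ROI course-total mean-dose ranges (`dose_scale_targets`)
#' that generated cohorts are expected to satisfy.
#'
#' @param site `"breast"`, `"pelvic"` or `"head_neck"`.
#' @param grid_shape voxels per axis (isotropic phantom), default 64.
#' @param grid_spacing_mm voxel size in mm, default 4 (25.6 cm extent).
#' @return a `site_template` object.
#' @export
site_template <- function(site = c("breast", "pelvic", "head_neck"),
                          grid_shape = 64L, grid_spacing_mm = 4) {
  site <- match.arg(site)
  geom <- switch(site,
    breast = list(
      rois = list(
        Breast_CNTR = list(shape = "ellipsoid", center = c(70, -60, 0),
                           size = c(45, 35, 45)),
        Lung_IPSI = list(shape = "ellipsoid", center = c(-50, 0, 0),
                         size = c(40, 55, 85)),
        Lung_CNTR = list(shape = "ellipsoid", center = c(50, 0, 0),
                         size = c(40, 55, 85)),
        Heart = list(shape = "sphere", center = c(25, 0, -25), size = 40)
      ),
      target = c(-70, -60, 0), rx_gy = 52.5, falloff_r0 = 53, falloff_w = 30,
      n_fractions = 25L, lateralized = TRUE,
      dose_scale_targets = list(
        Breast_CNTR = c(2.2, 5.5), Lung_IPSI = c(11, 26),
        Lung_CNTR = c(2.3, 5.6), Heart = c(4, 10))
    ),
    pelvic = list(
      rois = list(
        Rectum = list(shape = "cylinder", center = c(0, 70, -10),
                      size = c(15, 15, 45)),
        Bladder = list(shape = "sphere", center = c(0, 5, -10), size = 35),
        Bowel_Bag = list(shape = "ellipsoid", center = c(0, 30, 60),
                         size = c(70, 50, 50))
      ),
      target = c(0, 60, -10), rx_gy = 51.5, falloff_r0 = 78, falloff_w = 23,
      n_fractions = 28L, lateralized = FALSE,
      dose_scale_targets = list(
        Rectum = c(33, 60), Bladder = c(21, 50), Bowel_Bag = c(13, 33))
    ),
    head_neck = list(
      rois = list(
        Parotid_L = list(shape = "sphere", center = c(55, -10, 30), size = 20),
        Parotid_R = list(shape = "sphere", center = c(-55, -10, 30), size = 20),
        SpinalCord = list(shape = "cylinder", center = c(0, 60, -10),
                          size = c(5, 5, 110)),
        Brainstem = list(shape = "cylinder", center = c(0, 45, 85),
                         size = c(12, 12, 20)),
        OpticNerve_L = list(shape = "cylinder", center = c(15, 20, 95),
                            size = c(6, 6, 10)),
        OpticNerve_R = list(shape = "cylinder", center = c(-15, 20, 95),
                            size = c(6, 6, 10))
      ),
      target = c(3, 10, 20), rx_gy = 73, falloff_r0 = 44, falloff_w = 22,
      n_fractions = 35L, lateralized = FALSE,
      dose_scale_targets = list(
        Parotid_L = c(16, 38), Parotid_R = c(14, 33), SpinalCord = c(10, 24),
        Brainstem = c(10, 25), OpticNerve_L = c(9, 22), OpticNerve_R = c(9, 22))
    )
  )
  structure(
    c(list(site = site, grid_shape = as.integer(grid_shape),
           grid_spacing_mm = as.double(grid_spacing_mm)), geom),
    class = "site_template"
  )
}

#' Cohort generation settings
#'
#' @param site `"breast"`, `"pelvic"` or `"head_neck"`.
#' @param n_patients cohort size (site defaults from the emulated study:
#'   breast 30, pelvic 17, head & neck 20).
#' @param age_distribution proportions of patients in the three age strata
#'   `< 40`, `40-60`, `> 60`; ages are uniform within `[18, 40)`, `[40, 60]`,
#'   `(60, 85]`.
#' @param seed integer seed; every per-patient draw uses a substream derived
#'   from it, so regeneration is bit-reproducible.
#' @param mu_reference MU setting of the written per-fraction imaging grid.
#' @param imaging_dose_per_mu imaging dose scale at isocenter, Gy per MU
#'   (default 0.0065, i.e. a few cGy per acquisition).
#' @param noise relative SD of per-patient dose-scale jitter.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(site = c("breast", "pelvic", "head_neck"),
                        n_patients = NULL,
                        age_distribution = c(0.3, 0.4, 0.3),
                        seed = 1L, mu_reference = 5,
                        imaging_dose_per_mu = 0.0065, noise = 0.08) {
  site <- match.arg(site)
  if (is.null(n_patients)) {
    n_patients <- c(breast = 30L, pelvic = 17L, head_neck = 20L)[[site]]
  }
  stopifnot(n_patients >= 1, length(age_distribution) == 3,
            abs(sum(age_distribution) - 1) < 1e-9, mu_reference > 0,
            imaging_dose_per_mu >= 0, noise >= 0)
  structure(
    list(site = site, n_patients = as.integer(n_patients),
         age_distribution = as.double(age_distribution),
         seed = as.integer(seed), mu_reference = as.double(mu_reference),
         imaging_dose_per_mu = as.double(imaging_dose_per_mu),
         noise = as.double(noise)),
    class = "cohort_spec"
  )
}

patient_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * index) %% 2147483647)
}

phantom_grid <- function(template, frame_ref) {
  n <- template$grid_shape; sp <- template$grid_spacing_mm
  half_extent <- sp * (n - 1) / 2
  dose_grid(array(0, dim = c(n, n, n)), origin = rep(-half_extent, 3),
            spacing = rep(sp, 3), frame_ref = frame_ref)
}

# contours of a geometric primitive on the grid's axial slices
primitive_contours <- function(spec, grid, n_vertices = 48, mirror_x = FALSE) {
  ctr <- spec$center
  if (mirror_x) ctr[1] <- -ctr[1]
  zc <- grid_axis(grid, 3)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  out <- list()
  for (z in zc) {
    ab <- switch(spec$shape,
      sphere = {
        r2 <- spec$size^2 - (z - ctr[3])^2
        if (r2 < 1) NULL else rep(sqrt(r2), 2)
      },
      cylinder = {
        if (abs(z - ctr[3]) > spec$size[3]) NULL else spec$size[1:2]
      },
      ellipsoid = {
        u <- (z - ctr[3]) / spec$size[3]
        if (1 - u^2 < 1e-4) NULL
        else spec$size[1:2] * sqrt(1 - u^2)
      },
      stop(sprintf("unknown primitive '%s'", spec$shape))
    )
    if (is.null(ab)) next
    out[[length(out) + 1L]] <-
      cbind(ctr[1] + ab[1] * cos(th), ctr[2] + ab[2] * sin(th), z)
  }
  out
}

treatment_field <- function(grid, target, rx, r0, w) {
  dx2 <- (grid_axis(grid, 1) - target[1])^2
  dy2 <- (grid_axis(grid, 2) - target[2])^2
  dz2 <- (grid_axis(grid, 3) - target[3])^2
  dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  grid$values <- rx * stats::plogis(-(dist - r0) / w)
  grid
}

imaging_field <- function(grid, dose_at_iso, ap_gradient = 0.15) {
  yc <- grid_axis(grid, 2)
  rel <- (yc - mean(yc)) / diff(range(yc))      # -0.5 (anterior) .. 0.5
  fy <- dose_at_iso * (1 + ap_gradient * rel)
  n <- grid$shape
  grid$values <- array(rep(rep(fy, each = n[1]), times = n[3]), dim = n)
  grid
}

#' Generate one synthetic patient (DICOM-RT set on disk)
#'
#' Writes, under `out_dir/<patient id>/`, a CT geometry stub, an RTSTRUCT with
#' the template's organs, a course-total treatment RTDOSE (sigmoid distance
#' falloff from the target, per-patient dose-scale and falloff jitter) and a
#' per-fraction imaging RTDOSE at the reference MU (spatially broad with a
#' mild anterior-posterior gradient). Demographics are drawn from the cohort
#' spec's age mixture. All randomness comes from the per-patient substream of
#' the cohort seed, so a regenerated patient is byte-identical.
#'
#' @param template a [site_template()].
#' @param spec a [cohort_spec()].
#' @param index patient index (1-based) within the cohort.
#' @param out_dir output directory (created if needed).
#' @return one-row tibble: the manifest entry for this patient.
#' @export
generate_patient <- function(template, spec, index, out_dir) {
  stopifnot(inherits(template, "site_template"), inherits(spec, "cohort_spec"))
  set.seed(patient_seed(spec$seed, index))
  id <- sprintf("%s_%03d", template$site, index)
  pdir <- file.path(out_dir, id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(pdir)) stop(sprintf("cannot create directory %s", pdir))

  stratum <- sample.int(3L, 1L, prob = spec$age_distribution)
  age <- switch(stratum,
                sample(18:39, 1L), sample(40:60, 1L), sample(61:85, 1L))
  sex <- if (template$site == "breast") "F" else sample(c("F", "M"), 1L)
  laterality <- if (isTRUE(template$lateralized)) {
    sample(c("left", "right"), 1L)
  } else NA_character_
  mirror <- identical(laterality, "left")

  frame_ref <- sprintf("%s.5.%d.%d", UID_ROOT, spec$seed, index)
  grid <- phantom_grid(template, frame_ref)

  target <- template$target
  if (mirror) target[1] <- -target[1]
  s_treat <- max(0.5, stats::rnorm(1, 1, spec$noise))
  s_r0 <- max(0.5, stats::rnorm(1, 1, spec$noise / 2))
  treat <- treatment_field(grid, target, template$rx_gy * s_treat,
                           template$falloff_r0 * s_r0, template$falloff_w)

  s_img <- max(0.5, stats::rnorm(1, 1, spec$noise / 2))
  img <- imaging_field(grid, spec$imaging_dose_per_mu * spec$mu_reference * s_img)

  rois <- lapply(template$rois, primitive_contours, grid = grid,
                 mirror_x = mirror)
  ss <- structure_set(rois, frame_ref = frame_ref)

  uid <- function(k) sprintf("%s.%d.%d.%d.%d", UID_ROOT, spec$seed, index, k, 1L)
  ct_path <- file.path(pdir, "ct_geometry.dcm")
  ss_path <- file.path(pdir, "rtstruct.dcm")
  tx_path <- file.path(pdir, "rtdose_treatment.dcm")
  im_path <- file.path(pdir, "rtdose_imaging_fx.dcm")
  write_ct_geometry(grid, ct_path, sop_instance_uid = uid(1))
  write_rtstruct(ss, ss_path, label = id, sop_instance_uid = uid(2))
  write_rtdose(treat, tx_path, sop_instance_uid = uid(3),
               dose_summation_type = "PLAN")
  write_rtdose(img, im_path, sop_instance_uid = uid(4),
               dose_summation_type = "FRACTION")

  tibble::tibble(
    id = id, age_years = as.integer(age), sex = sex, site = template$site,
    laterality = laterality, n_fractions = template$n_fractions,
    structure_path = ss_path, treatment_dose_path = tx_path,
    imaging_dose_path = im_path, ct_path = ct_path
  )
}

#' Generate a full synthetic cohort with its manifest
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory; patients are written in subdirectories and
#'   the manifest to `manifest.csv`, plus a `cohort_config.json` recording the
#'   generation settings (including the seed).
#' @param template optional [site_template()] override; defaults to
#'   `site_template(spec$site)`.
#' @return the manifest tibble (one row per patient), invisibly also written
#'   to `out_dir/manifest.csv`.
#' @export
generate_cohort <- function(spec, out_dir, template = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(template)) template <- site_template(spec$site)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dplyr::bind_rows(lapply(seq_len(spec$n_patients), function(i) {
    generate_patient(template, spec, i, out_dir)
  }))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(site = spec$site, n_patients = spec$n_patients,
         age_distribution = spec$age_distribution, seed = spec$seed,
         mu_reference = spec$mu_reference,
         imaging_dose_per_mu = spec$imaging_dose_per_mu, noise = spec$noise,
         grid_shape = template$grid_shape,
         grid_spacing_mm = template$grid_spacing_mm),
    file.path(out_dir, "cohort_config.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' Analytic reference DVH fixtures with closed-form expectations
#'
#' Canonical fixtures shared by the test suites: a uniform-dose DVH, an
#' equal-volume two-level DVH, a linear-ramp DVH and an all-zero DVH, each
#' stored with its mean dose, OED (alpha' = 0.085) and gEUD (n = 1, 0.5, 0.25)
#' computed by direct brute-force summation over the defining dose levels —
#' independently of the histogram-based evaluators they are used to check.
#'
#' @param bin_width bin width passed to [ddvh_from_levels()].
#' @return named list of fixtures, each `list(dvh =, expected =)`.
#' @export
make_reference_dvh_fixtures <- function(bin_width = 0.01) {
  brute <- function(levels, fractions, alpha_prime = 0.085) {
    list(
      mean = sum(fractions * levels),
      oed = sum(fractions * levels * exp(-alpha_prime * levels)),
      geud = stats::setNames(
        vapply(c(1, 0.5, 0.25),
               function(n) sum(fractions * levels^(1 / n))^n, numeric(1)),
        c("n1", "n0.5", "n0.25"))
    )
  }
  fix <- function(levels, fractions, name) {
    list(dvh = ddvh_from_levels(levels, fractions, bin_width, roi_name = name),
         levels = levels, fractions = fractions,
         expected = brute(levels, fractions))
  }
  ramp_levels <- seq(0.05, 9.95, by = 0.1)
  list(
    uniform = fix(2, 1, "uniform_2gy"),
    two_level = fix(c(1, 3), c(0.5, 0.5), "two_level"),
    ramp = fix(ramp_levels, rep(1 / length(ramp_levels), length(ramp_levels)),
               "linear_ramp"),
    zero = fix(0, 1, "all_zero")
  )
}
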