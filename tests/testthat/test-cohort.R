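# One small generated breast cohort shared across this file
cohort_env <- new.env()
get_cohort <- function() {
  if (is.null(cohort_env$c4)) {
    dir <- tempfile("cohort4_")
    cohort_env$c4 <- local_breast_cohort(n = 4, seed = 11, dir = dir)
  }
  cohort_env$c4
}

test_that("run_patient chains accumulation, DVH and risk models correctly", {
  # hand-built patient: zero treatment, uniform imaging 0.03 Gy/fraction
  dir <- withr::local_tempdir()
  g0 <- dose_grid(array(0, dim = c(16, 16, 8)), c(-15, -15, -7),
                  c(2, 2, 2), frame_ref = "FOR.H")
  gi <- dose_grid(array(0.03, dim = c(16, 16, 8)), c(-15, -15, -7),
                  c(2, 2, 2), frame_ref = "FOR.H")
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  contours <- lapply(c(-5, -3, -1, 1, 3, 5), function(z)
    cbind(10 * cos(th), 10 * sin(th), z))
  ss <- structure_set(list(Lung_IPSI = contours), frame_ref = "FOR.H")
  write_rtdose(g0, file.path(dir, "t.dcm"))
  write_rtdose(gi, file.path(dir, "i.dcm"))
  write_rtstruct(ss, file.path(dir, "s.dcm"))
  rec <- list(id = "P1", age_years = 40, sex = "F", site = "breast",
              laterality = "right", n_fractions = 25,
              structure_path = file.path(dir, "s.dcm"),
              treatment_dose_path = file.path(dir, "t.dcm"),
              imaging_dose_path = file.path(dir, "i.dcm"))
  out <- run_patient(rec, protocol_spec("5MU", 5, 25))

  expect_identical(out$roi, "Lung_IPSI")
  expect_equal(out$mean_dose_gy, 0.75, tolerance = 1e-6)
  # hand-chained oracle on the uniform 0.75 Gy field
  reg <- load_parameter_registry()
  lung <- reg$organs$lung
  expect_equal(out$ntcp_pct,
               100 * ntcp_logistic(0.75, lung$ntcp$d50, lung$ntcp$gamma),
               tolerance = 1e-4)
  oed_ref <- 0.75 * exp(-0.085 * 0.75)
  expect_equal(out$oed_gy, oed_ref, tolerance = 1e-3)
  expect_equal(out$ear_per_10k_py,
               lung$ear$ear0 * oed_ref *
                 mu_age(40, 70, lung$ear$gamma_e, lung$ear$gamma_a),
               tolerance = 1e-3)

  # zero imaging dose: EAR identically zero in imaging-only mode
  write_rtdose(dose_grid(array(0, dim = c(16, 16, 8)), c(-15, -15, -7),
                         c(2, 2, 2), frame_ref = "FOR.H"),
               file.path(dir, "i0.dcm"))
  rec0 <- rec; rec0$imaging_dose_path <- file.path(dir, "i0.dcm")
  out0 <- run_patient(rec0, protocol_spec("5MU", 5, 25),
                      run_config(mode = "imaging_only"))
  expect_identical(out0$ear_per_10k_py, 0)
  expect_identical(out0$oed_gy, 0)
})

test_that("ROIs without contours or registry entries are skipped, run continues", {
  ch <- get_cohort()
  man <- ch$manifest
  # add a structure with an ROI the registry does not know
  ss <- read_rtstruct(man$structure_path[1])
  extra <- ss$rois[[1]]
  ss$rois[["Mystery_Organ"]] <- extra
  newpath <- file.path(dirname(man$structure_path[1]), "rtstruct_extra.dcm")
  write_rtstruct(ss, newpath)
  rec <- as.list(man[1, ]); rec$structure_path <- newpath
  expect_warning(out <- run_patient(rec, protocol_spec("5MU", 5, 25)),
                 "not in registry")
  expect_false("Mystery_Organ" %in% out$roi)
  expect_setequal(unique(out$roi),
                  c("Breast_CNTR", "Lung_IPSI", "Lung_CNTR", "Heart"))
  expect_identical(attr(out, "skipped_rois"), "Mystery_Organ")

  # breast patient without laterality: lateralized ROIs skipped with warning
  rec2 <- as.list(man[1, ]); rec2$laterality <- NA_character_
  expect_warning(out2 <- run_patient(rec2, protocol_spec("5MU", 5, 25)),
                 "laterality")
  expect_setequal(unique(out2$roi), "Heart")
})

test_that("protocol comparison detects a systematic dose increase by paired t-test", {
  ch <- get_cohort()
  p5 <- protocol_spec("5MU", 5, 25)
  p10 <- protocol_spec("10MU", 10, 25)
  cfg <- run_config(mode = "imaging_only")
  rep <- compare_protocols(ch$manifest, p5, p10, cfg)
  expect_s3_class(rep, "cohort_report")
  cmp <- tidy(rep)
  expect_true(all(cmp$n == 4))
  dose_cmp <- dplyr::filter(cmp, .data$metric == "mean_dose_gy")
  expect_true(all(dose_cmp$mean_diff > 0))
  expect_true(all(dose_cmp$p_value < 0.05))
  expect_true(all(dose_cmp$significant))
  # summaries carry mean and SD per protocol
  sm <- tidy(rep, "summaries")
  expect_true(all(c("mean", "sd", "n") %in% names(sm)))
  g <- glance(rep)
  expect_identical(g$n_patients, 4L)
  expect_identical(g$protocol_a, "5MU")
})

test_that("identical protocols yield the degenerate zero-variance flag", {
  ch <- get_cohort()
  pa <- protocol_spec("A", 5, 25)
  pb <- protocol_spec("B", 5, 25)
  rep <- compare_protocols(ch$manifest[1:2, ], pa, pb,
                           run_config(mode = "imaging_only"))
  cmp <- tidy(rep)
  expect_true(all(cmp$p_value == 1))
  expect_true(all(cmp$degenerate))
})

test_that("paired t-test matches the independent textbook computation", {
  a <- c(3.93, 6.89, 3.91, 18.77, 7.3)
  b <- c(4.65, 7.90, 4.66, 19.86, 8.9)
  ours <- rtimagerisk:::paired_test(a, b)
  ref <- brute_paired_t(a, b)
  expect_equal(ours$t, ref$t, tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p, tolerance = 1e-10)
  expect_false(ours$degenerate)
  # and against stats::t.test directly on another fixed pair
  set.seed(404)
  x <- rnorm(12, 10, 2); y <- x + rnorm(12, 0.5, 0.3)
  ours2 <- rtimagerisk:::paired_test(x, y)
  ref2 <- brute_paired_t(x, y)
  expect_equal(ours2$p_value, ref2$p, tolerance = 1e-10)
})

test_that("age stratification uses the stated boundary convention", {
  pp <- tibble::tibble(
    id = sprintf("p%d", 1:4), age_years = c(30L, 40L, 60L, 61L),
    roi = "Lung_IPSI", protocol = "5MU",
    ear_per_10k_py = c(5, 4, 3, 2))
  st <- stratify_by_age(pp)
  counts <- st$n[match(c("<40", "40-60", ">60"), st$age_group)]
  expect_identical(counts, c(1L, 2L, 1L))

  # single-age cohort: one nonempty stratum, empty ones present with n = 0
  pp2 <- pp; pp2$age_years <- 35L
  st2 <- stratify_by_age(pp2)
  expect_identical(sum(st2$n > 0), 1L)
  expect_identical(nrow(st2), 3L)  # all strata listed
  expect_true(all(is.na(st2$mean_ear[st2$n == 0])))
})

test_that("stratified EAR decreases with age on identical dosimetry", {
  # same DVH for three ages differing only in stratum
  dir <- withr::local_tempdir()
  g0 <- dose_grid(array(0, dim = c(12, 12, 6)), c(-11, -11, -5),
                  c(2, 2, 2), frame_ref = "FOR.AG")
  gi <- dose_grid(array(0.03, dim = c(12, 12, 6)), c(-11, -11, -5),
                  c(2, 2, 2), frame_ref = "FOR.AG")
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  ss <- structure_set(list(Heart = lapply(c(-3, -1, 1, 3), function(z)
    cbind(8 * cos(th), 8 * sin(th), z))), frame_ref = "FOR.AG")
  write_rtdose(g0, file.path(dir, "t.dcm"))
  write_rtdose(gi, file.path(dir, "i.dcm"))
  write_rtstruct(ss, file.path(dir, "s.dcm"))
  man <- dplyr::bind_rows(lapply(seq_along(c(30, 50, 65)), function(k) {
    tibble::tibble(id = sprintf("p%d", k), age_years = c(30L, 50L, 65L)[k],
                   sex = "F", site = "pelvic", laterality = NA_character_,
                   n_fractions = 25L,
                   structure_path = file.path(dir, "s.dcm"),
                   treatment_dose_path = file.path(dir, "t.dcm"),
                   imaging_dose_path = file.path(dir, "i.dcm"))
  }))
  rep <- compare_protocols(man, protocol_spec("5MU", 5, 25),
                           protocol_spec("10MU", 10, 25),
                           run_config(mode = "imaging_only"))
  st <- rep$strata
  for (proto in c("5MU", "10MU")) {
    ears <- st$mean_ear[st$protocol == proto][
      match(c("<40", "40-60", ">60"),
            st$age_group[st$protocol == proto])]
    expect_true(all(diff(ears) < 0))
  }
})

test_that("sensitivity sweep reproduces the documented monotonicities", {
  ch <- get_cohort()
  rec <- ch$manifest[1, ]
  p5 <- protocol_spec("5MU", 5, 25)
  cfg <- run_config(mode = "imaging_only")
  sw <- sensitivity_sweep(rec, "alpha_prime", c(0, 0.085, 0.2), p5, cfg)
  for (roi in unique(sw$roi)) {
    v <- sw$oed_gy[sw$roi == roi]
    expect_true(all(diff(v) < 0))  # OED non-increasing in alpha'
  }
  sw2 <- sensitivity_sweep(rec, "ear0", c(4, 8), p5, cfg)
  for (roi in unique(sw2$roi)) {
    v <- sw2$ear_per_10k_py[sw2$roi == roi]
    expect_equal(v[2], 2 * v[1], tolerance = 1e-9)
  }
  sw3 <- sensitivity_sweep(rec, "d50", c(20, 40, 60), p5, cfg)
  logistic_rois <- c("Lung_IPSI", "Lung_CNTR", "Breast_CNTR")
  for (roi in logistic_rois) {
    v <- sw3$ntcp_pct[sw3$roi == roi]
    expect_true(all(diff(v) < 0))  # NTCP decreasing in D50
  }
  expect_error(sensitivity_sweep(rec, "bogus", 1, p5, cfg), "unknown")
})

test_that("export writes consistent, deterministic tables and log plots drop zeros", {
  ch <- get_cohort()
  rep <- compare_protocols(ch$manifest, protocol_spec("5MU", 5, 25),
                           protocol_spec("10MU", 10, 25),
                           run_config(mode = "imaging_only"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_report(rep, d1, registry = load_parameter_registry())
  export_report(rep, d2)
  for (f in c("per_patient.csv", "summary.csv", "comparisons.csv",
              "strata.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readBin(file.path(d1, f), raw(), 1e7),
                     readBin(file.path(d2, f), raw(), 1e7))
  }
  pp <- utils::read.csv(file.path(d1, "per_patient.csv"))
  # 4 patients x 4 ROIs x 2 protocols
  expect_identical(nrow(pp), 32L)
  manifest <- jsonlite::read_json(file.path(d1, "run_manifest.json"))
  expect_identical(manifest$meta$n_patients, 4L)
  expect_true(!is.null(manifest$registry_sources$lung$ear))

  # log-scale autoplot drops non-positive values with a message
  rep0 <- rep
  rep0$per_patient$ear_per_10k_py[1] <- 0
  expect_message(p <- autoplot(rep0, "ear_per_10k_py", log_scale = TRUE),
                 "dropping")
  expect_s3_class(p, "ggplot")
})
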