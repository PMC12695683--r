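#' Pipeline run configuration
#'
#' Bundles everything [run_patient()] and [compare_protocols()] need besides
#' the manifest: the parameter registry, ROI nomenclature map, the reference
#' MU of the stored per-fraction imaging grids, the accumulation mode, and the
#' radiobiological constants.
#'
#' @param registry a `param_registry`; defaults to the shipped registry.
#' @param name_map named character vector mapping raw to canonical ROI names.
#' @param reference_mu MU at which per-fraction imaging RTDOSE grids were
#'   exported (imaging dose scales linearly with MU).
#' @param mode `"total"` (treatment + imaging) or `"imaging_only"` (treatment
#'   term zero, isolating the imaging contribution).
#' @param bin_width DVH bin width in Gy.
#' @param attained_age attained age for EAR, years (fixed default 70).
#' @param gy_per_sv photon dose-to-equivalent-dose factor.
#' @return a `run_config` object.
#' @export
run_config <- function(registry = load_parameter_registry(),
                       name_map = character(),
                       reference_mu = 5,
                       mode = c("total", "imaging_only"),
                       bin_width = 0.01,
                       attained_age = 70,
                       gy_per_sv = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(registry, "param_registry"), reference_mu > 0,
            bin_width > 0, attained_age > 0, gy_per_sv > 0)
  structure(
    list(registry = registry, name_map = name_map,
         reference_mu = reference_mu, mode = mode, bin_width = bin_width,
         attained_age = attained_age, gy_per_sv = gy_per_sv),
    class = "run_config"
  )
}

site_default_fractions <- c(breast = 25L, pelvic = 28L, head_neck = 35L)

normalize_record <- function(record) {
  record <- as.list(record)
  if (is.null(record$id) || !nzchar(record$id)) stop("patient record needs an id")
  if (is.null(record$age_years) || is.na(record$age_years) ||
      record$age_years < 18) {
    stop(sprintf("patient %s: age must be >= 18 years", record$id),
         call. = FALSE)
  }
  if (is.null(record$n_fractions) || is.na(record$n_fractions)) {
    if (is.null(record$site) || !record$site %in% names(site_default_fractions)) {
      stop(sprintf("patient %s: n_fractions unset and site unknown", record$id),
           call. = FALSE)
    }
    record$n_fractions <- site_default_fractions[[record$site]]
  }
  record
}

# Read a patient's inputs once and evaluate per-ROI metrics under each
# protocol. The mask and treatment DVH work is shared across protocols.
patient_metrics <- function(record, protocols, config) {
  record <- normalize_record(record)
  ss <- read_rtstruct(record$structure_path, name_map = config$name_map)
  img <- read_rtdose(record$imaging_dose_path)
  treat <- NULL
  if (config$mode == "total") {
    treat <- read_rtdose(record$treatment_dose_path)
    if (!same_lattice(img, treat)) img <- resample_to(img, treat)
  }
  lattice_grid <- if (is.null(treat)) img else treat

  roi_names <- names(ss$rois)
  skipped <- character(0)
  if (identical(record$site, "breast") &&
      (is.null(record$laterality) || is.na(record$laterality))) {
    lat_rois <- grep("_(IPSI|CNTR)$", roi_names, value = TRUE)
    if (length(lat_rois)) {
      warning(sprintf(
        "patient %s: laterality missing; skipping lateralized ROI(s) %s",
        record$id, paste(lat_rois, collapse = ", ")))
      skipped <- c(skipped, lat_rois)
      roi_names <- setdiff(roi_names, lat_rois)
    }
  }

  rows <- list()
  for (roi in roi_names) {
    pars <- registry_lookup(config$registry, roi)
    if (is.null(pars)) {
      warning(sprintf("patient %s: organ for ROI '%s' not in registry; skipped",
                      record$id, roi))
      skipped <- c(skipped, roi)
      next
    }
    mask <- rasterize(ss, roi, lattice_grid)
    for (proto in protocols) {
      proto_p <- proto
      proto_p$n_fractions <- as.integer(record$n_fractions)
      total <- accumulate_course(treat, img, proto_p,
                                 reference_mu = config$reference_mu)
      dvh <- compute_ddvh(total, mask, bin_width = config$bin_width)
      oed_gy <- oed(dvh, pars$ear$alpha_prime)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = record$id, age_years = as.integer(record$age_years),
        site = record$site %||% NA_character_,
        roi = roi, protocol = proto$label,
        mean_dose_gy = dvh$mean_dose_exact,
        ntcp_pct = 100 * ntcp_from_dvh(dvh, pars$ntcp),
        oed_gy = oed_gy,
        ear_per_10k_py = ear(oed_gy, record$age_years, pars$ear,
                             # attained age must exceed age at exposure;
                             # lift it for patients older than the fixed value
                             attained_age = max(config$attained_age,
                                                record$age_years + 1),
                             gy_per_sv = config$gy_per_sv)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped_rois") <- unique(skipped)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the full per-patient pipeline under one protocol
#'
#' Accumulates course dose (treatment + MU-scaled imaging, or imaging only),
#' rasterizes every contoured ROI, computes its differential DVH, and derives
#' mean dose, NTCP (per the organ's registered model), OED and EAR. ROIs whose
#' organ is absent from the registry are skipped with a warning and listed in
#' the `skipped_rois` attribute; the run continues.
#'
#' @param record one manifest row (list or one-row data frame): `id`,
#'   `age_years`, `sex`, `site`, `laterality`, `n_fractions`,
#'   `structure_path`, `treatment_dose_path`, `imaging_dose_path`.
#' @param protocol a [protocol_spec()]; its `n_fractions` is overridden by the
#'   record's when present.
#' @param config a [run_config()].
#' @return tibble with one row per ROI: `id`, `age_years`, `site`, `roi`,
#'   `protocol`, `mean_dose_gy`, `ntcp_pct` (percent), `oed_gy`,
#'   `ear_per_10k_py`.
#' @export
run_patient <- function(record, protocol, config = run_config()) {
  stopifnot(inherits(protocol, "protocol_spec"))
  patient_metrics(record, list(protocol), config)
}

#' Compare two imaging protocols across a cohort
#'
#' Runs every patient under both protocols, then per ROI and metric (mean
#' dose, NTCP, EAR) computes protocol-wise mean +/- SD and a two-tailed paired
#' t-test, with significance at p < 0.05. Pairing is per patient: a patient
#' contributes to a comparison only if both protocols were evaluable. A
#' degenerate comparison (all paired differences exactly zero) reports p = 1
#' with `degenerate = TRUE` rather than failing. Patients whose files cannot
#' be processed are dropped with a warning.
#'
#' @param manifest cohort manifest: tibble/data.frame, or path to the CSV.
#' @param protocol_a,protocol_b the two [protocol_spec()]s (e.g. 5 and 10 MU).
#' @param config a [run_config()].
#' @return a `cohort_report`: list of tibbles `per_patient`, `summaries`,
#'   `comparisons`, `strata` (filled by [stratify_by_age()]) plus `meta`.
#' @export
compare_protocols <- function(manifest, protocol_a, protocol_b,
                              config = run_config()) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  manifest <- tibble::as_tibble(manifest)
  stopifnot(nrow(manifest) >= 1,
            inherits(protocol_a, "protocol_spec"),
            inherits(protocol_b, "protocol_spec"))
  protocols <- list(protocol_a, protocol_b)
  labels <- c(protocol_a$label, protocol_b$label)
  if (labels[1] == labels[2]) stop("protocol labels must differ", call. = FALSE)

  failed <- character(0)
  per_patient <- dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    tryCatch(patient_metrics(rec, protocols, config),
             error = function(e) {
               warning(sprintf("patient %s failed: %s", rec$id,
                               conditionMessage(e)))
               failed <<- c(failed, rec$id)
               NULL
             })
  }))
  if (!nrow(per_patient)) stop("no patient could be evaluated", call. = FALSE)

  long <- tidyr::pivot_longer(per_patient,
                              cols = c("mean_dose_gy", "ntcp_pct",
                                       "ear_per_10k_py", "oed_gy"),
                              names_to = "metric", values_to = "value")
  summaries <- long |>
    dplyr::group_by(.data$roi, .data$protocol, .data$metric) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")

  comparisons <- long |>
    dplyr::filter(.data$metric != "oed_gy") |>
    tidyr::pivot_wider(id_cols = c("id", "roi", "metric"),
                       names_from = "protocol", values_from = "value") |>
    dplyr::group_by(.data$roi, .data$metric) |>
    dplyr::group_modify(~ paired_test(.x[[labels[1]]], .x[[labels[2]]])) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_value < 0.05)

  report <- structure(
    list(per_patient = per_patient, summaries = summaries,
         comparisons = comparisons, strata = NULL,
         meta = list(protocols = labels, alpha = 0.05,
                     n_patients = length(unique(per_patient$id)),
                     n_failed = length(failed), failed_ids = failed,
                     mode = config$mode,
                     reference_mu = config$reference_mu,
                     test = "two-tailed paired t-test",
                     multiple_testing = "none (raw per-ROI p-values)")),
    class = "cohort_report"
  )
  report$strata <- stratify_by_age(report)
  report
}

# Two-tailed paired t-test on complete pairs; returns a one-row tibble.
paired_test <- function(a, b) {
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) {
    warning("fewer than 2 complete pairs; statistics skipped")
    return(tibble::tibble(n = n, mean_diff = NA_real_, t = NA_real_,
                          p_value = NA_real_, degenerate = NA,
                          test = "paired t-test"))
  }
  d <- b - a
  if (all(d == 0)) {
    return(tibble::tibble(n = n, mean_diff = 0, t = NA_real_, p_value = 1,
                          degenerate = TRUE, test = "paired t-test"))
  }
  if (stats::sd(d) == 0) {
    # nonzero but constant differences: the t statistic diverges
    return(tibble::tibble(n = n, mean_diff = mean(d),
                          t = sign(mean(d)) * Inf, p_value = 0,
                          degenerate = TRUE, test = "paired t-test"))
  }
  ht <- stats::t.test(b, a, paired = TRUE, alternative = "two.sided")
  tibble::tibble(n = n, mean_diff = mean(d), t = unname(ht$statistic),
                 p_value = ht$p.value, degenerate = FALSE,
                 test = "paired t-test")
}

#' Age-stratified EAR summaries
#'
#' Groups patients into the three age strata `< 40`, `40-60` (both boundaries
#' inclusive in the middle group) and `> 60` years and summarises EAR per ROI,
#' protocol and stratum as mean +/- SD. Empty strata are kept with count 0 and
#' `NA` summaries.
#'
#' @param report a `cohort_report`, or a per-patient metrics tibble carrying
#'   `age_years` and `ear_per_10k_py`.
#' @param breaks the two stratum boundaries in years, default `c(40, 60)`.
#' @return tibble: `age_group`, `roi`, `protocol`, `n`, `mean_ear`, `sd_ear`.
#' @export
stratify_by_age <- function(report, breaks = c(40, 60)) {
  pp <- if (inherits(report, "cohort_report")) report$per_patient else report
  stopifnot(all(c("age_years", "ear_per_10k_py", "roi", "protocol") %in%
                  names(pp)))
  if (anyNA(pp$age_years)) stop("ages must be present for all patients")
  labels <- c(sprintf("<%d", breaks[1]),
              sprintf("%d-%d", breaks[1], breaks[2]),
              sprintf(">%d", breaks[2]))
  grp <- ifelse(pp$age_years < breaks[1], labels[1],
                ifelse(pp$age_years <= breaks[2], labels[2], labels[3]))
  pp$age_group <- factor(grp, levels = labels)
  pp |>
    dplyr::group_by(.data$age_group, .data$roi, .data$protocol,
                    .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ear = ifelse(dplyr::n() > 0, mean(.data$ear_per_10k_py), NA_real_),
      sd_ear = ifelse(dplyr::n() > 1, stats::sd(.data$ear_per_10k_py),
                      NA_real_),
      .groups = "drop")
}

#' One-parameter sensitivity sweep of the per-patient pipeline
#'
#' Re-evaluates one patient's metrics for each value of a single
#' radiobiological parameter, all else fixed: `alpha_prime`, `gamma_e`,
#' `gamma_a`, `ear0` (EAR side) or `d50`, `gamma` (logistic NTCP side). The
#' override applies to every organ in the registry. Risk-coefficient
#' uncertainty of a factor of a few is typical of these models, so sweeps over
#' such ranges show the induced spread directly.
#'
#' @param record one manifest row.
#' @param parameter parameter name (see above).
#' @param values numeric vector of parameter values to evaluate.
#' @param protocol a [protocol_spec()].
#' @param config a [run_config()].
#' @return tibble: `parameter`, `value`, plus the [run_patient()] columns.
#' @export
sensitivity_sweep <- function(record, parameter, values, protocol,
                              config = run_config()) {
  allowed <- c("alpha_prime", "gamma_e", "gamma_a", "ear0", "d50", "gamma")
  if (!parameter %in% allowed) {
    stop(sprintf("unknown parameter '%s' (one of %s)", parameter,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  dplyr::bind_rows(lapply(values, function(v) {
    cfg <- config
    cfg$registry$organs <- lapply(config$registry$organs, function(org) {
      if (parameter %in% c("alpha_prime", "gamma_e", "gamma_a", "ear0")) {
        org$ear[[parameter]] <- v
      } else {
        if (org$ntcp$model == "logistic" || parameter == "d50") {
          org$ntcp[[parameter]] <- v
        }
      }
      org
    })
    out <- run_patient(record, protocol, cfg)
    dplyr::bind_cols(tibble::tibble(parameter = parameter,
                                    value = rep(v, nrow(out))), out)
  }))
}

#' @export
print.cohort_report <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<cohort_report> %d patient(s), protocols %s vs %s (%s mode)\n",
              m$n_patients, m$protocols[1], m$protocols[2], m$mode))
  sig <- sum(x$comparisons$significant, na.rm = TRUE)
  cat(sprintf("  %d ROI(s); %d of %d comparisons significant at p < %.2f\n",
              length(unique(x$per_patient$roi)), sig, nrow(x$comparisons),
              m$alpha))
  invisible(x)
}

#' Tidy a cohort report
#'
#' @param x a `cohort_report`.
#' @param type which table: `"comparisons"` (default), `"per_patient"`,
#'   `"summaries"` or `"strata"`.
#' @param ... unused.
#' @return the requested tibble.
#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, type = c("comparisons", "per_patient",
                                           "summaries", "strata"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' One-row summary of a cohort report
#'
#' @param x a `cohort_report`.
#' @param ... unused.
#' @return one-row tibble: patient/ROI counts, protocols, number of
#'   significant comparisons.
#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  tibble::tibble(
    n_patients = x$meta$n_patients,
    n_failed = x$meta$n_failed,
    n_rois = length(unique(x$per_patient$roi)),
    protocol_a = x$meta$protocols[1],
    protocol_b = x$meta$protocols[2],
    n_comparisons = nrow(x$comparisons),
    n_significant = sum(x$comparisons$significant, na.rm = TRUE),
    alpha = x$meta$alpha
  )
}

#' Boxplots of a cohort metric by ROI and protocol
#'
#' @param object a `cohort_report`.
#' @param metric `"mean_dose_gy"`, `"ntcp_pct"`, `"oed_gy"` or
#'   `"ear_per_10k_py"`.
#' @param log_scale log10 y-axis (zero values are dropped with a message,
#'   mirroring log-scale risk plots).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, metric = "ear_per_10k_py",
                                   log_scale = FALSE, ...) {
  df <- object$per_patient
  stopifnot(metric %in% names(df))
  if (log_scale) {
    drop <- df[[metric]] <= 0
    if (any(drop)) {
      message(sprintf("dropping %d non-positive value(s) from log-scale plot",
                      sum(drop)))
      df <- df[!drop, ]
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$roi, .data[[metric]],
                                        fill = .data$protocol)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Export a cohort report to CSV tables, a JSON run manifest and plots
#'
#' Writes `per_patient.csv`, `summary.csv`, `comparisons.csv`, `strata.csv`
#' and `run_manifest.json` (protocols, mode, counts, registry provenance);
#' with `plots = TRUE` also linear- and log-scale boxplots per metric (PNG).
#' Identical reports produce byte-identical CSV output.
#'
#' @param report a `cohort_report`.
#' @param out_dir output directory (created if needed).
#' @param plots write boxplot PNGs as well.
#' @param registry optional `param_registry` whose sources are recorded in the
#'   manifest.
#' @return character vector of written file paths, invisibly.
#' @export
export_report <- function(report, out_dir, plots = FALSE, registry = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot write to %s", out_dir))
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$per_patient, "per_patient.csv")
  wr(report$summaries, "summary.csv")
  wr(report$comparisons, "comparisons.csv")
  strata <- report$strata %||% stratify_by_age(report)
  wr(strata, "strata.csv")

  manifest <- list(
    meta = report$meta,
    registry_sources = if (!is.null(registry)) {
      lapply(registry$organs, function(o) list(ntcp = o$ntcp$source,
                                               ear = o$ear$source))
    } else NULL
  )
  mp <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, mp)

  if (plots) {
    for (metric in c("mean_dose_gy", "ntcp_pct", "ear_per_10k_py")) {
      for (lg in c(FALSE, TRUE)) {
        p <- autoplot.cohort_report(report, metric = metric, log_scale = lg)
        fp <- file.path(out_dir, sprintf("boxplot_%s%s.png", metric,
                                         if (lg) "_log" else ""))
        suppressMessages(ggplot2::ggsave(fp, p, width = 7, height = 4.5,
                                         dpi = 120))
        paths <- c(paths, fp)
      }
    }
  }
  invisible(paths)
}
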