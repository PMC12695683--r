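#' Load the radiobiological parameter registry
#'
#' The registry maps canonical organ names to NTCP and EAR parameter records.
#' The package ships a default registry (JSON, every entry carrying a literature
#' citation) covering the ten organs at risk the pipeline analyses: breast,
#' lung, heart, rectum, bladder, bowel, parotid, spinal cord, brainstem and
#' optic nerve. A user file (JSON or YAML with the same schema) is merged over
#' the defaults field by field, so a partial override file is enough to swap a
#' single coefficient.
#'
#' Schema: top-level `organs`, one entry per organ with sub-records `ntcp`
#' (`model` = `"logistic"` with `gamma` in 1/Gy or `gamma50`, or `"lkb"` with
#' `m`, `n`; plus `d50` and `source`) and `ear` (`ear0`, `alpha_prime`,
#' `gamma_e`, `gamma_a`, `e0`, `a0`, `source`). `source` is mandatory
#' everywhere.
#'
#' @param path optional path to an override registry (JSON or YAML); `NULL`
#'   loads the shipped defaults only.
#' @param base registry to merge the override into; defaults to the shipped
#'   file. Pass `NA` to load `path` standalone.
#' @return a `param_registry`: named list `organs`, each element holding
#'   `$ntcp` ([ntcp_params()]) and `$ear` ([ear_params()]).
#' @export
load_parameter_registry <- function(path = NULL, base = NULL) {
  default_path <- system.file("extdata", "parameter_registry.json",
                              package = "rtimagerisk")
  raw <- if (is.null(base)) read_registry_file(default_path)
         else if (identical(base, NA)) list(organs = list())
         else stop("`base` must be NULL or NA", call. = FALSE)
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("registry file not found: %s", path), call. = FALSE)
    }
    over <- read_registry_file(path)
    raw$organs <- merge_registry(raw$organs, over$organs)
  }
  organs <- lapply(names(raw$organs), function(org) {
    rec <- raw$organs[[org]]
    list(ntcp = parse_ntcp_entry(org, rec$ntcp),
         ear = parse_ear_entry(org, rec$ear))
  })
  names(organs) <- names(raw$organs)
  structure(list(organs = organs), class = "param_registry")
}

read_registry_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
}

merge_registry <- function(base, over) {
  for (org in names(over)) {
    if (is.null(base[[org]])) {
      base[[org]] <- over[[org]]
    } else {
      for (block in names(over[[org]])) {
        for (field in names(over[[org]][[block]])) {
          base[[org]][[block]][[field]] <- over[[org]][[block]][[field]]
        }
      }
    }
  }
  base
}

field_or <- function(rec, name, default = NA_real_) {
  if (is.null(rec[[name]])) default else rec[[name]]
}

parse_ntcp_entry <- function(organ, rec) {
  if (is.null(rec)) {
    stop(sprintf("registry entry for organ '%s' lacks the 'ntcp' block", organ),
         call. = FALSE)
  }
  for (f in c("model", "d50", "source")) {
    if (is.null(rec[[f]])) {
      stop(sprintf("registry organ '%s': missing mandatory NTCP field '%s'",
                   organ, f), call. = FALSE)
    }
  }
  gamma <- field_or(rec, "gamma")
  if (!is.finite(gamma) && !is.null(rec$gamma50)) {
    gamma <- gamma50_to_gamma(rec$gamma50, rec$d50)
  }
  ntcp_params(organ, model = rec$model, d50 = rec$d50, gamma = gamma,
              m = field_or(rec, "m"), n = field_or(rec, "n"),
              source = rec$source)
}

parse_ear_entry <- function(organ, rec) {
  if (is.null(rec)) {
    stop(sprintf("registry entry for organ '%s' lacks the 'ear' block", organ),
         call. = FALSE)
  }
  for (f in c("ear0", "source")) {
    if (is.null(rec[[f]])) {
      stop(sprintf("registry organ '%s': missing mandatory EAR field '%s'",
                   organ, f), call. = FALSE)
    }
  }
  ear_params(organ, ear0 = rec$ear0,
             alpha_prime = field_or(rec, "alpha_prime", 0.085),
             gamma_e = field_or(rec, "gamma_e", 0),
             gamma_a = field_or(rec, "gamma_a", 0),
             e0 = field_or(rec, "e0", 30), a0 = field_or(rec, "a0", 70),
             source = rec$source)
}

#' @export
print.param_registry <- function(x, ...) {
  cat(sprintf("<param_registry> %d organ(s): %s\n", length(x$organs),
              paste(names(x$organs), collapse = ", ")))
  invisible(x)
}

#' Map a canonical ROI name to its registry organ
#'
#' Strips laterality suffixes (`_IPSI`, `_CNTR`, `_L`, `_R`) and normalizes
#' case and separators, e.g. `"Lung_IPSI"` -> `"lung"`, `"Bowel_Bag"` ->
#' `"bowel"`, `"SpinalCord"` -> `"spinal_cord"`, `"OpticNerve_L"` ->
#' `"optic_nerve"`.
#'
#' @param roi canonical ROI name(s).
#' @return registry organ key(s), lower case.
#' @export
organ_for_roi <- function(roi) {
  x <- sub("(?i)_(IPSI|CNTR|L|R|LEFT|RIGHT)$", "", roi, perl = TRUE)
  x <- gsub("([a-z])([A-Z])", "\\1_\\2", x)  # CamelCase -> snake
  x <- tolower(x)
  x[x == "bowel_bag"] <- "bowel"
  x
}

#' Look up an organ's parameters, by organ key or ROI name
#'
#' @param registry a `param_registry`.
#' @param roi ROI or organ name; mapped through [organ_for_roi()] when not a
#'   direct organ key.
#' @return list with `$ntcp` and `$ear`, or `NULL` if the organ is absent.
#' @export
registry_lookup <- function(registry, roi) {
  stopifnot(inherits(registry, "param_registry"))
  key <- if (roi %in% names(registry$organs)) roi else organ_for_roi(roi)
  registry$organs[[key]]
}

#' Evaluate NTCP from a DVH under an organ's registered model
#'
#' Logistic organs use the voxel-exact mean dose carried by the DVH (falling
#' back to the bin-midpoint mean); LKB organs use the gEUD with the registered
#' volume exponent.
#'
#' @param dvh a `differential_dvh`.
#' @param params an `ntcp_params` record.
#' @return probability in `[0, 1]`.
#' @export
ntcp_from_dvh <- function(dvh, params) {
  stopifnot(inherits(params, "ntcp_params"))
  if (params$model == "logistic") {
    d <- if (is.finite(dvh$mean_dose_exact)) dvh$mean_dose_exact
         else mean_dose(dvh)
    ntcp_logistic(d, params$d50, params$gamma)
  } else {
    ntcp_lkb(geud(dvh, params$n), params$d50, params$m)
  }
}
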