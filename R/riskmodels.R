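#' Logistic NTCP dose-response
#'
#' Normal tissue complication probability under the logistic model
#' `NTCP = 1 / (1 + exp(gamma * (d50 - dose)))`, evaluated on the organ mean
#' dose. `gamma` here is the raw slope in 1/Gy; published tables usually
#' report the normalized slope gamma50 instead — convert with
#' [gamma50_to_gamma()]. The expit is evaluated through `plogis()`, which is
#' numerically stable for large `|gamma * (d50 - dose)|` (tails underflow
#' gracefully to 0 or 1).
#'
#' @param dose mean organ dose in Gy (vectorized); must be `>= 0`.
#' @param d50 dose giving 50% complication probability, Gy.
#' @param gamma slope in 1/Gy; `> 0`.
#' @return probability in `[0, 1]`, strictly increasing in `dose` with
#'   `ntcp_logistic(d50, d50, gamma) == 0.5` exactly.
#' @export
ntcp_logistic <- function(dose, d50, gamma) {
  stopifnot(d50 > 0, gamma > 0)
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  stats::plogis(gamma * (dose - d50))
}

#' Convert a normalized logistic slope gamma50 to the raw slope
#'
#' Literature dose-response tables usually quote the normalized slope
#' `gamma50` (change in NTCP per relative change in dose at D50). For the
#' logistic model the raw slope is `gamma = 4 * gamma50 / d50` (1/Gy).
#'
#' @param gamma50 normalized slope, unitless.
#' @param d50 Gy.
#' @return raw slope in 1/Gy.
#' @export
gamma50_to_gamma <- function(gamma50, d50) {
  stopifnot(d50 > 0)
  4 * gamma50 / d50
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' `gEUD = (sum_i v_i * D_i^(1/n))^n` over the bin midpoints of a
#' differential DVH. `n` is the volume-effect exponent: `n = 1` recovers the
#' mean dose (parallel organ); `n -> 0` approaches the maximum dose (serial
#' organ).
#'
#' @param dvh a `differential_dvh`.
#' @param n volume-effect exponent, `0 < n <= 1` in LKB usage (any `n > 0`
#'   accepted).
#' @return equivalent uniform dose in Gy.
#' @export
geud <- function(dvh, n) {
  validate_ddvh(dvh)
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("n must be a single positive number", call. = FALSE)
  }
  d <- dvh_doses(dvh)
  v <- dvh$volume_fraction
  if (n == 1) return(sum(v * d))
  sum(v * d^(1 / n))^n
}

#' LKB (probit) NTCP
#'
#' Lyman-Kutcher-Burman complication probability
#' `NTCP = Phi((eud - d50) / (m * d50))` with `Phi` the standard normal CDF.
#' The dose summary `eud` is normally the gEUD computed with the organ's
#' volume exponent `n` (see [geud()]).
#'
#' @param eud equivalent uniform dose in Gy (vectorized).
#' @param d50 Gy; `m` unitless slope, `> 0`.
#' @param m slope parameter.
#' @return probability in `[0, 1]`.
#' @export
ntcp_lkb <- function(eud, d50, m) {
  stopifnot(d50 > 0)
  if (!is.numeric(m) || length(m) != 1L || m <= 0) {
    stop("m must be a single positive number", call. = FALSE)
  }
  stats::pnorm((eud - d50) / (m * d50))
}

#' Organ equivalent dose (OED), linear-exponential model
#'
#' Schneider's carcinogenesis dose summary
#' `OED = sum_i v_i * D_i * exp(-alpha_prime * D_i)` over the representative
#' bin doses of a differential DVH (the volume fractions `v_i` absorb the
#' `1/V` normalization). `alpha_prime` is the cell-sterilization parameter in 1/Gy;
#' at `alpha_prime = 0` the OED equals the mean dose, and for any
#' `alpha_prime >= 0` the OED never exceeds the mean dose.
#'
#' @param dvh a `differential_dvh`.
#' @param alpha_prime cell-sterilization parameter in 1/Gy, `>= 0`
#'   (default 0.085).
#' @return OED in Gy.
#' @export
oed <- function(dvh, alpha_prime = 0.085) {
  validate_ddvh(dvh)
  if (!is.numeric(alpha_prime) || length(alpha_prime) != 1L || alpha_prime < 0) {
    stop("alpha_prime must be a single number >= 0", call. = FALSE)
  }
  d <- dvh_doses(dvh)
  sum(dvh$volume_fraction * d * exp(-alpha_prime * d))
}

#' Age-modification factor for excess absolute risk
#'
#' `mu(e, a) = exp(gamma_e * (e - e0)) * (a / a0)^gamma_a`, with `e` the age
#' at exposure and `a` the attained age (years). Normalized to 1 at the
#' reference ages `(e0, a0)`; with the usual `gamma_e < 0` the factor — and
#' hence the risk — decreases with age at exposure.
#'
#' @param e age at exposure in years; must satisfy `0 < e < a`.
#' @param a attained age in years.
#' @param gamma_e age-at-exposure coefficient per year.
#' @param gamma_a attained-age exponent.
#' @param e0,a0 reference ages (years), default 30 and 70.
#' @return unitless modifier, `> 0`.
#' @export
mu_age <- function(e, a, gamma_e, gamma_a, e0 = 30, a0 = 70) {
  stopifnot(a0 > 0)
  if (any(e <= 0) || any(e >= a)) {
    stop("require 0 < age at exposure < attained age", call. = FALSE)
  }
  exp(gamma_e * (e - e0)) * (a / a0)^gamma_a
}

#' Excess absolute risk (EAR) of radiation-induced secondary cancer
#'
#' `EAR = ear0 * OED * mu(e, a)` in additional cancer cases per 10 000
#' person-years: linear in the organ equivalent dose and in the baseline risk
#' coefficient, modified by age at exposure and attained age. Photon dose in
#' Gy is taken as equivalent dose in Sv with a radiation weighting factor of 1
#' (configurable via `gy_per_sv`).
#'
#' @param oed_gy organ equivalent dose in Gy, `>= 0` (vectorized).
#' @param age_at_exposure years.
#' @param params an `ear_params` record (see [ear_params()]).
#' @param attained_age years; default 70.
#' @param gy_per_sv dose-to-equivalent-dose factor; default 1 for photons.
#' @return EAR in cases per 10 000 person-years.
#' @export
ear <- function(oed_gy, age_at_exposure, params, attained_age = 70,
                gy_per_sv = 1) {
  stopifnot(inherits(params, "ear_params"))
  if (any(oed_gy < 0)) stop("OED must be >= 0", call. = FALSE)
  mu <- mu_age(age_at_exposure, attained_age, params$gamma_e, params$gamma_a,
               params$e0, params$a0)
  params$ear0 * (oed_gy / gy_per_sv) * mu
}

#' NTCP parameter record
#'
#' @param organ canonical organ name.
#' @param model `"logistic"` or `"lkb"`.
#' @param d50 Gy; `> 0`.
#' @param gamma raw logistic slope in 1/Gy (logistic model).
#' @param m,n LKB slope and volume exponent (lkb model).
#' @param source literature citation (mandatory, non-empty).
#' @return an `ntcp_params` record.
#' @export
ntcp_params <- function(organ, model = c("logistic", "lkb"), d50,
                        gamma = NA_real_, m = NA_real_, n = NA_real_,
                        source) {
  model <- match.arg(model)
  if (missing(source) || !nzchar(source)) {
    stop(sprintf("organ '%s': NTCP parameters need a non-empty source citation",
                 organ), call. = FALSE)
  }
  if (!is.numeric(d50) || d50 <= 0) {
    stop(sprintf("organ '%s': d50 must be > 0", organ), call. = FALSE)
  }
  if (model == "logistic" && (!is.finite(gamma) || gamma <= 0)) {
    stop(sprintf("organ '%s': logistic model needs gamma > 0", organ),
         call. = FALSE)
  }
  if (model == "lkb" && (!is.finite(m) || m <= 0 || !is.finite(n) ||
                         n <= 0 || n > 1)) {
    stop(sprintf("organ '%s': lkb model needs m > 0 and 0 < n <= 1", organ),
         call. = FALSE)
  }
  structure(list(organ = organ, model = model, d50 = as.double(d50),
                 gamma = as.double(gamma), m = as.double(m), n = as.double(n),
                 source = source),
            class = "ntcp_params")
}

#' EAR parameter record
#'
#' @param organ canonical organ name.
#' @param ear0 baseline excess absolute risk, cases per 10 000 person-years
#'   per Sv; `>= 0`.
#' @param alpha_prime cell-sterilization parameter, 1/Gy; `>= 0`.
#' @param gamma_e age-at-exposure coefficient per year.
#' @param gamma_a attained-age exponent.
#' @param e0,a0 reference ages in years.
#' @param source literature citation (mandatory, non-empty).
#' @return an `ear_params` record.
#' @export
ear_params <- function(organ, ear0, alpha_prime = 0.085, gamma_e = 0,
                       gamma_a = 0, e0 = 30, a0 = 70, source) {
  if (missing(source) || !nzchar(source)) {
    stop(sprintf("organ '%s': EAR parameters need a non-empty source citation",
                 organ), call. = FALSE)
  }
  if (!is.numeric(ear0) || ear0 < 0) {
    stop(sprintf("organ '%s': ear0 must be >= 0", organ), call. = FALSE)
  }
  if (!is.numeric(alpha_prime) || alpha_prime < 0) {
    stop(sprintf("organ '%s': alpha_prime must be >= 0", organ), call. = FALSE)
  }
  if (a0 <= 0) stop(sprintf("organ '%s': a0 must be > 0", organ), call. = FALSE)
  structure(list(organ = organ, ear0 = as.double(ear0),
                 alpha_prime = as.double(alpha_prime),
                 gamma_e = as.double(gamma_e), gamma_a = as.double(gamma_a),
                 e0 = as.double(e0), a0 = as.double(a0), source = source),
            class = "ear_params")
}
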