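#' Log-linear slope from a relative risk per 10 ug m-3
#'
#' The log-linear exposure-response family is `RR(dC) = exp(beta * dC)`
#' with `beta = log(rr_per_10) / 10` per ug m-3, so `exp(10 * beta)`
#' recovers the headline RR exactly.
#'
#' @param rr_per_10 Relative risk per 10 ug m-3 (> 0).
#' @return Slope beta per ug m-3.
#' @examples
#' beta_from_rr(1.06)
#' @export
beta_from_rr <- function(rr_per_10) {
  if (any(rr_per_10 <= 0)) abort("relative risk must be > 0", class = "aqhia_domain_error")
  log(rr_per_10) / 10
}

#' Log-linear exposure-response function
#'
#' Parameterized by a cohort study's relative risk per 10 ug m-3 of annual
#' PM2.5 with its 95% CI. The numeric defaults used by the pipeline (see
#' [default_erfs()]) are taken from the cited cohort literature and are
#' configuration values, not outputs of this package.
#'
#' @param rr_per_10 Central relative risk per 10 ug m-3.
#' @param ci Length-2 vector `(lo, hi)` of the 95% CI on `rr_per_10`, or
#'   `NULL` when unavailable.
#' @param label Display label.
#' @param endpoint `"all-cause"` or `"non-accidental"` mortality.
#' @param age_band Age band the function applies to.
#' @return An object of class `c("loglinear_erf", "erf")`.
#' @export
loglinear_erf <- function(rr_per_10, ci = NULL, label = "log-linear",
                          endpoint = c("all-cause", "non-accidental"),
                          age_band = "30_99") {
  endpoint <- match.arg(endpoint)
  if (rr_per_10 <= 0) abort("rr_per_10 must be > 0", class = "aqhia_domain_error")
  if (!is.null(ci)) {
    if (length(ci) != 2 || any(ci <= 0)) abort("ci must be positive (lo, hi)")
    if (!(ci[1] <= rr_per_10 && rr_per_10 <= ci[2])) {
      abort("ci must bracket the central rr: lo <= central <= hi")
    }
  }
  structure(list(rr_per_10 = rr_per_10, ci = ci, beta = beta_from_rr(rr_per_10),
                 label = label, endpoint = endpoint, age_band = age_band),
            class = c("loglinear_erf", "erf"))
}

#' GEMM-form exposure-response function
#'
#' The Global Exposure Mortality Model hazard-ratio form:
#' `RR(z) = exp(theta * log(1 + z / alpha) * omega(z))` with logistic weight
#' `omega(z) = 1 / (1 + exp(-(z - mu) / nu))` and `z = max(0, c - c0)`,
#' where `c0` is the counterfactual concentration below which risk is null
#' (default 2.4 ug m-3, the source convention). Defaults are the published
#' adult all-age non-accidental parameters and are configuration values.
#'
#' @param theta Log-hazard coefficient.
#' @param se Standard error of `theta` (for CI propagation).
#' @param alpha,mu,nu Shape parameters, ug m-3 (`alpha`, `nu` > 0).
#' @param c0 Counterfactual concentration, ug m-3 (>= 0).
#' @param label Display label.
#' @param endpoint,age_band As for [loglinear_erf()].
#' @return An object of class `c("gemm_erf", "erf")`.
#' @export
gemm_erf <- function(theta = 0.143, se = 0.01807, alpha = 1.6, mu = 15.5,
                     nu = 36.8, c0 = 2.4, label = "GEMM",
                     endpoint = c("non-accidental", "all-cause"),
                     age_band = "25_99") {
  endpoint <- match.arg(endpoint)
  if (alpha <= 0 || nu <= 0) abort("alpha and nu must be > 0")
  if (c0 < 0) abort("c0 must be >= 0")
  structure(list(theta = theta, se = se, alpha = alpha, mu = mu, nu = nu,
                 c0 = c0, label = label, endpoint = endpoint,
                 age_band = age_band),
            class = c("gemm_erf", "erf"))
}

#' Relative risk under a GEMM-form function
#'
#' Vectorized in `c`; returns exactly 1 at and below the counterfactual and
#' is monotone non-decreasing in concentration.
#'
#' @param c Annual PM2.5 concentration(s), ug m-3 (>= 0).
#' @param erf A [gemm_erf()].
#' @param theta Optional override of the log-hazard coefficient (used for
#'   CI propagation).
#' @return Relative risk(s).
#' @examples
#' gemm_rr(71.04, gemm_erf()) # about 1.549
#' @export
gemm_rr <- function(c, erf, theta = erf$theta) {
  stopifnot(inherits(erf, "gemm_erf"))
  if (any(c < 0)) abort("concentration must be >= 0")
  z <- pmax(0, c - erf$c0)
  omega <- 1 / (1 + exp(-(z - erf$mu) / erf$nu))
  exp(theta * log(1 + z / erf$alpha) * omega)
}

#' Default exposure-response function set
#'
#' The three functions used in the scenario comparison: two all-cause
#' log-linear cohort ERFs (ages 30-99) and the GEMM non-accidental form
#' (ages 25-99). All parameter values come from the cited cohort
#' literature; none are estimated by this package, and each can be
#' overridden through the pipeline configuration.
#'
#' @return Named list of ERF objects (`pope`, `turner`, `burnett`).
#' @export
default_erfs <- function() {
  list(
    # American Cancer Society CPS-II style all-cause RR per 10 ug m-3
    pope = loglinear_erf(1.06, ci = c(1.02, 1.11), label = "Pope",
                         endpoint = "all-cause", age_band = "30_99"),
    turner = loglinear_erf(1.06, ci = c(1.04, 1.08), label = "Turner",
                           endpoint = "all-cause", age_band = "30_99"),
    burnett = gemm_erf(label = "Burnett (GEMM)")
  )
}
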