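#' Baseline mortality rate
#'
#' @param rate Deaths per 100 000 per year (>= 0).
#' @param age_band Age band the rate applies to.
#' @return An object of class `baseline_mortality`.
#' @export
baseline_mortality <- function(rate = 684.21, age_band = "30_99") {
  if (rate < 0) abort("baseline rate must be >= 0")
  structure(list(rate = rate, age_band = age_band),
            class = "baseline_mortality")
}

#' Attributable deaths under a log-linear ERF (aggregate form)
#'
#' `(y0 / 1e5) * pop * (1 - exp(-beta * dC))`: the attributable-fraction
#' form used for a single exposed population and a single concentration
#' change. Negative changes yield negative (avoided) deaths.
#'
#' @param y0 A [baseline_mortality()] (deaths per 100 000 per year).
#' @param pop Exposed persons in the ERF's age band.
#' @param delta_c Concentration change, scenario minus reference (ug m-3).
#' @param erf A [loglinear_erf()].
#' @param beta Optional slope override (CI propagation).
#' @return Attributable deaths (vectorized over `delta_c`/`pop`).
#' @export
attributable_deaths_loglinear <- function(y0, pop, delta_c, erf,
                                          beta = erf$beta) {
  stopifnot(inherits(y0, "baseline_mortality"), inherits(erf, "loglinear_erf"))
  if (any(pop < 0)) abort("population must be >= 0")
  (y0$rate / 1e5) * pop * (1 - exp(-beta * delta_c))
}

#' Attributable deaths under a GEMM ERF (risk-ratio form)
#'
#' `(y0 / 1e5) * pop * (RR(c_scenario) - RR(c_reference)) / RR(c_scenario)`,
#' zero when the two concentrations are equal.
#'
#' @param y0 A [baseline_mortality()].
#' @param pop Exposed persons in the ERF's age band.
#' @param c_scenario,c_reference Annual concentrations, ug m-3.
#' @param erf A [gemm_erf()].
#' @param theta Optional coefficient override (CI propagation).
#' @return Attributable deaths (vectorized).
#' @export
attributable_deaths_rr_ratio <- function(y0, pop, c_scenario, c_reference,
                                         erf, theta = erf$theta) {
  stopifnot(inherits(y0, "baseline_mortality"), inherits(erf, "gemm_erf"))
  if (any(pop < 0)) abort("population must be >= 0")
  rr_s <- gemm_rr(c_scenario, erf, theta)
  rr_r <- gemm_rr(c_reference, erf, theta)
  (y0$rate / 1e5) * pop * (rr_s - rr_r) / rr_s
}

erf_bounds <- function(erf) {
  if (inherits(erf, "loglinear_erf")) {
    if (is.null(erf$ci)) {
      abort("ERF carries no confidence interval", class = "aqhia_missing_ci")
    }
    list(lo = beta_from_rr(erf$ci[1]), hi = beta_from_rr(erf$ci[2]))
  } else {
    if (is.null(erf$se)) {
      abort("ERF carries no standard error", class = "aqhia_missing_ci")
    }
    list(lo = erf$theta - 1.96 * erf$se, hi = erf$theta + 1.96 * erf$se)
  }
}

cell_deaths <- function(erf, y0, pop_band, c_scen, c_ref, coef) {
  if (inherits(erf, "loglinear_erf")) {
    attributable_deaths_loglinear(y0, pop_band, c_scen - c_ref, erf,
                                  beta = coef)
  } else {
    attributable_deaths_rr_ratio(y0, pop_band, c_scen, c_ref, erf,
                                 theta = coef)
  }
}

#' Cellwise health impact assessment for a scenario pair
#'
#' The core computation: per grid cell, the exposed age-band population
#' (cell total times the citywide band fraction) is combined with the
#' cell's reference and scenario annual concentrations through the
#' exposure-response function, and attributable deaths are summed over
#' cells. Confidence bounds re-run the full nonlinear computation at the
#' risk-coefficient CI endpoints (no linearization), so for an exposure
#' increase `lo <= central <= hi` and for a decrease the order reverses,
#' matching the reporting convention for avoided deaths.
#'
#' @param reference,scenario Annual surface tibbles on the same grid
#'   (reference = the baseline year, scenario = the future case).
#' @param pop Population tibble from [simulate_population()] /
#'   [grow_population()].
#' @param y0 A [baseline_mortality()]; applied to the ERF's age band (when
#'   the band differs from the rate's own band, the same rate is used --
#'   flagged in the result -- because no band-specific rate is available).
#' @param erf A [loglinear_erf()] or [gemm_erf()].
#' @param scenario_label,reference_label Labels stored on the result.
#' @return An object of class `hia_result`; see [tidy.hia_result()] and
#'   [glance.hia_result()].
#' @export
cellwise_hia <- function(reference, scenario, pop, y0 = baseline_mortality(),
                         erf, scenario_label = attr(scenario, "scenario"),
                         reference_label = attr(reference, "scenario")) {
  check_same_grid(reference, scenario)
  check_same_grid(reference, pop)
  stopifnot(inherits(erf, "erf"))

  ages <- pop_ages(pop)
  f <- band_fraction(ages, erf$age_band)
  cells <- inner_join(reference, scenario, by = c("row", "col"),
                      suffix = c("_reference", "_scenario")) %>%
    inner_join(pop, by = c("row", "col")) %>%
    mutate(pop_band = .data$persons * f)

  central_coef <- if (inherits(erf, "loglinear_erf")) erf$beta else erf$theta
  bounds <- tryCatch(erf_bounds(erf), aqhia_missing_ci = function(e) NULL)

  cells$deaths <- cell_deaths(erf, y0, cells$pop_band,
                              cells$value_scenario, cells$value_reference,
                              central_coef)
  central <- sum(cells$deaths)
  lo <- hi <- NA_real_
  if (!is.null(bounds)) {
    lo <- sum(cell_deaths(erf, y0, cells$pop_band, cells$value_scenario,
                          cells$value_reference, bounds$lo))
    hi <- sum(cell_deaths(erf, y0, cells$pop_band, cells$value_scenario,
                          cells$value_reference, bounds$hi))
  }

  pop_band_total <- sum(cells$pop_band)
  baseline_deaths <- (y0$rate / 1e5) * pop_band_total
  pw_ref <- sum(cells$value_reference * cells$pop_band) / pop_band_total
  pw_scen <- sum(cells$value_scenario * cells$pop_band) / pop_band_total

  structure(
    list(excess_deaths = central, lo = lo, hi = hi,
         af = central / baseline_deaths,
         delta_pw = pw_scen - pw_ref,
         pop_band = pop_band_total,
         y0 = y0, erf = erf,
         rate_band_mismatch = !identical(y0$age_band, erf$age_band),
         scenario_label = scenario_label, reference_label = reference_label,
         cells = cells),
    class = "hia_result"
  )
}

#' @export
print.hia_result <- function(x, ...) {
  ci <- if (is.na(x$lo)) "" else sprintf(" (%.0f, %.0f)", x$lo, x$hi)
  cat(sprintf("<hia_result> %s: %+.0f excess deaths%s [%s vs %s], pw dC %+.2f ug m-3\n",
              x$erf$label, x$excess_deaths, ci,
              x$scenario_label %||% "scenario", x$reference_label %||% "reference",
              x$delta_pw))
  if (isTRUE(x$rate_band_mismatch)) {
    cat(sprintf("  note: baseline rate for ages %s applied to ERF band %s\n",
                x$y0$age_band, x$erf$age_band))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cell attributable deaths of an HIA result
#' @param x An `hia_result`.
#' @param ... Unused.
#' @return Tibble with per-cell concentrations, band population and deaths.
#' @export
tidy.hia_result <- function(x, ...) {
  as_tibble(x$cells) %>%
    select("row", "col", "value_reference", "value_scenario",
           "pop_band", "deaths")
}

#' One-row summary of an HIA result
#' @param x An `hia_result`.
#' @param ... Unused.
#' @return One-row tibble: excess deaths with CI, attributable fraction,
#'   population-weighted concentration change, scenario mortality rate and
#'   its percent change.
#' @export
glance.hia_result <- function(x, ...) {
  rates <- mortality_rate_change(x)
  tibble(erf = x$erf$label, endpoint = x$erf$endpoint,
         age_band = x$erf$age_band,
         scenario = x$scenario_label %||% NA_character_,
         reference = x$reference_label %||% NA_character_,
         excess_deaths = x$excess_deaths, deaths_lo = x$lo, deaths_hi = x$hi,
         af = x$af, delta_pw = x$delta_pw, pop_band = x$pop_band,
         scenario_rate = rates$scenario_rate,
         rate_pct_change = rates$pct_change)
}

#' Confidence interval of an HIA result
#'
#' The (lo, hi) excess-death bounds obtained by re-running the full
#' cellwise computation at the risk-coefficient CI endpoints. Errors when
#' the ERF carried no uncertainty information.
#'
#' @param result An `hia_result`.
#' @return Named numeric vector `c(lo = , hi = )`.
#' @export
confidence_interval <- function(result) {
  stopifnot(inherits(result, "hia_result"))
  if (is.na(result$lo) || is.na(result$hi)) {
    abort("ERF carried no confidence interval", class = "aqhia_missing_ci")
  }
  c(lo = result$lo, hi = result$hi)
}

#' Mortality-rate change implied by an HIA result
#'
#' Scenario rate = `y0 + excess_deaths / pop * 1e5`, with the percent
#' change relative to `y0`. Rates are derived from this package's own
#' death counts.
#'
#' @param result An `hia_result`.
#' @param pop Exposed band population (defaults to the result's).
#' @param y0 Baseline mortality (defaults to the result's).
#' @return One-row tibble with `scenario_rate` (per 100 000) and
#'   `pct_change` (%).
#' @export
mortality_rate_change <- function(result, pop = result$pop_band,
                                  y0 = result$y0) {
  if (pop <= 0) abort("population must be > 0")
  rate <- y0$rate + result$excess_deaths / pop * 1e5
  tibble(scenario_rate = rate, pct_change = 100 * (rate - y0$rate) / y0$rate)
}

#' Difference in excess deaths between two scenario results
#'
#' The headline co-benefit number: excess deaths under one scenario minus
#' excess deaths under another (both relative to the same baseline), e.g.
#' business-as-usual minus mitigation-and-adaptation.
#'
#' @param result_a,result_b `hia_result` objects sharing a reference, or
#'   plain numbers of excess deaths.
#' @return Deaths avoided by scenario B relative to scenario A.
#' @export
scenario_pair_delta <- function(result_a, result_b) {
  a <- if (inherits(result_a, "hia_result")) result_a$excess_deaths else result_a
  b <- if (inherits(result_b, "hia_result")) result_b$excess_deaths else result_b
  a - b
}

#' Air-quality attainment target
#'
#' Either a percent reduction from a baseline mean (national clean-air
#' programme style, default 30%) or an absolute annual level (national
#' standard 40 ug m-3; WHO guideline 5 ug m-3).
#'
#' @param name `"NCAP"`, `"NAAQS"`, `"WHO_AQG"` or `"custom"`.
#' @param percent_reduction Percent reduction from baseline (0-100), for
#'   percent-type targets.
#' @param level Absolute annual level, ug m-3, for level-type targets.
#' @return An object of class `attainment_target`.
#' @examples
#' attainment_target("NCAP")
#' attainment_target("WHO_AQG")
#' @export
attainment_target <- function(name = c("NCAP", "NAAQS", "WHO_AQG", "custom"),
                              percent_reduction = NULL, level = NULL) {
  name <- match.arg(name)
  if (name == "NCAP" && is.null(percent_reduction) && is.null(level)) {
    percent_reduction <- 30
  }
  if (name == "NAAQS" && is.null(level)) level <- 40
  if (name == "WHO_AQG" && is.null(level)) level <- 5
  if (is.null(percent_reduction) && is.null(level)) {
    abort("custom target needs percent_reduction or level")
  }
  if (!is.null(percent_reduction) &&
      (percent_reduction <= 0 || percent_reduction >= 100)) {
    abort("percent_reduction must lie in (0, 100)")
  }
  if (!is.null(level) && level <= 0) abort("level must be > 0")
  structure(list(name = name, percent_reduction = percent_reduction,
                 level = level),
            class = "attainment_target")
}

target_goal <- function(target, baseline_mean) {
  if (!is.null(target$level)) return(target$level)
  baseline_mean * (1 - target$percent_reduction / 100)
}

#' Roll an exposure surface back to an attainment target
#'
#' Uniform proportional rollback: when the surface's population-weighted
#' mean exceeds the goal concentration, every cell is scaled by
#' `goal / current mean`, so the rolled-back population-weighted mean
#' equals the goal; a surface already at or below the goal is returned
#' unchanged. (A per-cell cap-at-level alternative is available via
#' `method = "cap"` but is not used in the headline analysis.)
#'
#' @param surface Annual surface tibble.
#' @param pop Population tibble (defines the weighting).
#' @param target An [attainment_target()].
#' @param baseline_mean Baseline population-weighted mean used to resolve
#'   percent-reduction targets (defaults to the surface's own mean).
#' @param method `"proportional"` (default) or `"cap"`.
#' @return An annual surface tibble.
#' @export
rollback_to_target <- function(surface, pop, target,
                               baseline_mean = NULL,
                               method = c("proportional", "cap")) {
  method <- match.arg(method)
  stopifnot(inherits(target, "attainment_target"))
  cur <- population_weighted_mean(surface, pop)
  goal <- target_goal(target, baseline_mean %||% cur)
  if (goal <= 0) abort("target resolves to a non-positive goal")
  out <- surface
  if (method == "proportional") {
    if (cur > goal) out$value <- surface$value * goal / cur
  } else {
    out$value <- pmin(surface$value, goal)
  }
  attr(out, "scenario") <- paste0(target$name, "_rollback")
  set_grid(out, field_grid(surface))
}

#' Avoided deaths from attaining air-quality targets
#'
#' For each target, rolls the scenario surface back to the target and runs
#' the cellwise HIA of the rolled surface against the unrolled one, under
#' each exposure-response function. Reports avoided deaths (positive =
#' deaths prevented relative to the unrolled scenario) per ERF and the
#' across-ERF maximum (the "up to" convention).
#'
#' @param bau_surface Annual surface of the scenario being rolled back.
#' @param targets List of [attainment_target()]s.
#' @param pop Population tibble.
#' @param y0 A [baseline_mortality()].
#' @param erfs Named list of ERFs (default [default_erfs()]).
#' @param baseline_mean Baseline population-weighted mean for
#'   percent-reduction targets.
#' @return Tibble with `target`, `goal`, one avoided-deaths column per ERF
#'   and `max_avoided`.
#' @export
attainment_benefit <- function(bau_surface, targets, pop,
                               y0 = baseline_mortality(),
                               erfs = default_erfs(),
                               baseline_mean = NULL) {
  if (inherits(targets, "attainment_target")) targets <- list(targets)
  cur <- population_weighted_mean(bau_surface, pop)
  rows <- purrr::map(targets, function(tg) {
    goal <- target_goal(tg, baseline_mean %||% cur)
    rolled <- rollback_to_target(bau_surface, pop, tg,
                                 baseline_mean = baseline_mean)
    avoided <- purrr::map_dbl(erfs, function(erf) {
      res <- cellwise_hia(bau_surface, rolled, pop, y0, erf)
      -res$excess_deaths
    })
    dplyr::bind_cols(tibble(target = tg$name, goal = goal),
                     as_tibble(as.list(setNames(avoided,
                                                paste0("avoided_", names(erfs))))),
                     tibble(max_avoided = max(avoided)))
  })
  dplyr::bind_rows(rows)
}
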