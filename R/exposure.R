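#' Seasonally weighted annual exposure surface
#'
#' Collapses the four representative monthly fields into an annual
#' daily-average PM2.5 surface: per cell, the weighted sum of the monthly
#' values with weights `months_represented / 12` from the seasonal calendar.
#' The monsoon month (July, weight 4/12) therefore drives the annual value
#' most strongly. Because the weights sum to one, a set of identical monthly
#' fields maps to itself.
#'
#' @param monthly_fields Tibble with `row`, `col`, `month`, `value` holding
#'   exactly one field per representative month.
#' @param calendar A [season_calendar()].
#' @param scenario Optional scenario label stored on the result.
#' @return An annual surface tibble (`row`, `col`, `value`).
#' @examples
#' f <- simulate_background(grid_spec(4, 4),
#'                          c(Jan = 74.46, May = 69.72, Jul = 38.95, Oct = 86.20),
#'                          spatial_sd = 0, correlation_length = 1, seed = 1)
#' city_mean(annual_average(f)) # 63.40 at the study's 2018 monthly means
#' @export
annual_average <- function(monthly_fields, calendar = season_calendar(),
                           scenario = NULL) {
  grid <- field_grid(monthly_fields)
  have <- unique(monthly_fields$month)
  missing_m <- setdiff(calendar$month, have)
  if (length(missing_m) > 0) {
    abort(paste0("incomplete input: missing month(s) ",
                 paste(missing_m, collapse = ", ")),
          class = "aqhia_incomplete_input")
  }
  out <- monthly_fields %>%
    inner_join(calendar[, c("month", "weight")], by = "month") %>%
    group_by(.data$row, .data$col) %>%
    summarise(value = sum(.data$weight * .data$value), .groups = "drop")
  out <- set_grid(as_tibble(out), grid)
  attr(out, "scenario") <- scenario
  out
}

#' Unweighted city-mean concentration
#'
#' Arithmetic mean over all grid cells of an annual surface (the "manually
#' weighted" citywide annual daily average).
#'
#' @param surface Annual surface tibble.
#' @return City mean in ug m-3.
#' @export
city_mean <- function(surface) {
  if (nrow(surface) == 0) abort("empty surface")
  mean(surface$value)
}

#' Population-weighted mean concentration
#'
#' `sum(C_i * P_i) / sum(P_i)` over cells, the exposure metric used for
#' health impact estimation. Always lies between the minimum and maximum
#' cell concentration. Because the age structure is citywide, band
#' fractions cancel and every band has the same weighted mean; the band
#' argument exists to validate that the band population is positive.
#'
#' @param surface Annual surface tibble.
#' @param pop Population tibble from [simulate_population()].
#' @param band Age band: `"0_99"`, `"25_99"` or `"30_99"`.
#' @return Population-weighted mean in ug m-3.
#' @export
population_weighted_mean <- function(surface, pop, band = "0_99") {
  check_same_grid(surface, pop)
  f <- band_fraction(pop_ages(pop), band)
  joined <- inner_join(surface, pop, by = c("row", "col"))
  w <- joined$persons * f
  if (sum(w) <= 0) {
    abort("zero total population in band", class = "aqhia_undefined_weighting")
  }
  sum(joined$value * w) / sum(w)
}

#' Exposure difference between two scenarios
#'
#' Cellwise concentration change plus the aggregate population-weighted
#' change, expressed both absolutely and as a percentage of the reference
#' scenario's population-weighted mean.
#'
#' @param scenario,reference Annual surface tibbles on the same grid.
#' @param pop Population tibble used for weighting.
#' @return An object of class `exposure_delta`; see [tidy.exposure_delta()]
#'   for the cellwise table and [glance.exposure_delta()] for the aggregate.
#' @export
delta_exposure <- function(scenario, reference, pop) {
  check_same_grid(scenario, reference)
  cells <- inner_join(scenario, reference, by = c("row", "col"),
                      suffix = c("_scenario", "_reference")) %>%
    mutate(delta = .data$value_scenario - .data$value_reference)
  pw_s <- population_weighted_mean(scenario, pop)
  pw_r <- population_weighted_mean(reference, pop)
  structure(
    list(cells = set_grid(cells, field_grid(scenario)),
         pw_scenario = pw_s, pw_reference = pw_r,
         delta_pw = pw_s - pw_r,
         pct_change = 100 * (pw_s - pw_r) / pw_r,
         scenario = attr(scenario, "scenario"),
         reference = attr(reference, "scenario")),
    class = "exposure_delta"
  )
}

#' @export
print.exposure_delta <- function(x, ...) {
  cat(sprintf("<exposure_delta> pw mean %.2f -> %.2f ug m-3 (delta %+.2f, %+.2f%%)\n",
              x$pw_reference, x$pw_scenario, x$delta_pw, x$pct_change))
  invisible(x)
}

#' Tidy the cellwise exposure differences
#' @param x An `exposure_delta`.
#' @param ... Unused.
#' @return Tibble with per-cell scenario, reference and delta values.
#' @export
tidy.exposure_delta <- function(x, ...) as_tibble(x$cells)

#' One-row aggregate summary of an exposure delta
#' @param x An `exposure_delta`.
#' @param ... Unused.
#' @return One-row tibble with population-weighted means, delta and percent
#'   change.
#' @export
glance.exposure_delta <- function(x, ...) {
  tibble(pw_reference = x$pw_reference, pw_scenario = x$pw_scenario,
         delta_pw = x$delta_pw, pct_change = x$pct_change)
}

#' Seasonal model-vs-monitor bias
#'
#' For each season, compares the mean of monitor observations with the mean
#' of the modeled field sampled at the monitor cells over the same
#' monitor-days, reporting `100 * (monitored - modeled) / monitored`.
#' Positive values mean the model underestimates. Seasons with no monitor
#' data are reported as `NA` with `n_days = 0`, never as zero bias.
#'
#' @param modeled Monthly field tibble.
#' @param monitors Monitor series from [simulate_monitors()] (or any tibble
#'   with `row`, `col`, `month`, `value`).
#' @return Tibble with `season`, `percent_difference`, `n_days`.
#' @export
seasonal_model_bias <- function(modeled, monitors) {
  grid <- field_grid(modeled)
  bad <- monitors$row < 0 | monitors$row >= grid$n_rows |
    monitors$col < 0 | monitors$col >= grid$n_cols
  if (any(bad)) abort("monitor cell outside grid", class = "aqhia_bounds_error")
  joined <- monitors %>%
    inner_join(modeled, by = c("row", "col", "month"),
               suffix = c("_monitor", "_model")) %>%
    mutate(season = month_season(.data$month))
  per_season <- joined %>%
    group_by(.data$season) %>%
    summarise(
      percent_difference = 100 * (mean(.data$value_monitor) - mean(.data$value_model)) /
        mean(.data$value_monitor),
      n_days = dplyr::n(), .groups = "drop")
  season_calendar() %>%
    select("season") %>%
    left_join(per_season, by = "season") %>%
    mutate(n_days = dplyr::coalesce(.data$n_days, 0L))
}
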