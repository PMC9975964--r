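#' Scenario climate summary
#'
#' @param average_temperature Annual average temperature, deg C.
#' @param wind_speed_10m Wind speed at 10 m, m s-1.
#' @param relative_humidity_2m Relative humidity at 2 m, percent (0-100).
#' @return An object of class `climate_summary`.
#' @export
climate_summary <- function(average_temperature, wind_speed_10m = NA_real_,
                            relative_humidity_2m = NA_real_) {
  if (!is.na(relative_humidity_2m) &&
      (relative_humidity_2m < 0 || relative_humidity_2m > 100)) {
    abort("relative humidity must lie in [0, 100]")
  }
  structure(list(average_temperature = average_temperature,
                 wind_speed_10m = wind_speed_10m,
                 relative_humidity_2m = relative_humidity_2m),
            class = "climate_summary")
}

#' Warming increment between two climate summaries
#'
#' Future minus baseline annual average temperature; negative values
#' (cooling) are allowed.
#'
#' @param baseline,future [climate_summary()] objects.
#' @return Temperature change in deg C.
#' @examples
#' warming_increment(climate_summary(27.58), climate_summary(28.39)) # 0.81
#' @export
warming_increment <- function(baseline, future) {
  future$average_temperature - baseline$average_temperature
}

#' Annual electricity savings from cool roofs
#'
#' Converts added reflective-roof area to annual electricity savings at a
#' fixed intensity (default 14.2 kWh saved per m2 per year):
#' `km2 * 1e6 m2/km2 * kWh/m2 / 1e9 kWh/TWh`.
#'
#' @param added_area_km2 Added cool-roof coverage beyond baseline, km2.
#' @param intensity_kwh_m2 Savings intensity, kWh m-2 yr-1.
#' @return Savings in TWh yr-1.
#' @examples
#' cool_roof_savings(20.60) # 0.293 TWh
#' @export
cool_roof_savings <- function(added_area_km2, intensity_kwh_m2 = 14.2) {
  if (added_area_km2 < 0 || intensity_kwh_m2 < 0) {
    abort("area and intensity must be >= 0")
  }
  added_area_km2 * 1e6 * intensity_kwh_m2 / 1e9
}

#' Cooling-demand difference between scenarios
#'
#' @param bau_demand_twh,ma_demand_twh Annual cooling electricity demand
#'   (TWh) under business-as-usual and under mitigation-and-adaptation.
#' @return BAU minus M&A demand, TWh.
#' @export
cooling_demand_delta <- function(bau_demand_twh, ma_demand_twh) {
  if (bau_demand_twh < 0 || ma_demand_twh < 0) abort("demands must be >= 0")
  bau_demand_twh - ma_demand_twh
}

#' Scenario energy supply/demand block
#'
#' @param tpp_supply Coal plant supply to the city, TWh.
#' @param surat_supply Remote gas-plant supply, TWh.
#' @param renewable_supply Renewable supply, TWh.
#' @param cooling_demand Cooling electricity demand, TWh.
#' @param added_cool_roof_area Added cool-roof area beyond baseline, km2.
#' @param savings_intensity Cool-roof savings intensity, kWh m-2 yr-1.
#' @param coal_emission_factor Range (lo, hi) of coal CO2 intensity,
#'   kg CO2 per kWh. Defaults back-solved from the reported avoided-CO2
#'   range; configuration values, not physical constants.
#' @return An object of class `energy_scenario`.
#' @export
energy_scenario <- function(tpp_supply, surat_supply, renewable_supply,
                            cooling_demand, added_cool_roof_area = 0,
                            savings_intensity = 14.2,
                            coal_emission_factor = c(0.938, 1.243)) {
  vals <- c(tpp_supply, surat_supply, renewable_supply, cooling_demand,
            added_cool_roof_area)
  if (any(vals < 0)) abort("supplies, demands and areas must be >= 0")
  structure(list(tpp_supply = tpp_supply, surat_supply = surat_supply,
                 renewable_supply = renewable_supply,
                 cooling_demand = cooling_demand,
                 added_cool_roof_area = added_cool_roof_area,
                 savings_intensity = savings_intensity,
                 coal_emission_factor = coal_emission_factor),
            class = "energy_scenario")
}

total_supply <- function(s) s$tpp_supply + s$surat_supply + s$renewable_supply

#' Substitute coal supply with renewables
#'
#' Returns the scenario with the coal plant's supply moved to renewables:
#' `tpp_supply` becomes 0, `renewable_supply` gains the displaced amount,
#' all other entries unchanged. Total supply is conserved.
#'
#' @param bau An [energy_scenario()].
#' @return An `energy_scenario` with the substitution applied.
#' @examples
#' ma <- substitute_supply(energy_scenario(2.10, 5.26, 6.63, 4.22))
#' ma$renewable_supply # 8.73
#' @export
substitute_supply <- function(bau) {
  stopifnot(inherits(bau, "energy_scenario"))
  out <- bau
  out$renewable_supply <- bau$renewable_supply + bau$tpp_supply
  out$tpp_supply <- 0
  out
}

#' Avoided CO2 from displaced fossil generation
#'
#' `displaced TWh * 1e9 kWh/TWh * factor kg/kWh / 1e9 kg/Mt`, evaluated at
#' each end of the emission-factor range.
#'
#' @param displaced_twh Displaced fossil generation, TWh (>= 0).
#' @param factor_range Coal CO2 intensity (kg CO2 per kWh); scalar or
#'   (lo, hi) range.
#' @return Tibble with `factor` and `co2_avoided_mt`.
#' @examples
#' co2_avoided(2.10) # 1.97 - 2.61 Mt at the default factor range
#' @export
co2_avoided <- function(displaced_twh, factor_range = c(0.938, 1.243)) {
  if (displaced_twh < 0) abort("displaced energy must be >= 0")
  if (any(factor_range <= 0)) abort("emission factors must be > 0")
  tibble(factor = factor_range,
         co2_avoided_mt = displaced_twh * factor_range)
}

#' Scenario energy report table
#'
#' @param scenarios Named list of [energy_scenario()] objects.
#' @param climate Optional named list of [climate_summary()] objects with
#'   the same names.
#' @return Tibble with one row per quantity and one column per scenario.
#' @export
energy_report <- function(scenarios, climate = NULL) {
  stopifnot(is.list(scenarios), !is.null(names(scenarios)))
  rows <- purrr::imap(scenarios, function(s, nm) {
    tibble(
      scenario = nm,
      average_temperature_c = if (!is.null(climate)) climate[[nm]]$average_temperature else NA_real_,
      added_cool_roof_area_km2 = s$added_cool_roof_area,
      tpp_supply_twh = s$tpp_supply,
      surat_supply_twh = s$surat_supply,
      renewable_supply_twh = s$renewable_supply,
      cooling_demand_twh = s$cooling_demand,
      total_supply_twh = total_supply(s),
      cool_roof_savings_twh = cool_roof_savings(s$added_cool_roof_area,
                                                s$savings_intensity)
    )
  })
  dplyr::bind_rows(rows)
}
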