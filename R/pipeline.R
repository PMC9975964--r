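#' Read a pipeline configuration
#'
#' The whole analysis is driven by one YAML file: grid, seeds, background
#' field statistics, the point source, population structure and growth,
#' baseline mortality, per-scenario season means / emission scale / energy
#' block / climate block, the ERF set, attainment targets and the monitor
#' simulation block. `demo_config()` returns the bundled three-scenario
#' configuration (2018 baseline, 2030 business-as-usual, 2030
#' mitigation-and-adaptation).
#'
#' @param path Path to a YAML configuration.
#' @return A nested configuration list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
demo_config <- function() {
  read_config(system.file("extdata", "demo_config.yaml", package = "aqhia",
                          mustWork = TRUE))
}

#' Validate a pipeline configuration
#'
#' Checks the full schema and returns every violation found (not only the
#' first): required blocks and seeds, grid bounds, seasonal weights,
#' age-band nesting, non-negative scales/totals, ERF parameter positivity
#' and scenario label sanity.
#'
#' @param config Configuration list from [read_config()].
#' @return Character vector of error messages; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  errors <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)

  for (block in c("grid", "seeds", "background", "point_source",
                  "population", "baseline_mortality", "scenarios", "erfs")) {
    need(!is.null(config[[block]]), paste0("missing block: ", block))
  }
  if (length(errors)) return(errors)

  for (s in c("background", "population", "monitors")) {
    need(is.numeric(config$seeds[[s]]), paste0("seeds: missing seed '", s, "'"))
  }
  need(config$grid$n_rows >= 1 && config$grid$n_cols >= 1,
       "grid: n_rows and n_cols must be >= 1")
  ps <- config$point_source
  need(ps$row >= 0 && ps$row < config$grid$n_rows &&
         ps$col >= 0 && ps$col < config$grid$n_cols,
       "point_source: location outside grid")
  need(ps$decay_length > 0, "point_source: decay_length must be > 0")

  if (!is.null(config$calendar)) {
    w <- unlist(config$calendar$months_represented)
    need(sum(w) == 12, "calendar: months_represented must sum to 12")
  }

  for (yr in c("ages_2018", "ages_2030")) {
    a <- config$population[[yr]]
    need(all(unlist(a) > 0), paste0("population: ", yr, " totals must be > 0"))
    need(a$total_30_99 <= a$total_25_99 && a$total_25_99 <= a$total_0_99,
         paste0("population: ", yr, " bands must be nested 30-99 <= 25-99 <= 0-99"))
  }
  need(config$baseline_mortality$rate >= 0,
       "baseline_mortality: rate must be >= 0")

  labels <- names(config$scenarios)
  need(!anyDuplicated(labels), "scenarios: labels must be unique")
  for (nm in labels) {
    sc <- config$scenarios[[nm]]
    need(is.numeric(sc$emission_scale) && sc$emission_scale >= 0,
         paste0("scenarios: ", nm, ": emission_scale must be >= 0"))
    need(setequal(names(sc$season_means), c("Jan", "May", "Jul", "Oct")),
         paste0("scenarios: ", nm, ": season_means must name Jan, May, Jul, Oct"))
    need(all(unlist(sc$season_means) >= 0),
         paste0("scenarios: ", nm, ": season_means must be >= 0"))
    if (!is.null(sc$energy)) {
      need(all(unlist(sc$energy[c("tpp_supply", "surat_supply",
                                  "renewable_supply", "cooling_demand")]) >= 0),
           paste0("scenarios: ", nm, ": energy supplies/demand must be >= 0"))
    }
  }
  ref <- config$reference %||% "baseline_2018"
  need(ref %in% labels, paste0("reference scenario '", ref, "' not configured"))
  if (ref %in% labels) {
    need(config$scenarios[[ref]]$emission_scale == 1,
         "reference scenario must have emission_scale 1.0")
  }

  for (nm in names(config$erfs)) {
    e <- config$erfs[[nm]]
    if (identical(e$family, "loglinear")) {
      need(is.numeric(e$rr_per_10) && e$rr_per_10 > 0,
           paste0("erfs: ", nm, ": rr_per_10 must be > 0"))
    } else if (identical(e$family, "gemm")) {
      need(all(c(e$alpha, e$nu) > 0),
           paste0("erfs: ", nm, ": alpha and nu must be > 0"))
      need(e$c0 >= 0, paste0("erfs: ", nm, ": c0 must be >= 0"))
    } else {
      need(FALSE, paste0("erfs: ", nm, ": unknown family"))
    }
  }
  errors
}

build_erf <- function(spec, label) {
  if (identical(spec$family, "loglinear")) {
    loglinear_erf(spec$rr_per_10, ci = unlist(spec$ci), label = label,
                  endpoint = spec$endpoint %||% "all-cause",
                  age_band = spec$age_band %||% "30_99")
  } else {
    gemm_erf(theta = spec$theta, se = spec$se, alpha = spec$alpha,
             mu = spec$mu, nu = spec$nu, c0 = spec$c0 %||% 2.4,
             label = label, endpoint = spec$endpoint %||% "non-accidental",
             age_band = spec$age_band %||% "25_99")
  }
}

build_ages <- function(a) {
  age_structure(a$total_0_99, a$total_25_99, a$total_30_99)
}

#' Run the full co-benefits pipeline
#'
#' Executes generate -> expose -> energy-account -> HIA -> attainment as one
#' seeded run: simulates monthly background fields per scenario (shared
#' noise pattern, scenario-specific seasonal means), superimposes the
#' scenario-scaled point-source plume, builds the population raster
#' (correlated with the baseline annual surface and grown to the scenario's
#' year), aggregates to seasonally weighted annual surfaces, and produces
#' the exposure, energy, HIA and attainment report tables plus a
#' provenance manifest. Identical configuration and seeds give identical
#' tables.
#'
#' @param config Configuration list (see [demo_config()]).
#' @param seed Optional integer overriding every configured stage seed
#'   (stage seeds become `seed`, `seed + 1`, `seed + 2`).
#' @return An object of class `run_report`: a list of tibbles
#'   (`exposure`, `energy`, `hia`, `attainment`, `bias`) plus `surfaces`,
#'   `population` and `manifest`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  errs <- validate_config(config)
  if (length(errs)) {
    abort(paste0("invalid configuration:\n", paste("-", errs, collapse = "\n")),
          class = "aqhia_invalid_config")
  }
  seeds <- config$seeds
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    seeds <- list(background = seed, population = seed + 1L,
                  monitors = seed + 2L)
  }

  grid <- grid_spec(config$grid$n_rows, config$grid$n_cols,
                    cell_area = config$grid$cell_area %||% 4.2)
  calendar <- if (is.null(config$calendar)) season_calendar() else
    season_calendar(unlist(config$calendar$months_represented))
  ref_label <- config$reference %||% "baseline_2018"
  ps <- config$point_source
  y0 <- baseline_mortality(config$baseline_mortality$rate,
                           config$baseline_mortality$age_band %||% "30_99")
  erfs <- purrr::imap(config$erfs, build_erf)

  # -- generate: monthly fields per scenario (same noise pattern across
  #    scenarios, emulating shared meteorology) + scenario-scaled plume
  fields <- purrr::imap(config$scenarios, function(sc, nm) {
    bg <- simulate_background(grid, unlist(sc$season_means),
                              spatial_sd = config$background$spatial_sd,
                              correlation_length = config$background$correlation_length,
                              seed = seeds$background)
    src <- point_source(ps$row, ps$col, ps$monthly_contribution,
                        ps$decay_length, emission_scale = sc$emission_scale)
    apply_point_source(bg, src)
  })

  # -- expose: annual surfaces
  surfaces <- purrr::imap(fields, function(f, nm) {
    annual_average(f, calendar, scenario = nm)
  })

  # -- population: simulated against the reference-year surface, grown per
  #    scenario population year
  ages18 <- build_ages(config$population$ages_2018)
  ages30 <- build_ages(config$population$ages_2030)
  pop18 <- simulate_population(
    grid, ages18, surface = surfaces[[ref_label]],
    concentration_gradient_weight = config$population$gradient_weight %||% 0,
    dispersion = config$population$dispersion %||% 0.5,
    seed = seeds$population)
  pops <- purrr::imap(config$scenarios, function(sc, nm) {
    if (identical(sc$population_year %||% 2018, 2018)) pop18
    else grow_population(pop18, ages30)
  })

  exposure_tbl <- purrr::imap(surfaces, function(s, nm) {
    tibble(scenario = nm,
           manual_mean = city_mean(s),
           population_weighted_mean = population_weighted_mean(s, pops[[nm]]))
  }) %>% dplyr::bind_rows()

  deltas_tbl <- purrr::imap(surfaces[setdiff(names(surfaces), ref_label)],
                            function(s, nm) {
    d <- delta_exposure(s, surfaces[[ref_label]], pops[[nm]])
    glance(d) %>% mutate(scenario = nm, reference = ref_label, .before = 1)
  }) %>% dplyr::bind_rows()

  # -- energy accounting
  climate <- purrr::map(config$scenarios, function(sc) {
    cl <- sc$climate
    if (is.null(cl)) NULL else climate_summary(cl$average_temperature,
                                               cl$wind_speed_10m %||% NA_real_,
                                               cl$relative_humidity_2m %||% NA_real_)
  })
  scen_energy <- purrr::map(config$scenarios, function(sc) {
    en <- sc$energy
    if (is.null(en)) NULL else
      energy_scenario(en$tpp_supply, en$surat_supply, en$renewable_supply,
                      en$cooling_demand,
                      added_cool_roof_area = en$added_cool_roof_area %||% 0)
  })
  has_energy <- !purrr::map_lgl(scen_energy, is.null)
  energy_tbl <- if (any(has_energy)) {
    energy_report(scen_energy[has_energy], climate[has_energy])
  } else tibble()

  # -- HIA: every non-reference scenario against the reference, per ERF
  hia_results <- purrr::imap(
    surfaces[setdiff(names(surfaces), ref_label)],
    function(s, nm) {
      purrr::map(erfs, function(erf) {
        cellwise_hia(surfaces[[ref_label]], s, pops[[nm]], y0, erf,
                     scenario_label = nm, reference_label = ref_label)
      })
    })
  hia_tbl <- purrr::map(hia_results, function(by_erf) {
    purrr::map(by_erf, glance) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()

  # -- attainment rollback of the configured scenario (default: BAU-like,
  #    i.e. the first non-reference scenario)
  att_label <- config$attainment_scenario %||%
    setdiff(names(surfaces), ref_label)[1]
  attainment_tbl <- if (!is.null(att_label) && length(config$targets)) {
    targets <- purrr::map(config$targets, function(t) attainment_target(t))
    attainment_benefit(surfaces[[att_label]], targets, pops[[att_label]],
                       y0, erfs,
                       baseline_mean = population_weighted_mean(
                         surfaces[[ref_label]], pops[[ref_label]])) %>%
      mutate(scenario = att_label, .before = 1)
  } else tibble()

  # -- monitor bias diagnostic against the reference-year fields
  bias_tbl <- if (!is.null(config$monitors)) {
    mc <- config$monitors
    mons <- simulate_monitors(fields[[ref_label]],
                              n_monitors = mc$n_monitors %||% 10L,
                              bias_by_season = unlist(mc$bias_by_season),
                              noise_sd = mc$noise_sd %||% 0,
                              n_days = mc$n_days %||% 30L,
                              seed = seeds$monitors)
    seasonal_model_bias(fields[[ref_label]], mons)
  } else tibble()

  structure(
    list(exposure = exposure_tbl, deltas = deltas_tbl, energy = energy_tbl,
         hia = hia_tbl, attainment = attainment_tbl, bias = bias_tbl,
         surfaces = surfaces, population = pops, hia_results = hia_results,
         manifest = list(config_hash = rlang::hash(config),
                         seeds = seeds,
                         reference = ref_label,
                         package_version = as.character(utils::packageVersion("aqhia")),
                         timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  scenarios:", paste(x$exposure$scenario, collapse = ", "), "\n")
  cat("  config hash:", x$manifest$config_hash, "\n")
  print(x$exposure)
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes `exposure.csv`, `deltas.csv`, `energy.csv`, `hia.csv`,
#' `attainment.csv`, `bias.csv` and `manifest.json` into `dir`. The CSV
#' contents are a pure function of configuration and seeds, so re-running
#' with the same inputs reproduces them byte for byte (the manifest carries
#' a timestamp and is excluded from that guarantee).
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("exposure", "deltas", "energy", "hia", "attainment", "bias")
  for (nm in tables) {
    tbl <- report[[nm]]
    if (is.data.frame(tbl) && nrow(tbl)) {
      readr::write_csv(tbl, file.path(dir, paste0(nm, ".csv")))
    }
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
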