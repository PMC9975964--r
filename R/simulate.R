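#' Simulate background monthly PM2.5 fields
#'
#' Generates one gridded daily-average PM2.5 surface per representative
#' month with a prescribed city mean and a controllable spatial texture:
#' white noise smoothed with a separable Gaussian kernel of the given
#' correlation length, standardized to the requested spatial standard
#' deviation, shifted to the seasonal mean and clipped at zero. With
#' `spatial_sd = 0` every cell equals the seasonal mean exactly.
#'
#' @param grid A [grid_spec()].
#' @param season_means Named numeric vector of city-mean PM2.5 (ug m-3) for
#'   `Jan`, `May`, `Jul`, `Oct`.
#' @param spatial_sd Spatial standard deviation across cells (ug m-3).
#' @param correlation_length Gaussian smoothing length in cells.
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   output.
#'
#' @return A tibble with columns `row`, `col`, `month`, `value` (ug m-3)
#'   carrying the grid as an attribute.
#' @examples
#' f <- simulate_background(grid_spec(8, 8), c(Jan = 74, May = 70, Jul = 39, Oct = 86),
#'                          spatial_sd = 10, correlation_length = 2, seed = 1)
#' dplyr::count(f, month)
#' @export
simulate_background <- function(grid, season_means, spatial_sd = 12,
                                correlation_length = 3, seed) {
  stopifnot(inherits(grid, "grid_spec"))
  if (missing(seed)) abort("simulate_background() requires an explicit seed")
  if (!setequal(names(season_means), rep_months)) {
    abort("season_means must be named Jan, May, Jul, Oct")
  }
  if (any(season_means < 0)) abort("season_means must be >= 0")
  if (spatial_sd < 0) abort("spatial_sd must be >= 0")

  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  out <- purrr::map(rep_months, function(m) {
    vals <- smooth_noise(grid$n_rows, grid$n_cols, correlation_length)
    if (spatial_sd > 0 && length(vals) > 1 && sd(vals) > 0) {
      vals <- (vals - mean(vals)) / sd(vals) * spatial_sd
    } else {
      vals <- rep(0, length(vals))
    }
    tibble(row = rep(0:(grid$n_rows - 1L), each = grid$n_cols),
           col = rep(0:(grid$n_cols - 1L), times = grid$n_rows),
           month = m,
           value = pmax(0, season_means[[m]] + vals))
  })
  set_grid(dplyr::bind_rows(out), grid)
}

## Row-major white noise smoothed by a separable Gaussian kernel; returned
## in row-major cell order.
smooth_noise <- function(n_rows, n_cols, ell) {
  w <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (ell > 0) {
    sr <- gauss_smoother(n_rows, ell)
    sc <- gauss_smoother(n_cols, ell)
    w <- sr %*% w %*% t(sc)
  }
  as.vector(t(w)) # row-major
}

gauss_smoother <- function(n, ell) {
  idx <- seq_len(n)
  k <- exp(-outer(idx, idx, function(i, j) (i - j)^2) / (2 * ell^2))
  k / rowSums(k)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Describe a point emission source
#'
#' The plume of a stationary source (a coal-fired power plant in the
#' motivating application) is represented as an isotropic exponential kernel
#' in cell distance: the source cell gains the full monthly contribution and
#' a cell at distance `d` gains `exp(-d / decay_length)` of it, all scaled
#' by the scenario's `emission_scale` (1 at baseline, 1.06 for a 6% supply
#' growth scenario, 0 when the plant's emissions are eliminated).
#'
#' @param row,col 0-based cell index of the source.
#' @param monthly_contribution Concentration added at the source cell
#'   (ug m-3); either a scalar or a vector named by representative month.
#' @param decay_length e-folding distance of the plume, in cells (> 0).
#' @param emission_scale Dimensionless scenario multiplier (>= 0).
#' @return An object of class `point_source`.
#' @export
point_source <- function(row, col, monthly_contribution, decay_length = 3,
                         emission_scale = 1) {
  if (decay_length <= 0) abort("decay_length must be > 0")
  if (emission_scale < 0) abort("emission_scale must be >= 0")
  structure(list(row = as.integer(row), col = as.integer(col),
                 monthly_contribution = monthly_contribution,
                 decay_length = decay_length,
                 emission_scale = emission_scale),
            class = "point_source")
}

#' Superimpose a point-source plume on monthly fields
#'
#' Adds `emission_scale * monthly_contribution * exp(-d / decay_length)` to
#' every cell, where `d` is the Euclidean distance in cell units from the
#' source. Plumes are additive, so applying several sources commutes.
#'
#' @param field Monthly field tibble from [simulate_background()].
#' @param source A [point_source()].
#' @return A field tibble of the same shape; the input is not modified.
#' @export
apply_point_source <- function(field, source) {
  stopifnot(inherits(source, "point_source"))
  grid <- field_grid(field)
  if (source$row < 0 || source$row >= grid$n_rows ||
      source$col < 0 || source$col >= grid$n_cols) {
    abort("point source lies outside the grid", class = "aqhia_bounds_error")
  }
  contrib <- source$monthly_contribution
  months <- unique(field$month)
  if (is.null(names(contrib))) {
    contrib <- setNames(rep(contrib[[1]], length(months)), months)
  }
  d <- sqrt((field$row - source$row)^2 + (field$col - source$col)^2)
  inc <- source$emission_scale * unname(contrib[field$month]) *
    exp(-d / source$decay_length)
  out <- field
  out$value <- field$value + inc
  set_grid(out, grid)
}

#' Age structure of the exposed population
#'
#' Citywide totals for the age bands used by the exposure-response
#' functions: everyone (0-99), adults 25+ (non-accidental mortality) and
#' adults 30+ (all-cause mortality). Band totals must be nested.
#'
#' @param total_0_99,total_25_99,total_30_99 Persons in each band.
#' @return An object of class `age_structure`.
#' @examples
#' age_structure(8459139, 6344354, 5921397)
#' @export
age_structure <- function(total_0_99, total_25_99, total_30_99) {
  if (any(c(total_0_99, total_25_99, total_30_99) <= 0)) {
    abort("age band totals must be > 0")
  }
  if (!(total_30_99 <= total_25_99 && total_25_99 <= total_0_99)) {
    abort("age bands must be nested: 30-99 <= 25-99 <= 0-99",
          class = "aqhia_invalid_age_structure")
  }
  structure(list(total_0_99 = total_0_99, total_25_99 = total_25_99,
                 total_30_99 = total_30_99),
            class = "age_structure")
}

band_fraction <- function(ages, band = c("0_99", "25_99", "30_99")) {
  band <- match.arg(band)
  switch(band,
         "0_99" = 1,
         "25_99" = ages$total_25_99 / ages$total_0_99,
         "30_99" = ages$total_30_99 / ages$total_0_99)
}

#' Largest-remainder integer apportionment
#'
#' Allocates an integer `total` across cells proportionally to `weights`,
#' rounding so the allocation sums to `total` exactly: each cell gets the
#' floor of its exact share, and the remaining units go to the cells with
#' the largest fractional parts (ties broken by cell order).
#'
#' @param weights Non-negative weights, not all zero.
#' @param total Non-negative integer total.
#' @return Integer vector summing to `total`.
#' @export
largest_remainder <- function(weights, total) {
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative with a positive sum")
  }
  total <- as.numeric(total)
  q <- total * weights / sum(weights)
  base <- floor(q)
  short <- round(total - sum(base))
  if (short > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Simulate a gridded population raster
#'
#' Allocates the citywide 0-99 population across grid cells. Cell weights
#' combine optional lognormal heterogeneity (`dispersion`) with an optional
#' tilt toward a supplied concentration surface
#' (`concentration_gradient_weight`), which reproduces the situation where
#' people cluster where pollution is high and the population-weighted city
#' mean exceeds the unweighted one. Integer counts are produced by
#' largest-remainder apportionment, so the city total is conserved exactly.
#' Age-band totals ride along as a citywide structure: each cell's band
#' population is its total times the citywide band fraction.
#'
#' @param grid A [grid_spec()].
#' @param ages An [age_structure()].
#' @param surface Optional annual surface tibble to correlate with.
#' @param concentration_gradient_weight Strength of the tilt toward
#'   `surface` (0 = none); the weight multiplies the standardized surface in
#'   the log of the allocation weight.
#' @param dispersion Standard deviation of the lognormal cell heterogeneity
#'   (0 = deterministic allocation).
#' @param seed Integer seed.
#' @return Tibble with `row`, `col`, `persons`, carrying the grid and the
#'   age structure as attributes.
#' @export
simulate_population <- function(grid, ages, surface = NULL,
                                concentration_gradient_weight = 0,
                                dispersion = 0.5, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(ages, "age_structure"))
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  cells <- grid_cells(field_grid(grid_frame(grid)))[, c("row", "col")]
  n <- nrow(cells)
  logw <- if (dispersion > 0) rnorm(n, 0, dispersion) else rep(0, n)
  if (!is.null(surface) && concentration_gradient_weight != 0) {
    check_same_grid(grid_frame(grid), surface)
    s <- surface$value[order(surface$row, surface$col)]
    z <- if (sd(s) > 0) (s - mean(s)) / sd(s) else rep(0, n)
    logw <- logw + concentration_gradient_weight * z
  }
  persons <- largest_remainder(exp(logw), ages$total_0_99)
  out <- tibble(row = cells$row, col = cells$col, persons = persons)
  out <- set_grid(out, grid)
  attr(out, "age_structure") <- ages
  out
}

grid_frame <- function(grid) {
  set_grid(tibble(row = c(0L, grid$n_rows - 1L), col = c(0L, grid$n_cols - 1L)),
           grid)
}

#' Age structure carried by a population raster
#' @param pop Population tibble from [simulate_population()].
#' @return The [age_structure()] attribute.
#' @export
pop_ages <- function(pop) {
  a <- attr(pop, "age_structure", exact = TRUE)
  if (!inherits(a, "age_structure")) abort("population has no age structure")
  a
}

#' Rescale a population raster to future totals
#'
#' Scales every cell by the ratio of the target to the current citywide
#' total, preserving the spatial pattern, then re-apportions to integers so
#' the new total is met exactly. Band totals are replaced by the target
#' structure.
#'
#' @param pop Population tibble.
#' @param target Target [age_structure()].
#' @return Population tibble at the target totals.
#' @examples
#' g <- grid_spec(4, 4)
#' p18 <- simulate_population(g, age_structure(8459139, 6344354, 5921397), seed = 7)
#' p30 <- grow_population(p18, age_structure(9308479, 7488672, 7116333))
#' sum(p30$persons)
#' @export
grow_population <- function(pop, target) {
  stopifnot(inherits(target, "age_structure"))
  cur <- sum(pop$persons)
  if (cur <= 0) abort("current population total is zero", class = "aqhia_division_error")
  out <- pop
  out$persons <- largest_remainder(pop$persons, target$total_0_99)
  attr(out, "age_structure") <- target
  set_grid(out, field_grid(pop))
}

#' Simulate monitor time series with model-relative bias
#'
#' Draws `n_monitors` distinct grid cells and, for each representative
#' month, `n_days` daily observations. Monitor values inflate the model
#' field multiplicatively -- `field / (1 - bias) + noise` -- so a model that
#' underestimates truth by a seasonal fraction `bias` is recoverable by
#' [seasonal_model_bias()].
#'
#' @param fields Monthly field tibble.
#' @param n_monitors Number of monitor cells (the motivating network has 10).
#' @param bias_by_season Named fractions (`winter`, `pre-monsoon`,
#'   `monsoon`, `post-monsoon`): the model's fractional underestimate.
#' @param noise_sd Daily measurement/representation noise sd (ug m-3).
#' @param n_days Observation days per season.
#' @param seed Integer seed.
#' @return Tibble with `monitor_id`, `row`, `col`, `month`, `season`,
#'   `date`, `value`.
#' @export
simulate_monitors <- function(fields, n_monitors = 10L,
                              bias_by_season = c("winter" = 0,
                                                 "pre-monsoon" = 0,
                                                 "monsoon" = 0,
                                                 "post-monsoon" = 0),
                              noise_sd = 0, n_days = 30L, seed = 1L) {
  grid <- field_grid(fields)
  n_cells <- grid$n_rows * grid$n_cols
  if (n_monitors < 1L || n_monitors > n_cells) {
    abort("n_monitors must be between 1 and the number of cells")
  }
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  idx <- sample.int(n_cells, n_monitors)
  sites <- tibble(monitor_id = sprintf("M%02d", seq_len(n_monitors)),
                  row = (idx - 1L) %/% grid$n_cols,
                  col = (idx - 1L) %% grid$n_cols)
  month_start <- c(Jan = "2018-01-01", May = "2018-05-01",
                   Jul = "2018-07-01", Oct = "2018-10-01")
  obs <- tidyr::expand_grid(sites, month = rep_months, day = seq_len(n_days)) %>%
    inner_join(fields, by = c("row", "col", "month")) %>%
    mutate(season = month_season(.data$month),
           bias = unname(bias_by_season[.data$season]),
           date = as.Date(month_start[.data$month]) + .data$day - 1L,
           value = .data$value / (1 - .data$bias) +
             if (noise_sd > 0) rnorm(dplyr::n(), 0, noise_sd) else 0) %>%
    select("monitor_id", "row", "col", "month", "season", "date", "value")
  set_grid(obs, grid)
}
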