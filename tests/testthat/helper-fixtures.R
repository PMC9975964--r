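# Shared fixtures: printed scenario inputs and small synthetic builders.

# Monthly city-mean PM2.5 (ug m-3) per scenario, representative months
# Jan/May/Jul/Oct.
monthly_means <- list(
  baseline_2018 = c(Jan = 74.46, May = 69.72, Jul = 38.95, Oct = 86.20),
  bau_2030      = c(Jan = 92.83, May = 66.51, Jul = 39.52, Oct = 75.15),
  ma_2030       = c(Jan = 92.42, May = 66.37, Jul = 38.13, Oct = 74.95)
)

# Published per-scenario inputs used across tests.
pw_means <- c(baseline_2018 = 71.04, bau_2030 = 75.18, ma_2030 = 70.93)
pop_2030 <- list(total = 9308479, a25 = 7488672, a30 = 7116333)
pop_2018 <- list(total = 8459139, a25 = 6344354, a30 = 5921397)
y0_rate <- 684.21

uniform_fields <- function(grid, means) {
  simulate_background(grid, means, spatial_sd = 0, correlation_length = 1,
                      seed = 1)
}

uniform_surface <- function(grid, value, scenario = NULL) {
  s <- annual_average(uniform_fields(grid, c(Jan = value, May = value,
                                             Jul = value, Oct = value)),
                      scenario = scenario)
  s
}

uniform_pop <- function(grid, ages = age_structure(pop_2018$total,
                                                   pop_2018$a25,
                                                   pop_2018$a30)) {
  simulate_population(grid, ages, dispersion = 0, seed = 1)
}

random_surface <- function(grid, seed, lo = 30, hi = 110) {
  set.seed(seed)
  cells <- grid_cells(grid)[, c("row", "col")]
  s <- tibble::tibble(row = cells$row, col = cells$col,
                      value = stats::runif(nrow(cells), lo, hi))
  attr(s, "grid") <- grid
  s
}

random_pop <- function(grid, seed, ages = age_structure(1e6, 7.5e5, 7e5)) {
  simulate_population(grid, ages, dispersion = 0.6, seed = seed)
}

# Brute-force per-cell HIA loop, independent of the vectorized path.
brute_force_hia <- function(reference, scenario, pop, y0, erf) {
  ages <- pop_ages(pop)
  f <- switch(erf$age_band, "0_99" = 1,
              "25_99" = ages$total_25_99 / ages$total_0_99,
              "30_99" = ages$total_30_99 / ages$total_0_99)
  total <- 0
  for (i in seq_len(nrow(reference))) {
    r <- reference$row[i]; c <- reference$col[i]
    cref <- reference$value[i]
    cscn <- scenario$value[scenario$row == r & scenario$col == c]
    p <- pop$persons[pop$row == r & pop$col == c] * f
    if (inherits(erf, "loglinear_erf")) {
      total <- total + (y0$rate / 1e5) * p *
        (1 - exp(-log(erf$rr_per_10) / 10 * (cscn - cref)))
    } else {
      rr <- function(cc) {
        z <- max(0, cc - erf$c0)
        exp(erf$theta * log(1 + z / erf$alpha) /
              (1 + exp(-(z - erf$mu) / erf$nu)))
      }
      total <- total + (y0$rate / 1e5) * p * (rr(cscn) - rr(cref)) / rr(cscn)
    }
  }
  total
}
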