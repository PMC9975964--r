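test_that("log-linear slope conversion inverts exactly", {
  expect_equal(beta_from_rr(1), 0)
  expect_equal(beta_from_rr(1.06), 0.0058269, tolerance = 1e-5)
  set.seed(5)
  for (rr in stats::runif(10, 0.8, 1.5)) {
    expect_equal(exp(10 * beta_from_rr(rr)), rr, tolerance = 1e-12)
  }
  expect_error(beta_from_rr(0), class = "aqhia_domain_error")
  expect_error(beta_from_rr(-2), class = "aqhia_domain_error")
})

test_that("GEMM relative risk anchors at the counterfactual and is monotone", {
  erf <- gemm_erf()
  expect_identical(gemm_rr(2.4, erf), 1)
  expect_identical(gemm_rr(0, erf), 1)
  expect_equal(gemm_rr(71.04, erf), 1.5489, tolerance = 5e-4)
  sweep <- gemm_rr(seq(0, 150, by = 0.5), erf)
  expect_true(all(diff(sweep) >= 0))
  expect_error(gemm_rr(-1, erf))
  expect_error(gemm_erf(alpha = -1))
})

test_that("aggregate log-linear deaths follow the attributable-fraction formula", {
  y0 <- baseline_mortality(y0_rate, "30_99")
  erf <- loglinear_erf(1.06, ci = c(1.04, 1.08))
  expect_equal(attributable_deaths_loglinear(y0, 1e6, 0, erf), 0)
  # printed aggregate inputs under the headline RR of 1.06
  d <- attributable_deaths_loglinear(y0, pop_2030$a30, 4.14, erf)
  expect_equal(d, 1160.5, tolerance = 1e-4)
  # Taylor limit: linear in beta * dC when small
  small <- attributable_deaths_loglinear(y0, 1e6, 0.01, erf)
  expect_equal(small, (y0_rate / 1e5) * 1e6 * erf$beta * 0.01,
               tolerance = 0.01)
  # negative change gives avoided (negative) deaths
  expect_lt(attributable_deaths_loglinear(y0, 1e6, -5, erf), 0)
})

test_that("aggregate GEMM deaths use the risk-ratio form", {
  y0 <- baseline_mortality(y0_rate, "30_99")
  erf <- gemm_erf()
  expect_equal(attributable_deaths_rr_ratio(y0, 1e6, 50, 50, erf), 0)
  d <- attributable_deaths_rr_ratio(y0, pop_2030$a25, 75.18, 71.04, erf)
  expect_equal(d, 805.0, tolerance = 1e-3)
})

test_that("cellwise HIA equals the aggregate formula on uniform inputs and a brute-force loop on random ones", {
  g <- grid_spec(5, 5)
  y0 <- baseline_mortality(y0_rate, "30_99")
  pop <- uniform_pop(g, age_structure(1e6, 7.5e5, 7e5))
  ref <- uniform_surface(g, 71.04)
  scn <- uniform_surface(g, 75.18)
  for (erf in default_erfs()) {
    res <- cellwise_hia(ref, scn, pop, y0, erf)
    f <- if (erf$age_band == "30_99") 0.7 else if (erf$age_band == "25_99") 0.75 else 1
    agg <- if (inherits(erf, "loglinear_erf")) {
      attributable_deaths_loglinear(y0, 1e6 * f, 75.18 - 71.04, erf)
    } else {
      attributable_deaths_rr_ratio(y0, 1e6 * f, 75.18, 71.04, erf)
    }
    expect_equal(res$excess_deaths, agg, tolerance = 1e-9)
    # identical scenarios: exactly zero
    zero <- cellwise_hia(ref, ref, pop, y0, erf)
    expect_equal(zero$excess_deaths, 0)
    expect_equal(zero$af, 0)
  }
  # random heterogeneous surfaces against the independent loop oracle
  for (s in 1:5) {
    r <- random_surface(g, seed = s)
    x <- random_surface(g, seed = s + 100)
    p <- random_pop(g, seed = s)
    for (erf in default_erfs()) {
      res <- cellwise_hia(r, x, p, y0, erf)
      expect_equal(res$excess_deaths, brute_force_hia(r, x, p, y0, erf),
                   tolerance = 1e-9)
    }
  }
  expect_error(cellwise_hia(ref, uniform_surface(grid_spec(3, 3), 10), pop,
                            y0, gemm_erf()),
               class = "aqhia_grid_mismatch")
})

test_that("confidence intervals bracket the central estimate and flip with the sign of the change", {
  g <- grid_spec(4, 4)
  y0 <- baseline_mortality(y0_rate, "30_99")
  pop <- uniform_pop(g, age_structure(1e6, 7.5e5, 7e5))
  ref <- uniform_surface(g, 71.04)
  up <- uniform_surface(g, 75.18)
  down <- uniform_surface(g, 70.93)
  for (erf in default_erfs()) {
    pos <- cellwise_hia(ref, up, pop, y0, erf)
    ci <- confidence_interval(pos)
    expect_lte(ci[["lo"]], pos$excess_deaths)
    expect_gte(ci[["hi"]], pos$excess_deaths)
    neg <- cellwise_hia(ref, down, pop, y0, erf)
    # avoided deaths: bounds are both negative and the order reverses
    expect_lt(neg$hi, neg$excess_deaths)
    expect_gt(neg$lo, neg$excess_deaths)
    expect_true(all(c(neg$lo, neg$hi) < 0))
  }
  # degenerate CI collapses to a point; absent CI raises
  point <- loglinear_erf(1.06, ci = c(1.06, 1.06))
  res <- cellwise_hia(ref, up, pop, y0, point)
  expect_equal(res$lo, res$excess_deaths)
  expect_equal(res$hi, res$excess_deaths)
  no_ci <- cellwise_hia(ref, up, pop, y0, loglinear_erf(1.06))
  expect_error(confidence_interval(no_ci), class = "aqhia_missing_ci")
})

test_that("attributable fraction and scale invariances hold", {
  g <- grid_spec(4, 4)
  y0 <- baseline_mortality(y0_rate, "30_99")
  pop <- uniform_pop(g, age_structure(1e6, 7.5e5, 7e5))
  ref <- uniform_surface(g, 71.04)
  for (erf in default_erfs()) {
    up <- cellwise_hia(ref, uniform_surface(g, 90), pop, y0, erf)
    expect_gte(up$af, 0); expect_lt(up$af, 1)
    down <- cellwise_hia(ref, uniform_surface(g, 50), pop, y0, erf)
    expect_lte(down$af, 0); expect_gt(down$af, -1)
    # deaths scale linearly with population and baseline rate
    pop2 <- pop; pop2$persons <- pop$persons * 2L
    attr(pop2, "age_structure") <- age_structure(2e6, 1.5e6, 1.4e6)
    expect_equal(cellwise_hia(ref, uniform_surface(g, 90), pop2, y0,
                              erf)$excess_deaths,
                 2 * up$excess_deaths, tolerance = 1e-9)
    y0x <- baseline_mortality(2 * y0_rate, "30_99")
    expect_equal(cellwise_hia(ref, uniform_surface(g, 90), pop, y0x,
                              erf)$excess_deaths,
                 2 * up$excess_deaths, tolerance = 1e-9)
  }
})

test_that("heterogeneous exposure reductions avoid at least as many deaths cellwise as in aggregate", {
  # per-cell avoided deaths are convex in the size of the reduction, so a
  # heterogeneous reduction pattern beats the same mean reduction applied
  # uniformly (Jensen)
  g <- grid_spec(4, 4)
  y0 <- baseline_mortality(y0_rate, "30_99")
  pop <- uniform_pop(g, age_structure(1e6, 7.5e5, 7e5))
  ref <- uniform_surface(g, 80)
  scn <- ref
  set.seed(77)
  drop <- stats::runif(nrow(ref), 0, 30)
  scn$value <- ref$value - drop
  erf <- loglinear_erf(1.06, ci = c(1.04, 1.08))
  cellwise <- cellwise_hia(ref, scn, pop, y0, erf)$excess_deaths
  aggregate <- attributable_deaths_loglinear(y0, 1e6 * 0.7, -mean(drop), erf)
  expect_lte(cellwise, aggregate)
  expect_lt(cellwise, 0)
})

test_that("scenario antisymmetry holds up to the documented exponential bound", {
  g <- grid_spec(5, 5)
  y0 <- baseline_mortality(y0_rate, "30_99")
  pop <- random_pop(g, seed = 19)
  erf <- loglinear_erf(1.06, ci = c(1.04, 1.08))
  a <- random_surface(g, seed = 20, lo = 60, hi = 70)
  b <- random_surface(g, seed = 21, lo = 75, hi = 95) # deltas all one sign
  d_ab <- cellwise_hia(a, b, pop, y0, erf)$excess_deaths
  d_ba <- cellwise_hia(b, a, pop, y0, erf)$excess_deaths
  max_dc <- max(abs(b$value - a$value))
  bound <- (exp(erf$beta * max_dc) - 1) * abs(d_ab)
  expect_lte(abs(d_ab + d_ba), bound + 1e-9)
  # and the two directions agree to first order
  expect_equal(d_ab, -d_ba, tolerance = exp(erf$beta * max_dc) - 1)
})

test_that("mortality-rate changes derive from the package's own death counts", {
  y0 <- baseline_mortality(y0_rate, "30_99")
  fake <- structure(list(excess_deaths = 0, pop_band = pop_2030$a30, y0 = y0),
                    class = "hia_result")
  r0 <- mortality_rate_change(fake)
  expect_equal(r0$scenario_rate, y0_rate)
  expect_equal(r0$pct_change, 0)
  # an excess of 1389 deaths over the 30-99 population lifts the rate by
  # about 19.52 per 100 000
  fake$excess_deaths <- 1389
  r <- mortality_rate_change(fake)
  expect_equal(r$scenario_rate - y0_rate, 19.52, tolerance = 1e-4)
  # a printed rate/percent pair is internally consistent under this formula
  excess_from_rate <- (707.95 - y0_rate) * pop_2030$a30 / 1e5
  fake$excess_deaths <- excess_from_rate
  r2 <- mortality_rate_change(fake)
  expect_equal(r2$scenario_rate, 707.95, tolerance = 1e-9)
  expect_equal(r2$pct_change, 3.47, tolerance = 2e-3)
})

test_that("rollback scales the surface onto the target and leaves attaining surfaces alone", {
  g <- grid_spec(5, 5)
  pop <- random_pop(g, seed = 23)
  s <- random_surface(g, seed = 23, lo = 50, hi = 95)
  base_mean <- population_weighted_mean(s, pop)

  ncap <- rollback_to_target(s, pop, attainment_target("NCAP"),
                             baseline_mean = 71.04)
  expect_equal(population_weighted_mean(ncap, pop), 71.04 * 0.7,
               tolerance = 1e-9)
  expect_equal(71.04 * 0.7, 49.728) # 30% reduction arithmetic

  who <- rollback_to_target(s, pop, attainment_target("WHO_AQG"))
  expect_equal(population_weighted_mean(who, pop), 5, tolerance = 1e-9)
  # proportional rollback preserves the spatial pattern
  expect_equal(who$value / s$value, rep(5 / base_mean, nrow(s)),
               tolerance = 1e-9)

  low <- rollback_to_target(uniform_surface(g, 30), pop,
                            attainment_target("NAAQS"))
  expect_equal(low$value, rep(30, nrow(low)))
  # cap method never exceeds the goal in any cell
  capped <- rollback_to_target(s, pop, attainment_target("NAAQS"),
                               method = "cap")
  expect_true(all(capped$value <= 40 + 1e-12))
})

test_that("attainment benefits are ordered by target depth and match a two-scenario HIA", {
  g <- grid_spec(5, 5)
  pop <- random_pop(g, seed = 25)
  y0 <- baseline_mortality(y0_rate, "30_99")
  bau <- random_surface(g, seed = 25, lo = 60, hi = 95)
  targets <- list(attainment_target("NCAP"), attainment_target("NAAQS"),
                  attainment_target("WHO_AQG"))
  tbl <- attainment_benefit(bau, targets, pop, y0,
                            baseline_mean = 71.04)
  for (col in c("avoided_pope", "avoided_turner", "avoided_burnett")) {
    v <- setNames(tbl[[col]], tbl$target)
    expect_gt(v[["WHO_AQG"]], v[["NAAQS"]])
    expect_gt(v[["NAAQS"]], v[["NCAP"]])
  }
  # equivalence with an explicit rollback + cellwise HIA, via the loop oracle
  rolled <- rollback_to_target(bau, pop, attainment_target("NAAQS"))
  avoided_naaqs <- tbl[tbl$target == "NAAQS", ]
  erfs <- default_erfs()
  for (nm in names(erfs)) {
    oracle <- -brute_force_hia(bau, rolled, pop, y0, erfs[[nm]])
    expect_equal(avoided_naaqs[[paste0("avoided_", nm)]], oracle,
                 tolerance = 1e-9)
  }
  # a target above the current mean avoids nothing
  high <- attainment_benefit(uniform_surface(g, 20),
                             list(attainment_target("NAAQS")), pop, y0)
  expect_equal(high$max_avoided, 0)
})
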