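test_that("degenerate budgets behave as documented", {
  iv <- fixture_quietly()

  # zero budget: nothing covered, no underspend left over
  s0 <- solve_quietly(iv, uhc_config(budget = 0))
  expect_true(all(s0$results$coverage == 0))
  expect_equal(s0$underspend, 0)
  expect_error(marginal_productivity(s0), class = "uhc_empty_solution")

  # slack budget: interventions whose fitted benefit never declines reach
  # 100%; the two all-zero-benefit interventions stay out; interventions
  # whose rounded anchors make the fitted benefit dip near full coverage
  # (measles, zinc, syphilis) stop where further spending would buy a
  # strictly negative health increment
  big <- uhc_config(budget = 1e9)
  s1 <- solve_quietly(iv, big)
  zero_ids <- c("iptp", "malnutrition")
  dip_ids <- c("measles", "zinc", "syphilis")
  full_ids <- setdiff(iv$id, c(zero_ids, dip_ids))
  cov <- stats::setNames(s1$results$coverage, s1$results$id)
  expect_true(all(cov[full_ids] == 1))
  expect_true(all(cov[zero_ids] == 0))
  expect_true(all(cov[dip_ids] >= 0.85 & cov[dip_ids] < 1))
  expect_equal(s1$underspend, big$budget - s1$totals$spend, tolerance = 1e-9)
  expect_gt(s1$underspend, 0)
})

test_that("the underspend loop admits a skipped cheap alternative on a later pass", {
  # three interventions on a two-step grid; pass 1 admits both steps of A
  # (ICER 1), breaks on B's unaffordable step (ICER 1.2), and strands a
  # budget of exactly C's two cheap steps (ICER 1.5), which the second pass
  # picks up; confirmed equal to the exhaustive integral optimum
  iv <- dplyr::bind_rows(
    linear_record("A", cost_slope = 2, benefit_slope = 2, pop = 100),
    linear_record("B", cost_slope = 3, benefit_slope = 2.5, pop = 100),
    linear_record("C", cost_slope = 0.4, benefit_slope = 0.4 / 1.5, pop = 100)
  )
  cfg <- coarse_config(budget = 240, weights = unit_weights())
  sol <- solve_package(iv, cfg)
  expect_equal(stats::setNames(sol$results$coverage, sol$results$id),
               c(A = 1, B = 0, C = 1))
  passes <- sol$iteration_log$pass[sol$iteration_log$id == "C"]
  expect_true(all(passes >= 2))
  expect_equal(sol$underspend, 0, tolerance = 1e-9)

  bf <- brute_force_optimum(iv, cfg, mode = "integral")
  expect_equal(sol$totals$dalys, bf$total_benefit, tolerance = 1e-9)
})

test_that("solutions respect feasibility, contiguity and the single-fractional rule", {
  iv <- fixture_quietly()
  for (scen in c("variable_coverage", "equity_weighted", "all_or_nothing")) {
    cfg <- uhc_config(conversion_factor = 4.3, scenario = scen)
    sol <- solve_quietly(iv, cfg)
    expect_lte(sol$totals$spend, cfg$budget * (1 + 1e-6))
    expect_lte(sum(sol$results$fractional), 1)
    grid <- if (scen == "all_or_nothing") c(0, cfg$all_or_nothing_level) else
      coverage_grid(cfg)
    off_grid <- vapply(sol$results$coverage[!sol$results$fractional],
                       function(th) min(abs(th - grid)) > 1e-9, logical(1))
    expect_false(any(off_grid))
    # totals are the column sums of the per-intervention table
    expect_equal(sol$totals$dalys, sum(sol$results$dalys), tolerance = 1e-9)
    expect_equal(sol$totals$spend, sum(sol$results$spend), tolerance = 1e-9)
  }
})

test_that("unit equity weights reproduce the unweighted scenario exactly", {
  iv <- fixture_quietly()
  cfg1 <- uhc_config(conversion_factor = 4.3)
  cfg2 <- uhc_config(conversion_factor = 4.3, scenario = "equity_weighted",
                     weights = unit_weights())
  s1 <- solve_quietly(iv, cfg1)
  s2 <- solve_quietly(iv, cfg2)
  expect_equal(s1$results$coverage, s2$results$coverage, tolerance = 1e-12)
  expect_equal(s1$totals$dalys, s2$totals$dalys, tolerance = 1e-9)
})

test_that("jointly scaling costs and budget leaves the coverage vector unchanged", {
  iv <- fixture_quietly()
  base <- uhc_config(conversion_factor = 4.3)
  scaled <- uhc_config(conversion_factor = 4.3 * 11, budget = 15e6 * 11)
  s1 <- solve_quietly(iv, base)
  s2 <- solve_quietly(iv, scaled)
  expect_equal(s1$results$coverage, s2$results$coverage, tolerance = 1e-12)
})

test_that("marginal productivity reports the terminal ICER and league exceptions", {
  # single fully funded intervention: marginal ICER is its last step's ICER
  rec <- linear_record("solo", cost_slope = 2, benefit_slope = 1, pop = 100)
  cfg <- coarse_config(budget = 1000, weights = unit_weights())
  sol <- solve_package(rec, cfg)
  expect_equal(sol$results$coverage, 1)
  m <- marginal_productivity(sol)
  expect_equal(as.numeric(m), 2, tolerance = 1e-9)
  expect_identical(nrow(attr(m, "exceptions")), 0L)

  # fixture run: any increments admitted above the marginal ICER by the
  # reallocation loop are surfaced, not hidden
  iv <- fixture_quietly()
  sfix <- solve_quietly(iv, uhc_config(conversion_factor = 4.3))
  mfix <- marginal_productivity(sfix)
  exc <- attr(mfix, "exceptions")
  expect_true(all(exc$icer > as.numeric(mfix)))
})

test_that("the greedy fill stops at the first unaffordable alternative when reallocation is off", {
  iv <- dplyr::bind_rows(
    linear_record("A", cost_slope = 2, benefit_slope = 2, pop = 100),
    linear_record("B", cost_slope = 3, benefit_slope = 2.5, pop = 100),
    linear_record("C", cost_slope = 0.4, benefit_slope = 0.4 / 1.5, pop = 100)
  )
  cfg <- coarse_config(budget = 240, weights = unit_weights())
  sol <- solve_package(iv, cfg, reallocate_underspend = FALSE)
  # C is never reached; the stranded budget goes fractionally into B
  expect_equal(sol$results$coverage[sol$results$id == "C"], 0)
  expect_true(sol$results$fractional[sol$results$id == "B"])
  expect_equal(sol$results$coverage[sol$results$id == "B"], 40 / 150 * 0.5,
               tolerance = 1e-9)
})

test_that("conversion-factor calibration finds the landmark band deterministically", {
  # closed form: the full-coverage landmark factor is budget / total cost
  iv <- fixture_quietly()
  cal <- calibrate_conversion(iv, uhc_config(),
                              landmark = list(type = "full_coverage"))
  curves <- fit_curves(iv)
  total <- sum(vapply(seq_len(nrow(iv)), function(i) {
    cv <- curves[curves$id == iv$id[i] & curves$quantity == "cost", ]
    cumulative_total(cv, 1, iv$incident_population[i])
  }, numeric(1)))
  expect_equal(cal$factor, 15e6 / total, tolerance = 1e-12)

  # fractional-band landmark on a controlled instance: B is the marginal
  # intervention, fractional between 50% and 100% on the coarse grid
  iv2 <- dplyr::bind_rows(
    linear_record("A", cost_slope = 2, benefit_slope = 2, pop = 100),
    linear_record("B", cost_slope = 3, benefit_slope = 1, pop = 100)
  )
  cfg <- coarse_config(budget = 400, weights = unit_weights())
  cal2 <- calibrate_conversion(
    iv2, cfg,
    landmark = list(type = "fractional_band", id = "B", lower = 0.5, upper = 1),
    bracket = c(0.5, 50)
  )
  sol <- cal2$solution
  covB <- sol$results$coverage[sol$results$id == "B"]
  expect_true(sol$results$fractional[sol$results$id == "B"])
  expect_gt(covB, 0.5)
  expect_lt(covB, 1)
  expect_true(cal2$factor >= cal2$bracket[1] && cal2$factor <= cal2$bracket[2])

  # re-running at the returned factor reproduces the landmark (self-consistency)
  cfg2 <- cfg
  cfg2$conversion_factor <- cal2$factor
  sol2 <- solve_package(iv2, cfg2)
  expect_equal(sol2$results$coverage, sol$results$coverage, tolerance = 1e-9)

  # a landmark on an intervention that can never be covered is reported as
  # unattainable with the bracket-end diagnostics
  iv3 <- dplyr::bind_rows(iv2, linear_record("Z", cost_slope = 1,
                                             benefit_slope = 0, pop = 100))
  expect_error(
    calibrate_conversion(
      iv3, cfg,
      landmark = list(type = "fractional_band", id = "Z", lower = 0.5,
                      upper = 1),
      bracket = c(0.5, 50)
    ),
    class = "uhc_calibration_error"
  )
})

test_that("evaluate_coverage matches the solver's accounting at grid and fractional levels", {
  iv <- fixture_quietly()
  cfg <- uhc_config(conversion_factor = 4.3)
  sol <- solve_quietly(iv, cfg)
  ev <- suppressWarnings(
    evaluate_coverage(iv, stats::setNames(sol$results$coverage,
                                          sol$results$id), cfg)
  )
  expect_equal(ev$dalys, sol$results$dalys, tolerance = 1e-9)
  expect_equal(ev$weighted_dalys, sol$results$weighted_dalys, tolerance = 1e-9)
  expect_equal(ev$spend, sol$results$spend, tolerance = 1e-9)
})
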