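#' Generate a synthetic intervention table
#'
#' Samples per-intervention cost and benefit polynomials through the origin
#' and evaluates them at the 50/80/95% anchors, so that [fit_anchor_curve()]
#' recovers the sampled coefficients exactly (at zero anchor noise). Defaults
#' emulate the qualitative regime of the WHO-CHOICE data as the optimization
#' assumes it: cumulative costs convex and strictly increasing (marginal unit
#' cost non-decreasing in coverage, including the constant-increment segment
#' below 50%) and cumulative benefits concave and increasing (marginal
#' benefit non-increasing). In this regime every 5% step ICER is
#' non-decreasing with coverage, so dominance elimination is a no-op and the
#' league-table procedure attains the divisible-knapsack optimum.
#'
#' @param n Number of interventions.
#' @param seed Integer seed; the generator is deterministic given `seed`.
#' @param pop_range Range of incident populations (persons/year).
#' @param cost_slope_range,cost_curv_range Ranges of the cost polynomial's
#'   linear slope `b1` and curvature `b2` in
#'   `cost(theta) = b1 * theta + b2 * theta^2` (2000 Int$ per capita;
#'   curvature must be >= 0 for convex costs).
#' @param benefit_slope_range,benefit_curv_range Ranges of the benefit
#'   polynomial's marginal benefit at full coverage and curvature
#'   (curvature must be <= 0 for concave benefits).
#' @param noise Relative multiplicative anchor noise (0 = exact polynomial
#'   anchors); noisy anchors are re-sorted to keep monotonicity.
#' @return A tibble in the schema of [read_interventions()].
#' @export
#' @examples
#' simulate_interventions(4, seed = 1)
simulate_interventions <- function(n,
                                   seed = 1L,
                                   pop_range = c(5e4, 5e6),
                                   cost_slope_range = c(0.05, 1),
                                   cost_curv_range = c(0, 1),
                                   benefit_slope_range = c(0.001, 0.05),
                                   benefit_curv_range = c(-0.02, 0),
                                   noise = 0) {
  stopifnot(n >= 1)
  if (cost_curv_range[1] < 0 || benefit_curv_range[2] > 0) {
    abort("defaults require convex costs (curvature >= 0) and concave benefits (curvature <= 0)",
          class = "uhc_spec_error")
  }
  withr::with_seed(as.integer(seed), {
    anchors <- c(0.5, 0.8, 0.95)
    purrr::map_dfr(seq_len(n), function(i) {
      pop <- round(stats::runif(1, pop_range[1], pop_range[2]))
      # convex cost through the origin: positive slope, curvature >= 0
      b2c <- stats::runif(1, cost_curv_range[1], cost_curv_range[2])
      b1c <- stats::runif(1, cost_slope_range[1], cost_slope_range[2])
      cost <- b1c * anchors + b2c * anchors^2
      # concave benefit through the origin, marginal benefit at 1 positive
      b2b <- stats::runif(1, benefit_curv_range[1], benefit_curv_range[2])
      s1 <- stats::runif(1, benefit_slope_range[1], benefit_slope_range[2])
      b1b <- s1 - 2 * b2b
      ben <- b1b * anchors + b2b * anchors^2
      if (noise > 0) {
        cost <- sort(pmax(cost * (1 + stats::rnorm(3, sd = noise)), 0))
        ben <- sort(pmax(ben * (1 + stats::rnorm(3, sd = noise)), 0))
      }
      if (any(cost < 0) || any(ben < 0)) {
        abort("sampled curvature ranges force negative anchor values",
              class = "uhc_spec_error")
      }
      tibble::tibble(
        id = sprintf("synth_%02d", i),
        name = sprintf("Synthetic intervention %02d", i),
        incident_population = pop,
        population_definition = "synthetic",
        cost_50 = cost[1], cost_80 = cost[2], cost_95 = cost[3],
        dalys_50 = ben[1], dalys_80 = ben[2], dalys_95 = ben[3]
      )
    })
  })
}

#' Exact brute-force optimum for small instances
#'
#' Independent oracle for the league-table solver. `mode = "integral"`
#' exhaustively enumerates every grid coverage vector within budget and
#' maximizes total effective benefit. `mode = "divisible_last"` additionally
#' allows a single intervention to advance one fractional grid step beyond
#' its level, with benefit linear in the leftover spend (the relaxation the
#' greedy procedure's terminal scale-up targets); the best top-up is computed
#' in closed form for each enumerated vector.
#'
#' @param interventions An intervention table with at most 6 rows.
#' @param config A `uhc_config`; the grid may have at most 12 levels. Under
#'   the `equity_weighted` scenario the objective is weighted benefit.
#' @param mode `"integral"` or `"divisible_last"`.
#' @return A list with `total_benefit`, `coverage` (named vector of the best
#'   grid vector), and `mode`.
#' @export
brute_force_optimum <- function(interventions, config = uhc_config(),
                                mode = c("integral", "divisible_last")) {
  mode <- match.arg(mode)
  validate_interventions(interventions)
  grid <- coverage_grid(config)
  n <- nrow(interventions)
  if (n > 6 || length(grid) > 12) {
    abort("enumeration bound exceeded: at most 6 interventions and 12 grid levels",
          class = "uhc_size_error")
  }
  weighted <- identical(config$scenario, "equity_weighted")
  curves <- fit_curves(interventions, grid_floor = config$grid_floor)
  L <- length(grid)
  cost_m <- matrix(0, n, L)
  ben_m <- matrix(0, n, L)
  for (i in seq_len(n)) {
    rec <- interventions[i, ]
    ccost <- curves[curves$id == rec$id & curves$quantity == "cost", ]
    cben <- curves[curves$id == rec$id & curves$quantity == "benefit", ]
    cost_m[i, ] <- cumulative_total(ccost, grid, rec$incident_population) *
      config$conversion_factor
    if (weighted) {
      ben_m[i, ] <- c(0, vapply(grid[-1], function(th) {
        apply_equity_weights(0, th, cben, config$weights,
                             rec$incident_population)
      }, numeric(1)))
    } else {
      ben_m[i, ] <- cumulative_total(cben, grid, rec$incident_population)
    }
  }
  g <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  tot_c <- rowSums(matrix(cost_m[cbind(rep(seq_len(n), each = nrow(g)), c(g))],
                          nrow(g), n))
  tot_b <- rowSums(matrix(ben_m[cbind(rep(seq_len(n), each = nrow(g)), c(g))],
                          nrow(g), n))
  feasible <- tot_c <= config$budget + 1e-6 * max(config$budget, 1)
  if (!any(feasible)) {
    return(list(total_benefit = 0,
                coverage = stats::setNames(rep(0, n), interventions$id),
                mode = mode))
  }
  g <- g[feasible, , drop = FALSE]
  tot_c <- tot_c[feasible]
  tot_b <- tot_b[feasible]
  if (mode == "divisible_last") {
    leftover <- config$budget - tot_c
    gain <- rep(0, nrow(g))
    for (i in seq_len(n)) {
      idx <- g[, i]
      nxt <- pmin(idx + 1L, L)
      dc <- cost_m[i, nxt] - cost_m[i, idx]
      db <- ben_m[i, nxt] - ben_m[i, idx]
      ok <- dc > 0 & db > 0
      gi <- ifelse(ok, pmin(leftover, dc) * db / pmax(dc, 1e-300), 0)
      gain <- pmax(gain, gi)
    }
    tot_b <- tot_b + gain
  }
  best <- which.max(tot_b)
  list(
    total_benefit = tot_b[best],
    coverage = stats::setNames(grid[g[best, ]], interventions$id),
    mode = mode
  )
}

#' Property-checking suite for the optimizer
#'
#' Generates seeded synthetic instances and checks the solver's structural
#' guarantees on each: budget feasibility, contiguous coverage with at most
#' one fractional intervention, total benefit monotone in budget, identity of
#' the equity-weighted scenario with unit weights and the unweighted
#' scenario, scale invariance of the coverage vector under joint cost/budget
#' scaling, and agreement with the brute-force oracles (greedy total at least
#' the integral optimum, equal to the divisible-last optimum within
#' tolerance). Failures are rows of the returned report, not errors.
#'
#' @param n_instances Number of synthetic instances.
#' @param n Interventions per instance (oracle checks require `n <= 6`).
#' @param seed Base seed; instance `k` uses `seed + k`.
#' @param grid_floor,grid_step Coverage grid for the instances.
#' @param budget_fraction Budget as a fraction of each instance's total cost
#'   at full coverage. The default (0.7) reproduces the configuration the
#'   procedure is designed for: every worthwhile intervention's entry block
#'   (0 to `grid_floor`) is affordable and the budget binds among 5%
#'   scale-up steps, as in the published application.
#' @param sweep_points Number of budgets in the monotonicity sweep (run on
#'   the first instance only).
#' @return A tibble with columns `instance`, `seed`, `check`, `pass`,
#'   `detail`.
#' @export
#' @examples
#' report <- validate_optimizer(n_instances = 3, n = 3, seed = 7,
#'                              grid_step = 0.25)
#' all(report$pass)
validate_optimizer <- function(n_instances = 20, n = 4, seed = 1L,
                               grid_floor = 0.5, grid_step = 0.1,
                               budget_fraction = 0.7, sweep_points = 10) {
  oracle_ok <- n <= 6 && length(c(0, seq(grid_floor, 1, grid_step))) <= 12
  purrr::map_dfr(seq_len(n_instances), function(k) {
    inst_seed <- as.integer(seed) + k
    recs <- simulate_interventions(n, seed = inst_seed)
    curves <- fit_curves(recs, grid_floor = grid_floor)
    full_cost <- sum(purrr::map_dbl(seq_len(n), function(i) {
      cv <- curves[curves$id == recs$id[i] & curves$quantity == "cost", ]
      cumulative_total(cv, 1, recs$incident_population[i])
    }))
    cfg <- uhc_config(budget = budget_fraction * full_cost,
                      grid_floor = grid_floor, grid_step = grid_step,
                      seed = inst_seed)
    sol <- solve_package(recs, cfg)
    checks <- list()
    add <- function(check, pass, detail = "") {
      checks[[length(checks) + 1]] <<- tibble::tibble(
        instance = k, seed = inst_seed, check = check,
        pass = pass, detail = detail
      )
    }
    tol <- 1e-6 * max(cfg$budget, 1)
    add("budget_feasibility", sol$totals$spend <= cfg$budget + tol,
        sprintf("spend %.2f of %.2f", sol$totals$spend, cfg$budget))
    add("single_fractional", sum(sol$results$fractional) <= 1)
    on_grid <- vapply(sol$results$coverage[!sol$results$fractional],
                      function(th) {
                        min(abs(th - coverage_grid(cfg))) < 1e-9
                      }, logical(1))
    add("coverage_on_grid", all(on_grid))

    cfg_unit <- cfg
    cfg_unit$scenario <- "equity_weighted"
    cfg_unit$weights <- unit_weights()
    sol_unit <- solve_package(recs, cfg_unit)
    add("unit_weights_identity",
        isTRUE(all.equal(sol$results$coverage, sol_unit$results$coverage,
                         tolerance = 1e-9)))

    cfg_scaled <- cfg
    cfg_scaled$conversion_factor <- cfg$conversion_factor * 7
    cfg_scaled$budget <- cfg$budget * 7
    sol_scaled <- solve_package(recs, cfg_scaled)
    add("scale_invariance",
        isTRUE(all.equal(sol$results$coverage, sol_scaled$results$coverage,
                         tolerance = 1e-9)))

    if (oracle_ok) {
      # the optimality guarantee is for greedy fill + terminal fractional
      # step; the underspend-reallocation loop is a published heuristic that
      # may trade the fractional increment for whole higher-ICER increments
      sol_fill <- solve_package(recs, cfg, reallocate_underspend = FALSE)
      integral <- brute_force_optimum(recs, cfg, mode = "integral")
      divisible <- brute_force_optimum(recs, cfg, mode = "divisible_last")
      add("greedy_ge_integral",
          sol_fill$totals$dalys >= integral$total_benefit - 1e-6 * max(integral$total_benefit, 1),
          sprintf("greedy %.4f vs integral %.4f", sol_fill$totals$dalys,
                  integral$total_benefit))
      add("greedy_eq_divisible",
          isTRUE(all.equal(sol_fill$totals$dalys, divisible$total_benefit,
                           tolerance = 1e-6)),
          sprintf("greedy %.4f vs divisible %.4f", sol_fill$totals$dalys,
                  divisible$total_benefit))
    } else {
      add("greedy_ge_integral", NA, "skipped: above enumeration bound")
      add("greedy_eq_divisible", NA, "skipped: above enumeration bound")
    }

    if (k == 1) {
      budgets <- seq(0, full_cost, length.out = sweep_points)
      benefits <- purrr::map_dbl(budgets, function(b) {
        cfg_b <- cfg
        cfg_b$budget <- b
        solve_package(recs, cfg_b)$totals$dalys
      })
      add("benefit_monotone_in_budget",
          all(diff(benefits) >= -1e-6 * max(benefits, 1)),
          sprintf("sweep over %d budgets", sweep_points))
    }
    dplyr::bind_rows(checks)
  })
}
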