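#' Solve the budget-constrained benefit-package problem
#'
#' Runs the full league-table procedure for the configured scenario:
#'
#' 1. **Dominance screening** — within each intervention, strictly and
#'    extended-dominated coverage steps are merged forward until ICERs are
#'    non-decreasing in coverage ([eliminate_dominated()]).
#' 2. **Greedy fill** — non-dominated alternatives are admitted across
#'    interventions in ascending ICER order (respecting within-intervention
#'    coverage order) until the next alternative cannot be afforded.
#' 3. **Underspend reallocation** — alternatives whose cumulative cost from
#'    the current coverage exceeds the remaining budget are dropped, ICERs are
#'    recomputed incremental to current coverage (previously dominated steps
#'    may re-enter), and the fill repeats until no whole alternative is
#'    affordable. Finally the single next 5% increment with the lowest ICER
#'    is funded fractionally, coverage advancing linearly in spend, until the
#'    budget is exhausted.
#'
#' Scenarios: `"variable_coverage"` ranks unweighted ICERs;
#' `"equity_weighted"` ranks ICERs computed on equity-weighted benefits;
#' `"all_or_nothing"` gives each intervention a single alternative from 0 to
#' `all_or_nothing_level` with cost and benefit linear through the origin
#' (the only known points being do-nothing and the 95% anchor), with the
#' terminal fractional step allowed. All scenarios report both weighted and
#' unweighted DALY totals.
#'
#' Interventions with no positive effective benefit at any coverage (e.g.
#' printed benefits of 0.000 at every anchor) are never admitted. Coverage is
#' always contiguous: a funded level implies all lower levels are funded, and
#' at most one intervention ends at an off-grid (fractional) coverage.
#'
#' @param interventions An intervention table (see [read_interventions()]).
#' @param config A [uhc_config()].
#' @param reallocate_underspend Run the underspend-reallocation loop (step 3)?
#'   Default `TRUE`, the full published procedure. With `FALSE` the solve
#'   stops after the single greedy pass and goes straight to the terminal
#'   fractional step; in the regime of non-decreasing step ICERs this variant
#'   attains the optimum of the divisible (linear-programming) relaxation
#'   exactly, whereas the reallocation loop may trade the fractional
#'   increment for affordable whole increments with higher ICERs.
#' @return An object of class `uhc_solution`: a list with `results` (one row
#'   per intervention: `coverage`, `spend`, `dalys`, `weighted_dalys`,
#'   `icer_at_coverage`, `fractional`), `totals`, `underspend_pre_fractional`
#'   (budget remaining when the reallocation loop exits, before the
#'   fractional scale-up), `underspend` (after it), `marginal_icer`,
#'   `marginal_id`, `iteration_log`, and the echoed `config`.
#'   Use [tidy()] / [glance()] / [autoplot()] to inspect it.
#' @export
#' @examples
#' sol <- solve_package(who_choice_afr_e(), uhc_config(conversion_factor = 4.3))
#' glance(sol)
#' tidy(sol)
solve_package <- function(interventions, config = uhc_config(),
                          reallocate_underspend = TRUE) {
  validate_interventions(interventions)
  stopifnot(inherits(config, "uhc_config"))
  if (identical(config$scenario, "all_or_nothing")) {
    steps <- all_or_nothing_steps(interventions, config)
    weighted <- FALSE
  } else {
    steps <- build_alternatives(interventions, config)
    weighted <- identical(config$scenario, "equity_weighted")
  }
  sol <- league_solve(steps, budget = config$budget, weighted = weighted,
                      reallocate = reallocate_underspend)
  sol$scenario <- config$scenario
  sol$config <- config
  class(sol) <- "uhc_solution"
  sol
}

# Single 0 -> level alternative per intervention with linear cost/benefit
# through the origin (anchored at the 95% data point).
all_or_nothing_steps <- function(interventions, config) {
  level <- config$all_or_nothing_level
  curves <- fit_curves(interventions, grid_floor = config$grid_floor)
  purrr::map_dfr(seq_len(nrow(interventions)), function(i) {
    rec <- interventions[i, ]
    pop <- rec$incident_population
    ccost <- curves[curves$id == rec$id & curves$quantity == "cost", ]
    cben <- curves[curves$id == rec$id & curves$quantity == "benefit", ]
    v_cost <- curve_value(ccost, level)
    v_ben <- curve_value(cben, level)
    lin_ben <- linear_origin_curve(v_ben, level)
    dwb <- apply_equity_weights(0, level, lin_ben, config$weights, pop)
    tibble::tibble(
      row = i, id = rec$id, name = rec$name,
      theta_from = 0, theta_to = level,
      delta_cost = v_cost * pop * config$conversion_factor,
      delta_benefit = v_ben * pop,
      delta_weighted_benefit = dwb,
      clamped = FALSE,
      icer = step_icer(v_cost * pop * config$conversion_factor, v_ben * pop),
      merged_from = as.list(paste0(rec$id, ":", format_step(0, level)))
    )
  })
}

linear_origin_curve <- function(value_at_level, level) {
  tibble::tibble(
    form = "linear", a = 0, b1 = value_at_level / level, b2 = 0,
    grid_floor = level, floor_value = value_at_level
  )
}

# Core engine shared by all scenarios. `steps` are the raw single coverage
# steps per intervention in coverage order.
league_solve <- function(steps, budget, weighted, reallocate = TRUE) {
  eps <- 1e-9
  eff_col <- if (weighted) "delta_weighted_benefit" else "delta_benefit"
  ids <- unique(steps$id)
  state <- dplyr::distinct(steps[, c("row", "id", "name")])
  state$coverage <- 0
  state$spend <- 0
  state$dalys <- 0
  state$weighted_dalys <- 0
  state$icer_at_coverage <- NA_real_
  state$fractional <- FALSE

  total_eff <- tapply(steps[[eff_col]], factor(steps$id, levels = ids), sum)
  excluded <- names(total_eff)[total_eff <= 0]
  state$never_cost_effective <- state$id %in% excluded

  log <- list()
  spend <- 0
  pass <- 0

  admit <- function(alt, pass, fraction = 1) {
    k <- match(alt$id, state$id)
    state$coverage[k] <<- if (fraction < 1) {
      alt$theta_from + fraction * (alt$theta_to - alt$theta_from)
    } else alt$theta_to
    state$spend[k] <<- state$spend[k] + fraction * alt$delta_cost
    state$dalys[k] <<- state$dalys[k] + fraction * alt$delta_benefit
    state$weighted_dalys[k] <<-
      state$weighted_dalys[k] + fraction * alt$delta_weighted_benefit
    state$icer_at_coverage[k] <<- alt$icer
    state$fractional[k] <<- fraction < 1
    spend <<- spend + fraction * alt$delta_cost
    log[[length(log) + 1]] <<- list(
      pass = pass,
      event = if (fraction < 1) "fractional" else "admit",
      id = alt$id, theta_from = alt$theta_from, theta_to = alt$theta_to,
      fraction = fraction, cost = fraction * alt$delta_cost,
      effective_benefit = fraction * alt$eff, icer = alt$icer
    )
  }
  as_alt <- function(d, j) {
    list(id = d$id[j], theta_from = d$theta_from[j], theta_to = d$theta_to[j],
         delta_cost = d$delta_cost[j], delta_benefit = d$delta_benefit[j],
         delta_weighted_benefit = d$delta_weighted_benefit[j],
         eff = d[[eff_col]][j], icer = d$icer[j])
  }

  repeat {
    pass <- pass + 1
    u <- budget - spend
    cand <- steps[!(steps$id %in% excluded), ]
    cov_now <- stats::setNames(state$coverage, state$id)
    cand <- cand[cand$theta_from >= cov_now[cand$id] - eps, ]
    if (pass > 1 && nrow(cand) > 0) {
      # step 3(b): drop alternatives whose cumulative additional cost from
      # the current coverage exceeds the underspend
      cand <- cand[order(match(cand$id, ids), cand$theta_from), ]
      cum_cost <- stats::ave(cand$delta_cost, cand$id, FUN = cumsum)
      cand <- cand[cum_cost <= u + eps * max(budget, 1), ]
    }
    if (nrow(cand) == 0) break
    chains <- eliminate_dominated(cand, weighted = weighted)
    finite <- chains[is.finite(chains$icer), ]
    finite <- finite[order(finite$icer, finite$row, finite$theta_from), ]
    admitted <- FALSE
    for (j in seq_len(nrow(finite))) {
      alt <- as_alt(finite, j)
      if (abs(alt$theta_from - state$coverage[match(alt$id, state$id)]) > eps) {
        next # predecessor not yet admitted in this pass
      }
      if (alt$delta_cost <= (budget - spend) + eps * max(budget, 1)) {
        admit(alt, pass)
        admitted <- TRUE
      } else {
        break # step 2: stop at the first unaffordable alternative
      }
    }
    if (!admitted && nrow(finite) == 0) {
      # only non-positive-benefit steps remain: a slack budget completes
      # coverage through zero-benefit increments (harmless), but money is
      # never spent on a strictly negative health increment
      inf_chain <- chains[!is.finite(chains$icer) & chains[[eff_col]] >= 0, ]
      inf_chain <- inf_chain[order(inf_chain$row, inf_chain$theta_from), ]
      for (j in seq_len(nrow(inf_chain))) {
        alt <- as_alt(inf_chain, j)
        if (abs(alt$theta_from - state$coverage[match(alt$id, state$id)]) > eps) next
        if (alt$delta_cost <= (budget - spend) + eps * max(budget, 1)) {
          admit(alt, pass)
          admitted <- TRUE
        }
      }
    }
    if (!admitted) break
    if (!reallocate) break # stop after the single greedy pass
  }

  underspend_pre <- budget - spend
  marginal_icer <- NA_real_
  marginal_id <- NA_character_
  if (underspend_pre > eps * max(budget, 1)) {
    cov_now <- stats::setNames(state$coverage, state$id)
    nxt <- steps[!(steps$id %in% excluded), ]
    nxt <- nxt[abs(nxt$theta_from - cov_now[nxt$id]) <= eps, ]
    nxt <- nxt[nxt$delta_cost > 0 & nxt[[eff_col]] > 0, ]
    if (nrow(nxt) > 0) {
      nxt$icer <- step_icer(nxt$delta_cost, nxt[[eff_col]])
      nxt <- nxt[order(nxt$icer, nxt$row), ]
      alt <- as_alt(nxt, 1)
      fraction <- min(1, underspend_pre / alt$delta_cost)
      admit(alt, pass, fraction = fraction)
      marginal_icer <- alt$icer
      marginal_id <- alt$id
    }
  }
  if (is.na(marginal_icer)) {
    admits <- Filter(function(x) x$event == "admit", log)
    if (length(admits) > 0) {
      last <- admits[[length(admits)]]
      marginal_icer <- last$icer
      marginal_id <- last$id
    }
  }

  list(
    results = state,
    totals = list(
      spend = sum(state$spend),
      dalys = sum(state$dalys),
      weighted_dalys = sum(state$weighted_dalys)
    ),
    underspend_pre_fractional = underspend_pre,
    underspend = budget - spend,
    marginal_icer = marginal_icer,
    marginal_id = marginal_id,
    iteration_log = if (length(log) > 0) dplyr::bind_rows(log) else
      tibble::tibble(pass = integer(), event = character(), id = character(),
                     theta_from = double(), theta_to = double(),
                     fraction = double(), cost = double(),
                     effective_benefit = double(), icer = double()),
    passes = pass
  )
}

#' Marginal productivity of the discretionary budget
#'
#' The ICER of the last (possibly fractionally) funded increment: the
#' empirical counterpart of the Lagrange multiplier of the budget constraint.
#' Also verifies the league-table property that every admitted increment's
#' ICER is at most the marginal ICER; violations (possible through the
#' underspend-reallocation loop, which may admit previously dominated steps)
#' are reported in the `exceptions` attribute rather than hidden.
#'
#' @param solution A `uhc_solution`.
#' @return The marginal ICER (US$ per effective DALY), with attribute
#'   `exceptions`: a tibble of admitted increments whose ICER exceeds it.
#' @export
marginal_productivity <- function(solution) {
  stopifnot(inherits(solution, "uhc_solution"))
  log <- solution$iteration_log
  if (nrow(log) == 0) {
    abort("solution contains no admitted increments; marginal productivity is undefined",
          class = "uhc_empty_solution")
  }
  m <- solution$marginal_icer
  exceptions <- log[is.finite(log$icer) & log$icer > m * (1 + 1e-9), ]
  structure(m, exceptions = exceptions)
}

#' Calibrate the currency conversion factor from a structural landmark
#'
#' The factor converting 2000 Int$ costs into 2015 US$ is not a data item;
#' when reproducing a known solution it can instead be recovered from a
#' structural landmark. Because a uniform cost scaling leaves all ICER
#' rankings unchanged, the factor only moves the budget exhaustion point
#' along the league table, so the set of factors reproducing a landmark is an
#' interval and can be found by bisection.
#'
#' Two landmark types are supported:
#' * `type = "fractional_band"` (default): the terminal, fractionally funded
#'   intervention under the configured scenario is `id`, with final coverage
#'   strictly inside `(lower, upper)`.
#' * `type = "full_coverage"`: the largest factor at which every intervention
#'   is affordable at 100%; in closed form `budget / total cost at 100%`.
#'
#' @param interventions An intervention table.
#' @param config A `uhc_config`; its scenario is used for the trial solves.
#' @param landmark A list, e.g.
#'   `list(type = "fractional_band", id = "pneumonia", lower = 0.70, upper = 0.75)`.
#' @param bracket Search bracket for the factor.
#' @param tol Bisection tolerance on the factor.
#' @param max_iter Maximum bisection iterations.
#' @return A list with `factor` (midpoint of the satisfying band), `bracket`
#'   (the band of factors satisfying the landmark), and `solution` (the solve
#'   at `factor`).
#' @export
calibrate_conversion <- function(interventions,
                                 config = uhc_config(),
                                 landmark = list(type = "fractional_band",
                                                 id = "pneumonia",
                                                 lower = 0.70, upper = 0.75),
                                 bracket = c(0.5, 50),
                                 tol = 1e-4, max_iter = 100) {
  type <- landmark$type %||% "fractional_band"
  if (identical(type, "full_coverage")) {
    curves <- fit_curves(interventions, grid_floor = config$grid_floor)
    total <- sum(purrr::map_dbl(seq_len(nrow(interventions)), function(i) {
      cv <- curves[curves$id == interventions$id[i] & curves$quantity == "cost", ]
      cumulative_total(cv, 1, interventions$incident_population[i])
    }))
    return(list(factor = config$budget / total,
                bracket = c(0, config$budget / total), solution = NULL))
  }

  solve_at <- function(f) {
    cfg <- config
    cfg$conversion_factor <- f
    solve_package(interventions, cfg)
  }
  classify <- function(sol) {
    cov <- sol$results$coverage[sol$results$id == landmark$id]
    if (length(cov) == 0) {
      abort(paste0("landmark intervention not found: ", landmark$id),
            class = "uhc_config_error")
    }
    frac <- isTRUE(sol$results$fractional[sol$results$id == landmark$id])
    if (frac && cov > landmark$lower && cov < landmark$upper) return("hit")
    if (cov >= landmark$upper) "low" else "high" # factor too low / too high
  }
  lo <- bracket[1]
  hi <- bracket[2]
  sol_lo <- solve_at(lo)
  sol_hi <- solve_at(hi)
  if (classify(sol_lo) == "high" || classify(sol_hi) == "low") {
    abort(
      paste0(
        "landmark unattainable on bracket [", lo, ", ", hi, "]: marginal ",
        "intervention is ", sol_lo$marginal_id %||% "none", " at the lower ",
        "end and ", sol_hi$marginal_id %||% "none", " at the upper end"
      ),
      class = "uhc_calibration_error"
    )
  }
  hit <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cls <- classify(solve_at(mid))
    if (cls == "hit") {
      hit <- mid
      break
    } else if (cls == "low") {
      lo <- mid
    } else {
      hi <- mid
    }
    if (hi - lo < tol) break
  }
  if (is.na(hit)) {
    abort("bisection failed to locate the landmark band; refine the bracket",
          class = "uhc_calibration_error")
  }
  # refine the edges of the satisfying band
  edge <- function(a, b, want_left) {
    for (i in seq_len(max_iter)) {
      if (b - a < tol) break
      m <- (a + b) / 2
      if ((classify(solve_at(m)) == "hit") == want_left) b <- m else a <- m
    }
    if (want_left) b else a
  }
  band_lo <- edge(lo, hit, want_left = TRUE)
  band_hi <- edge(hit, hi, want_left = FALSE)
  factor <- (band_lo + band_hi) / 2
  if (classify(solve_at(factor)) != "hit") factor <- hit
  list(factor = factor, bracket = c(band_lo, band_hi),
       solution = solve_at(factor))
}

#' Evaluate a coverage vector's spend and (weighted) benefit
#'
#' Utility for re-costing an arbitrary coverage assignment (e.g. evaluating
#' the unweighted-optimal package under equity weights). Off-grid coverage is
#' interpreted the way the solver funds fractional steps: linearly in spend
#' within the surrounding grid step.
#'
#' @param interventions An intervention table.
#' @param coverage Named numeric vector (names = intervention ids) of coverage
#'   fractions.
#' @param config A `uhc_config`.
#' @return A tibble with one row per intervention: `coverage`, `spend`,
#'   `dalys`, `weighted_dalys`.
#' @export
evaluate_coverage <- function(interventions, coverage, config = uhc_config()) {
  validate_interventions(interventions)
  grid <- coverage_grid(config)
  curves <- fit_curves(interventions, grid_floor = config$grid_floor)
  purrr::map_dfr(seq_len(nrow(interventions)), function(i) {
    rec <- interventions[i, ]
    th <- coverage[[rec$id]] %||% 0
    pop <- rec$incident_population
    ccost <- curves[curves$id == rec$id & curves$quantity == "cost", ]
    cben <- curves[curves$id == rec$id & curves$quantity == "benefit", ]
    k <- findInterval(th - 1e-12, grid)
    base <- grid[max(k, 1)]
    if (th <= 0) {
      spend <- 0; dalys <- 0; wdalys <- 0
    } else {
      f <- if (th > base + 1e-12) {
        nxt <- grid[k + 1]
        (th - base) / (nxt - base)
      } else 0
      cost_base <- cumulative_total(ccost, base, pop)
      ben_base <- cumulative_total(cben, base, pop)
      wben_base <- if (base > 0) {
        apply_equity_weights(0, base, cben, config$weights, pop)
      } else 0
      if (f > 0) {
        nxt <- grid[k + 1]
        dc <- incremental(ccost, base, nxt, pop)
        db <- incremental(cben, base, nxt, pop)
        dwb <- apply_equity_weights(base, nxt, cben, config$weights, pop)
      } else {
        dc <- db <- dwb <- 0
      }
      spend <- (cost_base + f * dc) * config$conversion_factor
      dalys <- ben_base + f * db
      wdalys <- wben_base + f * dwb
    }
    tibble::tibble(id = rec$id, coverage = th, spend = spend,
                   dalys = dalys, weighted_dalys = wdalys)
  })
}
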