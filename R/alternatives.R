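#' Equity-weighted incremental benefit over a coverage interval
#'
#' Partitions the interval `(theta_from, theta_to]` at every weight-band
#' boundary and sums `weight x incremental benefit` over the pieces. On the
#' default 5% grid no single step straddles a decile boundary, but merged
#' alternatives and all-or-nothing intervals (e.g. 0 to 0.95) do, and are
#' split here by construction.
#'
#' @param theta_from,theta_to Coverage interval with
#'   `0 <= theta_from < theta_to <= 1`.
#' @param curve A fitted benefit curve ([fit_anchor_curve()]).
#' @param weights An equity weight schedule ([equity_weights()]); the empty
#'   schedule gives the unweighted increment.
#' @param incident_population Persons per year in need.
#' @return Weighted incremental DALYs averted over the interval.
#' @export
#' @examples
#' lin <- fit_anchor_curve(c("0.5" = 0.5, "0.8" = 0.8, "0.95" = 0.95))
#' # linear v(theta) = theta, population 100, default decile weights:
#' apply_equity_weights(0.85, 0.95, lin, default_equity_weights(), 100)
apply_equity_weights <- function(theta_from, theta_to, curve, weights,
                                 incident_population = 1) {
  if (theta_from >= theta_to || theta_from < 0 || theta_to > 1) {
    abort("interval must satisfy 0 <= theta_from < theta_to <= 1",
          class = "uhc_domain_error")
  }
  cuts <- sort(unique(c(theta_from, theta_to,
                        weights$lo[weights$lo > theta_from & weights$lo < theta_to],
                        weights$hi[weights$hi > theta_from & weights$hi < theta_to])))
  lo <- cuts[-length(cuts)]
  hi <- cuts[-1]
  w <- vapply(seq_along(lo), function(i) {
    hit <- which(weights$lo <= lo[i] & hi[i] <= weights$hi)
    if (length(hit) == 0) 1 else weights$weight[hit[1]]
  }, numeric(1))
  vals <- curve_value(curve, cuts) * incident_population
  sum(w * diff(vals))
}

#' Build the grid of incremental coverage alternatives for all interventions
#'
#' Expands each intervention into mutually exclusive coverage steps along the
#' grid: `(0, 0.5]`, `(0.5, 0.55]`, ..., `(0.95, 1]` by default. Each step
#' carries its incremental cost (converted to 2015 US$ and scaled by the
#' incident population), incremental DALYs averted, equity-weighted DALYs
#' averted, and the ICER on the scenario's effective benefit (weighted under
#' the equity-weighted scenario, unweighted otherwise).
#'
#' The segment beyond the top anchor (0.95 to 1.00) is extrapolated from the
#' fitted polynomial; a negative extrapolated increment is clamped at zero
#' with a warning. Steps with non-positive effective benefit carry an
#' infinite ICER.
#'
#' @param interventions An intervention table.
#' @param config A `uhc_config`.
#' @param curves Optional precomputed [fit_curves()] output.
#' @return A tibble of alternatives ordered by input row then coverage, with
#'   columns `row`, `id`, `name`, `theta_from`, `theta_to`, `delta_cost`,
#'   `delta_benefit`, `delta_weighted_benefit`, `clamped`, `icer`,
#'   `merged_from`.
#' @export
#' @examples
#' alts <- build_alternatives(who_choice_afr_e(), uhc_config())
#' dplyr::count(alts, id) # 11 alternatives per intervention on the 5% grid
build_alternatives <- function(interventions, config = uhc_config(),
                               curves = NULL) {
  validate_interventions(interventions)
  curves <- curves %||% fit_curves(interventions, grid_floor = config$grid_floor)
  grid <- coverage_grid(config)
  weighted_scenario <- identical(config$scenario, "equity_weighted")
  anchor_top <- 0.95

  n_steps <- length(grid) - 1
  pieces <- vector("list", nrow(interventions))
  for (i in seq_len(nrow(interventions))) {
    id_i <- interventions$id[i]
    ccost <- curves[curves$id == id_i & curves$quantity == "cost", ]
    cben <- curves[curves$id == id_i & curves$quantity == "benefit", ]
    pop <- interventions$incident_population[i]

    dc <- diff(curve_value(ccost, grid)) * pop * config$conversion_factor
    db <- diff(curve_value(cben, grid)) * pop
    dwb <- vapply(seq_len(n_steps), function(k) {
      apply_equity_weights(grid[k], grid[k + 1], cben, config$weights, pop)
    }, numeric(1))

    beyond <- grid[-length(grid)] >= anchor_top - 1e-12
    neg_c <- beyond & dc < 0
    neg_b <- beyond & db < 0
    if (any(neg_c)) dc[neg_c] <- 0
    if (any(neg_b)) {
      db[neg_b] <- 0
      dwb[neg_b] <- 0
    }

    pieces[[i]] <- list(
      row = rep(i, n_steps), id = rep(id_i, n_steps),
      name = rep(interventions$name[i], n_steps),
      theta_from = grid[-length(grid)], theta_to = grid[-1],
      delta_cost = dc, delta_benefit = db, delta_weighted_benefit = dwb,
      clamped = neg_c | neg_b
    )
  }
  out <- tibble::as_tibble(
    lapply(stats::setNames(names(pieces[[1]]), names(pieces[[1]])),
           function(col) unlist(lapply(pieces, `[[`, col), use.names = FALSE))
  )
  if (any(out$clamped)) {
    warning(
      "negative extrapolated increment(s) beyond the top anchor clamped to 0 for: ",
      paste(unique(out$id[out$clamped]), collapse = ", "),
      call. = FALSE
    )
  }
  eff <- if (weighted_scenario) out$delta_weighted_benefit else out$delta_benefit
  out$icer <- step_icer(out$delta_cost, eff)
  out$merged_from <- as.list(paste0(out$id, ":", format_step(out$theta_from, out$theta_to)))
  out
}

step_icer <- function(delta_cost, delta_eff) {
  ifelse(delta_eff > 0, delta_cost / delta_eff, Inf)
}

format_step <- function(from, to) {
  sprintf("%g-%g", from, to)
}

#' Strict and extended dominance elimination with increment merging
#'
#' Screens the coverage-ordered steps of each intervention. A step with no
#' effective benefit gain at positive cost is strictly dominated (infinite
#' ICER); a step whose ICER exceeds that of the next step is extended
#' dominated. Dominated steps are merged into their successor (incremental
#' cost and benefit summed, ICER recomputed on the merged deltas,
#' `merged_from` recording the constituents) until the retained sequence has
#' non-decreasing ICERs. Adjacent steps with exactly equal ICERs are kept
#' separate, preserving granularity. Total cost and benefit over the sequence
#' are conserved exactly.
#'
#' Trailing steps with non-positive effective benefit have no successor to
#' merge into; they are retained with an infinite ICER and are only ever
#' funded by a slack budget. An intervention whose every retained step has
#' non-positive effective benefit is flagged `never_cost_effective` and is
#' excluded from ranking altogether.
#'
#' @param alts Alternatives from [build_alternatives()] (one or more
#'   interventions; grouped internally by `id`).
#' @param weighted Rank on equity-weighted benefits? Defaults to the choice
#'   already baked into `alts$icer` being irrelevant: the ICERs are recomputed
#'   here from the requested benefit column.
#' @return A tibble of retained alternatives with recomputed `icer` and a
#'   `never_cost_effective` flag.
#' @export
#' @examples
#' alts <- build_alternatives(who_choice_afr_e(), uhc_config())
#' nd <- eliminate_dominated(alts)
#' # conservation: total cost and benefit are unchanged by elimination
#' all.equal(sum(nd$delta_cost), sum(alts$delta_cost))
eliminate_dominated <- function(alts, weighted = FALSE) {
  eff_col <- if (weighted) "delta_weighted_benefit" else "delta_benefit"
  split_alts <- split(alts, factor(alts$id, levels = unique(alts$id)))
  out <- lapply(split_alts, function(a) {
    a <- a[order(a$theta_from), ]
    from <- a$theta_from
    to <- a$theta_to
    dc <- a$delta_cost
    db <- a$delta_benefit
    dwb <- a$delta_weighted_benefit
    clamped <- a$clamped
    merged <- a$merged_from
    repeat {
      eff <- if (weighted) dwb else db
      icer <- step_icer(dc, eff)
      n <- length(dc)
      if (n <= 1) break
      dominated <- which(icer[-n] > icer[-1])
      if (length(dominated) == 0) break
      i <- dominated[1]
      from[i + 1] <- from[i]
      dc[i + 1] <- dc[i + 1] + dc[i]
      db[i + 1] <- db[i + 1] + db[i]
      dwb[i + 1] <- dwb[i + 1] + dwb[i]
      clamped[i + 1] <- clamped[i + 1] || clamped[i]
      merged[[i + 1]] <- c(merged[[i]], merged[[i + 1]])
      keep <- -i
      from <- from[keep]; to <- to[keep]; dc <- dc[keep]; db <- db[keep]
      dwb <- dwb[keep]; clamped <- clamped[keep]; merged <- merged[keep]
    }
    eff <- if (weighted) dwb else db
    tibble::tibble(
      row = a$row[1], id = a$id[1], name = a$name[1],
      theta_from = from, theta_to = to,
      delta_cost = dc, delta_benefit = db, delta_weighted_benefit = dwb,
      clamped = clamped, icer = step_icer(dc, eff), merged_from = merged,
      never_cost_effective = all(eff <= 0)
    )
  })
  dplyr::bind_rows(out)
}

#' Export an alternatives table as CSV
#'
#' Writes the league-table input (one row per retained alternative) with the
#' merged constituents flattened to a `;`-separated string.
#'
#' @param alts Alternatives, typically after [eliminate_dominated()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_alternatives <- function(alts, path) {
  flat <- dplyr::mutate(
    alts,
    merged_from = vapply(.data$merged_from, paste, character(1), collapse = ";")
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}
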