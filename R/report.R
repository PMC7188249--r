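#' @export
print.uhc_solution <- function(x, ...) {
  cat("<uhc_solution> scenario:", x$scenario, "\n")
  fmt <- function(v) format(round(v), big.mark = ",", scientific = FALSE)
  cat(sprintf("  budget %s US$, spend %s, underspend %s\n",
              fmt(x$config$budget), fmt(x$totals$spend), fmt(x$underspend)))
  cat(sprintf("  total DALYs averted %s (equity weighted %s)\n",
              fmt(x$totals$dalys), fmt(x$totals$weighted_dalys)))
  if (!is.na(x$marginal_icer)) {
    cat(sprintf("  marginal ICER %s US$ per %sDALY (%s)\n",
                format(round(x$marginal_icer), big.mark = ",",
                       scientific = FALSE),
                if (x$scenario == "equity_weighted") "weighted " else "",
                x$marginal_id))
  }
  covered <- x$results[x$results$coverage > 0, ]
  cat(sprintf("  %d of %d interventions covered, %d at 100%%\n",
              nrow(covered), nrow(x$results),
              sum(covered$coverage > 1 - 1e-9)))
  invisible(x)
}

#' Tidy a package solution into one row per intervention
#'
#' @param x A `uhc_solution`.
#' @param ... Unused.
#' @return A tibble mirroring the published results-table layout:
#'   intervention, ICER at the included coverage level, coverage, DALYs
#'   averted and equity-weighted DALYs averted.
#' @export
tidy.uhc_solution <- function(x, ...) {
  dplyr::transmute(
    x$results,
    id = .data$id, name = .data$name, scenario = x$scenario,
    icer_at_coverage = .data$icer_at_coverage,
    coverage = .data$coverage,
    dalys_averted = .data$dalys,
    equity_weighted_dalys = .data$weighted_dalys,
    spend = .data$spend,
    fractional = .data$fractional
  )
}

#' One-row summary of a package solution
#'
#' @inheritParams tidy.uhc_solution
#' @return A one-row tibble with totals, underspend and the marginal ICER.
#' @export
glance.uhc_solution <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    budget = x$config$budget,
    conversion_factor = x$config$conversion_factor,
    spend = x$totals$spend,
    dalys_averted = x$totals$dalys,
    equity_weighted_dalys = x$totals$weighted_dalys,
    underspend_pre_fractional = x$underspend_pre_fractional,
    underspend = x$underspend,
    marginal_icer = x$marginal_icer,
    n_covered = sum(x$results$coverage > 0),
    n_full = sum(x$results$coverage > 1 - 1e-9)
  )
}

#' Coverage bar chart for a solution
#'
#' @param object A `uhc_solution`.
#' @param ... Unused.
#' @return A ggplot: selected coverage level per intervention.
#' @export
autoplot.uhc_solution <- function(object, ...) {
  df <- tidy(object)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coverage, y = .data$name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Coverage level", y = NULL,
                  title = paste("Optimized coverage -", object$scenario)) +
    ggplot2::theme_minimal()
}

#' Solve all three scenarios and compare
#'
#' Runs the variable-coverage, equity-weighted and all-or-nothing scenarios
#' on the same data and budget.
#'
#' @param interventions An intervention table.
#' @param config A `uhc_config`; its `scenario` field is overridden per run.
#' @return An object of class `uhc_comparison`: a named list of the three
#'   solutions plus a `summary` tibble (one row per scenario).
#' @export
#' @examples
#' cmp <- compare_scenarios(who_choice_afr_e(),
#'                          uhc_config(conversion_factor = 4.3))
#' cmp$summary
compare_scenarios <- function(interventions, config = uhc_config()) {
  scenarios <- c("variable_coverage", "equity_weighted", "all_or_nothing")
  sols <- purrr::map(scenarios, function(s) {
    cfg <- config
    cfg$scenario <- s
    solve_package(interventions, cfg)
  })
  names(sols) <- scenarios
  structure(
    c(sols, list(summary = purrr::map_dfr(sols, glance))),
    class = "uhc_comparison"
  )
}

#' @export
print.uhc_comparison <- function(x, ...) {
  cat("<uhc_comparison> of", nrow(x$summary), "scenarios\n")
  print(x$summary)
  invisible(x)
}

#' @rdname compare_scenarios
#' @param x A `uhc_comparison`.
#' @param ... Unused.
#' @export
tidy.uhc_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tidy(x$variable_coverage),
    tidy(x$equity_weighted),
    tidy(x$all_or_nothing)
  )
}

#' @rdname compare_scenarios
#' @param object A `uhc_comparison`.
#' @export
autoplot.uhc_comparison <- function(object, ...) {
  df <- tidy(object)
  df$name <- factor(df$name, levels = rev(unique(df$name)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coverage, y = .data$name,
                                   fill = .data$scenario)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Coverage level", y = NULL,
                  title = "Optimized coverage by scenario") +
    ggplot2::theme_minimal()
}

#' Serialize a solution
#'
#' `write_solution_csv()` writes the per-intervention results table (the
#' published-table layout from [tidy()]); `write_solution_json()` writes the
#' full solution including totals, the iteration log and a provenance block
#' (data hash, configuration, package version), so a report can be
#' regenerated from the file without recomputation.
#'
#' @param solution A `uhc_solution`.
#' @param path Output path.
#' @param interventions Optional intervention table used, hashed into the
#'   provenance block.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  readr::write_csv(tidy(solution), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_solution_csv
#' @export
write_solution_json <- function(solution, path, interventions = NULL) {
  payload <- list(
    scenario = solution$scenario,
    provenance = list(
      package_version = as.character(utils::packageVersion("uhcoptim")),
      data_hash = if (!is.null(interventions)) rlang::hash(interventions) else NA,
      budget = solution$config$budget,
      conversion_factor = solution$config$conversion_factor,
      seed = solution$config$seed
    ),
    totals = solution$totals,
    underspend_pre_fractional = solution$underspend_pre_fractional,
    underspend = solution$underspend,
    marginal_icer = solution$marginal_icer,
    marginal_id = solution$marginal_id,
    results = solution$results,
    iteration_log = solution$iteration_log
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
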