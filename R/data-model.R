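#' Read an intervention table from CSV
#'
#' Reads a delimited text file describing one intervention per row: cumulative
#' annual cost (2000 Int$) and DALYs averted per member of the incident
#' population at the three coverage anchors 50%, 80% and 95%, plus the size of
#' the incident population. Coverage is always expressed as a fraction in
#' \[0, 1\], never as a percent.
#'
#' The expected header is exactly:
#' `id, name, incident_population, population_definition, cost_50, cost_80,
#' cost_95, dalys_50, dalys_80, dalys_95`.
#'
#' @param path Path to a UTF-8 CSV file with the schema above (decimal point,
#'   no thousands separators).
#' @return A tibble with one validated row per intervention, in file order
#'   (row order is used downstream for deterministic tie-breaking).
#' @seealso [who_choice_afr_e()] for the packaged WHO-CHOICE table,
#'   [write_interventions()] for the inverse operation.
#' @export
#' @examples
#' path <- system.file("extdata", "who_choice_afr_e.csv", package = "uhcoptim")
#' read_interventions(path)
read_interventions <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("interventions file not found: ", path), class = "uhc_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  missing_cols <- setdiff(intervention_schema(), trimws(header))
  if (length(missing_cols) > 0) {
    abort(
      paste0("interventions file is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "uhc_schema_error"
    )
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      name = readr::col_character(),
      incident_population = readr::col_double(),
      population_definition = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(
      paste0("non-numeric or malformed cell at row ", probs$row[1],
             ", column ", probs$col[1]),
      class = "uhc_parse_error"
    )
  }
  df <- df[, intervention_schema()]
  validate_interventions(df)
  df
}

intervention_schema <- function() {
  c("id", "name", "incident_population", "population_definition",
    "cost_50", "cost_80", "cost_95", "dalys_50", "dalys_80", "dalys_95")
}

#' Write an intervention table to CSV
#'
#' Inverse of [read_interventions()]: writes the documented schema so that a
#' read/write round trip reproduces the file field for field.
#'
#' @param interventions A tibble as returned by [read_interventions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interventions <- function(interventions, path) {
  validate_interventions(interventions)
  readr::write_csv(interventions[, intervention_schema()], path, progress = FALSE)
  invisible(path)
}

#' Validate an intervention table
#'
#' Checks the invariants every intervention record must satisfy: all three
#' coverage anchors present for both cost and benefit, anchor values
#' non-negative and non-decreasing in coverage, and a positive incident
#' population.
#'
#' @param interventions A data frame in the schema of [read_interventions()].
#' @return `interventions`, invisibly, if valid; otherwise an error condition
#'   of class `uhc_validation_error` naming the offending intervention and
#'   quantity.
#' @export
validate_interventions <- function(interventions) {
  stopifnot(is.data.frame(interventions))
  missing_cols <- setdiff(intervention_schema(), names(interventions))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "uhc_schema_error")
  }
  if (anyDuplicated(interventions$id) > 0) {
    abort("intervention ids must be unique", class = "uhc_validation_error")
  }
  num_cols <- setdiff(intervention_schema(), c("id", "name", "population_definition"))
  for (col in num_cols) {
    x <- interventions[[col]]
    if (!is.numeric(x) || anyNA(x)) {
      abort(paste0("column ", col, " must be numeric with no missing values"),
            class = "uhc_validation_error")
    }
    if (any(x < 0)) {
      bad <- interventions$id[which(x < 0)[1]]
      abort(paste0("negative value in ", col, " for intervention ", bad),
            class = "uhc_validation_error")
    }
  }
  if (any(interventions$incident_population <= 0)) {
    bad <- interventions$id[which(interventions$incident_population <= 0)[1]]
    abort(paste0("incident_population must be positive for intervention ", bad),
          class = "uhc_validation_error")
  }
  for (qty in c("cost", "dalys")) {
    a <- interventions[[paste0(qty, "_50")]]
    b <- interventions[[paste0(qty, "_80")]]
    c95 <- interventions[[paste0(qty, "_95")]]
    bad <- which(b < a | c95 < b)
    if (length(bad) > 0) {
      abort(
        paste0("anchor ", ifelse(qty == "cost", "cost", "benefit"),
               " values are not non-decreasing in coverage for intervention ",
               interventions$id[bad[1]]),
        class = "uhc_validation_error"
      )
    }
  }
  invisible(interventions)
}

#' WHO-CHOICE costs and benefits for 16 AFR-E interventions
#'
#' The packaged intervention table for a hypothetical East African (AFR-E)
#' country of 25 million people: 16 maternal, newborn, child health, malaria
#' and TB interventions with cumulative per-person-in-need annual cost
#' (2000 Int$) and DALYs averted at 50%, 80% and 95% coverage, together with
#' the annual incident population for each intervention.
#'
#' The anchor values are interpreted as cumulative annual totals per member of
#' the incident population at the given coverage level; multiplying the 95%
#' benefit anchor by the incident population reproduces the published
#' DALY-averted magnitudes (e.g. TB DOTS: 0.130 x 112,918 ~ 14,700).
#' Values are as printed, to three decimals; two interventions (IPTP and
#' management of severe malnutrition) have printed benefits of 0.000 at every
#' anchor and therefore can never enter an optimized package built from this
#' table.
#'
#' @return A tibble with 16 rows in the schema of [read_interventions()].
#' @export
#' @examples
#' who_choice_afr_e()
who_choice_afr_e <- function() {
  read_interventions(
    system.file("extdata", "who_choice_afr_e.csv", package = "uhcoptim",
                mustWork = TRUE)
  )
}

#' Equity weight schedules over coverage deciles
#'
#' An equity weight schedule maps bands of the coverage axis to multiplicative
#' weights (>= 1) on health benefits. The convention follows the assumption
#' that the hardest-to-reach patients (covered last) are the most
#' disadvantaged: the default schedule weights benefits accruing in the last
#' coverage decile (0.9, 1.0] by 4 and the penultimate decile (0.8, 0.9] by 2.
#' Coverage outside any band carries weight 1.
#'
#' @param lo,hi Numeric vectors of band bounds; each band is the half-open
#'   interval `(lo, hi]` with `0 <= lo < hi <= 1`.
#' @param weight Numeric vector of weights, all `>= 1`.
#' @return A tibble with columns `lo`, `hi`, `weight`, ordered by `lo`.
#' @export
#' @examples
#' default_equity_weights()
#' equity_weights(lo = 0.5, hi = 1, weight = 3)
#' unit_weights() # no weighting: weighted and unweighted benefits coincide
equity_weights <- function(lo = numeric(), hi = numeric(), weight = numeric()) {
  stopifnot(length(lo) == length(hi), length(lo) == length(weight))
  bands <- tibble::tibble(lo = as.numeric(lo), hi = as.numeric(hi),
                          weight = as.numeric(weight))
  bands <- dplyr::arrange(bands, .data$lo)
  if (nrow(bands) > 0) {
    if (any(bands$lo < 0) || any(bands$hi > 1) || any(bands$lo >= bands$hi)) {
      abort("weight bands must satisfy 0 <= lo < hi <= 1",
            class = "uhc_validation_error")
    }
    if (any(bands$weight < 1)) {
      abort("equity weights must all be >= 1", class = "uhc_validation_error")
    }
    if (nrow(bands) > 1 && any(bands$lo[-1] < bands$hi[-nrow(bands)])) {
      abort("weight bands must not overlap", class = "uhc_validation_error")
    }
  }
  bands
}

#' @rdname equity_weights
#' @export
default_equity_weights <- function() {
  equity_weights(lo = c(0.8, 0.9), hi = c(0.9, 1.0), weight = c(2, 4))
}

#' @rdname equity_weights
#' @export
unit_weights <- function() {
  equity_weights()
}

#' Analysis configuration
#'
#' Bundles the policy inputs of a package-design run: the discretionary budget
#' (2015 US$), the factor converting 2000 Int$ costs into 2015 US$, the
#' coverage grid, the scenario, and the equity weight schedule.
#'
#' The coverage grid is `{0} U {grid_floor, grid_floor + grid_step, ..., 1}`
#' and `grid_floor + k * grid_step` must land exactly on 1 for some integer
#' `k`. The default grid is the conventional one: 0, then 50% to 100% in 5%
#' steps.
#'
#' The conversion factor is deliberately an explicit user input with default 1
#' (no conversion); [calibrate_conversion()] can recover a factor from a
#' structural landmark of a known solution instead of baking in a constant.
#'
#' @param budget Discretionary annual budget in 2015 US$ (positive).
#' @param conversion_factor Multiplicative factor from 2000 Int$ to 2015 US$
#'   (positive).
#' @param grid_floor Minimum nonzero coverage fraction (default 0.5).
#' @param grid_step Coverage increment (default 0.05).
#' @param scenario One of `"variable_coverage"` (rank unweighted ICERs),
#'   `"equity_weighted"` (rank equity-weighted ICERs) or `"all_or_nothing"`
#'   (each intervention at `all_or_nothing_level` or not at all).
#' @param weights An equity weight schedule, see [equity_weights()].
#' @param all_or_nothing_level Coverage used by the all-or-nothing scenario
#'   (default 0.95).
#' @param population Total population the system serves; carried as metadata
#'   in reports (the computation itself uses per-intervention incident
#'   populations).
#' @param seed Integer seed recorded with results.
#' @return A list of class `uhc_config`.
#' @export
#' @examples
#' uhc_config()
#' uhc_config(scenario = "equity_weighted", budget = 2e7)
uhc_config <- function(budget = 15e6,
                       conversion_factor = 1,
                       grid_floor = 0.5,
                       grid_step = 0.05,
                       scenario = c("variable_coverage", "equity_weighted",
                                    "all_or_nothing"),
                       weights = default_equity_weights(),
                       all_or_nothing_level = 0.95,
                       population = 25e6,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  if (!is.numeric(budget) || length(budget) != 1 || is.na(budget) || budget < 0) {
    abort("budget must be a single non-negative number",
          class = "uhc_config_error")
  }
  if (!is.numeric(conversion_factor) || conversion_factor <= 0) {
    abort("conversion_factor must be positive", class = "uhc_config_error")
  }
  if (grid_floor <= 0 || grid_floor >= 1 || grid_step <= 0) {
    abort("grid_floor must lie in (0, 1) and grid_step must be positive",
          class = "uhc_config_error")
  }
  k <- (1 - grid_floor) / grid_step
  if (abs(k - round(k)) > 1e-9) {
    abort(
      paste0("coverage grid does not land exactly on 1: floor ", grid_floor,
             " + k * ", grid_step, " never equals 1"),
      class = "uhc_config_error"
    )
  }
  if (all_or_nothing_level <= 0 || all_or_nothing_level > 1) {
    abort("all_or_nothing_level must lie in (0, 1]", class = "uhc_config_error")
  }
  weights <- equity_weights(weights$lo, weights$hi, weights$weight)
  structure(
    list(
      budget = budget,
      conversion_factor = conversion_factor,
      grid_floor = grid_floor,
      grid_step = grid_step,
      scenario = scenario,
      weights = weights,
      all_or_nothing_level = all_or_nothing_level,
      population = population,
      seed = as.integer(seed)
    ),
    class = "uhc_config"
  )
}

#' @export
print.uhc_config <- function(x, ...) {
  cat("<uhc_config>\n")
  cat(sprintf("  scenario:          %s\n", x$scenario))
  cat(sprintf("  budget:            %s (2015 US$)\n",
              format(x$budget, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  conversion factor: %g (2000 Int$ -> 2015 US$)\n",
              x$conversion_factor))
  cat(sprintf("  coverage grid:     0, %g .. 1 by %g\n", x$grid_floor, x$grid_step))
  if (nrow(x$weights) == 0) {
    cat("  equity weights:    none (all 1)\n")
  } else {
    cat(sprintf("  equity weights:    %s\n",
                paste(sprintf("(%g,%g]x%g", x$weights$lo, x$weights$hi,
                              x$weights$weight), collapse = ", ")))
  }
  invisible(x)
}

#' Read an analysis configuration from JSON
#'
#' Parses a JSON object with any subset of the [uhc_config()] fields; absent
#' fields take their defaults. The weight schedule is encoded as a list of
#' `{"lo": ..., "hi": ..., "weight": ...}` objects.
#'
#' @param path Path to a JSON file. An empty object `{}` yields the default
#'   configuration (US$15M budget, 5% grid from 50%).
#' @return A `uhc_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "uhc_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  known <- c("budget", "conversion_factor", "grid_floor", "grid_step",
             "scenario", "weights", "all_or_nothing_level", "population",
             "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "uhc_config_error")
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$weights)) {
    w <- as.data.frame(args$weights)
    args$weights <- equity_weights(w$lo, w$hi, w$weight)
  }
  do.call(uhc_config, args)
}

#' Coverage grid of a configuration
#'
#' @param config A `uhc_config`.
#' @return Numeric vector `c(0, grid_floor, ..., 1)`.
#' @export
#' @examples
#' coverage_grid(uhc_config())
coverage_grid <- function(config) {
  k <- round((1 - config$grid_floor) / config$grid_step)
  c(0, config$grid_floor + config$grid_step * (0:k))
}
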