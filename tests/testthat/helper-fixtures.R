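# Hand-constructable intervention rows for controlled solver tests.
# Collinear anchors give exactly linear cumulative curves v(theta) = slope * theta,
# so every grid step has a closed-form cost and benefit.
linear_record <- function(id, cost_slope, benefit_slope, pop = 100,
                          name = paste("Linear", id)) {
  tibble::tibble(
    id = id, name = name,
    incident_population = pop, population_definition = "synthetic",
    cost_50 = 0.5 * cost_slope, cost_80 = 0.8 * cost_slope,
    cost_95 = 0.95 * cost_slope,
    dalys_50 = 0.5 * benefit_slope, dalys_80 = 0.8 * benefit_slope,
    dalys_95 = 0.95 * benefit_slope
  )
}

# Coarse two-step grid (0 -> 0.5 -> 1) keeps hand arithmetic easy.
coarse_config <- function(...) {
  uhc_config(grid_floor = 0.5, grid_step = 0.5, ...)
}

fixture_quietly <- function() suppressWarnings(who_choice_afr_e())

solve_quietly <- function(...) suppressWarnings(solve_package(...))
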