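# raw step table for dominance tests without going through curves
make_steps <- function(id, from, to, dc, db, dwb = db) {
  tibble::tibble(
    row = 1L, id = id, name = id,
    theta_from = from, theta_to = to,
    delta_cost = dc, delta_benefit = db, delta_weighted_benefit = dwb,
    clamped = FALSE, icer = ifelse(db > 0, dc / db, Inf),
    merged_from = as.list(paste0(id, ":", from, "-", to))
  )
}

test_that("the default grid yields 11 telescoping alternatives per intervention", {
  iv <- fixture_quietly()
  alts <- suppressWarnings(build_alternatives(iv, uhc_config()))
  counts <- table(alts$id)
  expect_true(all(counts == 11))
  expect_equal(alts$theta_to[alts$id == "tb_dots"], seq(0.5, 1, 0.05))

  # telescoping: step benefits sum to the cumulative total at full coverage
  curves <- fit_curves(iv)
  for (i in seq_len(nrow(iv))) {
    cb <- curves[curves$id == iv$id[i] & curves$quantity == "benefit", ]
    full <- cumulative_total(cb, 1, iv$incident_population[i])
    got <- sum(alts$delta_benefit[alts$id == iv$id[i]])
    clamp_adj <- alts$clamped[alts$id == iv$id[i]]
    if (!any(clamp_adj)) {
      expect_equal(got, full, tolerance = 1e-9, label = iv$id[i])
    } else {
      expect_gte(got + 1e-9, full) # clamping can only raise the sum
    }
  }
})

test_that("linear curves with unit weights give equal 5% step benefits", {
  rec <- linear_record("lin", cost_slope = 2, benefit_slope = 1, pop = 100)
  cfg <- uhc_config(weights = unit_weights())
  alts <- build_alternatives(rec, cfg)
  steps5 <- alts[alts$theta_from >= 0.5, ]
  expect_equal(steps5$delta_benefit, rep(5, 10), tolerance = 1e-9)
  expect_equal(steps5$delta_weighted_benefit, steps5$delta_benefit,
               tolerance = 1e-12)
  expect_equal(alts$delta_cost[1], 100, tolerance = 1e-9) # 0 -> 0.5 block
})

test_that("equity weighting partitions intervals at decile boundaries", {
  lin <- fit_anchor_curve(c("0.5" = 0.5, "0.8" = 0.8, "0.95" = 0.95))
  w <- default_equity_weights()

  # hand integration: (0.85, 0.95] splits into 0.05 x 2 + 0.05 x 4 per capita
  expect_equal(apply_equity_weights(0.85, 0.95, lin, w, 100), 30,
               tolerance = 1e-9)
  # interval spanning three bands: 0.05 x 1 + 0.1 x 2 + 0.1 x 4
  expect_equal(apply_equity_weights(0.75, 1, lin, w, 1), 0.65,
               tolerance = 1e-12)
  # identity schedule
  expect_equal(apply_equity_weights(0.6, 1, lin, unit_weights(), 50),
               incremental(lin, 0.6, 1, 50), tolerance = 1e-12)
  expect_error(apply_equity_weights(0.9, 0.9, lin, w, 1),
               class = "uhc_domain_error")
})

test_that("weighted benefit dominates unweighted exactly when weights exceed 1", {
  iv <- fixture_quietly()
  alts <- suppressWarnings(build_alternatives(iv, uhc_config()))
  # a weight >= 1 can only amplify a gain; steps whose fitted increment is
  # negative (a rounded-anchor artifact) are amplified downward too, so the
  # dominance statement applies to non-negative increments
  pos <- alts$delta_benefit >= 0
  expect_true(all(alts$delta_weighted_benefit[pos] >=
                    alts$delta_benefit[pos] - 1e-9))
  cfg1 <- uhc_config(weights = unit_weights())
  alts1 <- suppressWarnings(build_alternatives(iv, cfg1))
  expect_equal(alts1$delta_weighted_benefit, alts1$delta_benefit,
               tolerance = 1e-12)
})

test_that("extended dominance merges a worse middle step and recomputes the ICER", {
  # three steps with equal benefit 1 and costs 10, 30, 20: the middle step's
  # ICER (30) exceeds the next (20), so it merges forward into a combined
  # step with ICER (30 + 20) / 2 = 25; enumerating all merge outcomes of a
  # 3-step instance by hand confirms (10, 25) is the unique fixed point
  a <- make_steps("x", c(0, 0.5, 0.75), c(0.5, 0.75, 1), dc = c(10, 30, 20),
                  db = c(1, 1, 1))
  nd <- eliminate_dominated(a)
  expect_equal(nd$icer, c(10, 25))
  expect_equal(nd$theta_from, c(0, 0.5))
  expect_equal(nd$theta_to, c(0.5, 1))
  expect_identical(nd$merged_from[[2]], c("x:0.5-0.75", "x:0.75-1"))

  # single alternative passes through unchanged
  one <- make_steps("y", 0, 0.95, 5, 2)
  expect_equal(eliminate_dominated(one)$icer, 2.5)

  # exactly equal adjacent ICERs are kept separate (tie rule)
  tie <- make_steps("z", c(0, 0.5), c(0.5, 1), dc = c(10, 10), db = c(1, 1))
  expect_identical(nrow(eliminate_dominated(tie)), 2L)
})

test_that("strictly dominated zero-benefit steps merge forward or trail as unfundable", {
  # zero-benefit opener merges into its successor
  a <- make_steps("x", c(0, 0.5), c(0.5, 1), dc = c(10, 10), db = c(0, 2))
  nd <- eliminate_dominated(a)
  expect_identical(nrow(nd), 1L)
  expect_equal(nd$icer, 10)
  expect_false(nd$never_cost_effective)

  # trailing zero-benefit step is retained with infinite ICER
  b <- make_steps("y", c(0, 0.5), c(0.5, 1), dc = c(10, 10), db = c(2, 0))
  nd <- eliminate_dominated(b)
  expect_equal(nd$icer, c(5, Inf))

  # all-zero-benefit intervention is flagged never cost-effective
  z <- make_steps("z", c(0, 0.5), c(0.5, 1), dc = c(10, 10), db = c(0, 0))
  expect_true(all(eliminate_dominated(z)$never_cost_effective))
})

test_that("dominance elimination conserves totals and leaves non-decreasing ICERs", {
  iv <- fixture_quietly()
  for (weighted in c(FALSE, TRUE)) {
    cfg <- uhc_config(scenario = if (weighted) "equity_weighted" else
                        "variable_coverage")
    alts <- suppressWarnings(build_alternatives(iv, cfg))
    nd <- eliminate_dominated(alts, weighted = weighted)
    expect_equal(sum(nd$delta_cost), sum(alts$delta_cost), tolerance = 1e-9)
    expect_equal(sum(nd$delta_benefit), sum(alts$delta_benefit),
                 tolerance = 1e-9)
    expect_equal(sum(nd$delta_weighted_benefit),
                 sum(alts$delta_weighted_benefit), tolerance = 1e-9)
    for (id in unique(nd$id)) {
      icers <- nd$icer[nd$id == id]
      expect_false(is.unsorted(icers[is.finite(icers)]),
                   label = paste("non-decreasing ICERs for", id))
    }
  }
})

test_that("raising a band weight never increases any step or retained ICER", {
  iv <- fixture_quietly()
  heavier <- equity_weights(c(0.8, 0.9), c(0.9, 1), c(3, 6))
  cfg_a <- uhc_config(scenario = "equity_weighted")
  cfg_b <- uhc_config(scenario = "equity_weighted", weights = heavier)
  alts_a <- suppressWarnings(build_alternatives(iv, cfg_a))
  alts_b <- suppressWarnings(build_alternatives(iv, cfg_b))
  expect_true(all(alts_b$icer <= alts_a$icer + 1e-9))

  nd_a <- eliminate_dominated(alts_a, weighted = TRUE)
  nd_b <- eliminate_dominated(alts_b, weighted = TRUE)
  max_a <- tapply(nd_a$icer[is.finite(nd_a$icer)],
                  nd_a$id[is.finite(nd_a$icer)], max)
  max_b <- tapply(nd_b$icer[is.finite(nd_b$icer)],
                  nd_b$id[is.finite(nd_b$icer)], max)
  expect_true(all(max_b[names(max_a)] <= max_a + 1e-9))
})

test_that("alternatives tables export with flattened merge provenance", {
  a <- make_steps("x", c(0, 0.5, 0.75), c(0.5, 0.75, 1), dc = c(10, 30, 20),
                  db = c(1, 1, 1))
  nd <- eliminate_dominated(a)
  path <- withr::local_tempfile(fileext = ".csv")
  write_alternatives(nd, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(out$merged_from[2], "x:0.5-0.75;x:0.75-1")
})
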