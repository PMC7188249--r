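#' Fit a cumulative cost or benefit curve through three coverage anchors
#'
#' Interpolates cumulative per-capita annual cost (or DALYs averted) as a
#' function of coverage through the three anchors, conventionally at 50%, 80%
#' and 95% coverage. If the middle anchor lies on the chord between the outer
#' anchors (relative residual below `linear_tol`) the curve is classified
#' linear and fitted by least squares (exact for collinear points); otherwise
#' the unique interpolating quadratic `v(theta) = a + b1*theta + b2*theta^2`
#' is obtained by solving the 3x3 Vandermonde system. Either way the fitted
#' curve reproduces every anchor to numerical precision.
#'
#' Below the lowest anchor (`grid_floor`) incremental costs and benefits are
#' taken as constant, so the curve is the straight segment from the origin:
#' `v(theta) = (theta / grid_floor) * v(grid_floor)` for
#' `theta in [0, grid_floor)`. In particular `v(0) = 0`.
#'
#' @param anchors Named numeric vector of length 3: names are coverage
#'   fractions in (0, 1] (e.g. `c("0.5" = 0.428, "0.8" = 0.768, "0.95" = 1.069)`),
#'   values are cumulative per-capita quantities, non-decreasing in coverage.
#' @param grid_floor Coverage below which increments are constant; default the
#'   smallest anchor coverage.
#' @param linear_tol Relative tolerance for classifying the anchors as
#'   collinear.
#' @return A one-row tibble with columns `form` ("linear" or "quadratic"),
#'   `a`, `b1`, `b2`, `grid_floor`, `floor_value`.
#' @export
#' @examples
#' fit_anchor_curve(c("0.5" = 0.068, "0.8" = 0.109, "0.95" = 0.130))
fit_anchor_curve <- function(anchors, grid_floor = NULL, linear_tol = 1e-6) {
  theta <- as.numeric(names(anchors))
  value <- as.numeric(anchors)
  if (length(theta) != 3 || anyNA(theta)) {
    abort("anchors must be a named numeric vector of exactly three coverages",
          class = "uhc_curve_error")
  }
  ord <- order(theta)
  theta <- theta[ord]
  value <- value[ord]
  if (anyDuplicated(theta) > 0) {
    abort("duplicate anchor coverages", class = "uhc_curve_error")
  }
  if (any(theta <= 0) || any(theta > 1)) {
    abort("anchor coverages must lie in (0, 1]", class = "uhc_curve_error")
  }
  if (is.unsorted(value)) {
    abort("anchor values must be non-decreasing in coverage",
          class = "uhc_curve_error")
  }
  grid_floor <- grid_floor %||% theta[1]
  cf <- fit_anchor_coef(theta, value, grid_floor, linear_tol)
  tibble::tibble(
    form = cf$form, a = cf$a, b1 = cf$b1, b2 = cf$b2,
    grid_floor = grid_floor, floor_value = cf$floor_value
  )
}

# workhorse behind fit_anchor_curve / fit_curves; returns a plain list
fit_anchor_coef <- function(theta, value, grid_floor, linear_tol) {
  chord_mid <- value[1] +
    (value[3] - value[1]) * (theta[2] - theta[1]) / (theta[3] - theta[1])
  scale <- max(abs(value), 1e-12)
  if (abs(value[2] - chord_mid) / scale <= linear_tol) {
    # least-squares line; interpolates exactly when the points are collinear
    b1 <- stats::cov(theta, value) / stats::var(theta)
    a <- mean(value) - b1 * mean(theta)
    b2 <- 0
    form <- "linear"
  } else {
    coef <- solve(cbind(1, theta, theta^2), value)
    a <- coef[[1]]
    b1 <- coef[[2]]
    b2 <- coef[[3]]
    form <- "quadratic"
  }
  list(form = form, a = a, b1 = b1, b2 = b2,
       floor_value = a + b1 * grid_floor + b2 * grid_floor^2)
}

#' Fit cost and benefit curves for every intervention
#'
#' @param interventions An intervention table (see [read_interventions()]).
#' @param grid_floor Coverage below which increments are constant.
#' @param linear_tol Collinearity tolerance passed to [fit_anchor_curve()].
#' @return A tibble with one row per intervention and quantity
#'   (`quantity` in `"cost"`, `"benefit"`) holding the curve coefficients.
#' @export
#' @examples
#' fit_curves(who_choice_afr_e())
fit_curves <- function(interventions, grid_floor = 0.5, linear_tol = 1e-6) {
  validate_interventions(interventions)
  theta <- c(0.5, 0.8, 0.95)
  n <- nrow(interventions)
  fits <- vector("list", 2 * n)
  k <- 0
  for (i in seq_len(n)) {
    for (qty in c("cost", "benefit")) {
      prefix <- if (qty == "cost") "cost" else "dalys"
      value <- c(interventions[[paste0(prefix, "_50")]][i],
                 interventions[[paste0(prefix, "_80")]][i],
                 interventions[[paste0(prefix, "_95")]][i])
      if (is.unsorted(value)) {
        abort(paste0("anchor values must be non-decreasing in coverage for ",
                     interventions$id[i]), class = "uhc_curve_error")
      }
      cf <- fit_anchor_coef(theta, value, grid_floor, linear_tol)
      k <- k + 1
      fits[[k]] <- c(list(id = interventions$id[i], quantity = qty), cf)
    }
  }
  out <- dplyr::bind_rows(fits)
  out$grid_floor <- grid_floor
  out[, c("id", "quantity", "form", "a", "b1", "b2", "grid_floor",
          "floor_value")]
}

#' Evaluate a fitted curve at given coverage levels
#'
#' Applies the fitted polynomial on `[grid_floor, 1]` and the
#' linear-through-the-origin segment below `grid_floor`.
#'
#' @param curve A one-row tibble from [fit_anchor_curve()].
#' @param theta Coverage fraction(s) in \[0, 1\].
#' @return Per-capita cumulative value(s) at `theta`.
#' @export
curve_value <- function(curve, theta) {
  if (any(theta < 0 | theta > 1)) {
    abort("coverage must lie in [0, 1]", class = "uhc_domain_error")
  }
  ifelse(
    theta < curve$grid_floor,
    theta / curve$grid_floor * curve$floor_value,
    curve$a + curve$b1 * theta + curve$b2 * theta^2
  )
}

#' Cumulative population total at a coverage level
#'
#' `curve_value(curve, theta) * incident_population`: the total annual cost or
#' DALYs averted when the intervention reaches coverage `theta` of its
#' incident population. Zero at `theta = 0`.
#'
#' @inheritParams curve_value
#' @param incident_population Persons per year in need of the intervention.
#' @return Total annual value at `theta`.
#' @export
cumulative_total <- function(curve, theta, incident_population) {
  curve_value(curve, theta) * incident_population
}

#' Incremental population total between two coverage levels
#'
#' The difference of [cumulative_total()] at the two endpoints. Increments are
#' exactly additive over adjacent sub-intervals, which is the arithmetic used
#' to build budget impacts: the cost of going from 60% to 100% equals the sum
#' of the eight 5% step costs.
#'
#' @inheritParams cumulative_total
#' @param theta_from,theta_to Coverage interval `(theta_from, theta_to]` with
#'   `theta_from < theta_to`.
#' @return Incremental annual value over the interval.
#' @export
incremental <- function(curve, theta_from, theta_to, incident_population) {
  if (any(theta_from >= theta_to)) {
    abort("theta_from must be strictly below theta_to",
          class = "uhc_domain_error")
  }
  cumulative_total(curve, theta_to, incident_population) -
    cumulative_total(curve, theta_from, incident_population)
}

#' Marginal (per-capita) rate of a fitted curve
#'
#' The derivative `b1 + 2 * b2 * theta` of the fitted polynomial. This is a
#' diagnostic only: the optimizer always works with finite increments of the
#' cumulative curve, which conserve totals exactly.
#'
#' @inheritParams curve_value
#' @param below_floor What to do for `theta < grid_floor`: `"error"` (default)
#'   or `"segment"`, which returns the constant slope
#'   `floor_value / grid_floor` of the origin segment with attribute
#'   `below_floor = TRUE`.
#' @return Derivative value(s).
#' @export
marginal_rate <- function(curve, theta, below_floor = c("error", "segment")) {
  below_floor <- match.arg(below_floor)
  if (any(theta < 0 | theta > 1)) {
    abort("coverage must lie in [0, 1]", class = "uhc_domain_error")
  }
  below <- theta < curve$grid_floor
  if (any(below) && below_floor == "error") {
    abort("marginal_rate is defined on [grid_floor, 1]; use below_floor = \"segment\" for the origin segment",
          class = "uhc_domain_error")
  }
  out <- ifelse(below, curve$floor_value / curve$grid_floor,
                curve$b1 + 2 * curve$b2 * theta)
  if (any(below)) attr(out, "below_floor") <- below
  out
}

#' Flag curves with negative incremental cost or benefit on a grid
#'
#' Fitted quadratics through rounded anchors can dip, producing locally
#' negative increments (e.g. a benefit curve whose printed anchors are flat).
#' This helper reports every such grid step so they are surfaced rather than
#' silently accepted; downstream, strict dominance treats non-positive-benefit
#' steps as never admissible on their own.
#'
#' @param curves Output of [fit_curves()].
#' @param config A `uhc_config` supplying the coverage grid.
#' @return A tibble of offending steps (id, quantity, theta_from, theta_to,
#'   increment); zero rows if all increments are non-negative.
#' @export
flag_negative_increments <- function(curves, config = uhc_config()) {
  grid <- coverage_grid(config)
  purrr::map_dfr(seq_len(nrow(curves)), function(i) {
    cv <- curves[i, ]
    inc <- diff(curve_value(cv, grid))
    bad <- which(inc < 0)
    if (length(bad) == 0) return(NULL)
    tibble::tibble(
      id = cv$id, quantity = cv$quantity,
      theta_from = grid[bad], theta_to = grid[bad + 1], increment = inc[bad]
    )
  })
}
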