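---
title: "Methods: coverage-aware benefit-package optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-aware benefit-package optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhcoptim)
```

## The decision problem

A health system has a fixed discretionary budget $X$ (2015 US$) to spend on
$N$ candidate interventions. For intervention $i$, reaching a fraction
$\theta_i$ of its incident population costs $x_i(\theta_i)$ per member per
year and averts $b_i(\theta_i)$ DALYs per member per year, both cumulative
in $\theta$. The planner maximizes (optionally equity-weighted) DALYs
averted subject to the budget:

$$\max_{\theta_1,\dots,\theta_N} \sum_i P_i\, b^w_i(\theta_i)
\quad\text{s.t.}\quad \sum_i P_i\, x_i(\theta_i) \le X,$$

with $P_i$ the incident population. Coverage is *contiguous*: funding level
$\theta$ implies every lower level is funded — no "care gaps" where an
intermediate group is skipped — so each intervention has a single coverage
cut-off. At an interior optimum the familiar first-order condition holds:
the ratio of marginal (weighted) benefit to marginal cost of the last funded
increment is equalized across interventions and equals the shadow price
$\lambda$ of the budget. The package reports its empirical counterpart, the
ICER of the last funded increment, as the *marginal productivity* of the
budget.

Assumptions inherited from conventional CEA: interventions are independent
(no economies of scope), one budget period, coverage is equally effective
for everyone reached, and costs/benefits depend on coverage only.

## Curve construction

Cost and benefit anchors are available at $\theta \in \{0.5, 0.8, 0.95\}$.
Below 50% coverage incremental costs and benefits are taken as constant, so
the curve is the chord from the origin. On $[0.5, 1]$ three points determine
either a line or a quadratic $v(\theta) = a + b_1\theta + b_2\theta^2$
exactly:

* **Linearity test.** If the middle anchor lies on the chord of the outer
  anchors within relative tolerance $10^{-6}$ (configurable
  `linear_tol`), the curve is classified linear and fitted by least squares,
  which interpolates collinear points exactly. Printed three-decimal data is
  rarely exactly collinear, so the tolerance mostly matters for synthetic
  data.
* **Quadratic.** Otherwise the $3\times3$ Vandermonde system is solved
  exactly. Either way every anchor is reproduced to $10^{-9}$, which the
  tests assert for all packaged curves.
* **Extrapolation to 100%.** The anchors stop at 95% but the analysis
  evaluates full coverage; the fitted polynomial is extrapolated, and a
  negative extrapolated increment (possible when rounded anchors are flat at
  the top) is clamped to zero with a warning.

The optimizer always uses finite differences of the cumulative curve at grid
points — never derivative × step — so that increments telescope exactly and
totals are conserved through every later transformation. The analytic
derivative `marginal_rate()` is exposed for diagnostics only.

### Units

The anchor columns are interpreted as *cumulative annual cost (or DALYs
averted) per member of the incident population at the given coverage*. This
is the only reading under which the benefit anchors times the incident
populations reproduce the published DALY magnitudes (e.g. TB DOTS:
$0.130 \times 112{,}918 \approx 14{,}700$ at 95%), and it is asserted as a
consistency test rather than assumed.

## Incremental alternatives and dominance

Each intervention is expanded into mutually exclusive coverage steps along
the grid $(0, 0.5], (0.5, 0.55], \dots, (0.95, 1]$. Within an intervention:

* a step with no effective benefit gain at positive cost is **strictly
  dominated** (infinite ICER);
* a step whose ICER exceeds the next step's is **extended dominated**;

dominated steps are merged into their successor — incremental costs and
benefits summed, the ICER recomputed on the merged deltas, constituents
recorded — until the retained ICER sequence is non-decreasing in coverage.
Merging conserves totals exactly (tested at $10^{-9}$). Two numerical
choices: adjacent steps with *exactly equal* ICERs are kept separate
(finer granularity, deterministic), and trailing steps with non-positive
benefit, having no successor, are retained as unfundable rather than
deleted, so conservation still holds.

### Equity weights

The schedule maps coverage bands to weights $\ge 1$ (default: ×2 on
$(0.8, 0.9]$, ×4 on $(0.9, 1.0]$), under the assumption that the
hardest-to-reach decile of patients is the most disadvantaged. Weighted
benefits are computed **on the 5% grid before any merging**, by splitting an
interval at every band boundary and weighting each piece; merged or
all-or-nothing intervals that straddle a decile boundary are therefore
handled by construction. The weights are a policy dial, not data; an all-1
schedule must and does reproduce the unweighted analysis exactly.

## The optimizer

1. **Greedy fill.** Pool all retained alternatives, sort by ICER (ties
   broken by input row order, then coverage), and admit them while
   affordable, stopping at the first alternative that would exceed the
   budget. Within-intervention coverage order is automatic because retained
   ICERs are non-decreasing.
2. **Underspend reallocation.** Drop alternatives whose cumulative cost from
   the current coverage exceeds the remaining budget (this truncation can
   resurrect previously merged-away steps), recompute ICERs incremental to
   current coverage, re-rank, and admit again; repeat until no whole
   alternative is affordable. A pass that admits nothing exits the loop, so
   termination is guaranteed.
3. **Terminal fractional step.** Among each intervention's single next grid
   increment (the first constituent if the next retained alternative is
   merged), fund the lowest-ICER one fractionally, coverage advancing
   linearly in spend, until the budget is exhausted. At most one
   intervention ends off-grid.

Two deliberate behaviours deserve emphasis:

* **Money is never spent on strictly negative health increments.** Rounded
  anchors can make a fitted benefit curve *decline* over a top step; a
  literal completion to 100% under a slack budget would then buy negative
  DALYs and make total benefit non-monotone in the budget. Zero-benefit
  completion steps are admitted when the budget is slack (they are
  harmless); negative ones never are.
* **The reallocation loop is a heuristic, exactly as published.** Admitting
  affordable whole increments with higher ICERs before the fractional
  scale-up can fall short of the divisible-knapsack optimum at lumpy budget
  boundaries. The optimality guarantee — greedy fill plus terminal
  fractional step attains the linear-programming relaxation of the
  mutually-exclusive-alternatives knapsack whenever step ICERs are
  non-decreasing within each intervention — applies to the fill-only
  variant, available as `solve_package(..., reallocate_underspend = FALSE)`
  and certified against brute-force oracles in the validation suite. The
  default remains the full published procedure.

### Scenarios

* `variable_coverage` — ICERs on unweighted benefits.
* `equity_weighted` — identical construction, ICERs on weighted benefits;
  both weighted and unweighted totals are always reported.
* `all_or_nothing` — one alternative per intervention from 0 to 95% (the
  conventional package-design comparator), with cost and benefit linear
  through the origin because only the do-nothing point and the 95% anchor
  are treated as known; the terminal fractional step is allowed.

### Currency calibration

The factor converting 2000 Int$ costs to 2015 US$ is not a data item, and
the package refuses to bake one in: `uhc_config()` defaults it to 1 and
`calibrate_conversion()` recovers it from a structural landmark by
bisection. A uniform cost scaling leaves every ICER ranking unchanged, so
the factor only moves the budget-exhaustion point along the league table,
the landmark-satisfying set of factors is an interval, and bisection is
exact. The default landmark — the terminal fractional intervention of the
variable-coverage scenario is pneumonia treatment within the 70–75% band —
pins the factor to a band of about 4.28–4.31 on the packaged data; the
midpoint is used and both edges are reported.

## Tunable parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `budget` | 2015 US$/year | 15,000,000 | the study's discretionary budget (~15% of domestic government health spending in the region) |
| `conversion_factor` | US$ per Int$ | 1 (calibrate!) | not a published constant; see above |
| `grid_floor`, `grid_step` | coverage fraction | 0.5, 0.05 | the conventional coverage menu 0, 50%, 55%, …, 100%; the grid must land exactly on 1 |
| `weights` | multiplier ≥ 1 | ×2 on (0.8, 0.9], ×4 on (0.9, 1] | illustrative policy weights on the two hardest-to-reach deciles |
| `all_or_nothing_level` | coverage fraction | 0.95 | the anchor at which the comparator scenario offers each intervention |
| `linear_tol` | relative | 1e-6 | collinearity classification of printed anchors |

## What the synthetic generator emulates — and what it does not

`simulate_interventions()` samples cost polynomials through the origin with
positive slope and non-negative curvature, and benefit polynomials through
the origin with non-positive curvature and positive marginal benefit at full
coverage, then evaluates them at the three anchors. This reproduces the
qualitative regime the optimization assumes — marginal unit costs
non-decreasing and marginal benefits non-increasing in coverage, including
the constant-increment segment below 50% — so generated step ICERs are
non-decreasing, dominance elimination is a no-op, and the league-table
optimum is certifiable against exhaustive enumeration. Anchor noise (off by
default) perturbs and re-sorts the anchors.

What passing these tests does **not** show: real tabulated data is rounded,
and rounding produces exactly the pathologies the generator excludes by
design — locally decreasing benefit increments, entry blocks with
higher-than-subsequent ICERs (so dominance merging matters), and flipped
admission orders near the budget boundary. The packaged-data tests exercise
those paths separately; quantities that depend on *which* increment is
marginal (the marginal ICER, the pre-fractional underspend, the identity of
the last partially funded intervention) are sensitive to third-decimal
rounding of the anchors and should be read as calibration-dependent, whereas
scenario totals are dominated by a few large interventions and are robust to
within a few percent.

## Degenerate inputs and edge rules

* Zero budget is valid (empty solution, zero underspend); the marginal ICER
  of an empty solution is an error, signalled distinctly.
* Interventions with zero printed benefit at every anchor can never enter
  any solution and are flagged rather than producing division-by-zero ICERs.
* A coverage grid that does not land exactly on 1, negative budgets,
  overlapping weight bands, or weights below 1 are configuration errors.
* Budget feasibility is enforced to a relative $10^{-6}$; conservation and
  interpolation identities to $10^{-9}$.
* The league-table property (every admitted ICER ≤ marginal ICER) can be
  violated by design by the reallocation loop; `marginal_productivity()`
  reports the exceptions instead of hiding them.

## Problem sizes used in the shipped checks

The packaged analysis (16 interventions × 11 grid steps, three scenarios)
solves in well under a second. The validation suite enumerates brute-force
optima for instances of 4 interventions on up-to-12-level grids ($\le 12^4$
coverage vectors), and the shipped acceptance checks run 100 seeded
instances plus a 20-point budget sweep — sizes chosen so the exhaustive
oracle remains exact and the whole suite completes in a few minutes.

## Known limitations

* Three anchors identify at most a quadratic; no shape-constrained or
  monotone-spline alternative is offered, so rounded anchors can produce
  locally declining fitted benefits (flagged, clamped only beyond the top
  anchor, never purchased).
* The reallocation loop inherits the published procedure's myopia at lumpy
  budget boundaries (see above); an exact mixed-integer solver is
  deliberately out of scope except as a test oracle.
* User fees, financial-protection objectives, multi-period dynamics,
  economies of scope, and parameter uncertainty (e.g. Monte-Carlo on the
  anchors) are outside the model.
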