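# uhcoptim

Optimal design of the discretionary part of a universal health coverage
(UHC) benefit package when both the **depth** of the package (which
interventions) and its **breadth** (what fraction of each intervention's
incident population is reached) must be chosen under a fixed budget.

Health planners in low- and middle-income countries rarely face a clean
"include the intervention or not" decision: reaching the last, hardest-to-reach
patients costs more per person and often yields different health gains than
reaching the first. `uhcoptim` operationalizes the resulting trade-off with
the standard machinery of cost-effectiveness analysis, extended to coverage
levels:

1. **Curves** — for each intervention, cumulative annual cost `x(θ)` and
   DALYs averted `b(θ)` per member of the incident population are known at
   the coverage anchors θ = 0.5, 0.8, 0.95 (WHO-CHOICE convention).
   Increments are assumed constant below 50% coverage; above it, the three
   anchors identify a line or a quadratic exactly.
2. **Alternatives** — coverage enters in mutually exclusive increments along
   the grid 0, 50%, 55%, …, 100%. Each step `(θ₁, θ₂]` carries an
   incremental cost-effectiveness ratio `ICER = Δcost / Δbenefit`.
3. **Dominance** — within each intervention, steps that buy no benefit at
   positive cost (strict dominance) or whose ICER exceeds the next step's
   (extended dominance) are merged forward until ICERs are non-decreasing in
   coverage.
4. **Optimization** — non-dominated steps are funded across interventions in
   ascending ICER order until the budget binds (a greedy solution of the
   mutually-exclusive-alternatives knapsack), the resulting underspend is
   reallocated iteratively, and the single cheapest next increment is funded
   fractionally so the budget is exhausted. The ICER of that last increment
   is the marginal productivity of the budget — the empirical shadow price
   λ of the budget constraint, since at an interior optimum
   `b'(θ*) / x'(θ*) = λ` for every funded intervention.
5. **Equity** — benefits accruing in hard-to-reach coverage deciles can be
   up-weighted (by default ×2 in the penultimate and ×4 in the last decile),
   shifting the optimum toward fuller coverage of fewer interventions.

The package ships the published WHO-CHOICE table for 16 maternal, newborn,
child health, malaria and TB interventions in a hypothetical AFR-E country
of 25 million people (`who_choice_afr_e()`), a synthetic instance generator,
and exact brute-force oracles that certify the optimizer on small instances.

## Worked example

Costs are in 2000 international dollars while the budget is in 2015 US$;
the conversion factor is a user decision, recoverable from a structural
landmark of a known solution rather than baked in:

```r
library(uhcoptim)

iv  <- who_choice_afr_e()
cal <- calibrate_conversion(iv, uhc_config())   # pneumonia marginal in 70-75%
cfg <- uhc_config(conversion_factor = cal$factor)

sol <- solve_package(iv, cfg)
sol
#> <uhc_solution> scenario: variable_coverage
#>   budget 15,000,000 US$, spend 15,000,000, underspend 0
#>   total DALYs averted 198,477 (equity weighted 255,754)
#>   marginal ICER 482 US$ per DALY (pneumonia)
#>   14 of 16 interventions covered, 8 at 100%
```

Fourteen of the sixteen interventions enter the optimal package (the two with
printed benefits of 0.000 never can); malaria case management, TB DOTS,
bed nets and the other best buys are funded to 100%, while screening for
syphilis, measles vaccination and others stop at intermediate coverage.
The budget is exhausted by partially scaling pneumonia treatment up from
70% coverage, so its ICER (≈ US$482 per DALY averted at this calibration)
is the marginal productivity of the discretionary budget: any new money
would buy DALYs at about that price.

`tidy(sol)` returns the per-intervention table (coverage, spend, DALYs,
equity-weighted DALYs, ICER at the funded level), `glance(sol)` the one-row
summary, and `autoplot(sol)` the coverage bar chart. Running all three
scenarios side by side:

```r
cmp <- compare_scenarios(iv, cfg)
cmp$summary[, c("scenario", "dalys_averted", "equity_weighted_dalys")]
#>   scenario          dalys_averted equity_weighted_dalys
#> 1 variable_coverage       198477.               255754.
#> 2 equity_weighted         198390.               255735.
#> 3 all_or_nothing          190761.               240961.
```

Letting coverage vary averts ~4% more DALYs than the conventional
all-or-nothing package design (each intervention at 95% or excluded) under
the same budget — the quantified opportunity cost of insisting on full
breadth.

There is also a thin command-line wrapper:

```sh
Rscript inst/cli/uhcoptim solve --data builtin --scenario all --calibrate --out results/
Rscript inst/cli/uhcoptim validate --seeds 20 --n 4
```

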