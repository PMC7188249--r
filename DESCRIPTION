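Package: uhcoptim
Title: Optimal Design of Universal Health Coverage Benefit Packages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing the discretionary part of a universal health
    coverage (UHC) benefit package when both the set of interventions (depth)
    and the fraction of the incident population reached (breadth) must be
    chosen under a fixed budget. Cumulative cost and benefit curves are
    interpolated through coverage anchors (50, 80 and 95 percent), expanded
    into mutually exclusive 5 percent coverage increments, screened by strict
    and extended incremental cost-effectiveness ratio (ICER) dominance, and
    filled greedily against the budget with an iterative underspend
    reallocation loop and a terminal fractional scale-up. Supports equity
    weighting of hard-to-reach coverage deciles, an all-or-nothing comparison
    scenario, exact brute-force oracles for small instances, and Table-style
    reporting of the optimal package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
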