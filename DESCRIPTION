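Package: imacea
Title: Decision-Tree Cost-Effectiveness Analysis of Implant Movement
    Analysis for Aseptic Hip-Implant Loosening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Health-economic decision-tree model comparing an Implant
    Movement Analysis (IMA) diagnostic pathway against conventional X-ray
    follow-up for suspected aseptic loosening after total hip arthroplasty.
    Provides exact path-enumeration evaluation of expected costs (SEK) and
    quality-adjusted life years (QALYs) over a two-year horizon, trapezoidal
    integration of piecewise-linear health-related quality-of-life
    trajectories, incremental cost-effectiveness ratios with
    willingness-to-pay verdicts and net monetary benefit, probabilistic
    sensitivity analysis on the cost-effectiveness plane, bias-corrected
    bootstrap confidence intervals, scenario and tornado-diagram
    deterministic sensitivity analysis, and synthetic generators for
    cost-per-patient tables and surgeon probability elicitations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
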