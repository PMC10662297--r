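---
title: "Modelling the cost-effectiveness of IMA follow-up for aseptic loosening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of IMA follow-up for aseptic loosening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imacea)
```

## The decision problem

Patients with a painful hip replacement get a plain X-ray to rule aseptic
loosening in or out. The image classifies them as *loose*, *not loose*, or
*uncertain*. The two strategies compared differ only in what happens to the
uncertain group: an Implant Movement Analysis (IMA, a CT-based provocation
test) resolves the diagnosis immediately, whereas a follow-up X-ray does so
only months later, delaying any necessary revision surgery by about a year.
Each strategy is a decision tree of chance nodes; the "decision" itself is
the arm choice, handled at the comparison layer, so within each arm every
node is a chance node. Terminal states carry the resource-use components
accumulated along the path and the name of an HRQoL trajectory.

Evaluation is exact path enumeration: path probabilities are products of
branch probabilities (validated to sum to 1 within 1e-9 at every node), and
expected cost/QALY are probability-weighted sums over terminals. No
discounting is applied over the 2-year horizon, no indirect costs are
modelled (healthcare-payer perspective, largely retired population), and
survival over the horizon is assumed.

## HRQoL trajectories and QALY integration

All profiles share a baseline utility of 0.62 at month 0 and are sampled at
6-month knots to the 24-month horizon. Four constructors encode the
generating assumptions:

| profile | construction | QALYs |
|---|---|---|
| `immediate_surgery` | linear rise to a 0.8 plateau at 18 months | 1.465 |
| `untreated_loosening` | decline of 0.0528 per 6 months (floored at 0) | 1.0288 |
| `delayed_surgery` | decline to surgery at month 12, then linear rise to a delay-adjusted ceiling | 1.198 |
| `other_treatment` | constant 0.65 under conservative management | 1.2925 |

```{r qalys}
sapply(hrqol_profiles(), trapezoid_qaly)
```

Two reconstructions deserve a note, since the published model states the
trajectory assumptions but not every formula:

* **Integration rule.** QALYs are the trapezoid integral over the 6-month
  intervals, baseline included. This is the unique simple rule that
  reproduces all four published QALY totals exactly, so it is adopted (and
  cross-checked in the tests against fine-grid numerical integration).
* **Delay-adjusted ceiling.** The delayed-surgery profile ends at 0.7472 =
  0.8 − 0.0528: the recovery plateau lowered by exactly one 6-month decline
  step. `make_delayed_surgery()` exposes the ceiling as `adjusted_max` so
  alternative adjustment rules can be configured.

Profile-to-terminal assignment: surgery reached after the initial X-ray *or
after IMA* follows `immediate_surgery`; surgery after the follow-up X-ray
follows `delayed_surgery`; loose patients managed non-surgically follow
`untreated_loosening`; not-loose patients follow `other_treatment`. This is
the unique assignment among the four profiles under which the two arms'
expected QALYs round to the published 1.34 / 1.33 with an increment of
0.009.

## Costs and what the defaults can and cannot reproduce

Unit costs (SEK): X-ray 1,029; physician visit 2,635; IMA 9,000; surgery
152,187; CT 4,353; follow-up 5,318; other treatment 5,318. The published
account pins down the composition of only one terminal (revision surgery
after IMA: two physician visits, one X-ray, surgery, CT, IMA). The default
composition generalises that minimally: every path starts with a physician
visit plus X-ray; the IMA step adds a physician visit, CT and the IMA fee;
the follow-up X-ray step adds a physician visit and X-ray; surgery and
other-treatment terminals add their component. The full composition sits in
`inst/extdata/base_case.yaml` for recalibration.

Under these defaults the arm expected costs are about SEK 92,100 and 90,200
(incremental ≈ 1,850, ICER ≈ 205,000 — cost-effective at both thresholds).
The originally reported totals (94,184 / 93,279, incremental 905, ICER
99,681) depend on branch-level compositions in unavailable supplementary
material, so the package documents its totals as approximate rather than
hard-coding a calibrated composition: the QALY side is exact, the cost side
is structural. Correctness of the evaluator itself is guaranteed instead by
property tests (oracle equivalence on randomized trees, exact linearity in
every unit cost).

```{r basecase}
ev <- evaluate_bundle(base_case())
ev$arms
ev$comparison
```

Incremental-effect arithmetic, closed form: the arms differ only on the
uncertain → loose → surgery path (probability 0.15 × 0.3 × 0.75 = 0.03375),
where immediate surgery replaces delayed surgery, so
dQALY = 0.03375 × (1.465 − 1.198) = 0.00901125, printed as 0.009.

A comparison is judged cost-effective at threshold λ iff its net monetary
benefit λ·ΔE − ΔC is non-negative; for ΔE > 0 this is exactly "ICER ≤ λ",
for ΔE < 0 it demands savings of at least λ per QALY forgone (the base case
never leaves the NE quadrant, but the convention is needed for sensitivity
draws). All amounts stay in SEK throughout; any EUR conversion is display
only.

## Probabilistic sensitivity analysis

The published analysis reports a 1000-replicate bootstrap on the
cost-effectiveness plane without stating sampling families, so the package
adopts the standard conjugate conventions and exposes every choice:

* **probability vectors** — Dirichlet per chance-node label, concentration =
  11 × base probabilities (11 being the size of the surgeon panel behind the
  probability elicitation; nodes sharing a label across arms — the initial
  X-ray and its loose branch — receive one common draw, so shared
  assumptions move together);
* **unit costs** — gamma with the base mean and coefficient of variation 0.3
  for surgery, 0.2 elsewhere (the dispersions of the cost extract are not
  public; these are explicit synthetic defaults, matching the synthetic
  generator);
* **utilities** — beta with the base mean and precision κ = 100, applied to
  each profile's utility-valued parameters (baseline, plateau, level); κ =
  100 keeps the ±2 sd band at roughly ±0.1 utility, a typical elicitation
  spread, and is a parameter, not a finding.

`run_psa()` also offers `mode = "cost_resample"` — the reading of
"bootstrapping" in which the cost-per-patient rows themselves are resampled
and their category means become the replicate's unit costs — since the
published wording is ambiguous between parameter sampling and data
resampling; the mode used is recorded in the result.

```{r psa}
psa <- run_psa(base_case(), n = 300, seed = 42)
psa
```

With base-centred distributions the replicate cloud sits overwhelmingly at
positive incremental effect (NE/SE quadrants): the QALY gain is structural
(immediate vs delayed surgery on the uncertain branch) while its size
fluctuates. The vignette uses 300 replicates for speed; analyses and the
test suite use 1000, matching the published replicate count, and complete in
seconds.

## Bootstrap confidence intervals

`bc_bootstrap_ci()` implements the bias-corrected (BC) percentile bootstrap:
z0 is the normal quantile of the share of bootstrap statistics below the
observed statistic, and the interval takes the bootstrap distribution's
quantiles at Φ(2·z0 ± z<sub>α/2</sub>). "Bias-corrected" — not
"accelerated" — is implemented as stated, with BCa (jackknife acceleration)
behind the `accelerated` flag. The resample stream is drawn in one seeded
block so intervals are exactly reproducible; tests verify equivalence with
an independently coded oracle on the same stream and ≥ 90% empirical
coverage at nominal 95% across 200 seeded synthetic 30-patient samples
(small-n BC intervals undershoot nominal coverage slightly, hence the 90%
bar).

```{r boot}
surgery_costs <- gen_cost_records(n = 30, seed = 1)$Surgery
bc_bootstrap_ci(surgery_costs, mean, n_boot = 1000, seed = 2)
```

## Deterministic sensitivity: scenarios and tornado diagrams

`one_way_scenarios()` applies named parameter overrides (probability vectors
renormalised; shared parameters moved in both arms) and tabulates ΔC, ΔE,
ICER and threshold verdicts per scenario. The shipped
`scenarios_default.yaml` contains eight qualitative low/high probability
scenarios (1P–8P) in the style of questionnaire-bound analyses; the original
bounds are in unavailable supplementary material, so the file is labelled
synthetic and meant to be replaced by the user's own elicitation summaries
(`gen_elicitation()` + `summarize_elicitation()` produce compatible
min/mean/max bounds). Invalid overrides skip the scenario with a report
rather than aborting the table.

`tornado()` varies one parameter at a time between its low and high value
and sorts the output swings by width. Because expected cost is linear in
each unit cost, a cost component's bar width equals its total
path-probability weight times the range width — an identity the tests verify
against finite differences; surgery, with the largest cost and weight,
dominates the cost tornado under any proportional range.

## Synthetic data generators

`gen_cost_records()` emulates the hospital cost-per-patient extract:
independent gamma draws per category with the base-case means (IMA excluded
— the 2018 extract predates IMA use), cv 0.3 for surgery and 0.2 elsewhere,
and an optional acute-surgery flag applying a configurable multiplier
(default 1.5) to the surgery mean. Gamma is the conventional family for
non-negative right-skewed healthcare costs. `gen_elicitation()` emulates
surgeon questionnaires as per-respondent Dirichlet draws around base vectors
(default panel size 11; zero-probability branches floored at 1e-6 and
renormalised).

What the generators deliberately do not emulate: correlation between cost
categories (none was described), diagnosis-related-group cost clustering,
and between-surgeon systematic differences (cohort effects beyond Dirichlet
spread). Passing tests therefore demonstrate the pipeline's statistical
machinery — moment recovery, bootstrap coverage, seed discipline — on data
with the assumed structure, not fidelity to the unpublished samples.

## Numerical choices and limitations

* Probability-sum tolerance 1e-9; evaluation in plain double precision with
  no intermediate rounding; costs reported to whole SEK and QALYs to 2–3
  decimals only at display time.
* Single root seed per analysis; PSA, bootstrap and generators derive
  fixed-offset substreams (`derive_seed`) so stages never share draws.
* Trees are validated acyclic-by-construction with a depth guard at 32
  levels (the shipped trees have depth 3).
* Two-arm comparisons only; no efficiency frontier for >2 strategies, no
  Markov extension, no discounting, no value-of-information analysis.
* The cost side of the base case is a documented approximation (see above);
  conclusions that depend on the absolute ICER rather than the QALY
  increment should recalibrate `base_case.yaml` against local cost data.
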