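---
title: "Model and methods: screening-navigation microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: screening-navigation microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

navsim evaluates community patient-navigation programs that raise mammography
screening uptake in underserved populations. It answers the health-economic
question such programs face: given what navigation costs per participant and
how much it moves the screening rate, is the program cost-effective against a
willingness-to-pay threshold? The package simulates individual life courses
under a status-quo and a program screening policy, accrues discounted lifetime
costs and QALYs, and reports incremental cost-effectiveness.

## The disease and screening model

Each simulated woman enters the cohort at an integer age of 40 or older and is
advanced in annual cycles to an absorbing maximum age (default 100). The
disease process is the classic screening natural-history skeleton:

* **healthy** — subject to onset with annual hazard
  `onset_hazard_scale * exp(onset_age_shape * (age - 60))`;
* **preclinical DCIS → local → regional → distant** — screen-detectable but
  not yet symptomatic; at most one stage transition per cycle, plus a
  stage-specific chance of symptomatic (clinical) surfacing;
* **clinically diagnosed** — stage is frozen at diagnosis; a stage-specific
  excess annual death probability applies from then on, alongside background
  mortality;
* **death** — from breast cancer or other causes.

Within a cycle, events are resolved in a fixed order: other-cause death,
onset, progression, symptomatic surfacing, screening, breast-cancer death.
The order is a reproducibility device (ties are impossible by construction);
putting other-cause death first is conservative in that a woman who dies this
year can neither be screened nor diagnosed. Steps act on the state as already
updated within the cycle, so a cancer arising this year can in principle
surface this year; sojourn dynamics finer than one year are out of scope.

Screening acts purely through **stage shift**: a screen detects a preclinical
cancer with stage-dependent sensitivity, and everything downstream (excess
mortality, treatment cost, utility decrement) depends on the stage at
diagnosis. A healthy attendee can test false positive (cost consequence only,
no lasting utility decrement). The program's qualitative effects — knowledge,
attitudes, adherence — enter the model only through the uptake parameter,
which is the single quantitative channel the comparison uses.

The two arms differ *only* in the three-year program window: with probability
`three_year_uptake` (0.60 status quo, 0.80 program) a woman receives exactly
one window screen at a uniform year offset. We read the published 60%/80%
figures as cumulative three-year proportions screened at least once, matching
the program's horizon, rather than per-round adherence rates. After the
window, both arms share the same routine behaviour: rounds every two years,
attended independently with probability 0.60. This isolates the program
effect; the model deliberately does not assume permanent behaviour change.

## Randomness and common random numbers

Every decision consumes one uniform draw indexed by (person, decision
channel, age), derived deterministically from `root_seed + person_id`.
Because draws are positionally assigned rather than consumed on demand, the
two arms of a comparison share every draw: a woman attends the same
background rounds, has onset in the same year, and progresses identically in
both arms until a policy-driven event (the program-window screen) makes her
trajectories diverge. Incremental estimates therefore reflect the policy,
not sampling noise — essential here, where true incremental QALYs are three
orders of magnitude smaller than per-person variability. A scalar
per-person engine (`run_life_course()`) consumes the same draws as the
vectorized cohort engine (`simulate_arm()`); the test suite holds the two
routes equal person for person.

## Accounting conventions

* Annual cycles with a **half-cycle correction**: the year of death credits
  0.5 life years (and 0.5 years of utility and any per-year quantity). The
  closed-form oracle `expected_remaining_years()` returns expected complete
  years; accrued life years equal that plus exactly 0.5.
* Life expectancy is reported **undiscounted**; costs and QALYs are
  discounted at 3% per year to cohort entry, `(1 + r)^(-t)` at year offset
  `t`. (With per-arm QALYs near 14 against life expectancies near 22–23,
  only this reading is internally consistent.)
* Utility is `utility_healthy` while undiagnosed (preclinical disease is
  asymptomatic, so it carries no decrement) and
  `utility_healthy - utility_decrement_by_stage[s]` from the diagnosis year
  onward.
* Costs attach to events: each attended mammogram, each false-positive
  work-up, stage-specific treatment in the diagnosis year, terminal care in
  the year of breast-cancer death, and — in the program arm only — the
  program cost per participant, once, at entry (discount factor 1).
  No cost-year inflation adjustment is applied.

## Background mortality

Other-cause mortality is Gompertz–Makeham,
`q(x) = 1 - exp(-(c + a e^{bx}))`, with `q` forced to 1 at the maximum age.
The closed form gives exact oracles for annual death probabilities and
discrete life expectancy, against which the stochastic engine is tested. The
defaults (`c = 0.002`, `a = 5e-5`, `b = 0.092`) give the default 40–70
uniform entry mix a cancer-free life expectancy of about 23.4 years —
deliberately below general-population life tables, because the modelled
population is uninsured and low-income and its published status-quo life
expectancy (22.32 years from age 40+) implies elevated background mortality.
A life-table CSV override (`read_life_table()`) replaces the parametric law
when an empirical table is available.

## Calibration

The published evaluation reports per-arm outcomes (cost, life expectancy,
QALY for each arm) but not the underlying transition parameters, so the
shipped disease-model defaults are uncalibrated placeholders (tagged as such
in the configuration) and `calibrate()` is the sanctioned way to obtain a
parameter set that reproduces the outcomes. Six free parameters are fitted
to the six per-arm cells by minimising a weighted sum of squared *relative*
errors, which makes dollar-scale and QALY-scale cells commensurable:

* three epidemiological scales — the onset hazard scale and multiplicative
  scales on the symptomatic-surfacing and excess-mortality stage maps —
  searched by a Nelder–Mead simplex on a logit-box transform (golden-section
  search when only one is free), bounded so scaled probabilities stay inside
  `[0, 1]` and the strict stage ordering is preserved;
* three linearly entering parameters — the treatment-cost scale, the
  utility-decrement scale, and the program cost per participant — profiled
  *exactly* at every simplex evaluation by weighted least squares on the
  engine's per-person components. Profiling has the same minimum as the
  joint six-dimensional search but removes its worst conditioning, and it
  is re-applied exactly on the final confirmation run.

Each loss evaluation simulates both arms over 20,000 persons under common
random numbers with a fixed root seed, so the loss is a deterministic
function of the parameters; the final confirmation run uses 100,000 persons,
the published simulation scale. These sizes trade Monte-Carlo noise against
evaluation cost and are configurable. The fixed parameters (stage-progression
rates, sensitivity, unit costs, `utility_healthy = 0.92`) stay at their
defaults; `utility_healthy` in particular anchors the overall QALY level —
it was chosen so that plausible discounted life expectancies bracket the
published QALY levels with the decrement scale inside its bounds, a
deliberate identifiability choice. The calibrated set is a *sufficient*
reproduction of the published outcomes, not a unique recovery of the original
model: a parameter-recovery test (targets simulated at known parameters,
calibration from a perturbed start, all six parameters recovered within 10%)
checks the machinery, not uniqueness.

### What the calibrated model does and does not reproduce

At the confirmation scale the calibrated model reproduces all six per-arm
cells to within 2% (the cost cells exactly, by construction of the profiling
step), and its incremental cost-effectiveness ratio is well below the
$50,000/QALY threshold. It does **not** reproduce the published *incremental*
magnitudes (0.71 life years, 0.04 QALYs): under this model structure the arms
differ only in one program-window screen for the 20% of women between the two
uptake levels, while shared biennial background screening recovers most
missed detections a round or two later, so the structural increments are of
order 0.01 life years. A 0.71-year mean gain from a 20-point uptake change
would require either a much larger per-screen benefit than stage shift with
shared background screening can deliver, or arm differences (e.g. persistent
adherence change) that the published description does not quantify. The
incremental deltas are therefore reported as computed, with the per-arm
levels — and the cost-effectiveness conclusion — as the calibration surface.

## Sensitivity analysis

`two_way_frontier()` varies the achieved three-year screening rate and the
program cost per participant jointly. Because the program charge enters
per-person cost additively at discount factor 1, the incremental cost at a
fixed rate is affine in the charge; one simulation per rate (against a single
fixed status-quo run, common random numbers) yields the ICER at every cost
analytically, and the frontier — the largest charge keeping the program
cost-effective — solves `ICER = threshold` exactly:
`cost*(rate) = threshold × ΔQALY(rate) − ΔC₀(rate)`. A point with the ICER
exactly at the threshold counts as cost-effective; the boundary has
probability zero and the published wording is loose either way. At the
status-quo rate common random numbers force ΔQALY = 0 and the frontier is
undefined; it is also undefined wherever no non-negative charge qualifies.
Default grids are rates 0.60–0.80 by 0.01 and charges $0–$6,000 by $50.
Published frontier landmarks depend on the original unpublished parameter
set and are checked directionally only (the frontier rises toward the
80% end on the calibrated model).

## The synthetic cohort

No person-level data are distributed, so the cohort module generates the
target population: women aged 40 and older, entry ages drawn i.i.d. from a
configurable discrete distribution on 40–70 (default uniform; the program's
true entry-age mix was not published), all healthy at entry. A cohort CSV
(`person_id,entry_age`) can replace the generator. What the synthetic cohort
deliberately does not emulate: secular trends in background mortality or
incidence, insurance churn, risk heterogeneity beyond age, and men or women
under 40. Tests passing on this cohort show the machinery is correct under
the stated assumptions, not that the assumptions describe any particular
real population.

## Numerical choices and degenerate inputs

* Probabilities are validated into `[0, 1]` at construction; stage maps must
  be (strictly, where the model requires it) increasing with stage.
* `q(max_age) = 1` guarantees termination; a defensive loop guard forces
  other-cause death at the cap.
* A one-person cohort returns `NA` standard errors and a degeneracy flag.
* Identical policies in both arms give exactly zero deltas (flagged
  `NO_DIFFERENCE`); dominance quadrants are labelled `DOMINANT`/`DOMINATED`,
  and the southwest quadrant (cheaper, less effective) reports the ratio with
  a flag and counts as cost-effective when savings per QALY forgone meet the
  threshold.
* Display rounding (cents, two decimals, ICER to the cent) is applied only
  in printed tables and the `display_*` CSV companions; internal arithmetic
  is unrounded.

## Known limitations

Annual cycles cannot represent sub-year sojourn times; there is no tumour
growth model, no hormone-receptor subtypes, no recurrence after cure (the
excess-hazard formulation subsumes cure fractions without identifying them),
no indirect costs, and no probabilistic sensitivity analysis. The
calibration ties the model to six aggregate outcomes; many parameter sets fit
them equally well, and conclusions that depend on unidentified internals
(e.g. the split of incremental cost between program charge and averted
treatment) inherit that non-uniqueness.
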