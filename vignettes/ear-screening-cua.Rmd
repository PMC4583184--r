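---
title: "Methods: a lifetime Markov cost-utility model of ear-disease screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime Markov cost-utility model of ear-disease screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earcea)
```

## The problem

Indigenous Australian children experience some of the highest rates of
otitis media (AOM, OME, CSOM) and consequent conductive hearing loss in
the world. Untreated ear disease in childhood progresses to permanent
hearing loss, which carries lifelong costs: educational support,
hearing aids or cochlear implants, and reduced adult income. Screening
and surveillance programs aim to detect latent disease early enough for
medical (antibiotic) or surgical treatment to restore healthy hearing.

`earcea` implements a decision-analytic comparison of two screening
strategies for a regional Queensland community:

* **Deadly Ears** — the existing outreach program: ad-hoc screening by a
  community health worker (annual screening probability 0.39) plus a
  visiting ENT surgical service;
* **MTESS** — the same program supplemented by a mobile
  telemedicine-enabled screening van that raises the annual screening
  probability to 0.80, at a higher cost per screen ($117 vs $88).

## Model structure

The engine is a five-state Markov cohort model with annual cycles from
age 3 to age 50:

`HealthyEnrolled`, `HealthyDischarged`, `EarProblem`, `HearingLoss`,
`Dead`.

Each cycle, enrolled healthy children and children with an ear problem
are screened with the strategy's screening probability (until age 18).
The one-cycle transition probabilities are obtained by collapsing a
screening → detection → treatment → outcome probability tree
(`collapse_decision_tree()`):

* a screened ear problem is detected with probability $1 - p_{FN}$
  ($p_{FN} = 0.05$); an unscreened one is detected through a GP visit
  with probability 0.219;
* a detected case obtains treatment with probability 0.86, medical with
  probability 0.80 (else surgical), and treatment succeeds with
  probability 0.90, returning the child to health;
* failed or undetected disease progresses to permanent hearing loss
  with annual probability 0.10, otherwise persists;
* a screened healthy child returns a false positive with probability
  $1 - p_{TN}$ ($p_{TN} = 0.90$), incurring one medical work-up but
  staying healthy; a true-negative screen at or after age 9 discharges
  the child from the program (no further screening cost);
* hearing loss is permanent: its only exit is death. Mortality applies
  to every living state as a competing final split and is never altered
  by disease ("no additional mortality").

From 18 onwards nobody is screened; detection is GP-only and adult
treatment costs apply. Rewards (costs and utilities) accrue on
start-of-cycle occupancy; transitions are evaluated at cycle end. Costs
and QALYs are discounted at 5%/yr with half-cycle correction (half
weight on the first and terminal cycle), implemented in
`discount_and_correct()`.

The single largest structural assumption is this canonical tree itself:
the published state diagram of the source model is not fully
determined by its description, and several choices (annual rescreening
of symptomatic children, success returning to the enrolled-healthy
state, the discharge rule) were fixed once as the most natural reading.
The consequences are discussed under *Known limitations*.

## Parameters

All parameters live in a single validated `ear_spec` object
(`baseline_spec()`), serializable to YAML or JSON
(`save_model_spec()` / `load_model_spec()`); packaged fixtures
`base_case`, `age4_start` and `no_screening` ship under
`inst/extdata/`. Costs are 2013–14 AUD.

* **Screening**: probabilities 0.39 / 0.80; costs $88 / $117 per screen,
  derived from the itemised service bundles (below).
* **Treatment**: medical $82 (child) / $91 (adult); surgical $2,369
  (child, outreach clinic) / $6,021 (adult, hospital DRG).
* **Hearing-loss consequences**: education support $7,116/yr for ages
  5–17; income loss $6,681/yr from age 16; hearing-aid uptake 0.05
  (children) / 0.35 (adults) at $1,606/yr. The aid mix defaults to 100%
  non-cochlear; the cochlear cost ($3,152/yr, a $32,714 implant
  amortised over 15 years at 5%) enters through the configurable
  `aid_split` and the sensitivity analyses. The published cost table
  heads these items "(monthly)" while describing them per annum; they
  are treated as annual.
* **Utilities**: healthy child 1.000, healthy adult 0.900, hearing loss
  0.677; the ear-problem state takes the unweighted mean per age class
  (0.839 / 0.789, `derive_ear_utility()`, half-up rounding to 3
  decimals). Where the source text and its parameter table disagree
  (screening probability 0.35 vs 0.39; adult utility 0.95 vs 0.900) the
  table value is used — it is the one the sensitivity ranges bracket.
* **Incidence**: the annual probability of developing an ear problem is
  piecewise-constant in age. No schedule is published; the default is
  *calibrated* (`calibrate_incidence()`, bisection per band on
  [0, 0.5]) so that the unscreened validation scenario reproduces the
  published hearing-loss prevalences among survivors: 7.4% at age 15
  and 16.8% at age 45 (achieved within ±0.005). The calibrated bands
  are 0.0268/yr (ages 3–14) and 0.0090/yr (15+). Uniqueness is not
  claimed; the schedule is overridable.
* **Mortality**: Queensland Indigenous life tables are not published
  with the model; the default is a smooth Gompertz schedule
  $q(a) = 2.4\times10^{-4} e^{0.072a}$, a realistic fit to published
  Indigenous Queensland age-specific death rates (~3×10⁻⁴ at age 5 to
  ~6×10⁻³ at 45, ~89% survival to 50). Fully overridable.
* **Initial cohort**: split between healthy and ear problem at the
  start-age incidence; nobody starts with hearing loss.

## Costing

Capital items are converted to annual equivalent costs by dividing the
purchase cost by the annuity factor $\frac{1-(1+r)^{-L}}{r}$ (zero
salvage; straight-line at $r = 0$). Service bundles
(`deadly_ears_screening_bundle()`, `mtess_screening_bundle()`,
`outreach_surgery_bundle()`) sum annuitized capital and recurrent rows
at full precision; rounding to whole dollars happens only at reporting.
Two published cells are internally inconsistent and are handled
explicitly: the mobile service's staff line is computed as
2 × $73,238 = $146,476 (the printed total requires it), and recurrent
rows whose printed dollar cells differ slightly from quantity × rate
(mileage, visiting-staff hours) are stored at their printed values.

## Cost-effectiveness analysis

`compare_strategies()` reports increments (comparator − reference), an
ICER when both increments share a sign, and `Dominant` / `Dominated` /
`Indifferent` otherwise. Acceptability uses net monetary benefit
$\lambda \Delta Q - \Delta C \ge 0$, inclusive at the boundary.
`quadrant_table()` mirrors the published six-row plane summary
(quadrants I and III split at each threshold, dominance separate).

## Sensitivity analysis

* **One-way (DSA)**: `run_dsa()` re-runs the comparison with each of
  the 23 published parameters at its range bounds (`dsa_ranges()`),
  recording the verdict at each end without assuming direction.
* **Probabilistic (PSA)**: `run_psa()` samples every parameter carrying
  a distribution — beta for probabilities with SE = 20% of base (method
  of moments), gamma for costs (shape $(m/s)^2$, scale $s^2/m$),
  triangular over the published ranges for expert-elicited
  probabilities and utilities — independently (no correlation
  structure is published), in fixed declaration order from one seeded
  generator, so results are bit-reproducible. Ear-problem utilities are
  re-derived from the drawn healthy and hearing-loss utilities each
  draw. Triangular probability draws are clipped to [0, 1] (never
  active at base settings); the gamma is untruncated.

## Numerical choices

* Occupancy vectors conserve mass to 1e−12 by construction; a property
  test checks this on 100 random parameter sets.
* `run_cohort()` uses an unrolled scalar recursion for speed (~0.5 ms
  per lifetime run); a regression test pins it to the matrix-product
  path built from the exported transition matrices at 1e−12.
* Calibration: bisection (`uniroot`, tol 1e−8 on the incidence) per
  band, sequential because prevalence at a target age depends only on
  earlier bands; achieved prevalence within ±0.005 or an error.
* Problem sizes: the packaged analyses use the full 48-cycle horizon;
  the PSA uses 10,000 draws (a few tens of seconds); test-suite
  property loops use 25–100 random specs.

## The synthetic generator and what tests show

`generate_model_spec()` draws random valid parameter sets (probabilities,
costs, utilities respecting the ordering constraints) for property
testing, with degenerate modes (no death, no disease, two-state) that
zero parameters rather than switching code paths, so closed-form
oracles (`closed_form_two_state()`) exercise the production engine.
These specs emulate the *shape* of the model's inputs, not real
epidemiology: passing property tests demonstrates internal correctness
(stochasticity, conservation, monotonicity, oracle agreement), not that
any particular community's disease burden is represented.

## Known limitations

* With the canonical tree, screening detection (0.50–0.80/yr effective)
  so exceeds GP-only detection (0.219/yr) that the mobile service
  prevents far more hearing loss than the source model's own published
  traces imply (hearing-loss prevalence at 15: 3.7%/1.7% for the two
  strategies here vs 6.8%/5.8% published, against the same unscreened
  7.4%). The consequence-cost savings then make MTESS *dominant* at
  base (total costs $6,191 vs $4,188) rather than marginally more
  costly with a small ICER, and the PSA cloud sits ~97% in the
  dominant quadrant. The reference-program totals ($6,191 vs published
  $6,235) and the unscreened validation prevalences reproduce well; the
  strategy *difference* is structurally larger here. No published
  arrangement of this state space yields both the validation
  prevalences and the published strategy gap, so the divergence is
  documented rather than tuned away. The qualitative conclusion — the
  mobile service is cost-effective at any conventional threshold — is
  unchanged and, if anything, strengthened.
* Cohort (not individual-level) simulation: no memory of past episodes,
  no within-year event timing.
* One ear-problem state pools AOM/OME/CSOM severity; progression and
  treatment-success probabilities are averages.
* Mortality and incidence schedules are modelled defaults, not measured
  community data; both are configurable inputs.
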