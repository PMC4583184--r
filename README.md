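# earcea

Cost-utility modelling of ear-disease screening and surveillance
programs for Indigenous Australian children.

Chronic otitis media in Indigenous communities drives conductive
hearing loss with lifelong consequences — educational support needs,
hearing aids, reduced adult income. `earcea` is a lifetime five-state
Markov cohort model (ages 3–50, annual cycles) for asking whether a
supplemental mobile telemedicine-enabled screening service (**MTESS**,
annual screening probability 0.80 at $117/screen) is worth adding to an
existing outreach screening and surgical program (**Deadly Ears**,
probability 0.39 at $88/screen). It is aimed at health-economics
analysts who want the whole pipeline — costing, cohort engine,
incremental analysis, uncertainty analysis — as tested, scriptable R.

The core quantities are the discounted totals of each strategy and the
incremental cost-effectiveness ratio

ICER = (C_MTESS − C_DE) / (Q_MTESS − Q_DE)   [AUD per QALY],

with dominance when one strategy is both cheaper and more effective,
and the cost-effectiveness acceptability curve
P(λ·ΔQ − ΔC ≥ 0) over willingness-to-pay thresholds λ. Costs and QALYs
are discounted at 5%/yr with half-cycle correction; capital costs enter
as annual equivalents, `cost / ((1 − (1+r)^−L)/r)`.

## Worked example

```r
library(earcea)

unit_cost(deadly_ears_screening_bundle())   # 88   (AUD per screen)
unit_cost(outreach_surgery_bundle())        # 2369 (AUD per operation)
annual_equivalent_cost(32714, 15, 0.05)     # 3151.742 (cochlear implant, AUD/yr)

spec <- baseline_spec()
run_comparison(spec)
#> <ce_result> MTESS vs DeadlyEars
#>   cost:  DeadlyEars 6191 | MTESS 4188 | delta -2003.76
#>   QALYs: DeadlyEars 17.094 | MTESS 17.196 | delta +0.1019
#>   verdict: Dominant

ns <- no_screening_spec(spec)               # business-as-usual validation
hl_prevalence(run_cohort(ns, "DeadlyEars"), 45)
#> [1] 0.168
```

Reading: per person entering at age 3, the outreach program alone costs
a discounted $6,191 over the lifetime horizon; adding the mobile
service costs $4,188 — the extra screening spend is more than repaid by
avoided hearing-loss costs — while adding 0.102 discounted QALYs, so
under this model's structural assumptions the mobile service
*dominates* (see the methods vignette for how this relates to the
published base case, which put MTESS marginally dearer at an ICER of
$656/QALY). The validation scenario with no screening reaches 16.8%
hearing-loss prevalence among survivors at age 45, matching the survey
prevalence the incidence schedule is calibrated to.

The full analysis pipeline lives in `analysis/` as numbered drivers
(`01_costing.R` … `05_psa.R`), each writing its tables under
`results/`:

```sh
Rscript analysis/02_base_case.R   # base case + start-age/discount scenarios
Rscript analysis/05_psa.R         # 10,000-draw PSA, quadrants and CEAC
```

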