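---
title: "Model and methods: cervical cancer screening strategies in HIV-infected women"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervcost)
```

## The decision problem

HIV-infected women in sub-Saharan Africa carry a high burden of cervical
pre-cancer and cancer, and HIV-treatment clinics are a natural point of
integration for screening. `cervcost` models a cohort of HIV-infected women
who receive a single screening (or preventative treatment) intervention at
age 38 and are then followed to death, comparing seven strategies:

* **cryo_all** — preventative cryotherapy for every woman, no screening
  (1 visit);
* **VIA** — visual inspection with acetic acid, same-day screen-and-treat
  (1 visit);
* **Pap**, **HPV** — cytology or careHPV DNA testing, results and treatment
  at a follow-up visit (2 visits);
* **VIA+HPV**, **VIA+Pap**, **HPV+Pap** — paired testing with a confirmatory
  visit (3 visits).

Each strategy is scored by discounted lifetime cost (2014 USD, societal and
clinic perspectives) and discounted life expectancy from screening.

## Health states and monthly dynamics

The natural history uses the SIL framework common in models of HIV-infected
populations: `Normal`, `LSIL`, `HSIL`, three untreated invasive stages
(`LocalCancer`, `RegionalCancer`, `DistantCancer`), three treated stages,
and two absorbing death states (`DeadCancer`, `DeadOther`) — eleven states.
Movement occurs in monthly cycles. Within a cycle, background death is
applied first (the model's only competing-risk ordering; the published
inputs are monthly probabilities, not rates, so an ordering must be fixed
and this one is); conditional on surviving it, the monthly progression,
regression, cancer-mortality and cure probabilities apply directly, and the
residual mass stays in state. Rows are checked for oversubscription at
construction.

Background mortality is an age-indexed annual probability of death `q(a)`
from a female life table, converted to a monthly probability under a
constant hazard within the year and scaled by the standardized mortality
ratio (SMR) for treated HIV-infected women **on the hazard scale**:

```
q_m(a) = 1 - (1 - q(a))^(SMR / 12)
```

The hazard-scale application keeps `q_m <= 1` for any SMR and matches
demographic practice; for the small annual risks that dominate the horizon
it is within 3% of the naive multiplicative version (a tested property).

Treated cancer states use cancer mortality and onward progression scaled by
`1 - treatment_effectiveness` (base 0.9, i.e. a 90% hazard reduction) and
move to `Normal` with the monthly cure probability (base 0.15). The single
published effectiveness number also serves lesion treatment: treated HSIL
regresses to `Normal` immediately with probability 0.9, and a treatment
failure leaves untreated HSIL. This is the one genuinely open reading in
the model — the original analysis' software encoding is not recoverable —
and the one-way range 0.7–1 is propagated through it consistently.
Cured disease re-enters `Normal` with no memory: the progression inputs are
population aggregates with no history dependence, and recurrence is
deliberately not modeled.

## The screening cascade (month 0)

Test positivity is defined at the CIN2+ threshold: `HSIL` and all cancer
states trigger a positive result with the test's sensitivity; `Normal` and
`LSIL` with one minus its specificity. Pair strategies use their own
published joint sensitivity/specificity, and both tests' unit costs are
charged to every screened woman (only joint performance is published, so
the second test cannot be priced conditionally; the screening-cost tornado
ranges absorb this).

Loss to follow-up (LTFU) removes women before the final treatment visit:
completion is 1 for 1-visit strategies, `1 - ltfu_2visit` (base 0.32) for
2-visit, `1 - ltfu_3visit` (base 0.48) for 3-visit. Lost women accrue all
screening costs but no treatment, benefit, or side effects — the only
cost-consistent single reading of one aggregate LTFU number per visit
count.

Screen-positive completers with `Normal`/`LSIL`/`HSIL` receive ablative
treatment: cryotherapy with probability 0.8, LEEP with 0.2, plus one month
of side-effect risk (probability 0.01/month, 16% major). Screen-positive
completers in a cancer state receive colposcopy — the gateway to staging —
plus the stage-specific cancer-care package and enter the treated state.
Colposcopy is charged nowhere else: lesions are treated screen-and-treat,
without colposcopic confirmation.

Women whose invasive cancer goes undetected by screening (false negatives,
LTFU, and the whole `cryo_all` arm) are handled by a symptomatic-detection
rule: entering — or starting in — regional or distant cancer triggers
staging and treatment with probability 1 in that month; local cancers
remain undetected until they progress. The rule is a configuration block
(`symptomatic_detection`) so its influence can be probed; late-stage
symptomatic presentation is the standard assumption when no detection
probabilities are published.

Treated regional/distant states accrue monthly palliative care until cure
or death, and all treated cancer states carry monthly side-effect risk;
both start the month after entry (the entry month carries the stage cost).

## Discounting, accrual, horizon

Costs and life-years are discounted at 0.25% per month exactly as
published (not `1.03^(1/12) - 1`). Life-years accrue 1/12 per live
person-month at the start of each survived month; there is no half-cycle
correction — with monthly cycles the attainable difference is bounded by
half a cycle, about 0.04 years over the horizon, well below the precision
of any comparison made here. The iteration stops at the life-table closure
age (100, where `q = 1`) or when live mass falls below 1e-9. Both
discounted and undiscounted life expectancy are reported; the published
headline values are compared against the discounted series, since the
source states that costs *and benefits* were discounted.

## Parameters

All base-case values, one-way min–max ranges, and the CD4-scenario
overrides ship as YAML documents under `inst/extdata/` (one key per
published cell) and load through `load_parameters()`; `apply_scenario()`
overrides exactly the cells the CD4 ≤ 200 or CD4 > 500 column specifies,
with every `N/A` cell inheriting the base case. Two numerical conventions:

* the CD4 ≤ 200 column's normal/LSIL split is printed as 0.832/0.169
  (sum 1.001); it is stored as printed and the split vectors are
  renormalized where consumed. The same convention lets the one-way
  analysis vary a single simplex component (e.g. the HSIL share over
  0.762–1) without invalidating the distribution.
* each cost row publishes a single min–max; the range is applied to the
  societal value with the clinic value scaled proportionally.

## Synthetic life table

The reference analysis drew background mortality from the WHO Kenya 2011
female life table, which is not part of this package.
`synthetic_life_table()` generates a deterministic Gompertz–Makeham
schedule, `q(a) = 1 - exp(-(A + B c^a))`, with defaults `A = 0.004`,
`B = 4e-5`, `c = 1.095` over ages 30–100 chosen once to emulate the adult
female mortality of a high-HIV-burden East African population around 2011:
adult mortality (45q15) near 0.25, annual death probability rising to
roughly 6% by age 80, and closure `q(100) = 1`, which bounds the horizon at
744 monthly cycles from age 38. The synthetic schedule is smooth and
monotone; it does not reproduce the WHO table's exact age profile, so runs
on it support structural and qualitative conclusions (orderings,
directions, sensitivity structure) rather than exact reproduction of
published magnitudes. `read_life_table()` accepts any two-column CSV
(`age,q_annual`) for users who export the WHO table themselves.

## Validation strategy

Three layers, all in the test suite:

1. **Closed forms.** In the disease-free constant-mortality limit the
   engine's discounted life expectancy must match the geometric annuity
   `1 / (12 (1 - s v))`, `s = (1-q)^{1/12}`, `v = 1/1.0025`, to a relative
   error below 1e-6; a zero-mortality, zero-cost world must yield exactly
   62.0 undiscounted years.
2. **Invariants.** Mass conservation each cycle; row-stochastic matrices
   at every age and scenario; perfect specificity implies zero
   false-positive cost; life expectancy monotone in sensitivity
   (non-decreasing) and LTFU (non-increasing); societal cost dominates
   clinic cost; the LTFU bisection root must coincide with a 101-point
   grid search.
3. **Microsimulation oracle.** `microsimulate()` samples individual women
   through the identical cascade and transition logic, drawing the actual
   events (cryotherapy vs LEEP, side-effect occurrence and severity)
   whose expectations the cohort engine charges. Cohort and
   microsimulation must agree within 3 Monte Carlo standard errors on cost
   and life expectancy at n = 50 000 per strategy — the problem size used
   throughout the validation scripts and tests, large enough to resolve
   differences of a few dollars and a few hundredths of a year.

## Known limitations

* One lifetime screen at a fixed age; no periodic screening, no optimal-age
  search.
* No explicit HPV-DNA compartments: the published parameters describe only
  lesion/cancer grades, so the lesion-grade chain is the implementable
  model.
* No cancer recurrence and no history dependence, by design of the inputs.
* The symptomatic-detection rule and the pair-test costing are documented
  structural choices where the source is silent; both are exposed to
  sensitivity analysis rather than hidden.
* Quantitative agreement with the published lifetime costs and life
  expectancies depends on the WHO life table and on those structural
  choices; the bundled synthetic table supports the qualitative and
  structural claims, and the acceptance tests report the quantitative
  comparison transparently at the stated tolerances.
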