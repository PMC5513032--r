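# cervcost

A Markov cohort model of cervical cancer screening and preventative
cryotherapy in HIV-infected women, built for cost-effectiveness comparison
of screen-and-treat strategies at an HIV treatment clinic.

Cervical cancer is a leading cause of cancer death among women in
sub-Saharan Africa, and HIV infection raises both the risk of disease and
background mortality. `cervcost` is for health-economics and epidemiology
analysts who want a transparent, fully tested implementation of the
standard decision-model machinery for this question: which of seven
once-in-a-lifetime interventions — preventative cryotherapy for all women,
VIA (same-day screen-and-treat), Pap, careHPV testing, or their pairwise
combinations — minimizes lifetime cost and maximizes life expectancy.

## The model

A deterministic state-transition (Markov cohort) model over eleven health
states — Normal, LSIL, HSIL, local/regional/distant invasive cancer, the
corresponding treated states, and two absorbing death states — iterated in
monthly cycles from the screening age (38) to age 100. For state
distribution $x_t$ and age-specific transition matrix $P_t$:

$$x_{t+1} = x_t P_t, \qquad
  \text{LE} = \sum_t \frac{v^t}{12}\, \mathbf{1}^\top_{\text{live}} x_t, \qquad
  \text{Cost} = \sum_t v^t c_t^\top x_t, \qquad v = \tfrac{1}{1.0025}$$

Background mortality enters from a female life table as
$q_m = 1-(1-q_{\text{annual}})^{\text{SMR}/12}$ (SMR 1.77 for treated
HIV-infected women, applied on the hazard scale). The month-0 screening
cascade maps test sensitivity/specificity (CIN2+ threshold), multi-visit
loss to follow-up (32% for 2-visit, 48% for 3-visit cascades), the 80/20
cryotherapy/LEEP treatment mix, side effects, and colposcopy-gated cancer
staging into per-state treatment probabilities and expected costs, under a
societal or clinic cost perspective (2014 USD). An individual-level
microsimulation with identical logic serves as a Monte Carlo validation
oracle for the cohort engine. See `vignettes/cervcost-methods.Rmd` for the
full model account and design decisions.

## Worked example

```r
library(cervcost)

params <- load_parameters(system.file("extdata", "parameters_base_case.yaml",
                                      package = "cervcost"))
lt <- synthetic_life_table()   # Gompertz-Makeham stand-in for the WHO table
run_all(params, lt)
```

```
  strategy cost_societal cost_clinic le_discounted le_undiscounted
1 cryo_all         153.0       27.81         18.98           31.16
2      VIA         188.9       35.97         18.89           30.93
3      Pap         205.2       46.57         18.85           30.85
4      HPV         206.4       43.80         18.87           30.89
5  VIA+HPV         241.3       53.67         18.79           30.71
6  VIA+Pap         248.7       59.07         18.78           30.68
7  HPV+Pap         255.9       66.39         18.80           30.73
```

Each row is a strategy's discounted lifetime cost per woman (societal and
clinic perspective, 2014 USD) and life expectancy from screening in years
(discounted at 3%/year and undiscounted). Preventative cryotherapy is both
the cheapest strategy and the one with the highest life expectancy — it
treats every prevalent high-grade lesion at one visit with no screening
cost and no loss to follow-up. Among screening strategies VIA is cheapest;
test pairs cost more without adding life expectancy because their joint
sensitivity is lower and their three-visit cascade loses nearly half the
women before treatment.

The numbered scripts under `analysis/` drive the full set of analyses —
base case and CD4 scenarios, the single-visit scenario for Pap/HPV, tornado
(one-way) sensitivity analyses of VIA-vs-cryotherapy and HPV-vs-VIA
incremental costs, the loss-to-follow-up threshold at which HPV reaches
cost parity with VIA, and microsimulation validation — writing tables under
`results/`:

```sh
Rscript analysis/01_base_case_and_scenarios.R
Rscript analysis/04_ltfu_threshold.R
```

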