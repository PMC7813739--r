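# mrmcea

Decision-analytic cost-effectiveness model of contrast-enhanced
MR-mammography (MRM) used as the *sole* imaging test in women at
intermediate breast-cancer risk due to dense breast tissue — the setting
in which conventional X-ray mammography loses accuracy.

The package is aimed at health-economics and radiology researchers who
want to reproduce, audit or perturb the published evaluation: every model
input is an explicit parameter, every cycle-accounting convention is an
explicit knob, and a patient-level microsimulation provides an
independent stochastic check on the deterministic cohort engine.

## The model

A decision tree sends each screened woman down one of four branches
according to the test result and the ground truth. With pre-test
probability of malignancy *p*, test sensitivity *Se* and specificity
*Sp*:

    P(TP) = p·Se        P(FN) = p·(1 − Se)
    P(TN) = (1 − p)·Sp  P(FP) = (1 − p)·(1 − Sp)

Each branch feeds a three-state discrete-time Markov cohort model with
states *Alive – no cancer*, *Alive – present cancer* and *Dead* (yearly
cycles, 5-year horizon). A true positive is treated immediately (MRM +
biopsy + early surgery upfront) and starts cancer-free but carries a
recurrence hazard; a false negative starts with the untreated cancer,
accrues yearly cancer-care costs at utility 0.7, and pays the more
extensive delayed surgery once treatment succeeds; true negatives and
false positives start cancer-free, the false positive additionally
paying for the biopsy and its one-time QALY loss. Costs *c(s)* and
utilities *u(s)* accrue per cycle and are discounted at annual rate *r*
(3%), so e.g. expected QALYs are

    E[QALY] = u₀ + Σₜ (1 + r)^(−t) · xₜ·u

with `xₜ` the state-occupancy vector at cycle *t* and `u₀` any one-time
utility adjustment. The base case probability-weights the four branches
and reports expected cost, expected QALYs and the net monetary benefit
NMB = WTP·QALYs − cost at a willingness to pay of 100,000 €/QALY.

Base-case inputs (7% prevalence, Se = 100%, Sp = 97%, costs of
418.50 € / 300 € / 4,000 € / 10,000 € for MRM / biopsy / early /
delayed surgery, 10,000 €/yr cancer care, annual probabilities of 5.44%
cancer death, 4.5% recurrence, 60% treatment success) are the package
defaults; see `?mrm_params`.

## Worked example

```r
library(mrmcea)

# decision tree on the published per-branch values
m <- cea_model(branch_results = mrm_reference_results())
summary(m)
#> Per-branch 5-year discounted results:
#>  branch expected_cost expected_qalys
#>      TP       7606.80           4.62
#>      FN      17518.54           3.95
#>      TN       1193.16           4.70
#>      FP       1493.16           4.65
#> Base case: expected cost 1650.48 EUR, expected outcome 4.69 QALYs
#> Net monetary benefit at WTP 1e+05 EUR/QALY: 467650.02 EUR
#> Branch probabilities (TP/FN/TN/FP): 0.07 / 0 / 0.9021 / 0.0279
#> QALY gain of timely (TP) over delayed (FN) diagnosis: 0.67

# one-way sensitivity analysis over prevalence 0-20%, Se and Sp 70-100%
summary(one_way_dsa(mrm_params()))
#> Across all one-way variations (branch-values mode, 3 parameters):
#>   expected cost  1202.16 to 2483.09 EUR
#>   expected QALYs 4.68 to 4.70
```

The strategy costs 1650.48 € per woman over five years at 4.69 QALYs;
a missed cancer (FN) is both the most expensive and the worst-outcome
branch, and even at 20% prevalence or degraded test accuracy the
expected cost stays below 2,500 €. Evaluating the branch Markov models
from the raw parameters instead of fixed values (`cea_model()` with no
`branch_results`) gives 7350.87 € / 4.58 QALYs (TP), 26203.93 € / 3.96
(FN), 1183.22 € / 4.71 (TN) and 1483.22 € / 4.66 (FP) under the default
conventions; `calibrate_conventions()` quantifies how close each
convention setting comes to the published per-branch values, whose exact
cycle-accounting settings were never published (see the methods
vignette).

Other entry points: `simulate_cohort()` (patient-level microsimulation
and Monte-Carlo oracle), `compute_performance()` /
`branch_probabilities()` (diagnostic accuracy), `run_pipeline()` /
`load_config()` (end-to-end CSV reports from a flat `key = value`
config).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from
scratch against the installed package — diagnostic accuracy from the
study's confusion counts, the decision-tree base case, the Markov branch
evaluation, the one-way sensitivity analysis, the convention
calibration and a microsimulation cross-check — and writes a JSON file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
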