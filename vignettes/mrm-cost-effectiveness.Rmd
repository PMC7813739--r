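---
title: "Methods: the MRM dense-breast cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MRM dense-breast cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmcea)
```

## The question and the model

Screening women whose dense breast tissue degrades X-ray mammography is
a setting where contrast-enhanced MR-mammography (MRM) is highly
accurate but has a higher per-examination fee. The model in this
package asks what a strategy of MRM as the *sole* imaging test costs
per woman over five years, and what health it delivers in
quality-adjusted life years (QALYs), at the accuracy levels observed in
a prospective dense-breast screening cohort.

The structure is a textbook two-stage decision-analytic model:

1. **Decision tree.** The test result crossed with ground truth yields
   four branches — true positive (TP), false negative (FN), true
   negative (TN), false positive (FP) — with probabilities
   `p·Se`, `p·(1−Se)`, `(1−p)·Sp`, `(1−p)·(1−Sp)` for prevalence `p`,
   sensitivity `Se`, specificity `Sp`. Every positive finding is
   followed by a biopsy that is assumed to reveal the ground truth
   (sensitivity and specificity 100%), so the tree has no further
   depth: biopsy cost and disutility attach to the positive branches.
2. **Markov cohort models.** Each branch feeds a three-state
   discrete-time Markov model — "NoCancer", "Cancer", "Dead" — with
   yearly cycles over a 5-year horizon. "Dead" is absorbing with
   utility 0. In "NoCancer" the age-dependent background mortality
   applies; in "Cancer" the cancer-specific annual death probability
   (5.44%) is used *instead of* (not added to) background mortality,
   reading the two inputs as per-state alternatives. The cancer row is
   `success + stay + death = 1` with a 60%/yr probability of successful
   treatment.

Costs and utilities accrue per cycle on the state occupancy and are
discounted at 3%/yr; one-time transition costs (surgery on treatment
success) are charged in the cycle the transition occurs with that
cycle's discount factor. Acute time-zero quantities — the MRM fee,
biopsy cost and early surgery, and the one-time biopsy QALY decrement —
are added undiscounted outside the Markov accrual.

## Parameters

All inputs live in `mrm_params()` (units: EUR, years, probabilities per
year, utilities dimensionless in [0, 1]); the defaults are the
published base case. The ones that drive the results:

| parameter | default | role |
|---|---|---|
| `prevalence` | 0.07 | pre-test probability of malignancy |
| `sensitivity_mrm`, `specificity_mrm` | 1.00, 0.97 | test accuracy in the tree |
| `cost_mrm`, `cost_biopsy` | 418.50, 300 | acute diagnostic costs |
| `cost_early_surgery`, `cost_delayed_surgery` | 4000, 10000 | treatment cost of a timely vs delayed diagnosis |
| `yearly_cost_tumor` | 10000 | yearly care cost while in "Cancer" |
| `utility_no_tumor`, `utility_tumor` | 1.0, 0.7 | QALY weights |
| `qaly_loss_biopsy` | 0.05 | one-time decrement per biopsy |
| `p_death_tumor`, `p_recurrence`, `p_treatment_success` | 0.0544, 0.045, 0.60 | annual transition probabilities |
| `discount_rate`, `horizon`, `wtp` | 0.03, 5, 100000 | economic frame |

Each parameter also carries a distribution-family tag (beta for
probabilities and utilities, gamma for costs) as metadata only: the
package performs deterministic analyses, and no probabilistic
sensitivity analysis is implemented because no distributional results
exist to check it against.

**Background mortality.** The source analysis cites US female life
tables but prints no values. The default is a constant 0.0007/yr over
the 32–36-year age window — the right order of magnitude for women in
their early thirties — overridable by a per-age CSV
(`read_mortality_csv()`; ages outside the table are clamped to its
ends). At this magnitude its effect on every 5-year output is below
0.01 QALY, so the choice is immaterial; it was made once and is not
tuned.

## Cycle-accounting conventions and calibration

The original analysis was built in commercial decision-tree software
whose cycle-accounting settings are not published. Five settings
materially affect the per-branch numbers, and each is an explicit knob
in `mrm_conventions()`:

* **Discount timing** — begin-of-cycle (cycle 0 undiscounted; the
  default), end-of-cycle, or half-cycle.
* **Half-cycle correction** — state rewards on start-of-cycle occupancy
  (default) or on the mean of start and end occupancy.
* **Recurrence scope** — whether the 4.5%/yr recurrence hazard applies
  only to patients with a treated cancer (TP, and FN after successful
  treatment; the default) or also to test-negative patients. Restricting
  it to treated cancers is consistent with the near-full QALY value of
  the TN branch.
* **Recurrence treatment cost** — the surgery charged when a recurrence
  is treated: early (default; the tumor is under surveillance, so it is
  caught early), delayed, or none. The initial tumor of an FN patient
  always pays the delayed surgery.
* **Surveillance schedule** — the TN branch's published cost exceeds a
  single MRM fee by roughly two discounted fees. Since negative cases
  in the underlying study were followed for five years, the model gives
  test-negative patients follow-up MRMs within the horizon: biennial
  (years 2 and 4; the default), annual (years 1–4), or none. This is a
  reconstruction — the true source of the TN cost residual is not
  stated — which is why calibration *reports* rather than asserts.

`calibrate_conventions()` evaluates all four branches under every
combination (108 candidates) and reports, per candidate, the summed
relative error against supplied reference per-branch values plus the
FP−TN cost and QALY differences as audit columns; FP is TN plus the
biopsy by construction, so FP−TN must equal (+300 EUR, −0.05 QALY)
exactly under *every* candidate, and the test suite asserts this to
1e−9.

**What calibration achieves, honestly.** Against the published
per-branch values, the best setting reproduces TN, FP and TP costs and
all four branches' QALYs to within a few percent, but the FN *cost*
stays well above the published 17,518.54 EUR under every candidate: the
stated inputs (10,000 EUR/yr while in "Cancer", 10,000 EUR delayed
surgery on success, 60%/yr success, 5.44%/yr death) imply a larger
discounted cost accrual than the published figure under any combination
of the documented conventions. The residual is reported by
`calibrate_conventions()` and left standing; the decision-tree-level
results (base case, QALY gain, sensitivity-analysis claims) do not
depend on it because they are checked on the published per-branch
values directly.

**TP and the biopsy decrement.** Every positive test is followed by a
biopsy, so the TP branch carries the same one-time 0.05 QALY decrement
as FP. The remaining distance between TP and TN−0.05 is then the
recurrence time spent at utility 0.7 — the model's explanation for the
published TP value; an unpublished treatment disutility would be an
alternative, and the two cannot be distinguished from the printed
numbers.

**Utilities in the cycle of death.** Unstated in the source. Under the
default begin-of-cycle accrual a patient who dies during cycle *t*
still accrues cycle *t*'s reward (she was alive at its start); with
half-cycle correction she accrues half of it.

## The microsimulation: generator and oracle

`simulate_cohort()` draws each patient's branch from the tree
probabilities, then simulates her yearly trajectory from *the same*
transition matrices, rewards and discounting conventions as the cohort
engine, via inverse-CDF sampling on each row. Its per-branch means are
therefore unbiased Monte-Carlo estimates of `run_cohort()`'s
expectations, and the suite checks agreement within 3 standard errors
at n = 200,000 for every branch — the primary correctness property of
the engine, independent of any published number.
`generate_study_dataset()` likewise emulates the diagnostic study
itself (true status, test result per patient).

What the generator emulates: the branch mixture, the yearly state
dynamics, and the accounting. What it does not: individual
heterogeneity in risk or costs, within-year event timing, correlated
test errors, loss to follow-up, or stage progression — so a green
oracle test establishes that the cohort engine integrates the stated
model correctly, not that the stated model is clinically complete.

Reproducibility contract: one seeded pseudo-random stream per run with
a fixed patient order (there is no parallel execution); identical seeds
give bit-identical outputs, and the pipeline's CSV reports are
byte-identical across re-runs with the same configuration and seed.

## Numerical choices

* Transition-matrix rows must sum to 1 within 1e−9 and the occupancy
  vector is conserved to the same tolerance; violations are reported
  with the offending row and cycle named.
* The four branch probabilities sum to 1 within 1e−12 (algebraic
  identity; asserted, not renormalised).
* All metrics and results are exact fractions / full doubles
  internally; rounding to the customary precision (two decimals for
  EUR and QALYs, one decimal for percentages) happens only in print
  methods. The published accuracy of 95.5% for the full cohort is not
  reproducible from its own counts (1047/1095 = 95.6%) and is treated
  as a typo; the package reports the exact fraction.
* Undefined diagnostic metrics (zero denominator) are `NA` with a
  warning, never 0.
* Degenerate inputs: a one-point sensitivity range evaluates that
  point; an all-zero-swing tornado preserves input order (stable
  sort); `prevalence = 0` or `= 1` collapse the tree without special
  casing.
* The DSA grid uses 21 evenly spaced points including both endpoints;
  expected cost and QALYs are linear in each tree probability, so the
  extremes over a range occur at its endpoints — the grid exists to
  expose the full response curve, not to find the extremes.

## Limitations

* The model is non-comparative by design: it prices the MRM strategy
  against a willingness-to-pay threshold (NMB), not against X-ray
  mammography or ultrasound alternatives, and computes no ICER.
* Three health states only: no tumor-stage structure, no metastatic
  state, no tunnel states; cancer biology is reduced to four annual
  probabilities.
* The FN-branch cost cannot be reconciled with the published value
  under any documented convention (see above); conclusions that depend
  on the absolute FN cost level should use the published value via
  `branch_values()` / `mrm_reference_results()`.
* The 5-year horizon understates the lifetime consequences of a missed
  cancer; the QALY gain of a timely diagnosis is a lower bound in that
  sense.
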