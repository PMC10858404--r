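---
title: "A Markov cohort model for gene-specific cancer risk-reduction strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for gene-specific cancer risk-reduction strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csgprev)
```

## The decision problem

Women carrying pathogenic variants in *BRCA1*, *BRCA2*, *PALB2*, *RAD51C*,
*RAD51D* or *BRIP1* face substantially elevated lifetime risks of ovarian
cancer (OC) and, for all but *BRIP1*, breast cancer (BC). The management
options — risk-reducing salpingo-oophorectomy (RRSO), risk-reducing
mastectomy (RRM), intensive breast surveillance, and chemoprevention with
tamoxifen or anastrozole — differ in effectiveness, cost, timing and
quality-of-life consequences, and the sensible combinations differ by gene.
`csgprev` implements a decision-analytic Markov cohort model that compares
these gene-specific strategies on lifetime discounted cost, QALYs and
life-years, cancer cases and deaths per 1000 carriers, and the standard
decision statistics (ICER, net monetary benefit, cost-effectiveness
frontier and acceptability curves).

## Model structure

The cohort enters healthy at age 30 (configurable to 35) and cycles annually
to age 100. The state space has 36 states: healthy; ten annual tunnel states
for each of OC, BC and OC-after-BC; OC and BC survivor states; and three
absorbing death states (OC, BC, other). Tunnel states carry the
time-since-diagnosis dependence: excess cancer mortality and elevated
treatment costs apply in the first ten years, after which patients move to a
survivor state subject to background mortality only (a cure-type assumption
motivated by the similarity of long-term survival across carrier status).
OC after BC is modelled through a dedicated tunnel entered from any BC
state; BC after OC is excluded (poor OC survival makes it rare enough to
ignore). Entries into the OC-after-BC tunnel count as OC cases in the event
tallies, so one woman can contribute both a BC and an OC case.

Competing risks within a cycle are resolved by sequential conditioning in a
fixed, documented order: background death first, then OC onset among
survivors, then BC onset among the remainder. The order matters only at
O(p²) for annual probabilities of this size; having one testable convention
beats an implicit one. Transition rows always sum to 1 and the engine
refuses negative residuals.

Interventions act multiplicatively on annual incidence: RRSO scales OC
incidence by `rrso_oc_multiplier` (default 0.04, i.e. a 96% reduction, the
level reported even for average-risk women); RRM scales BC incidence by
`rrm_bc_multiplier` (default 0.08); premenopausal RRSO additionally scales
BC incidence for *BRCA2* and *PALB2* carriers only (default 0.56), reflecting
the meta-analytic finding that the BC benefit does not extend to *BRCA1*;
chemoprevention scales BC incidence by 0.70 premenopausally (0.50
postmenopausally, retained for scenario work) during its 5-year window.
Interventions with partial uptake enter as expectations: a multiplier `m`
taken up by fraction `u` contributes `u·m + (1−u)`. This is exact in a
linear cohort model and avoids doubling the state space per uptake fraction;
the two uptakes are hormone therapy (HT, 80%) and chemoprevention (16.3%).

Surgery takes effect at the start of the cycle of its scheduled age, so
"RRSO at 35" already shapes age-35 incidence, and its cost and disutility
accrue that cycle. Surveillance and chemoprevention stop at RRM. HT runs
from a premenopausal RRSO to the average menopause age (51). Excess
coronary heart disease after premenopausal RRSO without HT is represented by
its three quantitative hooks — a mortality multiplier of 1.03 on the
never-HT fraction (applied lifelong, a flagged assumption: the source
evidence does not state a duration), an expected annual cost and an expected
annual disutility — rather than by an explicit CHD state, which would
require incidence detail the model does not otherwise need. The post-RRSO
reduction in all-cause mortality (`rrso_acm_multiplier_*`, default 0.85)
applies only while cancer-free, and only to the healthy state.

Utilities use the multiplicative age-adjustment convention: an age-declining
healthy-state utility curve times a state multiplier, minus additive
disutilities for events active that cycle (surgery year, screening
attendance, the expected false-positive decrement `fp_prob × disutil_fp`,
chemoprevention years — applied in each active year, the more conservative
reading of "assigned for year of treatment" — and the expected CHD
decrement). Costs combine intervention events, state costs (first-year,
subsequent-year, survivor) and a terminal-care cost attached to the
transition into a cancer death state, discounted at that cycle's factor.

Costs and QALYs are discounted at 3.5% per year with the first cycle
undiscounted (`t = 0`); both conventions are explicit and switchable
(`half_cycle` applies a standard half-cycle correction; the default accrues
rewards on start-of-cycle occupancy). Event counts per 1000 carriers are
undiscounted: they count people, not value streams. Ten-year survival
fractions `s10` convert to constant annual excess death probabilities via
`1 − s10^(1/10)`.

## Parameters

Parameters live in a versioned YAML + CSV schema (see
`read_parameter_set()`); every scalar carries a base value, a (low, high)
range read as a 95% CI, and a sampling family — gamma for costs, beta for
probabilities and multipliers bounded by 1, log-normal for utilities and
relative risks. Key defaults and why:

* `discount_rate` 0.035/year — the UK reference-case rate.
* `rrso_oc_multiplier` 0.04; `rrm_bc_multiplier` 0.08;
  `chemoprev_bc_multiplier_pre` 0.70 — in-text effect sizes from the
  clinical literature the model's evidence base states directly.
* `ht_uptake` 0.80, `chemoprev_uptake` 0.163 — stated uptake assumptions.
* `rrso_acm_multiplier_*` 0.85 (range 0.70–0.99) — a deliberately
  conservative mid-range value for the observed reduction in all-cause
  mortality after RRSO among cancer-free carriers; the published
  case-control estimates are stronger but confounding-prone. The
  `no_rrso_mortality_benefit_nonBRCA` scenario removes it for the non-*BRCA*
  genes.
* 10-year survival: OC 0.35 (general population), BC 0.81 high-risk / 0.85
  moderate-risk.
* Costs are 2021 GBP, UK payer perspective (surgery ~£3 000/£8 100, MRI
  £181, mammogram £96, cancer first-year £13 600–£17 500); a ×1.38
  constant converts to USD for reporting only.

## The synthetic parameter generator

`generate_parameter_set()` produces a complete, validation-clean set without
any external download. It emulates the *structure* of the supplementary
evidence tables such a model is normally parameterised from: 5-year-banded
incidence curves per gene whose single scale factor is root-found so that
cumulative incidence to age 80 matches the published lifetime risks (BRCA1
OC 46%/BC 68.5%, BRCA2 18.5%/65%, PALB2 5%/53%, RAD51C 11%/21%, RAD51D
13%/20%); a Gompertz female life table (`qx = 0.00055·e^{0.092(a−30)}`,
matching the national female table's order of magnitude at ages 30, 80 and
100); a quadratic age-utility curve of the form used for UK female
population norms; and the scalar defaults above. The age 80 "lifetime"
horizon is the common penetrance convention and is configurable. The BRIP1
OC curve is constructed as the calibrated population curve times a relative
risk (base 3.41; the `brip1_rr_5.54` scenario raises it), so the scenario
propagates automatically.

What the generator does *not* emulate: the true age shapes (only plausible
band patterns), stage distributions, gene-specific survival differences
beyond the high/moderate split, and the exact published cost/utility
values. Tests passing on synthetic data therefore demonstrate the engine's
arithmetic, invariants and directional behaviour — not agreement with any
specific published cost-effectiveness table. A run intended to reproduce
published numbers should transcribe the source evidence tables into the
same schema and load them with `read_parameter_set()`; the base case is
deterministic and takes well under a second per gene.

## Uncertainty analysis

One-way analysis (`owsa()`) moves each parameter to its low and high bound
(defaults ±10% for probabilities and utilities without stated ranges, ±30%
for costs) and reports the ICER and NMB at both ends, sorted by NMB spread.
The probabilistic analysis (`run_psa()`) samples every non-fixed scalar
parameter independently by method-of-moments fits to (base, low, high) —
gamma via `shape = (m/s)²`, beta via `ν = m(1−m)/s² − 1`, log-normal matched
to mean and variance, with `s = (high − low)/3.92`. The SE convention is a
documented assumption: the evidence base states variation ranges, not
standard errors, and acceptability percentages inherit it. Draw order is
fixed by sorted parameter name under a single seeded generator, so runs are
bit-reproducible; draws yielding invalid probabilities are rejected,
logged and redrawn rather than truncated, preserving the stated families.
Incidence curves and the life table are treated as structural in the PSA;
their uncertainty enters through the scalar multipliers. No correlation
structure is imposed (none is stated in the evidence base). Acceptability
curves report, at each willingness-to-pay value on a 0–50 000 grid, the
fraction of draws in which each strategy attains the maximum net monetary
benefit, ties split equally, so the curves sum to one by construction.

## Numerical and design choices

* Annual cycles over ages 30–99 with the age-100 snapshot as the horizon: a
  zero-mortality cohort accrues exactly 70 undiscounted life-years.
* Incidence bands expand to constant per-year probabilities; ages below the
  first band get zero, ages beyond the last band carry it forward.
* Calibration root-finds with tolerance 1e-12, comfortably inside the 1e-4
  recovery contract.
* ICERs are reported against each gene's reference strategy (this is the
  convention that reproduces negative published ICERs for cost-saving
  strategies); the incremental frontier with extended dominance is a
  separate, clearly-labelled output. When a scenario flips the sign of the
  QALY difference, the ICER ratio is no longer monotone in favourability,
  so directional scenario statements are made on incremental NMB.
* The moderate surveillance tier's triennial mammograms run at ages 60, 63,
  66 and 69, the national programme's invitation window.
* Problem sizes used in the shipped tests and acceptance script (70-cycle
  cohorts, PSA draws in the hundreds) were chosen so the whole suite runs
  in minutes on a single core while keeping Monte-Carlo error well inside
  the tolerances tested.

## Worked example

```{r example, eval = FALSE}
ps <- default_parameters()
res <- evaluate_strategies("BRCA1", ps, wtp = 20000)
print(res)
plot(res)  # cost-effectiveness plane

psa <- run_psa(model_config(ps, "BRCA1"), n = 500, seed = 1)
plot(ceac(psa))
```

## Known limitations

* Cohort expectations only — no individual-level heterogeneity beyond the
  two uptake fractions, no microsimulation.
* No stage-specific cancer progression; stage mixes are folded into the
  aggregate per-state cost, utility and survival parameters.
* No explicit CHD incidence state; CHD enters as expected multipliers,
  costs and disutilities from the RRSO age onward.
* Intervention effects are age-based and applied uniformly to the at-risk
  states; the model does not track whether an individual still healthy at
  the surgery age actually underwent surgery (uptake of surgery and
  surveillance is 100% by assumption).
* Early salpingectomy with delayed oophorectomy is not modelled.
* The packaged defaults are synthetic approximations, clearly labelled as
  such, not a transcription of any study's supplementary values.
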