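---
title: "A five-state Markov cohort model of intravitreal corticosteroids for diabetic macular oedema"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A five-state Markov cohort model of intravitreal corticosteroids for diabetic macular oedema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmocea)
```

## The decision problem

Diabetic macular oedema (DMO) is a sight-threatening complication of
diabetic retinopathy. When anti-VEGF therapy is not an option or fails,
intravitreal corticosteroids are used: the dexamethasone 0.7 mg implant
(slow release, re-dosed about every 5 months, 1075 EUR per implant) or
the much cheaper triamcinolone 40 mg/ml injection (shorter action,
re-dosed about every 4 months, 207 EUR per injection). `dmocea`
implements a cohort state-transition model that asks, from the hospital
perspective, whether the implant's higher price buys enough additional
quality-adjusted life time.

## Model structure

A hypothetical cohort of 1000 patients is followed in cycles equal to
the re-dosing interval of each strategy. Five health states are defined
on the Snellen decimal acuity of the better-seeing eye:

| state | description | acuity | utility |
|---|---|---|---|
| 1 | unilateral DMO, good acuity | >= 0.5 | 0.97 |
| 2 | bilateral DMO, good acuity | >= 0.5 | 0.89 |
| 3 | bilateral DMO, mild impairment | 0.3-0.5 | 0.81 |
| 4 | bilateral DMO, moderate/severe impairment | 0.05-0.3 | 0.55 |
| 5 | bilateral DMO, blindness | < 0.05 | 0.40 |

Everyone starts in state 1. Treatment, once started, continues for the
whole follow-up and DMO is not curable at current evidence, so no
transition returns to state 1; blindness is the absorbing endpoint.
There is no background mortality and no death state: the model's
horizons (2 and 5 years) are short relative to life expectancy at the
mean onset age, and the endpoint of interest is visual, not vital.
A 2-line (10-letter) acuity change moves a patient one state; a 3-line
(15-letter) change can move two, which the transition matrices encode
as jumps of up to two states per cycle.

Each strategy has two matrices: one for cycles starting in the first
twelve months and one for later cycles, expressing that the first doses
are the most effective. A cycle starting before month 12 uses the early
matrix even if it ends after month 12, because the dose — and hence its
effect — is delivered at the cycle start.

## Cost and QALY accrual

Per cycle, with occupancy taken at the cycle start (no half-cycle
correction):

* **Treatment** (drug + administration) is paid per treated eye:
  one eye in state 1, both eyes in states 2-4 (doubling the cost),
  none in state 5 — the endpoint receives no further injections by
  default. Because the written description of continued treatment is
  ambiguous for blind patients, `state5_treatment` in the configuration
  restores bilateral dosing there.
* **Follow-up** (OCT + medical visit 115 EUR x 6/yr, IOP measurement
  76 EUR x 13/yr, fluorescein angiography 77 EUR x 1/yr; 1755 EUR per
  person-year) accrues pro rata temporis for states 1-4. A blind
  patient is assumed to leave imaging surveillance; the
  `followup_in_state5` switch reverses this.
* **Adverse events** are treatment-caused, so their incidences apply to
  the drug-treated population. Recurring events (IOP-lowering
  medication, endophthalmitis, retinal detachment) accrue every cycle.
  Cataract surgery, laser and vitrectomy are treated at most once per
  patient: the default model keeps a saturating ledger of the cohort
  fraction already treated, so each cycle only the not-yet-affected
  fraction can incur the cost; `once_only_mode = "lump_sum"` instead
  charges the full incidence once in the first cycle.
* **Rehabilitation** for visual impairment (7320 EUR per person-year:
  occupational 2496, discretionary 2176, medical 2648) accrues in
  states 4 and 5.
* **QALYs** weight person-time by the state utilities above; an
  alternative utility set (0.93, 0.85, 0.66, 0.58, 0.53), averaged from
  published ranges for eye disease in general, drives the third
  sensitivity analysis.

All prices are 2019 Kuopio University Hospital EUR; no inflation
adjustment is applied.

### Cycle accounting

A horizon is rarely a whole number of cycles (24 months on a 5-month
cycle is 4.8). The package's default, `final_cycle = "extend"`, runs
and accrues the last cycle in full, so a 2-year dexamethasone run
covers 25 months (5 doses) while a 2-year triamcinolone run covers 24
months (6 doses). We adopted this after checking it against the
arithmetic of the published results this model family reports: expected
2-year QALYs near 2016 per 1000 patients are only reachable if accrual
runs to the end of the fifth 5-month cycle (25 months x 0.97 = 2021
utility-years at the ceiling), and the printed 2-year QALY difference
of ~80 per 1000 is, almost exactly, one month of cohort utility
(0.97 x 1000/12) — the asymmetry between a 25- and a 24-month grid.
The alternative `final_cycle = "fractional"` weights the last cycle's
cost and QALY accrual by the fraction of it inside the horizon (0.8 for
the example above; transitions still apply in full, since a state
change is a discrete event tied to the dose). The fractional mode keeps
annual utilization at exactly 12/cycle-length doses per year but cannot
reproduce the published accrual arithmetic; both modes are first-class
and tested.

### Discounting

Costs and QALYs are discounted at 0% and 3% per annum, compounded over
fractional years. Each cycle is discounted at its **end** time. This
convention was identified, not assumed: with near-flat utility the
ratio of discounted to undiscounted QALYs over five 5-month cycles is
0.9758 under start-of-cycle discounting, 0.9698 under midpoint, and
0.9638 under end-of-cycle; the published ratios (0.96389 for the
5-month grid, 0.96625 for the 4-month grid) match the end-of-cycle
value to five digits. At rate 0 the convention is irrelevant and
discounted totals equal undiscounted ones exactly.

## Incremental analysis

`compute_icer()` takes dexamethasone as reference and triamcinolone as
comparator. When the reference costs more and yields more QALYs, the
ICER is the quotient of the differences (EUR per QALY) and a
willingness-to-pay rule (`decide()`) accepts the reference when the
ICER does not exceed the threshold. When one strategy costs less and
yields more it dominates; the primary ICER field is then `NA` and the
signed quotient is kept in `icer_signed` only, because a bare negative
ICER is ambiguous (a negative numerator and a negative denominator mean
opposite things). Published tables in this area conventionally print
the signed value, which is why the package retains it.

Three deterministic one-way sensitivity analyses are bundled:
a 3-month triamcinolone cycle (the same per-cycle matrices are reused
on the shorter grid — no re-estimated matrices exist for it, so the
scenario isolates the effect of more frequent dosing and is reported
with that caveat), a 20% dexamethasone price cut, and the alternative
utility set.

## Synthetic transition matrices

The transition probabilities behind the original analysis were
aggregated from nineteen clinical studies and are not printed in any
source available to this package, so `dmocea` generates matrices with
the structural properties the model requires and treats the numeric
values as configurable inputs, never as ground truth:

* rows are stochastic; no inflow to state 1; state 5 absorbing;
* jumps of up to `max_jump = 2` states per cycle, geometrically damped;
* triamcinolone's improvement probabilities are elementwise at least
  dexamethasone's (it is the slightly better drug at improving acuity);
* late-period improvement probabilities are scaled down by
  `early_late_decay` (first doses are the most effective);
* worsening is parameterized as a monthly probability converted to the
  strategy's cycle length (`1 - (1 - w)^cycle_months`), so disease
  progression is comparable in calendar time across the 5- and 4-month
  grids, while improvement is per dose, so more frequent dosing means
  more frequent chances to improve;
* dexamethasone has a protective advantage against worsening in the
  bilateral states (the implant's sustained release covers the whole
  cycle), strongest in the first year (`protection_persistence`
  scales it thereafter). Exit from state 1 is fellow-eye disease
  onset, which treating the first eye does not prevent, so row 1 is
  identical across strategies.

The default parameters describe slow disease under treatment — cohort
mean utility stays near 0.96 after two years — with a monthly worsening
scale of 0.008 (state profile 1.0, 1.0, 0.7, 0.4), per-dose improvement
0.08 for dexamethasone and 0.30 for triamcinolone, a 25% early
dexamethasone protection fading to 10%, and improvement decay 0.85
after month 12. Under these conditions the model reproduces the
qualitative published pattern: dexamethasone gains QALYs over 2 years
at a positive, finite ICER; triamcinolone is cheaper and more effective
(dominant) at 5 years; and the 2-year sensitivity ICERs order as
price-cut < 3-month-cycle < base. A lognormal per-state jitter
(sd 0.10, drawn once from the seed) prevents the matrices from being
a single hard-coded point; the qualitative pattern is stable across
seeds.

What the generator does not emulate: correlations between adverse
events and transitions, state-duration dependence, secular drift in
clinical practice, and of course the literature-derived numeric
probabilities themselves. Green tests therefore certify the engine,
the accrual rules and the analytics — not the clinical conclusions,
which inherit the uncertainty of the unavailable supplement.

## Calibration

`calibrate_matrices()` fits the generator's five free parameters
(progression scale, base improvement, triamcinolone advantage,
dexamethasone protection, early/late decay) to expected cost/QALY
targets by Nelder-Mead on logit-transformed bounded parameters,
minimizing summed squared relative error. The search starts from the
supplied spec and is deterministic given the seed. Self-generated
targets are recovered to below 1e-6 relative error and 1%-perturbed
targets to within 2%; against published expected values the fit report
states achieved errors without an accuracy promise, because five
aggregate parameters against a handful of totals leave flat directions
and the cost side depends on accrual choices the original analysis did
not fully specify.

## Numerical choices and degenerate inputs

Row-stochasticity is validated to 1e-9; occupancy conservation to 1e-6
per 1000 persons. A zero horizon yields an empty grid and zero accrual.
ICERs are undefined (`NA`) when |delta QALYs| < 1e-12. Generation fails
with a diagnostic, rather than renormalizing, when requested
probabilities exceed row budget. Problem sizes are small throughout —
5x5 matrices, at most 15 cycles per run — so the full test suite,
including the 5^4-path brute-force oracle and two calibration fits,
runs in well under a minute.

## Known limitations

The model is an average-cohort model: it cannot express between-patient
heterogeneity or individual dosing decisions. Cycle lengths are fixed
over follow-up, although in practice dosing intervals often lengthen.
Adverse events carry costs but no disutility. The societal perspective
(travel, caregiver time) is out of scope, as are probabilistic
sensitivity analysis and budget impact. And the synthetic matrices,
however structurally faithful, are placeholders for evidence this
package does not contain.
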