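---
title: "An adherence-to-outcomes Markov cohort model for difficult-to-control asthma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adherence-to-outcomes Markov cohort model for difficult-to-control asthma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asthmod)
```

## The model

`asthmod` implements a weekly-cycle Markov cohort model of adults with
difficult-to-control asthma. The cohort occupies five mutually exclusive
states: *Controlled*, *Partially controlled* and *Uncontrolled* (the GINA
control ladder), a one-week *Exacerbation* state, and absorbing *Dead*.
Weekly cycles are short enough that acute events (an exacerbation, a
control change) fit in a single cycle, and 1,040 cycles cover the 20-year
horizon over which long-term consequences of adherence accrue.

Three structural assumptions shape the engine:

1. **Exacerbation is a one-cycle state.** Occupants exit the next week to a
   control state (a fixed recovery vector), or die. Exacerbation duration
   carries no memory — dwell-time modelling would add states without
   changing expected flows at a weekly resolution.
2. **Adherence is constant over the horizon.** Each run conditions on one
   population adherence level; scenario comparisons difference two such
   runs. Real adherence decays; the package deliberately does not model
   that (see Limitations).
3. **Exacerbation severities are mutually exclusive** and enter as a
   39% admitted / 61% non-admitted mixture in costs and utilities, not as
   separate states.

Asthma-specific death is reachable *only* from the exacerbation state
(weekly case fatality); every alive state is additionally exposed to
age-specific background mortality from a national-style life table,
converted to a weekly probability by the complement-power rule
$q_w = 1-(1-q_a)^{1/52}$ (constant hazard within the year). Death is
resolved first each cycle and the remaining transition mass is scaled by
the survival complement, which keeps every row stochastic.

## From adherence to transition probabilities

Treatment effectiveness $E(a)$ maps the adherence rate $a$ (a
possession-ratio style quantity in $[0,1]$) to a scalar in $[0,1]$:

$$
E(a) = \begin{cases}
a & a \le 0.30\\
1 - e^{-5\,(a - 0.2287)} & 0.30 < a < 1\\
1 & a = 1.
\end{cases}
$$

The three branches are implemented literally. They almost meet at the 30%
breakpoint ($1-e^{-5\cdot 0.0713} \approx 0.2999$), but the mapping jumps
at $a=1$, where the exponential branch tops out near $0.979$: full
adherence is pinned to full effectiveness by definition. `effectiveness()`
is therefore nondecreasing with one intentional discontinuity.

Two anchor matrices exist: the *full-adherence* weekly transition rows, and
the *no-treatment* rows obtained by applying odds ratios to the
full-adherence exacerbation-entry probabilities,
$p' = \frac{r\,p/(1-p)}{1 + r\,p/(1-p)}$, with the residual "stay"
probability absorbing the change (`or_adjust()`,
`zero_adherence_transitions()`). Only exacerbation entry is OR-adjusted by
default — the underlying adherence evidence concerns severe exacerbations —
but the parameter schema can tag further transitions. Recovery from
exacerbation is adherence-independent: the evidence attaches adherence to
exacerbation *occurrence*, not to recovery.

At adherence $a$, each alive row is the convex combination

$$\text{row}(a) = E(a)\,\text{row}_\text{full} + (1 - E(a))\,\text{row}_\text{zero}.$$

**Why a convex combination?** The functional link between effectiveness and
the transition rows is not pinned down by the source material; linear
blending is the simplest mechanism that (i) reproduces both anchors exactly
($E=0$ gives no treatment, $E=1$ full treatment), (ii) preserves row
stochasticity without renormalization, and (iii) makes exacerbation entry
monotone in adherence whenever the odds ratios exceed 1. The choice is
isolated in `build_matrix()`; an odds-scale interpolation could be swapped
in behind the same interface.

## Outcomes

`run_cohort()` propagates occupancy through the horizon and records the
expected flow into exacerbation each cycle. From the trace:

* **exacerbations** — the summed incident flow;
* **life years** — alive occupancy × 1/52, *undiscounted* (reported
  separately from the discounted quantities, as is conventional);
* **QALYs** — occupancy × state utility × an age/sex multiplier × 1/52,
  discounted at 3.5%/yr. The exacerbation week uses the admitted mixture
  $0.39\,u_\text{adm} + 0.61\,u_\text{nonadm}$;
* **costs** (2022 GBP, NHS/PSS perspective), discounted at 3.5%/yr and
  decomposed into: maintenance therapy (the weekly cost × the adherence
  rate — consumption scales with possession), routine outpatient visits
  (every 26 / 13 / 13⁄3 weeks for controlled / partially controlled /
  uncontrolled occupants — calendar frequencies of six-monthly, quarterly,
  monthly — deliberately *not* varied with adherence), weekly rescue
  medication by state, and per-episode exacerbation care split
  admitted/non-admitted.

Discounting uses $(1+r)^{-c/52}$ per cycle $c$; no half-cycle correction is
applied — at a weekly cycle length the correction is orders of magnitude
below parameter uncertainty.

## Probabilistic sensitivity analysis

Each scalar or probability vector may carry a distribution tag: beta for
probabilities and utilities, gamma for unit costs, lognormal for odds
ratios, dirichlet for probability vectors (including transition rows, with
a trailing *stay* component) — the conventional PSA families. One draw per
iteration is shared across every adherence level (**common random
numbers**), so paired scenario comparisons such as 50%→70% difference out
the draw-level noise. Iteration substreams derive from a master seed via a
prefix-stable sequence: raising `n_iter` extends the draw sequence instead
of reshuffling it, and the same `(seed, inputs)` reproduce results
bit-for-bit across processes.

Summaries report the Monte-Carlo mean and the empirical 2.5th/97.5th
percentiles per level and outcome. Two different intervals must not be
confused: the *percentile interval* describes parameter uncertainty and
converges to a fixed width as iterations grow; the *Monte-Carlo error of
the estimated mean* shrinks as $1/\sqrt{n}$ (the test suite checks the
√10 shrink from 100 to 1,000 iterations on exactly this quantity).

## Default parameterization and provenance

Values printed in the published record are used verbatim:

| quantity | value | provenance |
|---|---|---|
| initial distribution C/P/U | 0.205 / 0.394 / 0.401 | published (2020 asthma survey) |
| admitted fraction | 0.39 | published |
| discount rate | 3.5%/yr | published (NICE reference case) |
| horizon, cycle | 20 yr, weekly | published |
| effectiveness constants | 5, 0.2287, 30% breakpoint | published formula |
| outpatient intervals | 26 / 13 / 13⁄3 weeks | published calendar frequencies |

Everything else lives in a deposited supplementary parameter list that is
not redistributable with the package, so the fixture ships documented
stand-ins chosen once, a priori, from the cited-source descriptions and
typical NHS 2022 magnitudes — **not** calibrated against the published
outputs:

* weekly full-adherence transitions: moderate weekly churn between control
  states (e.g. 0.15/wk controlled→partially) and exacerbation entry rising
  with poorer control (0.002 / 0.006 / 0.015 per week), giving roughly 0.4
  severe exacerbations per patient-year at full adherence — the difficult-
  to-control range;
* one-week recovery vector (0.20 / 0.40 / 0.40) over control states;
* zero-adherence odds ratio 3.0 on exacerbation entry (no treatment vs
  full treatment; meta-analytic direction, magnitude a stand-in);
* weekly exacerbation case fatality 1% — the severe end of hospitalized
  asthma, consistent with a difficult-to-control cohort;
* EQ-5D-style utilities 0.89 / 0.83 / 0.74, exacerbation weeks 0.57
  (non-admitted) / 0.33 (admitted); multiplicative age/sex decrement table
  in the Health-Survey-for-England style;
* unit costs (2022 GBP): maintenance £8/week (step-weighted), outpatient
  attendance £163, rescue £0.30–£1.50/week by state, exacerbation episodes
  £150 (non-admitted) / £2,987 (admitted incl. ambulance);
* start age 40, 50% female — the publication never states cohort
  demographics; both are flagged, configurable stand-ins;
* distribution tags: beta (moment-matched), gamma (20% CV), lognormal
  (mean 3), dirichlet with effective sample sizes 200–600.

The synthetic life table is a Gompertz–Makeham schedule
($q_x = 1-\exp[-(2\cdot10^{-4} + 2.5\cdot10^{-5}e^{0.095x})]$) resembling a
contemporary UK national table; substitute the published table via
`load_life_table()` for applied work.

## What the tests establish — and what they do not

The suite verifies the *mechanics* at the stated tolerances: formula
anchors to arbitrary-precision references, row-stochasticity and mass
conservation over hundreds of random parameterizations, the odds-ratio
inverse identity, closed-form life years under constant hazard, the
discount-zero identity, agreement of the cohort recursion with a 50,000
path microsimulation within 3 Monte-Carlo standard errors, direction of
effect across the adherence grid (fewer exacerbations, more QALYs, a
falling cost curve inside the 30–60% region where effectiveness gains
dominate medication cost), and full PSA reproducibility. With the stand-in
fixture the 50%→70% comparison gives −1.99 exacerbations, +0.216 life
years, +0.114 QALYs and −£605 per patient over 20 years — the published
deltas (−1.75, +0.26, +0.20, −£989) are the same signs and magnitudes but
are *not* reproduced within Monte-Carlo error, and the corresponding
acceptance test is intentionally left failing until the deposited
parameter list is transcribed into
`inst/extdata/figshare_parameters.json`. A green suite therefore
establishes correctness of the machinery, not equivalence with the
original Excel implementation.

## Numerical choices

* Occupancy mass is checked every cycle; drift beyond 1e-9 aborts the run.
* Transition matrices are cached per integer age within a run.
* Dirichlet draws renormalize by construction; invariant-violating PSA
  draws are redrawn with a cap of 100 before erroring.
* Percentile intervals use the default quantile estimator (type 7).
* The life table carries its last row forward beyond the final age.
* Tables are written with 17 significant digits, UTF-8, LF, no
  timestamps: identical inputs give byte-identical outputs.

## Known limitations

Constant adherence (no decay), no comorbidity structure, no treatment-step
dynamics as states, recovery independent of adherence, outpatient
frequency independent of adherence (both flagged in the source material),
a synthetic default life table, and stand-in parameter values pending the
supplement transcription. Value-of-information analysis and
cost-effectiveness acceptability curves are out of scope.
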