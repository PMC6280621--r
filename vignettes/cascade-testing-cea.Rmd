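---
title: "Methods: the cascade-testing cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cascade-testing cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadecea)
```

## The decision problem

When an ovarian-cancer patient is found to carry a pathogenic germline
BRCA1/2 variant, her first-degree female relatives have a 50% chance of
carrying it too. The intervention modelled here offers every such relative
genetic counselling plus NGS+MLPA testing at age 30 and, on a positive
result, bilateral prophylactic mastectomy and risk-reducing
salpingo-oophorectomy (RRSO). The comparator is usual care: no testing, and
annual breast MRI + mammography only for relatives a risk algorithm flags as
high-risk (probability 0.24). Effectiveness is cancer cases prevented; both
costs (2014 BRL) and cases are discounted at 5%/year over a 40-year horizon
(ages 30–70).

## Model structure

Each strategy is a weighted decision tree whose leaves share one Markov
structure with states *well*, *breast cancer*, *ovarian cancer*; the cancer
states are absorbing. The testing strategy has nine arms: {BRCA1, BRCA2} ×
{both surgeries, RRSO only, mastectomy only, neither} plus a test-negative
arm. Uptake of the two surgeries (0.18 mastectomy, 0.57 RRSO) is treated as
independent, the simplest joint model consistent with two marginal uptake
probabilities. Usual care keeps the same latent 0.45/0.05/0.50 carrier
mixture with unmodified penetrance.

Cost conventions, chosen once and applied uniformly:

* counselling (R$200) and testing (R$683.61) are charged once, at entry, to
  every relative in the testing strategy — testing is the intervention being
  priced, and no partial test-uptake probability is available;
* surgery costs (R$3,158.04 mastectomy, R$542.46 RRSO) are charged at entry
  in the arms that accept them;
* carriers who refuse mastectomy accrue R$333.75/year of breast screening
  while cancer-free, regardless of RRSO status (screening is tied to the
  refused mastectomy; there is no effective ovarian screening in any arm);
* test-negative relatives accrue no further cost: with the family variant
  excluded they would not be flagged by a mutation-risk algorithm, so they
  do not revert to usual-care screening;
* usual-care screening is charged as its expected value, 0.24 × R$333.75 =
  R$80.10 per cycle, uniformly across arms, rather than splitting every arm
  by algorithm outcome — the data do not support a correlation between
  latent carrier status and the algorithm's verdict.

## Hazard conversion

Published penetrances are cumulative (to age 70). The engine needs annual
transition probabilities, and the only reconstruction the available inputs
support is a constant hazard over the span:

$$p_\text{annual} = 1 - (1 - P_\text{cum})^{1/n}, \qquad n = 40.$$

Post-surgery risks are treated as replacement cumulative risks over the same
span (they are published as probabilities of developing cancer, parallel in
form to the no-surgery rows), not as hazard ratios. Age-specific or
piecewise hazards are out of scope. `lifetime_to_annual()` rejects
$P_\text{cum} = 1$ (infinite hazard) and round-trips with
`annual_to_lifetime()` to within $10^{-12}$ across the domain — this
identity is enforced by a property test.

## Cycle mechanics

Within a cycle the two cancer transitions compete. The joint same-cycle mass
$p_b p_o$ is assigned to breast cancer (the higher-incidence site):
$P(\text{well}\to\text{breast}) = p_b$,
$P(\text{well}\to\text{ovarian}) = p_o(1-p_b)$. At the model's risks the
choice is immaterial — switching the tie-break to ovarian moves every
reported total by less than $10^{-3}$, which a test asserts.

Accrual timing, with no half-cycle correction: one-off costs at cycle 0
undiscounted; per-cycle costs for well-state occupants at the start of each
cycle $t$, discounted by $(1+r)^{-t}$; new cases counted at transition time
$t+1$, discounted by $(1+r)^{-(t+1)}$. Occupancy conservation is checked
every cycle at $\pm 10^{-12}$ and a breach raises an internal-consistency
error rather than propagating silently. There is no death state and no
background mortality: effectiveness is cases prevented, not life-years, so
competing mortality would complicate the model without touching its
endpoint. This overstates time at risk late in the horizon; it is the main
structural limitation.

## Effectiveness scales

Cost-per-case-prevented analyses in this literature often print
effectiveness values without units. Two conventions are implemented:

* `per100` (default): $(1 - \text{discounted cases}) \times 100$, a
  discounted cancer-free index per 100 relatives;
* `person_years`: discounted well-state person-years accrued at cycle
  starts (the same timing as per-cycle costs; its maximum over 40 cycles at
  5% is $\sum_{t=0}^{39} 1.05^{-t} = 18.017$).

At the defaults the person-years convention yields 16.17 vs 14.96 — the
scale on which published effectiveness magnitudes for this comparison are
typically reported — so the acceptance script reports that convention. The
ICER classification is the same under both conventions here, and the ICER
itself is invariant under joint cohort rescaling (asserted by computing at
per-person and per-100 scales).

## Incremental analysis

`icer()` works off the signs of $\Delta C$ and $\Delta E$: a genuine
trade-off yields the ratio, a cheaper-and-better intervention is *dominant*,
a costlier-and-worse one *dominated*, and $\Delta E = 0$ yields no ratio.
Threshold classification against R$7,543.50 / R$23,786.70 per case
prevented uses inclusive boundaries (a value exactly at a threshold takes
the weaker verdict); boundaries are measure-zero, so only the convention
needs documenting. All internal arithmetic is full precision — reproducing
an ICER from independently rounded cost and effectiveness figures can
therefore differ from the internally computed one by several BRL, which is
why the reporting layer prints monetary values at 2 decimals but never
rounds intermediates.

## Sensitivity analysis

`one_way_dsa()` sweeps each probability that has a published 95% range
(16 of the 19 at the defaults) to its low and high bound, all others held
at their point estimates, and ranks parameters by absolute ICER spread.
Parameters printed without ranges — the carrier split, the high-risk
probability, all costs — are deliberately *not* given invented ±20% ranges:
ranges here represent published confidence intervals, and fabricating them
would manufacture evidence. A user can supply ranges in a custom parameter
file. An excursion that destroys the quadrant-I structure is reported as a
dominance flag in the entry, not raised. `restore_check()` guards the
sweep's purity: the baseline analysis must be bit-for-bit identical before
and after.

## The microsimulation oracle

`simulate_relatives()` is both the package's synthetic-data generator and
an independent check on the cohort engine: each simulated relative draws an
arm by the arm weights, then walks annual Bernoulli transitions with
exactly the cohort engine's probabilities, costs, discounting and
tie-break. One seeded RNG stream is consumed in a fixed counter order
(arm-assignment uniforms first, then one uniform per individual per cycle,
drawn whether or not the individual is already absorbed), so results are
bit-for-bit reproducible for a seed and independent of storage order. A
single uniform per cycle encodes the competing transitions:
$u < p_b$ is breast, $p_b \le u < p_b + p_o(1-p_b)$ ovarian.

What it emulates: annual Bernoulli transitions among well / breast-cancer /
ovarian-cancer under each strategy arm, with per-individual cost and case
discounting. What it does not emulate: mortality, sequential second
cancers, age-varying hazards, correlated surgical uptake, or any
heterogeneity beyond arm membership — so agreement between engine and
microsim validates the implementation of *this* model, not the model's
fidelity to real cohorts. The oracle check runs both strategies at
$n = 200{,}000$ and requires cohort expectations within 3 standard errors
of the Monte-Carlo means; SE convergence is additionally checked at
$n \in \{10^3, 4\times10^3, 1.6\times10^4\}$ against the $n^{-1/2}$ law
(tolerance factor 1.5).

## Numerical and degenerate-input choices

* Probability bounds, range ordering ($\text{low} \le \text{point} \le
  \text{high}$), nonnegative costs and the one-off/per-cycle recurrence
  vocabulary are validated at load; violations are collected and reported
  together, each naming its parameter.
* Zero prevalence of both genes makes the carrier split undefined and is a
  domain error; full adherence collapses the refusal arms to zero weight and
  is handled without special-casing.
* Degenerate sensitivity ranges (low = high = point) produce zero spread
  and rank last.
* Arm weights must sum to 1 within $10^{-12}$ at construction.

## Problem sizes

The shipped configuration is the study condition itself: 40 annual cycles,
nine intervention arms, three comparator arms — a cohort model that runs in
milliseconds, so no test scales anything down. The microsimulation oracle
uses $n = 200{,}000$ individuals (about a second, vectorised); the
convergence ladder uses $10^3$–$1.6\times10^4$.

## Known limitations

* No mortality or competing risks; no quality adjustment (cases, not QALYs).
* Constant hazards over ages 30–70 compress real age-incidence curves.
* One cancer per individual: a breast cancer censors later ovarian cancer
  (and vice versa), which keeps "cases prevented" well-defined but slightly
  undercounts total incidence.
* Expected costs over a 40-year horizon are highly sensitive to whether
  recurring screening costs compound over the horizon; analyses built on
  closed-source cycle mechanics can differ substantially on the cost side
  while agreeing closely on effectiveness, and the package documents its own
  conventions precisely so its numbers are reproducible from the text above.
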