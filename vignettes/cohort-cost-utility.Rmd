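---
title: "Cohort Markov cost-utility analysis with cohortcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort Markov cost-utility analysis with cohortcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cohortcea)
```

# The model

`cohortcea` implements cohort state-transition (Markov) modelling for
cost-utility analysis of two competing treatment strategies. A model is a
set of ordered health states with one terminal absorbing state, a per-cycle
row-stochastic transition kernel $P$, a start distribution $\pi_0$, timing
(cycle length $L$ in years, horizon $n$ cycles), an annual discount rate
$r$, per-state utilities, and two strategy arms (reference and comparator)
that share the kernel but differ in costs and in a utility adjustment
coefficient.

The cohort trace is the deterministic recursion
$\pi_k = \pi_{k-1} P$. Person-time in cycle $k$ is half-cycle corrected in
the life-table (trapezoid) sense, $\bar\pi_k = (\pi_{k-1} + \pi_k)/2$; this
is the standard discrete-time correction for the bias of attributing a full
cycle to people who transition mid-cycle. The correction is applied
identically to costs and QALYs, since the discounting policy applies to
both.

Discounting uses $w_k = (1+r)^{-L(k-1)}$ by default: the first cycle
accrues undiscounted value and a full year's discount has accrued after
$1/L$ cycles. Because the alternative convention (discounting from time
zero, $w_k = (1+r)^{-Lk}$) is also common, the choice is an explicit
`discount_from` switch in the model file rather than a buried constant.
Over a 20-year quarterly horizon at 5% the two conventions differ by about
1.2% in totals — roughly $\pm 0.01$ QALYs on a total of 1.6 — which is the
natural reproduction tolerance for totals published without stating the
convention.

An arm's value is
$$\mathrm{QALY} = \sum_{k=1}^n \sum_{s\,\mathrm{living}} \bar\pi_k(s)\,
u_a(s)\, L\, w_k, \qquad
\mathrm{Cost} = \sum_{k=1}^n \Big(\sum_{s\,\mathrm{living}}
\bar\pi_k(s)\Big)\, c_a(k)\, w_k,$$
and the incremental comparison reports $\Delta C$, $\Delta E$, the ICER
$\Delta C/\Delta E$ (only in the trade-off quadrants), the dominance
classification, and net monetary benefit
$\mathrm{NMB}(\lambda) = \lambda \Delta E - \Delta C$.

# The bundled ALS edaravone model

The shipped fixture (`als_edaravone_spec()`) encodes a published Chinese
cost-utility comparison of sublingual (SL, comparator) versus intravenous
(IV, reference) edaravone for amyotrophic lateral sclerosis: King's stages
1–4 plus death, irreversible progression, quarterly cycles over 20 years,
5% annual discounting, cohort entry at age 54 (metadata only — no model
input is age-dependent; the source model carries age the same way).

The transition table is stored exactly as printed in its source. As
printed, it is the *columns* that sum to 1 — e.g. stage 1's column
$0.677+0.217+0.064+0.038+0.004 = 1$ — so the only self-consistent reading
is that columns index the from-state. The loader therefore declares
`orientation: columns-are-from` and transposes; orientation is always
explicit because a silently mis-oriented kernel is the classic cohort-model
failure.

```{r}
spec <- als_edaravone_spec()
spec$transition
```

## Costing rules

Costs are course-based. A 28-day course has 14 administration days the
first time and 10 thereafter, at 2 doses/day; the per-course cost is drug
acquisition plus per-course device maintenance plus the amortized share of
the annually replaced PICC catheter (insertion cost divided by the
conventional 13 courses/year). This reproduces the published per-course
figures to the cent: SL 2600.00 (3640.00 first), IV first course
$2431.24 + 206.34 + 142.15 = 2779.73$. The published IV subsequent-course
figure differs from this arithmetic by 0.04 (2085.05 printed vs 2085.09
reconstructed); the fixture stores the formula inputs, not the printed
total.

Expected adverse-event cost per course is the probability-weighted sum over
the event table (6.49 for SL, 55.93 for IV). Indirect cost per care visit
is employment rate × hours lost × hourly wage
($0.15 \times 6.23 \times 18.44 = 17.23$).

Two quantities the source prices but never counts had to be chosen here,
and both are explicit integer knobs (`visit_policy`) calibrated once
against the published lifetime totals, then frozen:

* **Courses per cycle.** A quarterly cycle fits 365/112 ≈ 3.26 calendar
  course-lengths, but that density cannot reproduce the published
  incremental cost and ICER simultaneously for any whole number of visits.
  The fixture uses 3 courses per cycle (12/year) — i.e. treatment pauses
  slightly more than the calendar minimum — which is also the only reading
  consistent with the published lifetime totals. The constructor default
  remains 365/112 for models that state their dosing density.
* **Visits per course.** SL incurs none (self-administered at home). IV at
  home is assigned 7 productivity-loss visits per course (supervised
  infusion and catheter-care encounters) and no transport. IV in hospital
  (scenario) is assigned 9 visits per course, each incurring both the
  116.67 transport round trip and the productivity loss.

With these two calibrations the engine reproduces the published base case
to 1.2% on incremental cost and 0.8% on the ICER, and the scenario saving
to 3.4% — all computed, never stored.

The first-course premium (first minus subsequent course cost) accrues once,
in cycle 1; treatment and its costs continue for every living patient over
the whole horizon, as no stopping rule is stated. Costs accrue on the same
half-cycle-corrected person-time as QALYs.

## Utilities

Stage utilities (0.740, 0.630, 0.510, 0.370) are strictly decreasing in
stage, as the staging system requires. The comparator's quality-of-life
advantage from its administration route enters as a single multiplicative
coefficient on every living-state utility. The fixture stores 1.021 — the
value its source reports and uses, i.e. the ratio of the route factors
0.99 (oral) / 0.97 (IV) rounded to 3 decimals — so the SL/IV QALY ratio is
*exactly* 1.021 and the QALY gain is IV QALYs × 0.021 ≈ 0.033. Using the
unrounded ratio instead would give 0.0327; the rounded coefficient is what
reproduces the published 0.034. The raw factors are kept per arm because
the probabilistic analysis samples them separately.

The hospital scenario *replaces* the coefficient with 1.147 rather than
multiplying: the published scenario QALY gain equals IV QALYs × 0.147,
which is only consistent with replacement (the home-vs-hospital contrast
subsumes the route contrast).

```{r}
run_cua(spec)
run_cua(apply_scenario(spec, hospital_iv_scenario()))
```

A survival note: the trace puts ~53% of the cohort dead by year 3 and ~86%
by year 5 (so ~33% die inside the 3–5-year window), and 99.99% by year 20.
Published prose accompanying this model claims "82% survive 3 to 5 years";
no reading of the kernel we can construct reproduces that figure, and its
definition of "survival period" is ambiguous, so `survival_quantiles()`
reports the windowed fractions and the claim is deliberately not a
reproduction target.

# Sensitivity analyses

## One-way (tornado)

`run_owsa()` varies one parameter at a time: costs by ±20%, effects
(transition probabilities, utilities) by ±10%, parameters bounded by 1
clamped at 1, and the discount rate over the 0–8% policy window. A
perturbed transition entry is absorbed by the same-state (diagonal) entry
so the row stays stochastic; an absorption that would drive the diagonal
negative — or any perturbation that breaks a model invariant — is flagged
infeasible rather than silently renormalized. Items carry both the ICER
and the NMB under each bound; the tornado is *ordered* by the NMB span,
because ICER ordering is undefined when a range drives the QALY difference
across zero (which the utility coefficient's range does here). Both
outcomes are exported.

```{r}
ow <- run_owsa(spec)
head(tidy(ow)[, c("parameter_id", "kind", "span", "nmb_low", "nmb_high")], 5)
```

The most influential inputs are the two drug prices and the utility
adjustment coefficient; adverse-event rates and costs are two orders of
magnitude down — matching the published sensitivity narrative.

## Probabilistic

`run_psa()` samples every parameter independently: gamma distributions for
monetary quantities, beta for probabilities and utilities, parameterized by
method of moments from (mean, se). Published dispersions are not stated, so
the default is se = 10% of the mean, overridable per parameter; the
consequence, stated plainly, is that the published "35.22% probability
cost-effective" is a qualitative target only, not an exact one.

Two numerical choices deserve note:

* **Beta dispersion cap.** For a beta-distributed parameter with mean
  0.99, a 10%-of-mean se is 99.5% of the admissible bound
  $\sqrt{m(1-m)}$; the implied beta is a two-point distribution piling on
  0 and 1 whose draws underflow to exactly 0. Beta standard errors are
  therefore capped at 30% of the admissible bound. Only the route factors
  are affected; transition probabilities and utilities keep their 10% se.
* **Coefficient as a factor ratio.** The comparator coefficient cannot be
  beta-drawn directly (mean > 1). Each draw scales the stored coefficient
  by the ratio of the two route-factor draws to their means, so the
  coefficient's sampling distribution is a ratio of betas centred on its
  base value — and falls below 1 with appreciable probability, which is
  what spreads draws into quadrants II/III of the CE plane.

Transition rows are rebuilt per draw by sampling the off-diagonal entries
and giving the diagonal the remainder (redraw on a negative remainder, cap
100 attempts). The discount rate is not sampled: its range is a policy
question, handled deterministically. Draw $i$ uses an RNG substream
derived from the seed and the draw counter, so it is identical whatever
`n_draws` is, and reruns are bit-identical.

Summaries are computed from the $(\Delta E, \Delta C)$ cloud — quadrant
proportions, percentile 95% intervals, and the acceptability curve
$\Pr(\lambda \Delta E - \Delta C > 0)$ — never as a mean of per-draw
ICERs, which is unstable whenever $\Delta E$ crosses zero.

```{r, eval = FALSE}
psa <- run_psa(spec, n_draws = 5000, seed = 20241028)
autoplot(psa, "plane")
autoplot(psa, "ceac")
```

# The synthetic generator and the microsimulation oracle

`generate_model()` produces random valid decision problems with the
structure the analysis assumes: living-row kernels from a flat simplex
sampler (independent exponentials normalized per row, masked to the upper
triangle for progression-only staging, with guaranteed positive absorption
mass), strictly decreasing utilities, and positive course-based costs for
both arms. It emulates the *shape* of real decision problems, not real
data: there are no correlations between parameters, no age-dependence, no
time-varying kernels. Tests passing on generated models therefore
demonstrate that the arithmetic pipeline is correct on the model class,
not that any particular parameterization is clinically faithful.

`microsimulate()` is the engine's independent oracle: it simulates
individual patient paths directly from the kernel (one categorical draw
per patient-cycle, from a snapshot so nobody transitions twice in a
cycle), tabulates empirical per-cycle frequencies, and values them through
the *same* valuation code as the cohort engine. It deliberately shares the
valuation path but not the trace path, so an error in the matrix recursion
is detectable while valuation rules stay comparable. The test suite checks
cohort-microsimulation agreement at 100,000 patients on ten random models
(entry-wise 3-SE agreement, with a Bonferroni-adjusted simultaneous bound
since ~1,000 comparisons at a 3-SE band must produce a few chance
exceedances), exact agreement on deterministic chains, and the
$n^{-1/2}$ error decay across patient counts.

# Problem sizes and degenerate inputs

The test suite runs the full 80-cycle fixture everywhere, 5,000 PSA draws
for the probabilistic checks, 100,000-patient microsimulations for the
oracle property, and 50,000 draws for distribution-moment recovery; the
whole suite completes in well under a minute on one core. Degenerate
inputs are handled explicitly: a zero discount rate gives undiscounted
sums, identical arms give a zero-difference result with an undefined-ICER
flag (never a division blow-up), identity kernels freeze the cohort and
report no deaths, empty scenarios are the identity, and zero-se
distributions reproduce the base case exactly.

# Limitations

* Exactly two strategies; no efficiency frontier over three or more.
* One fixed kernel: no tunnel states, no time-varying or age-dependent
  transitions, no background mortality beyond the kernel's death column.
* Independent parameter sampling in the PSA (no Dirichlet rows, no
  correlation structure).
* No caregiver work-absence costs and no treatment-stopping rule, mirroring
  the bundled model's own scope.
* The visit counts and course density discussed above are calibrated, not
  sourced; anyone re-using the fixture with different care assumptions
  should treat `visit_policy` and `courses_per_cycle` as the first knobs to
  revisit.
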