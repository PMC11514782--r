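# cohortcea

Cohort Markov models for cost-utility analysis, in tidy R.

`cohortcea` is for health economists and modellers who need a transparent,
scriptable alternative to spreadsheet state-transition models: it reads a
decision problem from a YAML file, runs a half-cycle-corrected and
discounted cohort trace, values competing strategies as discounted lifetime
costs and quality-adjusted life-years (QALYs), and reports incremental
cost-effectiveness with full deterministic and probabilistic sensitivity
machinery. Results come back as tibbles with `tidy()`/`glance()` methods
and `autoplot()` figures, so they drop straight into a dplyr/ggplot2
workflow.

## The model

A decision problem is an ordered set of health states (terminal absorbing
state last), a per-cycle row-stochastic transition matrix *P*, a start
distribution π₀, cycle length *L* (years), horizon *n* (cycles), an annual
discount rate *r*, per-state utilities, and two strategy arms. The engine
computes the cohort trace πₖ = πₖ₋₁*P*, half-cycle-corrected person-time
π̄ₖ = (πₖ₋₁ + πₖ)/2, and per arm *a*

    QALY_a = Σₖ Σ_s π̄ₖ(s) · u_a(s) · L · wₖ
    Cost_a = Σₖ (Σ_s π̄ₖ(s)) · c_a(k) · wₖ,      wₖ = (1+r)^(−L(k−1))

then ΔC, ΔE, the ICER ΔC/ΔE, dominance classification, and net monetary
benefit λΔE − ΔC. One-way sensitivity analysis (±20% costs, ±10% effects,
tornado-ordered), probabilistic sensitivity analysis (gamma/beta sampling
by method of moments, CE plane, CEAC), named scenarios, a random-model
generator, and an individual-level microsimulation oracle complete the
pipeline.

The package ships a fully parameterized model comparing sublingual (SL)
and intravenous (IV) edaravone for amyotrophic lateral sclerosis in the
Chinese setting: King's stages 1–4 plus death, quarterly cycles over 20
years, 5% discounting, course-based drug/device/adverse-event/productivity
costs, and an SL utility adjustment coefficient of 1.021.

## Worked example

```r
library(cohortcea)

spec <- als_edaravone_spec()      # bundled YAML fixture
run_cua(spec)
#> <cea_result> ALS edaravone SL vs IV (base case)
#>   SL           cost       93069.83   QALYs   1.621
#>   IV           cost       80549.19   QALYs   1.588
#>   incremental: 12520.64 CNY, 0.033 QALYs
#>   ICER: 375423.80 CNY/QALY
#>   NMB at WTP 268074: -3580.19
```

Sublingual therapy costs ¥12,521 more and gains 0.033 QALYs over the
lifetime horizon; at ¥375,424 per QALY it is not cost-effective against a
willingness-to-pay threshold of 3× the 2023 Chinese per-capita GDP
(¥268,074 — hence the negative net monetary benefit). Moving IV
administration into hospital flips the conclusion: the comparator now both
saves money and gains QALYs (dominance):

```r
run_cua(apply_scenario(spec, hospital_iv_scenario()))
#> <cea_result> ALS edaravone SL vs IV (base case) [hospital_iv]
#>   SL           cost       93069.83   QALYs   1.822
#>   IV           cost      118841.31   QALYs   1.588
#>   incremental: -25771.48 CNY, 0.233 QALYs
#>   comparator is dominant
#>   NMB at WTP 268074: 88354.63
```

Sensitivity analyses follow the same pattern:

```r
ow  <- run_owsa(spec)                      # tornado-ordered tibble
autoplot(ow)                               # tornado diagram
psa <- run_psa(spec, n_draws = 5000, seed = 1)
glance(psa)                                # quadrants, 95% CIs, P(cost-effective)
autoplot(psa, "plane"); autoplot(psa, "ceac")
```

Everything also works on models you write yourself (`read_model_spec()`,
schema documented in `inst/extdata/als_edaravone.yaml`) or generate
randomly (`generate_model()`), and `microsimulate()` cross-checks any
cohort result by simulating individual patients.

See `vignettes/cohort-cost-utility.Rmd` for the model's assumptions,
calibrated knobs, numerical choices, and limitations.

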