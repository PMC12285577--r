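# gxlife

Gene–lifestyle interaction analysis for obesity and obesity-related
morbidities, built for epidemiologists who want to study — or teach, or
prototype against — the interplay between a polygenic score (PGS) for BMI
and a composite obesogenic lifestyle score, without access-controlled
biobank data. The package provides the full analysis pipeline plus a
first-class synthetic cohort generator that emulates the statistical
structure such studies assume, so every stage is testable end to end.

## What it computes

Participants carry a standardized PGS *z* (quintile categories: low /
intermediate / high) and five binary favorable-lifestyle indicators
(physical activity, diet, sedentary behavior, alcohol, sleep), summed into
a 0–5 score banded as healthy (4–5), intermediate (2–3), poor (0–1), with a
weighted variant `(b₁x₁ + … + b₅x₅)·5/Σbᵢ` from fitted per-factor weights.

The analysis stages are:

* **Exclusion cascade** with an inclusion–exclusion ledger (missing BMI,
  missing outcome records).
* **Effect estimation** — Cox proportional hazards (Breslow ties) for
  incident obesity, logistic regression for prevalent obesity (BMI ≥ 30):
  isolated genetic and lifestyle effects (each adjusted for the other), the
  3×3 joint-category grid against the low-genetic/healthy reference, and
  trend tests on the continuous scores.
* **Absolute risk by age 75** from the Breslow baseline:
  1 − S₀(t\*)^exp(η) across PGS percentiles for the healthy and poor
  lifestyle groups, and their difference in percentage units.
* **Interaction** — multiplicative (product-term Wald test) and additive:
  RERI = RR₁₁ − RR₁₀ − RR₀₁ + 1 evaluated at a configurable exposure
  contrast, decomposed into attributable proportions
  AP_G = (RR₁₀−1)/(RR₁₁−1), AP_L = (RR₀₁−1)/(RR₁₁−1),
  AP_I = RERI/(RR₁₁−1), which sum to 1 identically; bootstrap or
  delta-method CIs.
* **Morbidity scan** — adjusted hazard ratios for 20 obesity-related
  morbidities in top-20% PGS carriers vs the remaining 80%, lifestyle
  subgroups among carriers, Bonferroni flags, and BMI-mediation assessment
  by adjustment (attenuation of the genetic HR toward 1).

See the methods vignette
(`vignettes/gene-lifestyle-interaction.Rmd`) for the generative model, the
parameter defaults and why they were chosen, and the numerical conventions.

## Worked example

```r
library(gxlife)

cfg    <- sim_config(n_participants = 20000, seed = 7)
cohort <- generate_cohort(cfg)
cohort <- simulate_orm_endpoints(cohort, cfg)
cohort <- inject_missingness(cohort, cfg)

ex <- apply_exclusions(cohort)
print(ex$ledger)
#> Exclusion cascade: 20000 -> 19942 (removed 58)
#>   missing_bmi        58
#>   missing_outcome    0
#>   overlap missing_bmi & missing_outcome: 0

cohort <- add_genetic_risk(ex$cohort)
cohort <- add_lifestyle(cohort)

isolated_effect(cohort, "prevalent", "genetic")
#> Isolated genetic effect (prevalent endpoint), adjusted for the other domain:
#>                          term estimate     se ratio ci_low ci_high       p
#>  genetic_categoryintermediate    0.689 0.0508  1.99   1.80    2.20 7.1e-42
#>          genetic_categoryhigh    1.184 0.0570  3.27   2.92    3.65 5.0e-96
#>   trend p (continuous score): 3.63e-119

gxe_interaction(cohort, ci = "delta")
#> Additive gene-lifestyle interaction (OR as RR approximation)
#>   RR11 5.244, RR10 3.651, RR01 2.002 -> RERI 0.592
#>   attributable proportions: genetic 62.5%, lifestyle 23.6%, interaction 13.9%
#>   95% CIs (delta):
#>      estimate  lower upper
#> RERI    0.592 -0.522 1.706
#> AP_G    0.625  0.447 0.803
#> AP_L    0.236  0.132 0.340
#> AP_I    0.139 -0.117 0.396

risk_gradient_curve(fit_risk_model(cohort))
#> Predicted obesity probability (%) by age 75 across PGS percentiles
#>   median healthy 1.78%, median poor 2.89%; difference 0.83 at p5, 1.47 at p95
```

Reading the output: carrying a top-quintile PGS multiplies the odds of
prevalent obesity by about 3.3 even after lifestyle adjustment; the joint
genetic+lifestyle exposure carries about 5.2 times the odds of the doubly
unexposed, and 62% of that excess is attributable to genetic risk alone,
24% to lifestyle alone and 14% to their supra-additive interaction
(RERI > 0). On the absolute scale, the healthy-vs-poor lifestyle gap in
predicted obesity risk by age 75 widens from 0.8 to 1.5 percentage units
between the 5th and 95th PGS percentiles — lifestyle matters most where
genetic risk is highest.

The whole pipeline, including the run manifest and TSV/JSON artifacts, is
also available as one call, or from a shell:

```r
run_pipeline(sim_config(n_participants = 20000, seed = 7), out_dir = "run1")
```

```sh
Rscript inst/scripts/gxlife-pipeline.R --n 20000 --seed 7 --out run1
```

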