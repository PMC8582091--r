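# cfrs — a continuous fall risk score for community-dwelling older adults

Falls are the leading cause of injury-related death in people over 65,
and screening instruments that dichotomize each risk factor lose most of
the information they collect. `cfrs` implements a *continuous* fall risk
score for epidemiologists and clinical researchers working with cohorts
of community-dwelling older adults: ten intrinsic and exposure risk
factors — chronic diseases, physical impairments, cognition (MMSE),
physical function (CPF), multidimensional balance (FAB), fear of falling
(FES-I), affordance-perception error, gait, physical activity
(IPAQ MET-min/week), and environmental hazards — are each regressed on
age and sex, and the standardized residuals are summed:

```
cFRs_i = sum_k s_k * z_ik,    z_ik = (y_ik - yhat_ik) / sd(resid_k)
```

with `s_k = -1` for the six protective components (cognition, physical
function, balance, affordance accuracy, gait, physical activity) and
`+1` otherwise, so a higher score always means higher risk. The score
has mean zero over its fitting sample by construction. Around this core
the package provides:

* a validated cohort data model with CSV input/output and a documented
  column dictionary (`component_registry()`, `load_cohort()`),
* a synthetic two-group cohort generator reproducing the published
  occasional/recurrent-faller component profiles, with configurable
  correlation and missing-at-random missingness (`simulate_cohort()`),
* fully conditional specification multiple imputation with a
  convergence trace (`impute_fcs()`, `pool_imputations()`),
* group comparisons: Student's t, Pearson chi-square, Cohen's d with
  90% CIs and magnitude bands, one-way ANOVA with Tukey HSD, and
  finite-population sample-size planning (`fall_group_table()`,
  `anova_tukey()`, `min_sample_size()`),
* ROC machinery: trapezoid/Mann-Whitney AUC, Hanley-McNeil intervals,
  Youden-optimal cutoffs, Wilson intervals for sensitivity/specificity
  and bootstrap intervals for predictive values (`evaluate_score()`),
* an end-to-end pipeline with a hash manifest for reproducibility
  (`run_pipeline()`) and a thin command-line front end
  (`inst/cli/cfrs.R`).

See the methods vignette (`vignettes/cfrs-methods.Rmd`) for the model,
its assumptions, and every numerical choice.

## Worked example

```r
library(cfrs)

cohort <- simulate_cohort(cohort_config(n = 504, seed = 1))
imp    <- impute_fcs(cohort, m = 8, seed = 2)
pooled <- pool_imputations(imp)
score  <- cfrs_score(pooled)
score
#> Continuous fall risk score: 504 participants (pooled fit)
#>   mean -0.000, sd 5.543, range [-13.41, 18.28]

status <- classify_fall_status(pooled$falls_12m)
ev <- evaluate_score(score$cfrs, status$binary == "recurrent", seed = 3)
ev
#> AUC 0.794 (95% CI 0.746-0.841), moderately_accurate
#> cutoff 0.21: sensitivity 78.9%, specificity 67.1%

tab <- fall_group_table(pooled, cfrs = score$cfrs)
round(subset(tab, variable == "cfrs",
             c(mean_occasional, mean_recurrent, d, d_ci_low, d_ci_high)), 2)
#>    mean_occasional mean_recurrent    d d_ci_low d_ci_high
#> 12           -1.66           4.22 1.21     1.03      1.38

an <- anova_tukey(score$cfrs, status$three_level)
round(an$group_means, 2)
#> zero_falls   one_fall   two_plus
#>      -1.89      -1.07       4.22
```

Reading the output: the score is mean-centred over the fitted sample and
spreads the cohort over roughly ±14 score units. On this synthetic
cohort it discriminates recurrent fallers with AUC 0.794 — "moderately
accurate" on the conventional bands — and the Youden-optimal cutoff
trades sensitivity 78.9% against specificity 67.1%. The recurrent group
sits about 1.2 pooled standard deviations above the occasional group
(Cohen's d 1.21, a *large* effect), and the mean score rises
monotonically across the 0 / 1 / ≥2 falls groups.

The same analysis runs from the shell:

```sh
Rscript inst/cli/cfrs.R simulate --n 504 --seed 1 --out cohort.csv
Rscript inst/cli/cfrs.R pipeline --config config.yml
```

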