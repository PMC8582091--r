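---
title: "Methods behind the continuous fall risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the continuous fall risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cfrs)
```

## The score

Fall risk in community-dwelling older adults is multifactorial: disease
burden, sensorimotor deficits, cognition, fear of falling, and the
*exposure* a person's activity level and home environment create. The
continuous fall risk score (cFRs) condenses ten such components into one
dimensionless number per person. For each component $k$, the raw value is
regressed by ordinary least squares on age and sex,

$$y_{ik} = \beta_{0k} + \beta_{1k}\,\mathrm{age}_i +
\beta_{2k}\,\mathrm{male}_i + \varepsilon_{ik},$$

and the standardized residual $z_{ik} = \hat\varepsilon_{ik} / s_k$
(with $s_k$ the sample SD of the residuals, denominator $n-1$) expresses
how the person deviates from peers of the same age and sex, in SD units.
The score is the signed sum

$$\mathrm{cFRs}_i = \sum_{k=1}^{10} s_k\, z_{ik}, \qquad
s_k = \begin{cases}-1 & k \text{ protective}\\ +1 & k \text{
risk-increasing,}\end{cases}$$

where the six protective components — cognitive performance (MMSE),
physical function (CPF), multidimensional balance (FAB), affordance
perception accuracy, gait, and physical activity — are flipped so that a
higher cFRs always means higher risk. Because OLS residuals are centred,
the score has mean exactly zero over its own fitting sample; it is
*sample-specific* by construction. Scoring new individuals against a
frozen reference fit is supported through the stored model artifact
(`save_cfrs_model()` / `predict()`).

Participants reporting $\ge 2$ falls in the previous 12 months are
*recurrent fallers*; the rest (one fall or none) are *occasional
fallers*. The binary label drives the ROC analysis; the three-level
grouping (0 / 1 / $\ge 2$ falls) drives the ANOVA.

### Pooled vs. sex-stratified adjustment

The component regressions can be read two ways: one pooled regression
per component with a sex indicator, or separate per-sex regressions with
within-sex standardization. The pooled form is the package default
(`stratify_by_sex = FALSE`): it matches the description of the
adjustment as a regression *onto age and sex*, keeps all participants in
one fit, and is the less variance-hungry choice given the 78/22 ratio of
women to men. The fully stratified variant is one flag away and shares
every invariant (zero mean per stratum and overall).

## Imputation

Component values are allowed to be missing; demographics are not. The
package implements fully conditional specification (FCS) with a
stochastic normal-linear model per variable: missing cells are
initialized by draws from the variable's observed values, then the
algorithm cycles over the incomplete variables, regressing each on all
other components plus age and sex on the currently completed data, and
replacing its missing cells with the prediction plus Gaussian noise
scaled by the residual SD. Imputed values are clipped into the
component's valid range (and rounded for count-valued components).
Defaults: `m = 8` completed tables and `maxit = 10` cycles; a
convergence trace of per-iteration imputed-cell means is returned so
stability can be inspected. Predictive mean matching was deliberately
not used — the stochastic regression draw is the simplest fully
specifiable FCS variant, and the clipping step keeps range invariants
without donor pools.

Eight completed tables must become one score per person. The default
policy averages the imputed cell values across tables
(`pool_imputations()`) and scores the pooled table once; the alternative
— score each table and average the scores (`pool_scores()`) — is
exposed because neither is canonical for a composite score that is not a
model coefficient. For linear pipelines the two nearly coincide; the
cell-level average is the default because it yields a single complete
table that all downstream reports can share. Rubin's rules are out of
scope: no pooled inferential variances are reported.

## Group comparison and effect sizes

Numeric contrasts between faller groups use Student's pooled-variance
t-test (Welch by flag), proportions use Pearson's $\chi^2$ without
continuity correction (Yates by flag). Effect sizes are Cohen's
$d = (\bar x_{rec} - \bar x_{occ}) / s_p$ with the pooled SD, reported
with 90% confidence intervals from the normal-approximation standard
error $\sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}$; a noncentral-t
interval is available as an option. Magnitudes follow the thresholds
trivial ($<0.2$), small ($<0.6$), moderate ($<1.2$), large ($<2.0$),
very large ($\ge 2.0$); the published bands leave exactly 2.0
unassigned, and this package assigns the boundary to *very large*.
Score differences across the three fall-count groups use one-way ANOVA
with Tukey's HSD (studentized range). The sample-size planner is the
finite-population-corrected proportion formula
$n = \lceil N z^2 p(1-p) / (e^2(N-1) + z^2 p(1-p)) \rceil$, capped at
$N$ since a sample cannot exceed its population.

## Discrimination

`roc_curve()` sweeps every unique observed score plus $\pm\infty$ under
the rule "positive if score $\ge$ threshold". The AUC is computed two
independent ways — trapezoid over $(1-\mathrm{spec}, \mathrm{sens})$ and
the Mann–Whitney mid-rank statistic — which agree to machine precision
on every instance; this dual route is kept as a standing cross-check of
tie handling. The Youden-optimal cutoff maximizes
$J = \mathrm{sens} + \mathrm{spec} - 1$; ties are broken toward the
lowest threshold (the more sensitive cutoff), deterministically.
Sensitivity and specificity carry Wilson score 95% intervals (the
interval family behind the common clinical calculators; continuity
correction by flag); predictive values carry percentile-bootstrap
intervals over participant-level resamples (default 2000, fixed seed).
The AUC interval uses the Hanley–McNeil standard error by default, with
a bootstrap alternative, and is clipped into $[0,1]$. Interpretation
bands: 0.5 noninformative, $(0.5, 0.7]$ less accurate, $(0.7, 0.9]$
moderately accurate, $(0.9, 1)$ highly accurate, 1.0 perfect; an AUC
below 0.5 is reported as noninformative in the stated direction.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` reproduces the *study conditions* the score was
developed under: 29.4% recurrent fallers, 77.6% women, group ages 73.1
(SD 6.4) vs 73.8 (SD 6.5), and the published per-group component means
and SDs, with the observed per-variable missingness rates (1.1–8.5%).
Within each group the ten components are drawn from a multivariate
normal, rounded for counts and clipped into their valid ranges; fall
counts are drawn consistently with the group (occasional fallers report
0 falls with probability 0.7 — the 0-vs-1 split is not published, so
this is an explicit knob, not a reproduced value — and recurrent fallers
report $2 + \mathrm{Poisson}(1)$). Missingness is missing-at-random
keyed to the always-observed age: the oldest tertile carries a 1.5-fold
relative rate, renormalized to the marginal target.

Only the marginals are published, so the dependence structure is an
explicit modelling choice: an exchangeable correlation $\rho$ (default
0.2) applied on the **risk-aligned** scale — protective components are
negated before correlating — so that a positive $\rho$ means deficits
co-occur: the participant with many impairments also tends toward worse
balance, worse gait and more fear of falling. This orientation is the
epidemiologically plausible one, and it matters: risk-aligned
correlation inflates the within-group variance of the *summed* score
and yields composite AUCs around 0.77–0.79 at $\rho = 0.2$, squarely in
the moderately-accurate band where the real score landed. Correlating
on the raw scale instead would make the sign flips cancel variance and
push the synthetic composite AUC above 0.90 — better discrimination
than the real data supports.

The generator is deliberately not a copy of the real joint
distribution. Its Gaussian marginals miss the strong skew and ceiling
effects of the real instruments — most visibly the MMSE, where a normal
with the published moments (27.0 ± 3.2 vs 22.2 ± 4.2) discriminates the
groups far better (single-component AUC ≈ 0.82 in simulation) than the
real ceiling-compressed MMSE plausibly did (the best published
single-component AUC was 0.757, for physical impairments). Consequently,
on synthetic cohorts the composite reliably beats *most* but not every
single component — the Gaussian cognitive channel is an artifact of the
emulation, not a property of the method. Passing tests therefore
demonstrate the pipeline's internal correctness and the composite's
expected behaviour under the published group structure; they do not
certify performance on real, non-Gaussian data.

## Numerical choices and degenerate inputs

* Residual SD uses the $n-1$ denominator, so the z-scores have sample SD
  exactly 1; the zero-mean and unit-SD invariants are asserted at
  tolerances 1e-10 and 1e-8.
* A component whose residual variance is numerically zero (constant, or
  an exact linear function of age/sex) is refused with an error naming
  the component: a z-score would be 0/0.
* Scoring requires $n \ge 4$, non-constant age, and at least two
  participants of each sex (pooled mode fits a sex contrast).
* Out-of-range values in loaded CSVs are hard errors naming row and
  column; a `permissive` flag coerces them to missing instead.
* Imputation requires at least 10 observed cells per incomplete
  variable; collinear predictors are dropped from the within-FCS
  regression rather than failing it.
* Participant order is preserved through every stage; no operation
  reorders the cohort.
* All randomness (generation, imputation, bootstraps) flows from single
  integer seeds; identical seeds give bit-identical results, which the
  pipeline manifest makes checkable via file hashes.

## Problem sizes used in the test suite

The package's own checks run at the sizes the questions need: n = 504
(the development cohort's size) for score and discrimination
properties, n = 1000 for mask-and-recover imputation experiments,
n = 5000–8000 for law-of-large-numbers checks of the generator's
prevalence, missingness and clipped-normal group means, and 200
replicate cohorts for the sampling distribution of composite and
single-component AUCs.

## Known limitations

* The score is sample-specific; cross-cohort comparability requires a
  frozen reference model, and even then z-scores are relative to the
  reference cohort's age/sex structure.
* Equal component weights are an assumption, not an estimate;
  data-driven weighting (e.g. principal components) is out of scope.
* The synthetic generator's Gaussian marginals understate skew and
  ceiling effects of real instruments (see above).
* DeLong AUC comparison tests and partial AUCs are not implemented; the
  Hanley–McNeil interval is the default and a bootstrap the fallback.
```{r}
sessionInfo()
```
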