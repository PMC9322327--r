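---
title: "Modelling trait-environment-performance relationships in nested crop trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trait-environment-performance relationships in nested crop trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitenv)
```

## The scientific problem

Plant functional traits influence performance, but rarely uniformly: the
payoff of a trait depends on the environment in which the plant grows, and —
in crops — on the genotype carrying it. `traitenv` implements a
three-dimensional analysis that treats trait, environment and variety
(genotype) jointly. Performance currencies are eco-physiological proxies for
fitness — here light-saturated photosynthesis ($A_{sat}$) and instantaneous
water-use efficiency ($WUE = A_{sat}/TR$) — measured on individual plants in
a hierarchical on-farm trial: farms, one plot per variety within each farm,
subplots within plots, plants within subplots.

## The model

For one standardized trait $T$ and one standardized environmental variable
$E$, the fixed-effect backbone is the quadratic selection-surface model

$$
y_{ij} = \beta_0 + \beta_1 T_i + \beta_2 T_i^2 + \beta_3 E_j + \beta_4 E_j^2
 + \beta_5 T_i E_j,
$$

with $y$ the (transformed) performance of plant $i$ in environment $j$.
Because $T$ is centred, $\beta_1$ is the mean trait-performance slope,
$\beta_2$ its curvature, and $\beta_5$ is the trait-environment interaction.
Gathering the terms linear in $T$ gives the **trait-environment
relationship**: the environment-dependent slope

$$
\varphi(E) = \beta_1 + \beta_5 E ,
$$

a line whose height ($\beta_1$) and tilt ($\beta_5$) summarize how the
trait's payoff shifts along the environmental gradient. With several traits,
several environmental variables and a variety factor, the family expands to
variety main effects, trait and environment linears and quadratics,
farm-level climate covariates, and trait x environment, trait x variety,
environment x variety and trait x environment x variety interactions. Under
treatment coding, each variety-containing term carries $g - 1$ dummy
columns; per-variety $\varphi$ lines are assembled as reference coefficients
plus variety offsets. Quadratics do not interact with variety, and
environment quadratics do not interact with traits: with 4 traits, 2 soil
variables, 5 varieties and 2 covariates this yields exactly 83 fixed-effect
columns (`count_fixed_effects()` reproduces the count, and an enumeration
test checks the closed form $1 + (g-1) + 2p + 2q + c + pq + (p + q + pq)(g-1)$
on a parameter grid).

The random part mirrors the sampling design: independent nested intercepts
for farm, plot and subplot,

$$
y = X\beta + Z_f u_f + Z_p u_p + Z_s u_s + \varepsilon,
\qquad V = \sigma^2_\varepsilon I + \sigma^2_f Z_f Z_f^\top +
\sigma^2_p Z_p Z_p^\top + \sigma^2_s Z_s Z_s^\top .
$$

No selection is ever applied to the random part.

## Estimation and small-sample inference

Fitting is by REML through `lme4::lmer()` (the field-standard fitter for
this model class); `fit_lmm()` wraps the fit together with the term graph
and a column map that links every design column to its term and variety
level. The model family is deliberately narrow — Gaussian responses,
polynomial degree two, interactions up to three-way with exactly one
categorical — and the package does not expose a general formula interface.

With 9 farms and 45 plots, asymptotic Wald inference is too optimistic for
farm- and plot-level contrasts. The package therefore implements the
Kenward-Roger small-sample adjustment in its linear-covariance form (the
covariance $V$ above is linear in the variance parameters, so all
second-derivative terms vanish): the adjusted coefficient covariance
$\Phi_A$ inflates the model-based $\Phi = (X^\top V^{-1} X)^{-1}$ using the
REML information of the variance parameters, and each F-statistic is scaled
and referred to a moment-matched denominator df. Solves with $V$ use the
Woodbury identity, so the per-fit cost is governed by the number of
random-effect levels (189 here), not $n$ — this is what makes the
simulation studies below affordable. On balanced designs the machinery
collapses to classical ANOVA df (a farm-level slope in a 9-farm trial gets
exactly 7 denominator df), and the unit tests cross-check the adjusted
covariance and F-tests against an independent implementation (`pbkrtest`)
to near machine precision. A Satterthwaite approximation (delta-method df
for one-df contrasts) is available as `df_method = "satterthwaite"`; it
uses the expected rather than observed information, so it can differ from
`lmerTest` in the second decimal of the df, which is inconsequential for
p-values.

## Type-II marginality ANOVA and backward elimination

Terms are tested by type-II F-tests under the principle of marginality:
each term is adjusted for every term that does not contain it and ignores
its higher-order relatives. Containment is defined on factor multisets, so
$T$ is contained in $T^2$, $T\times E$ and $T\times E\times V$, while $T^2$
is *not* contained in $T\times E$. Treating the quadratic as containing its
linear term is a deliberate design choice (it keeps a main effect in the
model while its quadratic survives); implementations that treat `I(T^2)` as
an unrelated column (e.g. `car::Anova`) will differ exactly on linear terms
whose quadratic is present, and agree elsewhere — the test suite pins both
facts down. The type-II hypothesis matrix for a term with design columns
$X_2$, relatives $X_3$ and remainder $X_1$ is
$L = [\,0 \;|\; I \;|\; (X_2^\top M_1 X_2)^{-1} X_2^\top M_1 X_3\,]$ with
$M_1$ the projector off $X_1$; in orthogonal balanced designs it reduces to
testing the raw coefficients, and type-II sums of squares equal sequential
ones. The printed `Sum Sq` / `Mean Sq` columns are presentational
reconstructions ($SS = F \cdot \mathrm{ndf} \cdot \hat\sigma^2_\varepsilon$)
consistent with the F statistic; the F, df and p-values are the inferential
content. No multiple-testing correction is applied — tables report raw
p-values at $\alpha = 0.05$, as is conventional for this analysis.

Backward elimination (`backward_select()`) removes, at each step, the least
significant *removable* term — one not contained in any term still present —
whenever its type-II p-value exceeds $\alpha$, then refits. Ties are broken
deterministically (highest interaction order, then lexicographic label).
Whether the original procedure tested terms by F or likelihood ratio is not
observable from the reported tables; F-tests with the adjusted df were
chosen for consistency with how the final tables are printed. The trace is
replayable (`replay_selection()`), and a test re-validates that replaying
reproduces the final model exactly.

When two environmental predictors are too collinear to co-occur (the
screening threshold is a pairwise $|r| > 0.6$, strict), `screen_collinearity()`
spawns one alternative predictor set per member — the soil-N versus soil-C
branch — and `compare_alternatives()` arbitrates between the *final* models
by AIC. The default AIC uses the REML likelihood with
$k = k_{fixed} + k_{random} + 1$, mirroring common mixed-model reporting;
comparing REML-based AIC across different fixed-effect sets is heterodox
(the REML criterion conditions on the fixed-effect basis), so
`aic_likelihood = "ml"` refits under ML for an orthodox comparison. With
either choice the arbitration is a strict argmin with ties resolved by
input order and flagged.

## Outputs

- `phi_slope()` / `slope_table()`: per (trait, environment, variety)
  $\varphi$ intercepts and slopes with adjusted standard errors, Wald 95%
  confidence intervals at per-contrast denominator df, and a retained flag
  for pairs whose interaction was eliminated (those report slope 0).
- `variety_slope_contrasts()`: slope offsets against the reference variety
  (the treatment-coding reference, default `H1`); under this coding the
  offset *is* the three-way coefficient, so its Wald test is exact in the
  adjusted-covariance sense.
- `response_surface()` / `stationary_point()`: the fitted quadratic surface
  over the standardized trait-environment plane (non-focal predictors held
  at 0, their standardized mean; covariates at their mean), with the
  stationary point classified by the Hessian
  $[[2\beta_2, \beta_5], [\beta_5, 2\beta_4]]$ as maximum, minimum, saddle,
  or degenerate (singular Hessian; the flat axis is returned instead of a
  point). With both quadratics zero and $\beta_5 \ne 0$ the surface is a
  ruled saddle whose optimum sits in opposite trait corners at the two ends
  of the environmental gradient.
- `r2_nakagawa()`: marginal and conditional $R^2$,
  $R^2_m = \sigma^2_f / (\sigma^2_f + \Sigma\theta + \sigma^2_\varepsilon)$
  and $R^2_c$ with $\Sigma\theta$ added to the numerator, where
  $\sigma^2_f$ is the sample variance of $X\hat\beta$. For Gaussian
  identity-link models the delta-method variant collapses to this standard
  variance ratio, which is implemented directly.

## Preprocessing conventions

Raw field measurements become analysis variables as follows: gas-exchange
triplicates are averaged per plant (fewer than three readings are averaged
with a warning; none at all flags the plant as missing-physiology);
$WUE = A_{sat}/TR$; leaf mass per area is dry mass over area; taproot
volume uses the truncated-cone formula
$V = \tfrac{1}{3}\pi\, RL\,(RD^2 + r^2 + RD\,r)$ with $r = 0.05$ cm, the
threshold radius at which root length is measured, and tissue density is
dry mass over volume. The volume formula is evaluated verbatim with the
recorded `RD` (converted from mm to cm); note that a cone formula in radii
would halve it first — `use_radius = TRUE` provides that variant, and a
cylinder alternative supports sensitivity runs. At $r = RD$ the truncated
cone coincides with the cylinder, which the tests verify as a continuity
check.

Predictors are transformed (log: TTD, LMA, soil P/N/C; square root: LA, PD)
and then z-scored with the sample mean and sample (n-1) standard deviation;
responses are transformed ($\sqrt{A_{sat}}$, $\log WUE$) but never
standardized, so slopes are per-SD-of-predictor effects on the response's
transformed scale. The transforms for variables whose choices are not
pinned down by the reported tables (LMA, the climate covariates) follow the
same convention: log for ratio-type positive variables, identity for
climate. Standardization parameters are stored for back-transforming
surface axes to original units. Outliers are removed *after*
standardization as $|z| > 4$ on leaf area, a conservative reading of
"extremely high" values that reproduces the documented attrition without
inventing a sharper rule; the screen is global rather than within-variety,
and the data are not re-standardized after removal. Missing-physiology
plants are excluded by an explicit preprocessing step, never silently on
read.

## The synthetic trial generator

`simulate_trial()` emulates the study conditions end to end: 9 farms x 5
varieties (one plot each) x 3 subplots x 3 plants (405 plants); farm-level
temperature and precipitation uniform over 16.6-20.5 C and 97.2-237.9 mm;
log-normal subplot soils with soil N and C correlated at 0.8 at both the
farm and subplot level; plant-level traits drawn on their transformed
scales with mild exchangeable correlation (0.3, below the 0.6 screening
threshold) and inverted to natural units so the full preprocessing path is
exercised; and the response generated from the polynomial-interaction fixed
model plus nested random intercepts with variance ordering farm (0.16) >
plot (0.06) > subplot (0.025) and residual 0.09 on the transformed scale.
These variance defaults were chosen once so that the marginal/conditional
R-squared split of fitted models lands in the empirically typical range for
this kind of trial (marginal near 0.1-0.2, conditional near 0.6-0.8). The
default fixed-effect truth is sparse — a trait x soil interaction of -0.105
SD plus soil x variety slope offsets — mimicking the final-model structure
the analysis is designed to find. Five missing-physiology plants and two
extreme leaf-area plants are injected so the 405 -> 398 attrition path is
part of every end-to-end test.

What the generator does *not* emulate: real soil spatial structure beyond
the two-level lognormal, climate time series, trait measurement error
(traits are measured once; only gas exchange carries triplicate noise), and
non-Gaussian residuals. Passing tests therefore demonstrate that the
estimation and selection machinery is correct and calibrated under the
design and the model's own assumptions — not that the model is adequate for
any particular field dataset; `diagnostics()` exists for that judgement on
real data.

`recovery_experiment()` is the simulation harness built on the generator:
per-coefficient bias, RMSE and 95% CI coverage (using the adjusted
covariance and per-contrast df), variance-component relative bias, and —
with `do_selection = TRUE` — per-term retention rates. In recovery runs the
preprocessing standardizes with the generator's population constants rather
than per-sample estimates, isolating estimator behaviour from the (tiny)
sampling noise of the standardization itself.

## Numerical choices and degenerate inputs

- REML optimization is `lme4`'s profiled criterion; boundary (zero)
  variance components are legitimate estimates, and singular-fit messages
  are suppressed during simulation loops. A brute-force grid oracle on
  12-observation toys confirms the optimum in the tests.
- Variance parameters at or below `1e-12` of the scale are dropped from
  the Woodbury factor (they contribute nothing to $V$) but retained in the
  information matrix, whose inverse falls back to a pseudo-inverse at the
  boundary.
- A negative adjusted variance (possible in principle at extreme
  boundaries) falls back to the unadjusted covariance with a warning.
- The denominator-df scaling degenerates when the moment-matching
  denominator vanishes; the residual df is used as a fallback.
- Duplicated predictors abort with the aliased columns named; contrast
  matrices are checked for rank; a single farm or one-plant subplots
  produce explicit confounding warnings from `random_design()`.
- Ties in backward elimination are broken by interaction order then label,
  making the whole pipeline a pure function of (input, configuration,
  seed); reruns are byte-identical and the test suite asserts it.

## Problem sizes used in the tests

The acceptance-level tests run at the study's own design size (405 plants,
83 fixed effects) with simulation counts chosen as the package's standard
evidence levels: 5000 null replicates for the size of the adjusted F-test,
500 replicates for coefficient coverage and variance-component bias, 200
replicates for selection retention, and analytic/grid oracles elsewhere.
The calibration harness assesses size conditional on one drawn design, as
in a real trial.

## Known limitations

- Only nested random intercepts: no crossed random effects, random slopes,
  heteroscedastic residuals, or non-Gaussian responses.
- The model family is closed (degree <= 2, interactions <= 3-way with one
  categorical); it is not a formula language.
- One plot per variety per farm is assumed; other plot-variety mappings
  are rejected by validation.
- AIC arbitration between alternative predictor sets defaults to the REML
  likelihood (see above) — switch to ML for cross-family comparisons.
- No imputation: missing physiology means exclusion, mirroring the
  analysis the package reproduces.
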