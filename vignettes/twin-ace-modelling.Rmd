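---
title: "Twin ACE modelling with twinace: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin ACE modelling with twinace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The biometric model

The classical twin design identifies genetic and environmental variance by
contrasting monozygotic (MZ) pairs, genetically identical at conception,
with dizygotic (DZ) pairs, sharing on average half of segregating additive
genetic variation. For trait $i$ with standardized components
$A_i + C_i + E_i = 1$ and total variance $\sigma_i^2$, the model-implied
per-pair covariance used throughout the package
(`build_pair_covariance()`) has within-person block
$\Sigma_A + \Sigma_C + \Sigma_E$ and cross-twin block
$\Sigma_A + \Sigma_C$ (MZ) or $\tfrac12\Sigma_A + \Sigma_C$ (DZ), where

$$\Sigma_X[i,j] = r_X \sqrt{X_i X_j}\,\sigma_i \sigma_j, \qquad
  \Sigma_X[i,i] = X_i \sigma_i^2 .$$

In the bivariate *correlated factors* solution each trait keeps its own
A/C/E decomposition and the like-type factors correlate across traits
($r_A$, $r_C$, $r_E$), giving 11 free parameters: two means, two total
variances, four standardized proportions (two per trait; the third is
$1 - A - C$), and the three correlations. The decomposition of the
phenotypic correlation, $r_{ph} = \sum_X r_X\sqrt{X_1 X_2}$, is exact by
construction, which is why `bivariate_decomposition()` reproduces the
implied twin correlations to machine precision rather than to an
optimization tolerance.

Key assumptions: multivariate normality of (residualized) trait scores;
equal means and variances across twin order and zygosity (tested by
`assumption_tests()`); equal shared environments for MZ and DZ pairs; no
assortative mating, dominance or gene–environment interaction. E includes
measurement error and is therefore bounded away from zero.

## Estimation

All twin models are fitted by full-information maximum likelihood
(`fiml_minus2ll()`): each pair contributes $-2\log$ of the multivariate
normal density of exactly its observed entries, so incomplete pairs are
used without imputation. Internally pairs are grouped by zygosity and
missingness pattern, reducing each objective evaluation to a handful of
small matrix operations on sufficient statistics regardless of sample
size.

**Parameterization.** Each trait is parameterized as (mean, log total SD,
standardized $A$, standardized $C$) with $E = 1 - A - C$, and the
aetiological correlations enter directly with box constraints
$[-1, 1]$. This differs from the path-coefficient parameterization
traditional in SEM twin software, but spans the identical model space and
has two practical advantages: profile confidence intervals can be taken
directly on the reported quantities (the standardized proportions and
correlations), and boundary solutions — $A = 0$, or $r_A$ pinned at $-1$,
both of which occur at realistic sample sizes — are exact boundary points
of the optimization box rather than limits of a transform. $r_E = \pm 1$
would make the unique-environment block singular and the implied pair
covariance non-positive-definite, so its box stops at $\pm 0.999$;
infeasible proposals ($E \le 10^{-8}$, non-PD covariance) return an
effectively infinite objective, which the bounded quasi-Newton optimizer
(`nlminb`) handles safely.

**Starting values and restarts.** Fits start from moment estimates:
observed means/SDs, and Falconer-style proportions
$A_0 = 2(r_{MZ} - r_{DZ})$, $C_0 = 2 r_{DZ} - r_{MZ}$ clipped to the
interior. Up to `n_restarts` (default 10) seeded random restarts run only
when the moment start fails to converge; in practice the moment start
succeeds for essentially all realistic datasets, and unconditional
restarting would multiply the cost of the simulation studies roughly
tenfold for no measurable change in the optima. Optimizer stops flagged
"singular convergence" (a flat Hessian direction at the optimum, routine
when a variance component sits near zero) are accepted as converged;
"false convergence" is not.

**Fit statistics.** `df` is the number of non-missing data points minus
the number of free parameters, the FIML convention that makes the
saturated bivariate model (28 parameters: 8 means plus two free 4×4
covariance matrices) comparable across missingness patterns.
`AIC = -2LL + 2k`. For BIC the sample size is the number of pairs
contributing data — the natural unit of independent observation in this
design. Model selection in `compare_models()` follows BIC alone, with the
likelihood-ratio statistic and its $\chi^2$ p-value reported for
transparency.

**Assumption ladder.** The four assumption submodels are cumulative
equality constraints on the saturated model — means equal across twins
within pair; additionally across zygosity; variances equal across twins;
additionally across zygosity — each compared to the saturated model by
LRT. Rejections warn rather than abort, since the modeller may judge a
marginal rejection ignorable.

**Profile confidence intervals.** `profile_ci()` finds the points where
the profile $-2LL$ (all other parameters refitted) rises by
$\chi^2_1(0.95) = 3.841$, by bisection with warm-started refits. When the
threshold is not reached before a domain edge (e.g. $r_A \to -1$), the
edge is returned and flagged `pinned`. Boundary-adjacent variance
components make these intervals conservative; no mixture correction is
applied to the CIs (the power module optionally applies a 50:50
$\chi^2_0/\chi^2_1$ mixture reference for boundary null hypotheses).

## GEE screening and residualization

Covariate screening uses Gaussian GEE with identity link on the
twin-level data, clusters being pairs, with the robust sandwich
covariance $B^{-1} M B^{-1}$ and z-based Wald tests (no small-sample df
correction, the large-sample GEE convention). The working correlation
defaults to exchangeable — the natural structure for twins — with
independence available; the coefficients are consistent under either, and
the test suite verifies their agreement. Response and all predictors are
z-scored so slopes are standardized; binary and ordinal covariates
(income, education ranks) are treated numerically. Screening fits all
candidates jointly per trait (one model per trait) and retains a
covariate when its p-value is at or below `alpha` on either trait;
per-covariate marginal screening is available by flag since reported
covariate tables can be built either way.

Residualization regresses each trait on the retained covariates over the
pooled sample (both twins, both zygosities, one fit per trait) and models
the residuals downstream. The residualizing fit uses the independence
working correlation, which makes the residuals exactly mean-zero and
exactly uncorrelated with every regressor in the sample; a correlated
working structure would perturb these identities by a weighting factor
without changing the estimand. Pooling across zygosity preserves
between-group mean differences, so the assumption tests remain
meaningful after residualization.

## What the generator emulates — and what it does not

`batss_sim_spec()` encodes the reference study conditions the package was
validated against: 164 MZ + 131 DZ pairs; a motor trait (mean 10.27,
SD 1.05) and a combined social-communication trait (mean 34.22, SD 1.65);
bivariate ACE structure $A = 0.21/0.12$, $C = 0.67/0.78$, $E = 0.12/0.10$,
$r_A = -0.39$, $r_C = 0.45$, $r_E = 0.32$; demographic covariates with
the reported distributions (age about 167 ± 9 days; term age 259 ± 8
days; 11-level ordinal household income 7.5 ± 2.4; 5-level parental
education; parental age; sex as a pair-level binary, since same-sex pairs
only). Covariates whose reported associations were significant carry
their reported standardized effects (age 0.28/0.15, term age 0.17/0.11,
income −0.19/−0.11 per SD); covariates whose reported intervals include
zero (sex, parental age, parental education) carry null generating
effects, so that the screening stage's expected retained set matches the
reported one. Missingness is independent per twin-trait at rate 0.01,
which reproduces a handful of incomplete pairs per sample; pairs losing
all trait values are dropped, and the generator supports both
one-twin-missing and one-trait-missing patterns since either can occur.

The generating distribution is multivariate normal with covariates
entering as additive mean shifts only. This matches the modelling
assumptions (reported trait skewness is near zero), and that is precisely
its limitation: passing recovery tests on these data demonstrates the
correctness of the estimation machinery, not robustness to skewed scales,
floor effects of item-limited instruments, rater bias processes, or
covariate-dependent variance, none of which are simulated. Polygenic
score columns (`simulate_pgs_columns()`) are standardized normals shared
exactly within MZ pairs and correlated 0.5 within DZ pairs; ancestry PCs
are independent standard normals, so ancestry confounding is not
emulated — PC adjustment is exercised mechanically, not substantively.

## Descriptive statistics

Twin order within a pair carries no information, so twin–twin and
cross-twin cross-trait correlations are computed on double-entered data
by default (each pair contributes both orderings), making the estimates
label-invariant; a flag restores raw single-order Pearson correlations.
Confidence intervals use the Fisher z transform with the number of
distinct pairs (not the doubled count). The phenotypic correlation is an
individual-level Pearson correlation whose CI comes from a cluster
bootstrap resampling whole pairs (default 2000 seeded resamples), because
individuals within a pair are far from independent and the i.i.d. Fisher
interval would be too narrow; the output records the method. Skewness and
excess kurtosis use the adjusted Fisher–Pearson estimators.

## Power analysis

`posthoc_power()` estimates, by simulation at given generating values and
design size, the probability that the LRT dropping one parameter (set to
zero) rejects at `alpha` on 1 df. Per-replicate seeds derive from the
master seed, failed fits are excluded and counted, and more than 10%
failures flags the report. Detection is LRT-based rather than
CI-excludes-zero: the two agree asymptotically and the LRT is cheaper and
better behaved at boundaries. For variance components the null value lies
on the boundary, making the nominal $\chi^2_1$ reference conservative;
`boundary_mixture = TRUE` switches to the 50:50 mixture reference. At the
reference generating values and design size, power is essentially 1 for
the shared-environment components and correlation and low for the
additive genetic component and correlation — small twin samples inform C
far better than A.

## Problem sizes used in the shipped studies

The simulation studies in the test suite and acceptance script use: 200
replicates of the full design (164 + 131 pairs) for bivariate parameter
recovery; 200 replicates for univariate profile-CI coverage; 2000
replicates of a 60-pair null design for the robust Wald type-I error
check; 100-replicate power runs; and 25,000 pairs per zygosity for
moment-recovery checks. These sizes put Monte-Carlo error comfortably
below the tolerances being asserted while keeping a full run on a single
CPU in the minutes range.

## Known limitations

- No ADE/AE/CE sub-model search, sex-limitation, moderation (GxE) or
  Cholesky/common-pathway alternatives; the correlated-factors ACE family
  is the scope.
- Boundary estimates are reported as-is; p-values for variance components
  near boundaries are conservative (no mixture correction outside the
  power module).
- Gaussian identity-link GEE only; no non-Gaussian links.
- The generator's normality means simulation-based validation speaks to
  estimator correctness under the model, not to instrument-level
  artefacts of real questionnaire scales.
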