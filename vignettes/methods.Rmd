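---
title: "Measurement invariance of a binary violence-experience instrument: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement invariance of a binary violence-experience instrument: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vawinvar)
```

## The scientific problem

The WHO violence-against-women instrument asks fifteen yes/no questions
about acts of psychological (items 1–3), physical (items 4–11) and sexual
(items 12–15) violence experienced in the past 12 months. Comparing
prevalence or latent "exposure to violence" scores across groups — sites,
age groups, education levels — is only meaningful if the instrument is
*measurement invariant*: the items must relate to the underlying constructs
in the same way in every group. `vawinvar` implements a two-stage
psychometric assessment for this kind of binary-item battery:

1. **Configural stage.** Exploratory structural equation modeling (ESEM) of
   the tetrachoric correlation matrix establishes whether a 3-factor
   structure with the WHO domain pattern fits.
2. **Invariance stage.** A Bayesian MIMIC (multiple-indicator
   multiple-cause) probit model regresses the three factors on the
   covariates (B coefficients: genuine latent-mean differences) and the
   items directly on the covariates (A coefficients). A direct effect whose
   95% credible interval excludes zero means the item's threshold differs
   across levels of that covariate beyond what the factors explain —
   scalar noninvariance, a form of differential item functioning.

All stages run against synthetic data from a generator that emulates the
study population, so the full pipeline is testable end to end without the
original survey file.

## The probit latent-response model

Each binary response arises from a latent continuous variable:

$$
y^*_{ij} = \nu_j + \lambda_j^\top \eta_i + a_j^\top x_i + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, 1), \qquad
y_{ij} = \mathbf{1}\{y^*_{ij} > 0\},
$$
$$
\eta_i = B x_i + \zeta_i, \qquad \zeta_i \sim N(0, \Psi),
$$

with $J = 15$ items, $m = 3$ factors, and $x_i$ the dummy-coded covariate
vector (22 columns from 11 categorical covariates). Identification fixes
the probit residual variance at 1 and $\operatorname{diag}(\Psi) = 1$.
Integrating $\zeta$ out gives the closed-form marginal
$P(y_j = 1 \mid x) = \Phi\big((\nu_j + (\lambda_j^\top B + a_j^\top)x) /
\sqrt{\lambda_j^\top \Psi \lambda_j + 1}\big)$, which serves as the
generator's analytic oracle, and the implied latent-response correlation
matrix is the population tetrachoric matrix — the second oracle.

## The synthetic-data generator and its preset

`vaw_preset("dreams")` encodes the study conditions: the standardized
3-factor loading pattern (major loadings 0.543–0.943, cross-loadings up to
0.352), total factor correlations 0.575/0.446/0.467, covariate effects on
the factors, five noninvariant item-level direct effects (items 1, 2 and 15
by food insecurity; item 5 by marital status and education; item 10 by site
and wealth), and intercepts calibrated by root finding (tolerance 1e-8) so
that population prevalences span 1.6%–26.5%. Reported cohort values pin the two
prevalence extremes and a handful of covariate marginals (site 617:464,
57.8% in school, 59.4% ever had sex, 78% never married, 84.8% Christian);
the remaining 13 prevalences and the other covariate marginals are fixed
plausible values for an urban-slum adolescent-girl cohort, chosen once and
kept: declining prevalence within each violence domain, a five-level
education split centred on incomplete secondary, a 7-group ethnicity mix
with a small Somali reference group, 32% food insecurity, and equal wealth
terciles.

Standardization back and forth is exact: the preset is built on the probit
scale from the standardized tables by closed form (the total factor
correlation matrix is fixed, $SD(\eta_k) = 1$, and
$SD(y^*_j) = 1/\sqrt{1 - c_j}$ with $c_j$ the standardized communality),
so `standardize_parameters()` reproduces the input tables to machine
precision.

What the generator deliberately does **not** emulate: joint dependence
among covariates (they are drawn independently from their marginals; the
real survey's education–age–marital dependence is absent), missing data
(the study reports none), and any clustering or survey weighting. The
asset battery for the wealth index is 12 binary indicators whose ownership
probabilities follow a logistic model in a latent standard-normal wealth
score (slope 1.5, baseline ownership 15%–85%) — invented, since only asset
domains are reported for the cohort, and documented here. Passing tests therefore show
the *methods* behave correctly under the stated statistical structure, not
that any particular real-world dataset satisfies that structure.

## Tetrachoric estimation

Thresholds come from the margins ($\tau_j = \Phi^{-1}(1 - \text{prev}_j)$,
the `y = 1` iff `y* > τ` convention); for a 2×2 table the margin quantiles
are the joint MLE, so the two-step estimator *is* maximum likelihood. The
correlation maximizes the orthant-probability likelihood over
(−0.999, 0.999) with bivariate-normal CDFs evaluated to 1e-12; estimates
beyond |0.998| are flagged as boundary cases. Pairs with an empty cell get
a 0.5 continuity correction (relevant here: a 1.6% item makes empty cells
likely in subsamples). The asymptotic variance per pair, used both as the
DWLS weight and in WRMR, is the inverse profile information
$\big(n\,\phi_2(\tau_1,\tau_2,\rho)^2 \sum_c 1/\pi_c\big)^{-1}$. If the
assembled matrix has negative eigenvalues it is repaired by clipping at
1e-8 and rescaling to unit diagonal, and flagged.

## ESEM: extraction, rotation, fit

Extraction minimizes the diagonally-weighted least-squares discrepancy
$F = \sum_{j<l} (s_{jl} - \lambda_j^\top\lambda_l)^2 / v_{jl}$ over an
echelon-form loading matrix (quasi-Newton with analytic gradient; a 1e-8
ridge breaks ties among discrepancy-equivalent solutions toward zero
loadings; uniquenesses below 0.001 are clamped and flagged as Heywood
cases). Oblique Geomin rotation ($\epsilon = 0.001$) runs the
gradient-projection algorithm from 30 seeded random starts plus the
identity, keeps the smallest criterion, then aligns columns to the WHO
domain pattern by maximal absolute congruence and fixes signs so each
column's largest loading is positive.

The test statistic is $T = n F_{\min}$. Because the tetrachoric estimates
are correlated across pairs, the raw $T$ is mis-calibrated; the default
`adjust = "mean"` rescales by $df/e$ so the null expectation matches the
degrees of freedom. This is a deliberately cheap surrogate for the
mean-and-variance–adjusted statistics of commercial SEM software, whose
exact adjustment needs the full asymptotic covariance of all 105
tetrachorics; fit indices computed from it should be read comparatively,
not as exact frequentist calibrations. CFI/TLI are clamped to [0, 1],
RMSEA uses $n$ in the denominator (categorical-data convention; an
$n{-}1$ switch exists) with a 90% CI from inverting the noncentral
chi-square CDF, and WRMR is
$\sqrt{\sum_r (s_r-\hat\sigma_r)^2/v_r \, / \, e}$.

## Covariate screening

The two-stage per-item probit screen mirrors common epidemiological
practice: stage 1 tests each candidate covariate (jointly over its
$k{-}1$ dummies, LRT with $df = k-1$) adjusted for DREAMS invitation,
site and age; survivors at $p \le 0.10$ enter one multivariable model per
item; blocks significant at $p \le 0.05$ in a single backward pass define
the item's direct effects. Invitation, site and age are always retained.
No multiple-testing correction is applied across the 15 items — a
deliberate mirror of the original procedure, and a caveat: with 8
candidates × 15 items, a handful of false inclusions is expected. Perfect
separation falls back to a ridge-penalized Newton fit (penalty 1e-4) with
a warning.

## The Gibbs sampler

Data augmentation follows the classic probit scheme: truncated-normal
draws of $y^*$, conjugate normal draws for factor scores, item rows
$(\nu_j, \lambda_j, a_j)$ and factor regressions, and a
parameter-expanded inverse-Wishart step for $\Psi$ rescaled to a
correlation matrix each iteration (the compensating rescaling of
$\Lambda$, $B$ and $\eta$ keeps the likelihood invariant). Two additions
matter for this model class:

* **Partially collapsed B update.** $B$ is drawn with the factor scores
  integrated out ($\eta$ is then redrawn immediately), removing the slow
  $B \leftrightarrow \eta$ coupling.
* **Translation moves.** The always-retained covariates carry direct
  effects on *every* item, so the likelihood cannot separate
  factor-mediated from direct effects for those columns: the map
  $B_c \mapsto B_c + \delta$, $A_{\cdot c} \mapsto A_{\cdot c} -
  \Lambda\delta$, $\eta_i \mapsto \eta_i + \delta x_{ic}$ leaves it
  unchanged. The conditional of $\delta$ under the priors is Gaussian, so
  an exact generalized-Gibbs move resamples the ridge position each
  iteration; a second move of the same type recenters the factor location
  against the intercepts. Without these moves the potential scale
  reduction factor for the affected parameters stays near 3; with them it
  drops to ~1.1–1.4 at moderate run lengths.

Priors: variance 25 (diffuse) on intercepts, major loadings and factor
regressions; 0.04 on cross-loadings — the probit-scale equivalent of the
BSEM-literature default of 0.01 on the standardized scale, given this
instrument's latent-response SDs of roughly 1.4–2.2; and variance 1
(weakly informative) on direct effects. The direct-effect prior cannot be
diffuse: it is the only source of identification for the
factor-mediated/direct split of the always-retained covariates, and with
variance 25 the split — and with it every noninvariance flag — would be
prior noise. All five variances are config-exposed.

Two consequences of the small-variance cross-loading prior are worth
knowing. First, items whose true cross-loadings are large re-express in
the posterior as slightly larger majors with near-zero crosses — an
observationally near-equivalent representation; on synthetic data the
affected majors sit up to ~0.1–0.2 above the generating values while the
ESEM stage recovers the same loadings to within 0.05. Second, factor
correlations shift relative to ESEM's (harder shrinkage pushes them up),
which is expected behaviour of this model family, not a defect of either
stage. Relatedly, because the direct-effect prior shrinks toward zero,
credible intervals under a no-effect truth over-cover: the realized
false-flag rate is well below the nominal 5%, i.e. the flagging is
conservative.

Model fit uses the posterior predictive p-value. The default discrepancy
is a weighted squared distance between the pairwise cross-product moments
(all 105 item pairs plus the 15 margins) of the data and those of
replicates drawn from the current parameters: four replicates form the
reference (averaging shrinks reference noise), one more plays the role of
new data, and since all replicates are iid given the draw, observed and
replicated discrepancies are exchangeable under the model — PPP
concentrates near 0.5 when the model reproduces its own data. The moment
form matters: any discrepancy that decomposes per item (a Bernoulli
deviance, marginal or conditional on the factors) is blind to the
dependence structure, because the latent factors absorb it — such a
discrepancy cannot flag a wrong factor structure even in principle. The
marginal-likelihood deviance (factors integrated out analytically per
item) is still recorded and available via
`compute_ppp(fit, method = "deviance")` as a check on the item margins
given covariates. Convergence
is monitored by split-chain potential scale reduction with threshold 1.1;
summaries refuse to run on non-converged draws unless forced.

Standardization of the draws is STDYX: loadings by
$SD(\eta_k)/SD(y^*_j)$, covariate coefficients additionally by the
empirical $SD(x_c)$, with all SDs from the model-implied variances per
draw. Flags are per covariate *level* (dummy column).

## Problem sizes and numerical choices

The test suite exercises: generator-vs-closed-form agreement at
n = 200,000; tetrachoric estimates against an independent quadrature
oracle on 100 random tables (agreement to 1e-5); ESEM recovery at
n = 100,000 (within 0.05); MIMIC recovery at n = 2,000 with 2 chains of
5,000 iterations; flag calibration across 100 null datasets of n = 1,000
(2 × 2,000 iterations); PPP calibration across 50 replicates of n = 600;
and a full-pipeline run at the study size n = 1,081. These sizes were
chosen so each property is measured at a scale where Monte-Carlo noise is
small relative to its tolerance while a complete run stays desk-scale.

Degenerate inputs are handled explicitly: non-positive-definite $\Psi$ is
rejected naming the matrix; zero-margin 2×2 tables are fatal with advice
to enable the continuity correction; zero-variance assets and constant
covariates are dropped with warnings; separation triggers the ridge
fallback; Heywood solutions are clamped and flagged; tercile ties stay in
the lower group.

## Known limitations

* The ESEM chi-square adjustment is a mean rescaling, not the full
  mean-and-variance adjustment; printed fit indices from other software
  will differ in the second decimal.
* Loading standard errors (and significance stars) for the ESEM stage are
  not computed.
* The wealth covariate and the asset battery are generated independently
  by default; deriving the covariate from the assets is available through
  `wealth_index()` but is not wired into the generator.
* Covariates are sampled independently; analyses sensitive to covariate
  collinearity should supply their own design.
* No missing-data machinery beyond fail/listwise-drop at read time.
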