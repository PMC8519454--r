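# vawinvar

Bayesian psychometric analysis of the 15-item WHO violence-against-women
(VAW) instrument for adolescent girls and young women: does the instrument
measure the same three constructs — psychological, physical and sexual
violence — in the same way across population subgroups, so that group
differences in latent means are real differences rather than measurement
artifacts?

The package implements the full analysis pipeline for a respondent-level
table of 15 binary items plus categorical covariates:

* **Synthetic survey generator** — samples from the probit MIMIC model
  y\*ᵢⱼ = νⱼ + λⱼᵀηᵢ + aⱼᵀxᵢ + εᵢⱼ, ηᵢ = Bxᵢ + ζᵢ, yᵢⱼ = 1{y\*ᵢⱼ > 0},
  with a preset (`vaw_preset("dreams")`) mirroring the study conditions
  (major loadings 0.543–0.943, factor correlations 0.575/0.446/0.467,
  item prevalences 1.6%–26.5%, five noninvariant item-covariate effects),
  plus closed-form oracles for marginal probabilities and the implied
  tetrachoric structure.
* **Descriptives** — per-item prevalence, cumulative acts-of-violence
  curves (overall and stratified), sample summaries, and a
  Filmer–Pritchett PCA wealth index with terciles.
* **Tetrachoric correlations** — pairwise ML with continuity correction,
  asymptotic variances, and PSD repair.
* **ESEM** — DWLS extraction on the tetrachorics, oblique Geomin rotation
  (ε = 0.001, multi-start gradient projection), CFI/TLI/RMSEA (90% CI)/WRMR.
* **Covariate screen** — the two-stage per-item probit LRT screen
  (p ≤ 0.10 then p ≤ 0.05, invitation/site/age always retained) that
  decides which direct effects enter the MIMIC model.
* **Bayesian MIMIC** — Gibbs sampler (RcppArmadillo) with BSEM
  small-variance cross-loading priors, partially collapsed updates and
  exact translation moves, posterior predictive p-value, STDYX
  standardized summaries, and per-level noninvariance flags from 95%
  credible intervals.
* **Pipeline driver** — `run_pipeline()` executes all stages from a config
  (simulate or CSV input) into a deterministic CSV/JSON bundle;
  `compare_to_reference()` checks a bundle against expected values.

## Worked example

```r
library(vawinvar)

params <- vaw_preset("dreams")           # study-conditions truth
sv     <- generate_survey(params, n = 1081, seed = 7)
Y      <- item_response_matrix(sv$responses)

# descriptive surface
pv <- item_prevalence(Y)
range(pv$percent)                        # 1.76 25.35  (min item 11, max item 3)
acts_distribution(Y)
# Acts of violence among 1081 respondents:
#   >=1 act: 523 (48.4%)
#   >=half (8) of the acts: 42 (3.9%)

# configural stage
sol <- esem(Y, n_factors = 3, seed = 1)
sol
# ESEM solution: 15 items, 3 factors, n = 1081
#   CFI = 1.000, TLI = 1.000, RMSEA = 0.000 (90% CI 0.000-0.000), WRMR = 0.479
round(sol$Lambda_rotated[7, ], 2)        # -0.01 0.90 0.01  (item 7 loads physical)

# invariance stage
cd  <- structure(list(X = sv$X, raw = sv$covariates_raw,
                      codebook = params$covariate_spec),
                 class = "covariate_design")
scr <- run_screen(Y, cd)                 # two-stage probit LRT screen
fit <- mimic_fit(Y, cd, scr,
                 mimic_config(chains = 2, iter = 4000, burn = 2000,
                              ppp_every = 4), seed = 2)
summ <- mimic_standardize(fit, force = TRUE)
summ$ppp                                 # 0.452  (~0.5 = model reproduces its data)
flag_noninvariance(summ)                 # pairs whose 95% CrI excludes 0, e.g.
#   item10  site:Viwandani  -0.230  [-0.405, -0.067]
#   item10  wealth:medium   -0.169  [-0.304, -0.049]
#   item15  hungry:yes       0.173  [ 0.095,  0.240]
```

On this synthetic cohort the ESEM stage reproduces the WHO 3-factor
pattern (all 15 major loadings on their designated domain, fit above the
CFI/TLI ≥ 0.95, RMSEA < 0.06, WRMR < 1.0 thresholds), and the MIMIC stage
fits well by PPP. The flags recover the larger injected noninvariant
effects with the right signs (item 10 lower in Viwandani and in the medium
wealth tercile, item 15 higher under food insecurity); a single cohort of
n ≈ 1000 with ~180 screened coefficients also yields a handful of
borderline flags, and the weakest injected effects (standardized ≈ 0.07)
sit at the edge of detectability — the expected behaviour of
interval-based flagging under shrinkage priors.

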