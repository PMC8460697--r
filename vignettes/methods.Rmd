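---
title: "Emulating a pragmatic trial of ART conception: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a pragmatic trial of ART conception: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artgrowth)
```

## The scientific problem

Assisted reproductive technology (ART) conception has been associated with
smaller child stature and altered cardiometabolic profiles, but couples who
conceive by ART differ systematically from spontaneously conceiving
couples. A randomized trial of ART versus expectant management is
infeasible, so the analysis this package implements emulates one: the
"control arm" is drawn from spontaneously conceiving couples whose medical
history (recurrent miscarriage, PCOS, uterine fibroids, ovarian cysts,
thyroid disease, fertility-related medication use) suggests they belong to
the same subfertile source population as the ART couples. ART effects on
child growth are then estimated with estimators of complementary
assumptions — covariate adjustment, inverse-probability weighting, and
doubly robust collaborative targeting — and a candidate mediator (fetal
cord-tissue DNA methylation) is interrogated by parametric g-computation
with a maternal-methylation negative control.

## The structural model

All mediation machinery rests on a recursive linear system over ART status
$A$, maternal fasting glucose FG, pregnancy systolic blood pressure SBP,
gestational age at delivery GA, the methylation residual CPG, the child
outcome $Y$, and a fixed confounder vector $C$:

$$
\begin{aligned}
\mathrm{FG} &= \beta_1 A + \Gamma_1 C + \alpha_1 + \varepsilon_1\\
\mathrm{SBP} &= \beta_2 A + \beta_3 \mathrm{FG} + \Gamma_2 C + \alpha_2 + \varepsilon_2\\
\mathrm{GA} &= \beta_4 A + \beta_5 \mathrm{FG} + \beta_6 \mathrm{SBP} + \Gamma_3 C + \alpha_3 + \varepsilon_3\\
\mathrm{CPG} &= \beta_7 A + \beta_8 \mathrm{FG} + \beta_9 \mathrm{SBP} + \beta_{10} \mathrm{GA} + \Gamma_4 C + \alpha_4 + \varepsilon_4\\
Y &= \beta_{11} A + \beta_{12} \mathrm{FG} + \beta_{13} \mathrm{SBP} + \beta_{14} \mathrm{GA} + \beta_{15} \mathrm{CPG} + \Gamma_5 C + \alpha_5 + \varepsilon_5
\end{aligned}
$$

`fit_structural_system()` estimates each equation by least squares with a
shared confounder encoding. `gcompute_effects()` propagates each subject's
observed confounders through the fitted chain under $A = 1$ versus $A = 0$
(total effect, TE), and under $A = 1$ with CPG held at its $A = 0$
predicted level (natural direct effect, NDE); the natural indirect effect
is NIE = TE − NDE, so additivity holds by construction within every
bootstrap replicate. For this all-linear system the counterfactual
contrasts have closed forms — e.g.
$\mathrm{NIE} = \beta_{15}\,[\beta_7 + \beta_8\beta_1 +
\beta_9(\beta_2+\beta_3\beta_1) +
\beta_{10}(\beta_4+\beta_5\beta_1+\beta_6(\beta_2+\beta_3\beta_1))]$ —
and the test suite verifies the engine against that path-tracing oracle to
10⁻¹⁰.

Design choices that were genuinely open:

- **Mean propagation versus residual draws.** Counterfactuals propagate
  conditional means; for a linear system this equals the expectation of
  residual-draw simulation while removing within-replicate Monte-Carlo
  noise. A draw-based mode (`draw_residuals = TRUE`) exists for non-linear
  extensions, and a test confirms the two agree on average.
- **Point estimates from the original sample, SEs from 100 bootstrap
  resamples** with normal-based intervals. The alternative (bootstrap-mean
  point estimates) differs only at higher order for these smooth
  functionals.
- **The NDE's "untreated methylation level"** is computed per subject from
  the fitted CPG equation with $A = 0$ and upstream mediators also at
  their $A = 0$ values; this is the only convention under which
  TE = NDE + NIE holds exactly.
- **Negative control.** Maternal mid-pregnancy methylation replaces the
  fetal measure under the reordering CPG$_M$ → FG → SBP → GA → $Y$ (the
  maternal epigenome precedes the pregnancy physiology it might influence).
  Under fetal imprinting and no unmeasured parental confounding its NIE is
  zero; simulations in the test suite confirm both the null calibration and
  that a planted latent parental trait (raising ART odds and shifting
  maternal methylation and outcome together) drives the estimate many SEs
  from zero.

## What the generator emulates — and what it does not

`generator_config()` defaults encode the study conditions: 83 expected
treated versus 1154 untreated triads; treatment assigned by a logistic
model on maternal age, education, income, household smoking, parity and
pre-pregnancy BMI, with the intercept calibrated to the target arm
fraction (median assignment probability ≈ 5%, so the treated arm is
sparse, as in the source design); subfertility indications more common in
treated couples; mediator scales matched to clinical ranges (FG ≈ 4.35
mmol/L, SBP ≈ 110 mmHg, GA ≈ 38.5 weeks); standardized CpG residuals; and
16 visits at 0–78 months whose outcome-equation treatment block is scaled
by a multiplier ramping linearly from 0.25 at birth to 1 at 78 months, so
ART effects grow with age. Structural coefficients default to
`default_path_coefs()` (e.g. $\beta_{11} = -2$ cm, $\beta_7 = -0.3$ SD,
$\beta_{15} = 0.5$ cm/SD, giving a true total height effect of −2.50 cm at
78 months, ~6% mediated). Missingness defaults: paternal anthropometry
roughly one-third missing (MAR given ART status and education), smaller
fractions for BMI, income and glucose, and a per-visit dropout hazard of a
few percent, monotone once a family leaves.

One shared RNG stream is consumed in a fixed order (confounders →
treatment → indication flags → mediators → CpGs → outcomes → missingness),
so a seed reproduces the cohort byte-for-byte.

The generator does **not** attempt to reproduce the source cohort's exact
joint covariate distribution, genotype-level LD structure, device-level
measurement error, or non-linear growth-curve residual correlation within
child. Passing tests therefore demonstrate that the estimators are correct
under the assumed data-generating mechanism (linear structural equations,
logistic assignment, MAR missingness) — not that real-data estimates are
unbiased when those assumptions fail.

## Estimators

**Covariate adjustment with multiple imputation.** `adjusted_effect()`
fits OLS of the outcome on ART plus either the pre-conception confounder
set or that set plus pregnancy factors, within each of (default) ten
chained-equation imputations, pooling by Rubin's rules. Imputation models
are covariate-only by default (outcomes are not used as predictors);
predictive conditional draws use linear residual noise for continuous
variables, Bernoulli draws for binary, multinomial draws for categorical;
ten cycles with per-variable mean traces retained for convergence
inspection.

**Inverse-probability weighting.** `fit_weights()` is deliberately
complete-case (it trades power for a different missingness assumption than
imputation). Weights combine inverse treatment and inverse censoring
probabilities and are truncated at the 1st/99th percentiles by default —
with ~7% treated, extreme weights are routine, and truncation bounds their
influence; the bounds are recorded in the fit. Weighted fits use HC0
sandwich variances because weighting invalidates the OLS variance.

**Collaborative TMLE.** `ctmle_ate()` scales the outcome to [0, 1]
(min–max, bounds recorded), takes an initial outcome regression from the
stacking ensemble, and then builds the propensity model greedily: starting
from intercept-only, each candidate covariate is provisionally added, the
intercept-free logistic fluctuation of the scaled outcome on
$H(A,W) = A/g - (1-A)/(1-g)$ with offset $\mathrm{logit}\,\bar Q$ is fit,
and the candidate minimizing 5-fold cross-validated squared error of the
updated prediction is kept; the search stops at the first non-improving
step (no patience), with ties broken by candidate order. Propensities are
bounded into [0.01, 0.99] before forming $H$ — unbounded estimates make
$H$ explode in a sparse-treatment cohort. The fluctuation's score equation
$\sum_i H_i (Y_i - \bar Q^*_i) = 0$ is verified to 10⁻⁸ in tests, and the
ATE is invariant to affine outcome rescaling.

**Stacking ensemble.** Out-of-fold predictions from GLM, GLM with all
pairwise interactions, a ridge-penalized GLM (the shrinkage analog of a
weakly informative Bayesian GLM), the observed mean, a single-hidden-layer
neural net (width 5, iteration-capped, seeded) and depth-≤3 boosted trees
(≤200 rounds; default 50) are combined by non-negative least squares. The
raw NNLS coefficients are used as weights — this guarantees the meta-fit's
risk on the out-of-fold matrix never exceeds any single learner's, a
property the suite checks on 25 random problems. A learner that fails to
fit is dropped with a warning.

## Methylation and polygenic score

`residualize_technical()` removes indicator-coded technical structure
(chip position, extraction batch, bisulfite batch) per CpG by exact linear
projection; upstream array preprocessing (empirical-Bayes batch
correction, cell-type deconvolution) is out of scope. The candidate scan
fits one adjusted OLS per site and flags at $\alpha/m$ and at the
epigenome-wide 3.6×10⁻⁸ bound; p-values are verified uniform under a
global null. The PRS follows two clumping rounds — windows interpreted as
± the stated distance around the index SNP on the same chromosome, allelic
correlation computed on observed counts (composite LD), round 2 re-ranking
survivors by p — and the retained threshold per ethnicity maximizes the
mean absolute correlation of the standardized score with the two anchor
phenotypes (birth weight and BMI); the combining rule is the package's
choice, as no single criterion is canonical.

## Numerical and protocol details

- HOMA-β is set to missing at fasting glucose ≤ 3.5 mmol/L (non-positive
  denominator); HOMA-IR is always computed.
- A third blood-pressure reading is required only when the first two
  differ by *more than* 10 mmHg on either scale — a spread of exactly 10
  does not trigger it.
- The length/height correction is a fixed +0.7 cm applied only when
  standing height stands in for recumbent length.
- LMS z-scores interpolate L, M, S linearly in exact age (days); ages
  outside the chart raise a coverage error rather than extrapolating. The
  shipped chart (`inst/extdata/synthetic_lms_chart.csv`) is synthetic —
  smooth curves of realistic shape — and real WHO/AAP tables load through
  the same format.
- Percent differences for log-scale outcomes are
  $(e^\beta - 1)\times 100$, applied identically to both CI limits.
- Subfertility flags denote pre-pregnancy diagnoses; medication-based
  inclusion is a single precomputed flag rather than free-text drug
  matching.
- Comparison-arm predicates combine by OR; AND-rules can be expressed via
  composite flags. The `random_none` arm defaults to 204 draws.

## Problem sizes and known limitations

The test suite and acceptance script validate at deliberately modest
scale: parameter recovery on cohorts of 800–2500, interval coverage over
200 generator replicates (60 bootstrap resamples each), null calibration
over 100 replicates, double robustness at n = 5000, and two-visit
schedules where the full 16-visit grid adds nothing to the property being
checked. These sizes make the properties sharp while keeping a full run in
minutes.

Known limitations: no linear mixed models for the repeated measures (the
single-level estimates are the primary surface); no exposure–mediator
interactions in the structural system (the printed equations contain
none); influence-function variance only for C-TMLE (no cross-validated
TMLE variant); imputation is impute-once-then-resample relative to the
mediation bootstrap; and the genome-scale EWAS path is the same per-CpG
engine as the candidate scan, not a specialized large-matrix
implementation.
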