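---
title: "Candidate-gene methylation analysis of HPA-axis dysregulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene methylation analysis of HPA-axis dysregulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpameth)
```

## The scientific problem

The hypothalamic–pituitary–adrenal (HPA) axis is the body's central
stress-hormone cascade: hypothalamic CRH drives pituitary ACTH release,
which drives adrenal cortisol, and cortisol feeds back through the
glucocorticoid receptor to shut the cascade down. Impaired feedback is
measurable with the low-dose dexamethasone suppression test (DST):
individuals whose morning cortisol stays at or above 138 nmol/L after an
evening 0.5 mg dexamethasone dose are *non-suppressors*. The question this
package operationalises is whether DST non-suppression is accompanied by
differential DNA methylation at CpG sites in the promoters of six core
HPA-axis genes — *CRH*, *CRHBP*, *CRHR1*, *CRHR2*, *FKBP5* and *NR3C1* —
and whether methylation at those sites tracks gene expression in
independent cohorts.

The design is a candidate-gene screen on array methylation data: of the
hundreds of thousands of probes on a methylation BeadChip, only the CpGs
within 2000 bp of a transcription start site (TSS) of a panel gene are
analysed — promoter-proximal methylation is where the methylation–expression
coupling is strongest — giving a panel of a few dozen probes (76 in the
reference configuration) measured on ~93 samples (20 non-suppressors,
73 suppressors).

## Analysis model

### Scale: beta versus M

Array methylation is reported as a beta value, the methylated fraction
$\beta \in [0,1]$. Statistics are computed on the M-value scale,
$M = \log_2\!\big(\beta/(1-\beta)\big)$, which is approximately
variance-stabilised; betas are clipped to $[\varepsilon, 1-\varepsilon]$
(default $\varepsilon = 10^{-6}$) before the transform so boundary values
stay finite. `beta_to_m()` / `m_to_beta()` are exact inverses away from the
clipped tails, and matrices carry their scale so a double transform is
refused rather than silently computed.

### Per-probe linear models with empirical-Bayes moderation

For each probe $g$, the M-values are regressed on the phenotype of interest
(binary DST status, or a continuous trait such as baseline cortisol or the
TSH/T4 ratio) plus the covariates retained by the forward screen:

$$ M_{gi} = \alpha_g + \beta_g \, x_i + \boldsymbol{\gamma}_g^\top
\mathbf{z}_i + \epsilon_{gi}, \qquad \epsilon_{gi} \sim N(0, \sigma_g^2). $$

With ~90 samples the per-probe variance estimates $s_g^2$ (on $d_g$
residual df) are noisy, so they are shrunk under the standard hierarchical
model for array data: $s_g^2 \mid \sigma_g^2 \sim \sigma_g^2
\chi^2_{d_g}/d_g$ with a scaled-inverse-$\chi^2$ prior $1/\sigma_g^2 \sim
\chi^2_{d_0}/(d_0 s_0^2)$. The posterior-mean variance

$$ \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g} $$

yields the moderated t-statistic $\tilde t_g = \hat\beta_g /(u_g \tilde
s_g)$ on $d_0 + d_g$ df, where $u_g$ is the unscaled coefficient SD from
$(X^\top X)^{-1}$. The prior $(d_0, s_0^2)$ is estimated by matching the
first two moments of $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$: the
excess of the spread of $e_g$ over its sampling variance
$\psi'(d_g/2)$ identifies $\psi'(d_0/2)$, inverted by Newton iteration
(`trigamma_inverse()`, relative tolerance $10^{-8}$). Zero or negative
excess spread means the variances are mutually consistent and $d_0 =
\infty$ (full shrinkage to $s_0^2 = e^{\bar e}$; on exactly degenerate
input this log-scale estimator carries a benign $\sim 1/d_g$ bias factor).
This machinery is implemented in closed form in this package; the test
suite cross-checks it, probe for probe, against an independent reference
implementation of the same hierarchy and against normal-equation oracles.

Two limits anchor the implementation: $d_0 = 0$ reproduces the ordinary
OLS t exactly, and $d_0 = \infty$ uses $s_0^2$ for every probe. Per-probe
p-values are two-sided; FDR control is Benjamini–Hochberg (`bh_fdr()`).

### Transcript-level binomial enrichment

A single CpG rarely survives FDR in a small panel, so evidence is
aggregated per transcript: with $k$ of a transcript's $n$ probes nominally
significant (raw $p < 0.05$, direction ignored), $k$ is referred to
$\mathrm{Binomial}(n, p_0 = 0.05)$ with an exact test, and transcript
p-values are Bonferroni-multiplied by the number of tested transcripts.
The default sidedness is the two-sided minimum-likelihood convention of
`binom.test`; for the flagged $k = n$ patterns the one- and two-sided
conventions coincide, so the headline numbers are convention-proof. The
test ignores inter-probe correlation within a transcript — a known
optimism of this design, inherited deliberately.

### Covariate screen, group table, post-hoc models

* `forward_select()` admits a clinical covariate into the phenotype model
  only if the nested-model F-test (or likelihood-ratio test in the
  logistic variant) gives $p < 0.10$; greedy forward selection with a
  deterministic alphabetical tie-break, full trace retained. Binary
  outcomes are screened with the same linear-model ANOVA by default,
  matching common practice for this kind of screen; whether previously
  admitted covariates should be re-tested is ambiguous in the field's
  descriptions, and classic greedy forward (no re-testing) is implemented.
* `cohort_table1()` contrasts the groups variable by variable: Shapiro–Wilk
  at $p \ge 0.05$ per group gates a two-sample t-test versus
  Kruskal–Wallis; 2×2 tables use the chi-squared test with Yates
  continuity correction (the correction is what reproduces the published
  hypersexuality p-value of 5.78E-02 from counts 17/20 vs 43/73; the
  uncorrected statistic is available by flag). The 0.05 gate alpha is our
  choice; the field convention rarely states one.
* `interaction_linear()` / `interaction_logistic()` test disease-state
  dependence: `cg ~ a + b + a:b` by OLS, and `outcome ~ cg + b + cg:b` by
  binomial GLM (IRLS, deviance tolerance $10^{-10}$). Complete or
  quasi-separation is detected (fitted probabilities collapsing onto the
  outcome, or a coefficient norm above 15 on the logit scale) and raised
  as an explicit error rather than returned as a divergent fit.

### Methylation–expression correlation

For each candidate transcript, probe M-values are averaged when a
transcript has several probes, then correlated with the gene's normalized
expression across the samples of a small independent cohort, twice:
Pearson's product-moment correlation with its exact t-based p-value, and
an MM-type robust simple regression (high-breakdown S-estimate start,
bisquare IRLS refinement at ~90% normal efficiency, tuning constant 3.88,
Wald p on $n-2$ df). The robust route is what a 10-sample cohort needs:
one gross outlier moves the OLS slope arbitrarily but perturbs the MM
slope only slightly. The S-stage's subsampling runs under a fixed internal
seed, so robust fits are deterministic. On exactly linear data the robust
and OLS fits coincide to machine precision; on clean Gaussian data they
agree only up to the estimator's efficiency (a few percent), which is the
realistic statement of the "robust ≈ OLS when nothing is wrong" sanity
check.

### Sample QC

`pca_outlier_flags()` replaces visual inspection of a PCA display with a
reproducible rule: probes with beta-SD above a threshold (default 0.2, a
variability filter) enter a centred PCA, and samples whose PC1 score falls
outside mean ± 1.96·SD (a 95% reference range) are flagged. Two caveats
are intentional. First, the variability-filter interpretation of the
threshold is an assumption, recorded as such. Second, a 95% reference
range flags ~5% of perfectly healthy samples by construction — the rule
trades a small false-positive rate for reproducibility, and the report
carries scores and the variance share so a human can overrule it.

## The synthetic cohort generator

No raw data are deposited for the motivating study, so the package ships a
generator (`cohort_config()` / `generate_cohort()`) whose defaults *are*
the study conditions: 20 cases vs 73 controls; 76 probes over nine
transcripts of the six panel genes, mirroring every publicly printed
transcript/probe-count (including the 2-probe *NR3C1* transcript AJ877169
and the 14-probe *CRHR2* transcript EU012442); hypersexuality prevalence
0.85 / 0.589 per group; continuous covariates at the published group
means/SDs (baseline cortisol 515.2 (147.2) vs 458.5 (133.5) nmol/L, IL-6
2.03 (0.12) vs 2.30 (0.98) ng/L, TSH/T4 0.017 (0.0099) vs 0.023 (0.0233),
and so on).

The generative model is logit-normal: per-probe baselines are drawn from a
bimodal beta mixture (the hypo-/hyper-methylated peaks of real arrays),
planted case effects are added on the M scale, Gaussian noise with
`noise_sd = 0.5` M-units is added, and the inverse logit2 maps back to
betas strictly inside (0,1). Effects are additive on the analysis scale by
construction, which is exactly what makes parameter recovery checkable.
Defaults that the study does not pin down were chosen once on realism
grounds: 0.5 M-units is a typical residual SD for whole-blood promoter
CpGs, +1.0 M-units is the planted effect used in power checks (a large but
within-range promoter shift), and `planted_effects` defaults to empty — a
null cohort — because the study asserts no true effect size. The two
expression cohorts are emulated as bivariate-normal pairs at n = 11 and
n = 10 with configurable correlation (default 0.5, the magnitude of the
published robust coefficients).

What the generator does **not** emulate: probe-type chemistry and
background noise of the array, batch structure, cell-type composition
shifts, inter-probe spatial correlation along a promoter, and non-Gaussian
clinical covariate distributions. Passing tests therefore demonstrate that
the statistical machinery is correct and calibrated under the cohort's
sampling structure — not that the biological findings would replicate on
real arrays.

## Numerical choices and problem sizes

* Beta clipping $\varepsilon = 10^{-6}$; trigamma Newton tolerance
  $10^{-8}$ relative (typically converges to machine precision);
  logistic IRLS: 50 iterations, deviance tolerance $10^{-10}$; robust
  IRLS: 200 iterations (small-n bisquare fits can need more than the
  usual 50), non-convergence is a hard error.
* Ties in forward selection break alphabetically; all simulation streams
  derive from a single integer seed; internal randomness (robust
  subsampling) is seeded locally and restores the caller's RNG state.
* Calibration suites run at: 500 null-cohort replicates for type-I error
  (38,000 probe-level tests), 50 seeded runs for planted-transcript
  recovery, 5000 probes for variance-prior recovery at $d_0 = 4$,
  $s_0^2 = 0.05$, $d_g = 89$. These sizes give Monte-Carlo standard errors
  comfortably inside the tolerances asserted.

## Known limitations

* The binomial enrichment assumes independent probes within a transcript;
  promoter CpGs are correlated, so transcript p-values are optimistic.
* The forward screen's linear-model treatment of a binary outcome is a
  screening heuristic, not a calibrated model; the logistic variant is
  provided.
* The QC rule flags ~5% of unremarkable samples by design (see above).
* A probe within the TSS window of two panel genes is kept in both
  transcripts' counts; the alternative (unique assignment) is not
  implemented because the per-transcript framing of the enrichment test
  wants each transcript's full probe complement.
* Expression cohorts are consumed pre-normalized, one value per gene and
  sample; raw array processing is out of scope.
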