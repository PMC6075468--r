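---
title: "Models and methods: bivariate latent change score analysis of a serum biomarker and brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsem)
```

## The scientific problem

Serum S100B is a calcium-binding protein found mostly in glia; elevated
concentrations accompany CNS injury and blood-brain-barrier leakage, which
makes it a candidate blood biomarker of brain aging. The question this package
operationalizes is longitudinal: in a cohort measured at two waves about three
years apart, (1) is the *level* of serum S100B associated with the level of a
brain MRI measure at baseline, and (2) is the *change* in S100B coupled to the
change in that measure? The MRI outcomes are white matter hyperintensity
volume (WMH, log-transformed), total brain and gray matter volume (optionally
as proportions of intracranial volume), a visual rating of perivascular-space
change, general factors of tract-averaged fractional anisotropy (gFA) and mean
diffusivity (gMD) over seven white matter tracts (genu, splenium, and
left-right averages of the anterior thalamic radiation, cingulum, uncinate,
arcuate and inferior longitudinal fasciculi), and the individual tract
averages.

## The model family

Every analysis is a **bivariate latent change score (LCS) model** fit in a
structural equation framework. For a construct measured at waves 2 and 3, the
wave-3 score is decomposed as

\[ y_3 = 1 \cdot \eta_2 + 1 \cdot \Delta, \]

with \(\eta_2\) the latent wave-2 level and \(\Delta\) a latent change, both
with free means and variances and a free level-change covariance.
Single-indicator constructs (volumes, serum, single tracts) carry zero
measurement residuals, so \(\Delta\) is an adjusted difference score — the
design has no way to separate measurement error from true change with one
indicator per wave. The two constructs in a bivariate model are joined only by
covariances (all six among the two levels and two changes are free); no
level-to-change regressions are included, because the quantities reported are
the standardized **cross-sectional** (level-level) and **longitudinal**
(change-change) correlations, which carry reserved labels `cov_lvl_lvl` and
`cov_chg_chg` in every builder.

For gFA and gMD the construct is a common factor over the seven tract
averages under **strong factorial invariance**: each tract's loading and
intercept are equality-constrained across waves, identification is by marker
(the genu: loading 1, intercept 0 at both waves), and the latent means are
free. Same-tract residuals covary across waves (7 covariances), and further
tract-tract residual pairs can be supplied as configuration;
`suggestResidualPairs()` ranks candidate pairs by the standardized covariance
residual of a fitted model. No canonical list of extra pairs is shipped: the
default is none, which keeps the model family honest on synthetic data where
no such residual structure exists.

The **PVS variant** replaces the outcome's latent change with the observed
ordinal change rating (treated as numeric, correlated with the serum level
and change); there is no PVS level variable.

**Covariates** (ages in years at serum draw and at scan, per wave; sex;
diabetes and hypertension flags) enter as exogenous observed variables with
free means, variances and intercorrelations, regressing onto manifest
variables only: serum manifests on the wave's serum age and sex, MRI manifests
on the wave's scan age, sex, diabetes and hypertension. The PVS rating, which
spans both scans, is corrected for both scan ages plus sex, diabetes and
hypertension. Because the rating is binary-ish ordinal, its "correlation" with
the latent serum terms should be read as a point-biserial-style quantity.

**Auxiliary variable.** Attrition in aging cohorts is typically selective on
baseline gray matter. To make the missing-at-random assumption behind FIML
more plausible, `addAuxiliary()` adds baseline GM as a saturated correlate: it
covaries freely with every other observed variable (with the residual, for
endogenous manifests). On complete data this augmentation leaves substantive
estimates untouched and, because the auxiliary block is exactly saturated, the
model degrees of freedom are unchanged; under GM-driven attrition it reduces
the bias of the change-change covariance (the test suite measures both
properties).

## Estimation

The engine is a general RAM path-model implementation: directed paths `A`,
symmetric covariances `S`, means `M`, observed selector `F`, with implied
moments \( \Sigma = F(I-A)^{-1} S (I-A)^{-\top} F^\top\),
\( \mu = F(I-A)^{-1} M \). Free parameters are labels in the matrices; shared
labels impose equality. The casewise (full-information) likelihood sums each
case's multivariate-normal log-density over its observed subset; cases are
grouped by missingness pattern purely as an optimization, and the grouped
value equals the case-by-case sum (tested). The score is analytic — the
per-pattern derivatives with respect to \((\Sigma,\mu)\) are chained through
the RAM structure — which keeps optimization cost independent of the
parameter count.

Numerical choices, recorded for reproducibility:

* Optimizer: `nlminb` (PORT) with the analytic gradient and a parameter
  `scale` built from the start-value implied standard deviations; serum
  variances (~1e-3) and volumes (~1e3 cm^3) coexist in one model, and PORT
  stalls without this scaling. A quasi-Newton polish from the solution
  certifies the stationary point; a fit is declared converged when the
  optimizer reports success, the scaled gradient is negligible, or the polish
  cannot improve the objective beyond 1e-7 relative.
* Start values are deterministic: observed means/variances from the data,
  loadings 1, covariances 0, covariate regressions 0; a latent seeded from an
  indicator only it reaches (level factors), change components from zero mean
  and half the indicator variance. Fits therefore contain no randomness.
* Variances are unconstrained (Heywood cases allowed) and flagged in
  `warnings` rather than hidden by bounds.
* The saturated model is estimated by EM for the unstructured multivariate
  normal under missingness (closed form on complete data); the independence
  baseline factorizes, so per-variable ML is its exact FIML solution. The
  likelihood-ratio statistic is \( \chi^2 = 2(\ell_{sat} - \ell_{model}) \)
  with N (not N-1) scaling — natural under FIML; exact numeric parity with any
  particular SEM package's conventions is not claimed.
* Standard errors come from the inverse observed information (central-
  difference Jacobian of the analytic score); the Wald z on the unstandardized
  covariance provides the p-values for the two reserved associations.
* Fit indices use the canonical definitions: RMSEA with the (n-1) divisor
  (0 when df = 0), CFI/TLI in noncentrality form, SRMR as the rms of
  standardized covariance residuals (lower triangle including the diagonal,
  means excluded) against the saturated (EM) moments so it stays defined under
  missingness.
* Bias-corrected bootstrap: participants are resampled with replacement,
  replicates refit from the point estimates, and the BC percentile interval
  uses \( z_0 = \Phi^{-1}(P(\hat\theta^* < \hat\theta)) \) with endpoints at
  \( \Phi(2z_0 \pm z_{(1+c)/2}) \). Non-converged replicates are dropped and
  counted (warning above 20%); a degenerate bootstrap distribution collapses
  the interval to the point estimate. The headline analysis uses 1000
  replicates; tests use fewer for speed.
* Standardization divides covariances by the model-implied total SDs of the
  two variables (correlation metric) and rescales paths by sd(tail)/sd(head);
  entries with zero implied variance are returned as `NA` and flagged, never
  dropped.

## Preprocessing rules

`preprocessCohort()` applies, in order: (1) exclusion of participants with
self-reported dementia or MMSE < 24 at either wave, and of participants
reporting melanoma at either wave (melanoma raises serum S100B for non-CNS
reasons); (2) a one-sided serum outlier filter — cells more than 4 SDs *above*
the wave mean, with the mean/SD computed once on the wave's pre-removal
values, non-iteratively — and a wave-3 assay floor (< 0.02 µg/L, the assay's
minimal detectable concentration); both are cell-level removals so the other
wave remains usable under FIML; (3) optional division of WMH/TB/GM by
intracranial volume, then a natural-log transform of WMH (base unspecified in
the field's convention; natural log only changes scale). A transform flag
guards idempotency, and every exclusion/removal lands in an audit log. The
outlier filter runs after the participant exclusions, following the narrated
order of the emulated protocol.

## The synthetic cohort generator

No participant-level data ship with this package; the generator exists so
that every downstream stage is testable against known truth. It draws the six
constructs' latent levels and changes from one joint normal whose moments are
set by the shipped calibration (`inst/extdata/calibration.yaml`):

* Serum: the latent moments are solved in closed form so the **observed**
  wave means/SDs and the wave-to-wave Pearson correlation hit the calibrated
  values (0.085/0.035 and 0.092/0.040 µg/L; r = 0.585) after the centered
  covariate effects are added.
* Volumes: wave means/SDs from the calibration table; WMH is lognormal with
  log-medians matched to the printed medians (the printed WMH row is
  median/IQR — raw WMH is strongly skewed). Wave-to-wave stabilities are not
  printed anywhere, so field-realistic defaults are fixed once: TB 0.98,
  GM 0.95, log-WMH 0.90, gFA 0.80, gMD 0.85 — high for volumes, lower for
  diffusion metrics, consistent with the measurement properties of each
  modality.
* Serum-MRI latent couplings default to the calibrated standardized values
  (gFA level -0.150, etc.); MRI-MRI couplings default to zero, which makes
  recovery simulations clean. `zeroCouplings()` gives the all-null
  configuration used for false-positive-rate studies.
* Tract indicators follow intercept + loading x factor + residual, with the
  configured cross-wave residual covariance; bilateral tracts are generated
  per hemisphere with an inter-hemisphere residual correlation of 0.7 and
  averaged downstream, so the pipeline exercises the averaging step. Loadings
  (0.75-1.0) and intercepts are set so tract means sit in realistic FA
  (0.38-0.55) and MD (0.70-0.82 x 10^-3 mm^2/s) ranges.
* Covariate effects are added to manifests in centered form (so the latent
  means remain the marginal means): modest sex and age effects on serum
  (females higher), age/diabetes/hypertension effects on MRI of plausible
  sign and size. Ages are drawn normal around the wave means and truncated at
  +/-3 SD; wave-3 age is wave-2 age plus the inter-wave lag.
* The PVS rating defaults to the two observed categories (0 and +1 with the
  calibrated frequencies); an optional coupling draws it by thresholding a
  latent propensity correlated with the standardized serum change, enabling
  non-null PVS scenarios. All five rating levels are supported.
* Missingness: wave-3 attrition follows
  \( \mathrm{logit}^{-1}(\alpha + \beta\, z(\mathrm{GM}_2)) \) — missing at
  random, tied to observed baseline gray matter (default ~20% attrition,
  slope -0.3) — plus an MCAR per-wave scan-missingness rate (default 0.236,
  the fraction of serum donors without MRI). Wave-2 serum is never removed.
* Artifact injection plants serum outliers strictly above the 4-SD filter
  threshold and wave-3 values below the 0.02 µg/L assay floor, with an audit
  log, so the preprocessing filters are exercised end to end.

What the generator does **not** emulate: non-normal latent distributions,
scanner drift or batch effects, more than two waves, nonlinear change,
region-level spatial structure beyond the single common factor, and
measurement error in single-indicator constructs. Passing recovery tests
therefore show the estimator is correct *under its own assumptions*, not that
real cohort data satisfy them.

### Tract-protocol calibration

For single-indicator tract analyses, the factor measurement model attenuates
any observed tract-serum correlation below the latent coupling (by
loading x sd(factor)/sd(indicator)), so no factor-based configuration can
reproduce a calibrated per-tract correlation larger than the factor's own.
`tractCalibration()` therefore makes the named tract the construct itself —
loading 1, zero residual — and sets the serum-level/construct-level
correlation to the shipped per-tract value (-0.155 anterior thalamic, -0.111
cingulum, -0.087 splenium and arcuate). This is the generating configuration
for the tract-recovery simulations.

## Reporting pipeline

`runAssociationSuite()` builds, fits, standardizes and bootstraps each
outcome's model and applies Benjamini-Hochberg FDR within the suite. Two
families are corrected separately — the global suite (six outcomes x
level/change = 12 tests) and the per-tract suite — matching how such results
are presented; family membership is logged with the rows. Cohen's d in
`compareGroups()` is the pooled-SD two-sample formula; Welch's t and
Satterthwaite df are used for all group comparisons. The attrition report
compares baseline serum, TB, WMH and GM between returners and non-returners
and crosses sex with MRI participation.

## Problem sizes used in the shipped simulations

Recovery protocols use 25 replicates of n = 600 (about the analyzed sample
size of the emulated study) for the latent-factor and tract models; the MAR
correction study uses 200 replicates of n = 300 with a deliberately strong
attrition slope (-2) and GM-coupled changes, because the default calibration's
zero MRI-MRI couplings make GM-driven attrition ignorable for non-GM models
(nothing to correct); the FDR-control study uses 200 all-null replicates of
n = 400 over the four fast single-indicator/PVS outcomes with covariate
adjustment off. These sizes were chosen once as the smallest designs that
leave Monte-Carlo error well below the effects being measured.

## Known limitations

* Single-group models only; no multi-group or moderated invariance testing.
* No robust (sandwich) standard errors or scaled chi-square variants; the
  PVS rating is treated as numeric rather than ordinal-categorical.
* The observed-information standard errors assume an interior optimum;
  boundary solutions (variances near zero) are flagged, not corrected.
* Bootstrap intervals for the latent-factor models are computationally heavy
  (a full refit per replicate); the default suite leaves them off and the
  headline run enables `nBoot = 1000` explicitly.
* With two waves, change is essentially a difference score for
  single-indicator constructs; lead-lag questions are out of reach by design.
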