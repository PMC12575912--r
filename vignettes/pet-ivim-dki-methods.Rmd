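---
title: "Models and design of the PET-IVIM-DKI biomarker pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the PET-IVIM-DKI biomarker pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petivimdki)
```

## What the package models

Lymphovascular invasion (LVI) — tumor cells inside lymphatic or blood-vessel
endothelial spaces — is an early step toward metastasis in non-small cell
lung cancer, and predicting it before surgery changes management. Integrated
PET/MRI probes it from two directions at once: FDG-PET measures glucose
metabolism (SUVmax, metabolic tumor volume MTV, total lesion glycolysis
TLG), while multi-b-value diffusion MRI measures water mobility through
three nested models:

* **mono-exponential ADC**: $S_b = S_0 e^{-b\,\mathrm{ADC}}$;
* **bi-exponential IVIM**:
  $S_b/S_0 = (1-f)e^{-bD} + f e^{-b(D^*+D)}$, separating true tissue
  diffusion $D$ from capillary pseudo-diffusion $D^*$ weighted by the
  perfusion fraction $f$;
* **diffusion kurtosis (DKI)**:
  $S_b = S_0 \exp(-b D_{app} + b^2 D_{app}^2 K_{app}/6)$, whose apparent
  kurtosis $K_{app}$ quantifies departure from Gaussian diffusion.

The package implements this whole quantitative chain — forward models,
inversion, PET volume-of-interest metrics, and the biomarker statistics
layer (ICC, normality-routed group comparison, ROC with DeLong inference,
logistic combination) — and, because no patient data are distributable,
exercises it entirely on synthetic data calibrated to the group-level
summaries published for a 73-patient cohort (26 LVI-positive, 47
LVI-negative).

## Acquisition schemes

Three fixed b-value schemes mirror the lung protocol: a 10-step IVIM scheme
(0–1000 s/mm² with dense low-b sampling, `bvalue_scheme("ivim")`), a 4-point
DKI scheme (0, 500, 1000, 2000 s/mm²), and the 2-point DWI pair (0, 800
s/mm²) used for the standard ADC. The published protocol table renders the
DWI cell as "0.800"; we read that as the pair {0, 800} s/mm² — a 2-point DWI
at b = 800 is the conventional lung ADC acquisition, and a single b of 0.8
s/mm² would be meaningless — but flag the reading here rather than hiding it.

## Model inversion

**ADC** is the negated OLS slope of $\log S$ on $b$; with two points this is
the textbook log-ratio. When the truth is bi-exponential with $f > 0$, the
perfusion term contaminates ADC upward (ADC $>$ D); with the LVI-positive
median parameters the 2-point ADC is $\approx 1.39 \times 10^{-3}$ mm²/s
against a generating $D = 0.72\times10^{-3}$ — the package treats this as a
feature of the ADC definition, not a fitting error.

**IVIM** is inverted by the conventional segmented two-stage fit (the
vendor's workstation algorithm is unpublished; the segmented split is the
standard answer to the ill-posedness of the joint problem): $D$ from the
log-linear high-b segment ($b \ge 200$ s/mm², the conventional threshold,
leaving 5 of the 10 scheme points), $f$ from the b = 0 intercept gap, and
$D^*$ by a bounded one-dimensional least-squares fit with the scale $s_0$
profiled out analytically. `fit_ivim_full()` optionally refines all
parameters jointly by bounded Levenberg–Marquardt; by contract it never
worsens the residual, and on noise-free curves it restores the generating
parameters to near machine precision. Bounds are
$D \in [10^{-5}, 5\times10^{-3}]$, $D^* \in [D, 0.5]$ mm²/s, $f \in [0,1]$;
clipping is flagged rather than silent, and ties are resolved toward the
segmented estimate. $s_0$ is estimated as a fitted scale rather than pinned
to the measured b = 0 point so that noise at b = 0 is absorbed like noise
anywhere else.

**DKI** is linear in $(D_{app},\, D_{app}^2 K_{app}/6)$ after taking logs,
so the fit is a quadratic regression solved by QR; with exactly three
distinct b-values and clean data it reproduces the closed-form solve.
Negative fitted curvature (which would mean $K_{app} < 0$) falls back to the
mono-exponential boundary $K_{app} = 0$ with a flag. The quadratic exponent
stops decreasing at $b = 3/(D_{app} K_{app})$; for the LVI-positive values
($D_{app} = 2.29\times10^{-3}$, $K_{app} = 0.84$) that bound is
$\approx 1560$ s/mm², *below* the protocol's b = 2000 point. Generation
beyond the bound therefore warns by default (`validity = "warn"`) instead of
refusing: the published protocol itself operates there, fitting is
unaffected (the fitted quadratic is the same polynomial), and an error would
make the printed acquisition unusable. `validity = "error"` restores strict
behavior.

**Noise.** Magnitude MR data are Rician; `add_rician_noise()` implements
$\sqrt{(s+n_1)^2+n_2^2}$ with $\sigma = s_0/\mathrm{SNR}$. The default
working SNR of 50 at b = 0 reflects a good lung DWI ROI average; at that
level the Rician bias at the lowest simulated intensities (~0.2 of $s_0$) is
below one percent, which is why median recoveries stay within a few percent
of truth while $D^*$ — whose information lives in the handful of low-b
points — shows an order-of-magnitude larger dispersion, reproducing its
well-known instability.

## The synthetic cohort

The generator emulates the *published summary table*, not patients: for each
of the nine biomarkers and each group it draws independently from a
positive-support distribution calibrated to the printed summary, then
simulates two readers per subject.

**Distribution family.** Skewed biomarkers use a log-normal anchored at the
printed median ($\mu = \log m$). A two-parameter log-normal cannot also
match an asymmetric (lower, upper) pair exactly, so the pair only sets the
spread and the implied pair is reported with its discrepancy
(`calibrate_quantiles()` prints it) rather than hidden. MK, published as
mean ± sd, uses a zero-truncated normal.

**Reading the parenthetical pairs.** The source table prints values such as
D = 0.72 (0.01, 1.28)×10⁻³ mm²/s and SUVmax = 6.07 (0.48, 13.81). Read as
quartiles these are physically implausible — a 25th-percentile D of
0.01×10⁻³ mm²/s or SUVmax of 0.48 in FDG-avid tumors — and would imply
log-sds up to 2.65, i.e. cohorts spanning six orders of magnitude of MTV.
We therefore read them as the observed minimum and maximum by default
(`spread = "range"`), mapping the extremes to Blom normal scores
$z_n = \Phi^{-1}\!\big((n-3/8)/(n+1/4)\big)$ for the group size $n$; the
quartile reading remains available (`spread = "iqr"`, and it is the default
of the standalone `calibrate_quantiles()`, whose (median, Q1, Q3) signature
matches the usual table convention). Under the range reading the generated
cohorts are clinically plausible and the large-sample medians round-trip the
printed medians to well within sampling error.

**Readers.** Each subject is read twice with multiplicative log-normal
reader noise (additive for MK) sized as
$\sigma_r = \sigma_b\sqrt{(1-\rho)/\rho}$ for a target ICC of
$\rho = 0.9$ — the center of the published agreement range (0.862–1). The
calibration is exact on the log scale; on the raw, skewed scale the measured
ICC(2,1) lands slightly lower but stays in the "excellent" band.

**What the generator does not emulate.** Biomarkers are drawn independently
within subject (the source reports no correlation structure; a Gaussian
copula hook exists, defaulting to identity), so the multivariate logistic
and combined-ROC layers see a *null* correlation structure: their outputs
exercise the machinery but will not reproduce the published model
coefficients or combined AUCs, which depend on unpublished between-biomarker
correlations. Likewise the cohort-level draws (layer b) are not forced to be
consistent with the voxel-signal layer (layer a) — e.g. the drawn ADCstand
is not the ADC of the drawn D, D*, f — because the printed ADC includes
perfusion contamination that no single draw can reproduce. Percent-scale f
is truncated to (0, 100), shifting its median by under 2%. Passing tests
therefore demonstrate correctness of the computational chain and of the
marginal calibration, not clinical reproducibility.

## PET lesion metrics

`generate_lesion_volume()` builds a spherical lesion (uniform or radially
tapered uptake, optional Gaussian noise) on a voxel grid; it is a
deliberately simple synthetic stand-in for a reconstructed PET volume.
`extract_voi()` applies the most common automatic VOI rule in the FDG-PET
literature — the 40%-of-SUVmax isocontour, 26-connected to the hottest
voxel (26-connectivity avoids splitting thin isocontour shells at coarse
grids); the fraction is a parameter and is echoed into every output.
`compute_pet_metrics()` returns SUVmax, MTV (voxel count × voxel volume) and
TLG = SUVmean × MTV, an identity that holds exactly by construction. The
voxelized sphere volume converges to $\tfrac43\pi r^3$ as spacing shrinks
(within 5% at 2 mm spacing for a 10 mm radius).

## The statistics layer

The pipeline mirrors the clinical analysis chain:

* **ICC**: two-way random-effects, absolute-agreement, single-measure
  ICC(2,1), computed from the ANOVA mean squares (the source does not state
  the ICC form; ICC(2,1) is the standard choice for two interchangeable
  readers). Bands: ≥ 0.75 excellent, 0.60–0.75 good, 0.40–0.60 fair,
  < 0.40 poor.
* **Group comparison**: Shapiro–Wilk screen at 0.05 in each group; both
  normal → pooled-variance t-test with mean ± sd summaries, otherwise
  Mann–Whitney U with median (Q1, Q3). Constant data route to Mann–Whitney
  with a note.
* **ROC**: all-pairs concordance AUC (ties ½), DeLong variance for the 95%
  CI (truncated to [0, 1]) and for comparing correlated AUCs. The operating
  point maximizes Youden's J; J-ties break toward higher specificity,
  consistent with the high-specificity operating points typical of this
  literature. Auto-orientation keeps AUC ≥ 0.5 and records the flip
  (diffusion biomarkers predict LVI negatively, so they orient "lower").
* **Logistic combination**: univariate screen at p < 0.1, joint fit of the
  survivors, independent predictors at p < 0.05 (matching the significance
  convention of the source tables); combined scores are predicted
  probabilities, so combination cutoffs live in (0, 1). Separation and
  collinearity are flagged, never silently reported. No multiple-testing
  correction is applied across the nine biomarkers — a deliberate
  faithful-reproduction choice, as the source applies none. Evaluation is
  in-sample (no cross-validation), again mirroring the source procedure.

## Problem sizes and numerical choices

The recovery studies use 500 noisy curves per protocol and the calibration
round-trip uses 200 cohorts (≈ 5 000–10 000 draws per group-biomarker cell);
both were chosen so that Monte-Carlo error is a fraction of the tolerances
of interest (e.g. the pooled-median SE for LVI-positive MTV is ≈ 1.6%
against a 5% round-trip tolerance) while a full run stays in the seconds
range. One-dimensional optimization uses `optimize()` at tolerance 1e-10;
the joint IVIM refinement uses `nls.lm` with ftol = ptol = 1e-15, which is
what makes the clean-data inversion tests at 1e-6 relative error pass with
three orders of magnitude of margin. All stochastic entry points accept a
seed and restore the global RNG state (`withr::with_seed`), so every table
in the workflow is bit-reproducible.

## Known limitations

* No k-space/EPI artifacts, respiratory motion, registration error, or
  attenuation-correction modeling; signals are single-direction
  (trace-weighted isotropic), so MD/MK equal the single-direction
  Dapp/Kapp by construction, with direction-averaging left as a hook.
* The cohort generator reproduces marginal summaries only; joint behavior
  (combined models, DeLong comparisons between modalities) is exercised,
  not validated against the clinical values.
* The VOI rule is a single-threshold isocontour; no partial-volume
  correction or adaptive thresholding.
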