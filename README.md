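# petivimdki

Simulation and statistical analysis of integrated PET-IVIM-DKI imaging
biomarkers for predicting lymphovascular invasion (LVI) in non-small cell
lung cancer.

LVI — tumor cells inside lymphatic or blood-vessel endothelial spaces — is
an early driver of metastasis, and predicting it before surgery informs the
choice of resection and adjuvant therapy. Imaging-biomarker studies attack
it with FDG-PET metabolic metrics (SUVmax, MTV, TLG) and multi-b-value
diffusion MRI. Because patient-level data from such studies are not
released, this package provides the complete quantitative chain as tested,
reusable code over *synthetic* data calibrated to published group-level
summaries — for methodologists who want to study the estimators themselves
(bias, stability, calibration, operating characteristics) rather than
re-analyze patients.

The chain consists of:

* **Forward diffusion models and their inversion**
  - mono-exponential ADC: `S_b = S_0 exp(−b·ADC)`
  - bi-exponential IVIM: `S_b/S_0 = (1−f)·exp(−bD) + f·exp(−b(D*+D))`,
    inverted by the conventional segmented two-stage fit (`D` from the
    high-b segment, `f` from the intercept gap, `D*` by bounded 1-D least
    squares) with an optional full Levenberg–Marquardt refinement
  - diffusion kurtosis: `S_b = S_0 exp(−b·Dapp + b²·Dapp²·Kapp/6)`,
    inverted by quadratic log-regression with the `Kapp ≥ 0` boundary
  - Rician noise simulation for magnitude MR data
* **PET lesion metrics**: synthetic lesion volumes, 40%-of-SUVmax
  isocontour VOI extraction (26-connected to the hottest voxel), SUVmax /
  MTV / TLG
* **A quantile-calibrated cohort generator**: 26 LVI+ / 47 LVI− subjects,
  nine biomarkers matched to published medians and ranges, two readers per
  subject with ICC-calibrated reader noise
* **The statistics layer**: ICC(2,1) with qualitative bands,
  Shapiro–Wilk-routed t / Mann–Whitney comparisons, all-pairs AUC with
  DeLong confidence intervals and tests, Youden cutoffs (ties toward
  specificity), and univariate → multivariate logistic biomarker
  combination.

## Worked example

Simulate one noisy IVIM acquisition at the published LVI-positive median
parameters and invert it:

```r
library(petivimdki)
b <- bvalue_scheme("ivim")            # 0, 25, ..., 1000 s/mm2
clean <- ivim_signal(b, d = 0.72e-3, dstar = 75.06e-3, f = 0.4156)
noisy <- add_rician_noise(clean, s0 = 1, snr = 50, seed = 1)
fit_ivim_segmented(b, noisy)
#> IVIM fit (segmented): D = 0.000701, D* = 0.07643, f = 0.4101, s0 = 0.9938
```

The fitted `D` (0.701e-3 mm²/s vs. the generating 0.72e-3) and `f` (41.0%
vs. 41.56%) come back close even on a single noisy curve, while `D*` is the
least stable parameter — over 500 such curves its fitted spread is orders
of magnitude wider than that of `D`, reproducing its known
unreliability in lung diffusion imaging.

Generate a full two-reader cohort and run the study statistics:

```r
cohort <- generate_cohort(seed = 1)
report <- run_pipeline(cohort)
report
#> Two-group imaging-biomarker study report
#>   subjects: 26 LVI+ / 47 LVI-
#>   selected into multivariate model: mk, md, suvmax, mtv, tlg, adc
#>   independent predictors (p < 0.05): mk, suvmax, mtv
#>   best combination: DKI+IVIM+PET (AUC 0.926)
report$icc[1:3, ]
#>   biomarker   icc      band
#> 1        mk 0.897 excellent
#> 2        md 0.925 excellent
#> 3    suvmax 0.811 excellent
```

`report` holds tibbles mirroring the tables of a clinical biomarker study:
inter-reader ICC per biomarker, normality-routed group comparisons,
univariate/multivariate logistic odds ratios, and ROC rows (AUC with DeLong
CI, Youden cutoff, sensitivity/specificity/FPR/FNR) per biomarker and per
modality combination. Because the generator draws biomarkers independently
within subject, the multivariate and combined-model rows exercise the
machinery on a null correlation structure — which biomarkers surface as
"independent predictors" varies from cohort to cohort, and combined AUCs
are not expected to match any published cohort.

## The analysis workflow

The `analysis/` directory holds the four numbered drivers of the standard
run, each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # cohort CSV, config YAML, lesion NIfTI, noisy curves
Rscript analysis/02_fit.R        # model inversion + 500-curve recovery study + PET VOI metrics
Rscript analysis/03_analyze.R    # ICC / comparison / logistic / ROC report tables
Rscript analysis/04_report.R     # collated plain-text report
```

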