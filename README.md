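# dscradiomics

Tracer-kinetic quantification of dynamic susceptibility contrast (DSC) MRI
and radiomic classification of IDH mutation status in gliomas, as a tested
R pipeline driven by a synthetic phantom generator.

## The problem

DSC-MRI tracks a gadolinium bolus through brain tissue with rapid
T2\*-weighted imaging. Modeling the resulting signal-time curves turns them
into physiological parametric maps — blood flow, blood volume, transit time,
bolus-shape descriptors, and blood-brain-barrier leakage parameters. Because
those maps are produced by one algorithm regardless of scanner or site, they
are a natural substrate for multi-center radiomics: texture features
extracted from the maps inside the tumor ROI feed a classifier that predicts
whether a glioma carries an IDH mutation (better prognosis) or is wildtype,
without harmonizing raw intensities across sites.

The package implements that pipeline end to end for researchers in perfusion
MRI and radiogenomics: every stage is a plain R function, every stage is
unit-tested against analytic oracles, and a phantom generator with known
kinetic ground truth stands in for patient data so the whole chain is
verifiable on any machine.

## The models

**Gamma-variate transport model.** The tissue concentration follows the
indicator-dilution relation

&nbsp;&nbsp;&nbsp;&nbsp;C\_t(t) = F\_t · (AIF ⊛ R)(t),&nbsp;&nbsp;
R(t) = 1 − ∫₀ᵗ h(τ) dτ,

with a gamma-variate transit-time density
h(t) = (1/A₁)(t − t₁)^{a₁} e^{−(t−t₁)/σ₁}, A₁ = σ₁^{1+a₁} Γ(1+a₁).
Voxelwise Levenberg–Marquardt fits of [F\_t, t₁, σ₁, a₁] give
rCBF = F\_t, rMTT = t₁ + σ₁(1 + a₁), and rCBV = rCBF · rMTT (central volume
principle). TMAX and the mean slope of increase
MSI = (1/N) Σ [C(tᵢ₊₁) − C(tᵢ)] (baseline end → curve maximum) are computed
on the measured curve. Signal converts to concentration via
C(t) = −(1/TE) ln(S(t)/S(0)).

**Leakage-corrected blood volume.** With a leaky blood-brain barrier, the
voxel curve is modeled through the whole-brain average concentration
C̄(t) of non-enhancing voxels:

- unidirectional: C\_t(t) = K₁ C̄(t) − K₂ ∫₀ᵗ C̄ (linear least squares);
- bidirectional: C\_t(t) = K₁ C̄(t) − K₂ (C̄ ⊛ e^{−K\_ep t}) (profiled
  nonlinear least squares, exact inner linear solve).

The fitted leakage term is added back before integrating
nrCBV = ∫ C\_t(t) dt between bolus arrival and replenish.

**Radiomics and classification.** Each parametric map yields first-order,
GLCM/GLRLM/GLSZM/GLDM texture and shape features, plus filtered variants
(wavelet bands, Laplacian-of-Gaussian, gradient, log/exp, LBP-2D). Features
run through a three-step selection (variance threshold → one-way ANOVA →
L1-penalized logistic regression at C = 0.3), SMOTE balances the minority
class inside each training fold, and an SVM with RBF kernel is evaluated in
stratified 5-fold cross-validation (sensitivity, specificity, F1, accuracy,
AUROC, per map). Shapley values explain the best-accuracy map's model.

## Worked example

```r
library(dscradiomics)

tg  <- seq(0, by = 1.87, length.out = 60)          # 60 frames at 1.87 s
aif <- make_aif(gamma_bolus_params(amplitude = 12, t1 = 14.96,
                                   sigma1 = 2, a1 = 3), tg)
ct  <- simulate_tissue_curve(list(Ft = 0.8, t1 = 3, sigma1 = 1.5, a1 = 2.5),
                             aif, tg)
set.seed(1)
noisy <- ct + rnorm(60, sd = 0.05)

fit <- fit_gamma_model(noisy, aif, tg)
sprintf("rCBF = %.3f, rMTT = %.3f s, rCBV = %.3f",
        fit$Ft, fit$t1 + fit$sigma1 * (1 + fit$a1),
        fit$Ft * (fit$t1 + fit$sigma1 * (1 + fit$a1)))
#> "rCBF = 0.806, rMTT = 8.203 s, rCBV = 6.613"
```

The fit recovers the simulated truth (F\_t = 0.8, rMTT = 3 + 1.5·3.5 =
8.25 s, rCBV = 6.6) to within the noise. On the measured curve,

```r
tm <- curve_tmax(noisy, tg)
mean_slope_increase(noisy, t0_index = 8, tm$index)$msi
#> 0.985      # s^-2: average concentration increment per frame up to TMAX
```

## The analysis workflow

Numbered drivers under `analysis/` chain the study end to end, writing
tables and NIfTI maps under `results/`:

1. `01_simulate.R` — build a demonstration phantom (4D series, masks, AIF,
   ground truth) and check the noise calibration.
2. `02_fit_maps.R` — signal → concentration, voxelwise gamma fits, leakage
   fits; writes all 13 parametric maps and compares medians to the truth.
3. `03_extract_features.R` — generate the 41/119 phantom cohort with
   class-shifted F\_t and K₂, extract the radiomic feature table.
4. `04_select_classify.R` — per-map selection + SMOTE + SVM-RBF in
   stratified 5-fold CV; writes the mean ± SD metrics table.
5. `05_explain.R` — Shapley attribution for the best-accuracy map's model.

Each script prints what it found; run them in order from the repository
root with the package installed.

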