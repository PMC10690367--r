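---
title: "Models, numerical choices and synthetic validation in dscradiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerical choices and synthetic validation in dscradiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscradiomics)
```

# Scope

`dscradiomics` quantifies dynamic susceptibility contrast (DSC) MRI into
parametric perfusion maps, corrects blood-volume estimates for blood–brain
barrier leakage, extracts radiomic features from the maps inside a tumor
ROI, and classifies a binary molecular label (IDH mutation status) with a
cross-validated SVM, including SMOTE class balancing and Shapley
explanation. Because no patient cohort is bundled, a phantom generator with
known kinetic ground truth drives all validation. This vignette records the
models, the tunable parameters, the numerical decisions, and what the
synthetic validation does and does not establish.

# Tracer-kinetic models

## Gamma-variate transport model

The tissue concentration is $C_t(t) = F_t\,(AIF \circledast R)(t)$ with
residue function $R(t) = 1 - \int_0^t h(\tau)\,d\tau$ and a gamma-variate
transit-time density

$$h(t) = \frac{1}{A_1}(t-t_1)^{a_1} e^{-(t-t_1)/\sigma_1},\qquad
A_1 = \sigma_1^{1+a_1}\Gamma(1+a_1),$$

which is the Gamma(shape $1+a_1$, scale $\sigma_1$) density delayed by
$t_1$. `transport_function()` and `residue_function()` therefore evaluate
through `dgamma`/`pgamma` rather than raw powers and exponentials: the
closed forms are exact, numerically stable for large $a_1$, and make
$\int h = 1$ and the mean transit time $t_1 + \sigma_1(1+a_1)$ hold by
construction. Derived maps: rCBF $= F_t$, rMTT $= t_1 + \sigma_1(1+a_1)$,
rCBV $=$ rCBF $\times$ rMTT (central volume principle, an identity of the
implementation, not an approximation).

Signal and concentration are linked by
$C(t) = -\tfrac{1}{TE}\ln(S(t)/S(0))$ with $S(0)$ the mean over the
pre-bolus baseline frames. TMAX and the mean slope of increase (MSI) are
computed on the *measured* concentration curve, not the fitted one, since
they describe the curve itself. MSI divides the telescoping sum of
successive increments between the baseline end $t_0$ and TMAX by $N$, the
**number of increments** (intervals, not samples); the sum then equals
$(C(\mathrm{TMAX}) - C(t_0))/N$ exactly, which the tests assert to
$10^{-12}$. When the curve maximum does not lie after $t_0$, MSI is
undefined and the voxel is flagged invalid.

## Units and key parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `dt` | temporal resolution | s | 1.87 |
| `te` | echo time | s | 0.040 |
| `n_baseline` | pre-bolus frames | frames | 8 |
| $F_t$ | relative flow scale | arbitrary | fit |
| $t_1$ | tissue arrival delay (relative to the AIF) | s | fit |
| $\sigma_1, a_1$ | dispersion scale / shape | s, — | fit |
| $K_1$ | susceptibility scaling | s⁻¹ (as conventionally printed) | fit |
| $K_2$ | intra→extravascular permeability term | s⁻¹ | fit |
| $K_{ep}$ | extra→intravascular return constant | s⁻¹ | fit |

The default acquisition (60 frames at 1.87 s, TE 40 ms) mirrors a common
3 T echo-planar DSC protocol. $K_1$ acts as a dimensionless scaling in the
unidirectional model; it is reported in the s⁻¹ convention without
attempting to reconcile the units.

## Fitting

`fit_gamma_model()` uses Levenberg–Marquardt (`minpack.lm::nls.lm`) on
$[F_t, t_1, \sigma_1, a_1]$ with bounds $\ge 0$, $a_1 \le 20$,
$\sigma_1 \le 20$ s. Initialization is data-driven: $t_1$ one frame past
the lag between the concentration and AIF arrivals (both detected at 5% of
peak), $a_1 = 3$, $\sigma_1 = 1.5$ s, $F_t$ from the peak-height ratio.
The $(t_1, \sigma_1, a_1)$ directions are strongly correlated and the
$a_1 = 0$ boundary is an attracting basin for dispersed curves, so the
solver runs a fixed ladder of three additional shape restarts and keeps the
best residual, exiting early once the residual is numerically zero. This
keeps the fit deterministic (no random restarts) while recovering all four
parameters to machine precision on noiseless forward curves. Iteration-cap
exits with a usable iterate are kept; genuine failures return NaN
parameters with `converged = FALSE`, and such voxels are excluded from
feature masks downstream. Nonpositive signal samples are clamped to
$10^{-3} S(0)$ before the log (with a count reported) rather than dropping
the voxel; a nonpositive baseline invalidates it.

Only the product $F_t \cdot AIF$ is identified by the data: doubling the
AIF amplitude halves the fitted $F_t$ and leaves rMTT unchanged, which the
tests check explicitly. All maps are therefore *relative*, as the r-prefix
indicates.

## Leakage models and quadrature

The unidirectional model
$C_t = K_1 \bar{C} - K_2 \int_0^t \bar{C}$ is linear in $(K_1, K_2)$ and is
solved by QR least squares, unconstrained over the reals — both
T2\*-dominant ($K_2 > 0$) and T1-dominant ($K_2 < 0$) regimes are
representable, and no sign is enforced. The bidirectional model replaces
the running integral with $\bar{C} \circledast e^{-K_{ep} t}$. For fixed
$K_{ep}$ it is again linear, so the fit profiles: an exact inner linear
solve nested in a deterministic 1-D golden-section search over
$K_{ep} \in [0, 2]$ s⁻¹, with the $K_{ep} = 0$ endpoint checked explicitly.
When the fitted $K_2$ is numerically zero the exchange term vanishes and
$K_{ep}$ is reported but flagged unidentifiable.

Two quadrature conventions coexist deliberately:

* the gamma-model tissue convolution uses a plain rectangle rule
  ($dt \cdot \Sigma$), which keeps the unit-impulse identity exact — an
  impulse AIF of area 1 convolves to $F_t R(t)$ bit for bit;
* every leakage-module convolution and cumulative integral uses
  trapezoid-consistent weights, so that the exponential kernel at
  $K_{ep} = 0$ degenerates *exactly* to the trapezoidal running integral of
  the unidirectional model. The nesting of the two models then holds to
  $10^{-10}$ rather than to first order in $dt$.

The correction step adds the fitted leakage term back to the measured
curve ($C_{t,corr} = C_t + K_2 \cdot \text{term}$), mirroring the
unidirectional add-back in both models; the package uses the kernel
$e^{-K_{ep}(t-\tau)}$ inside the convolution. nrCBV integrates the
(corrected) curve between the arrival index (last baseline frame) and a
replenish index. The replenish point has no universal definition; the
package takes the first local minimum of the whole-brain reference curve
after its global peak, falling back to the last frame when the first
passage never ends within the acquisition (the case for a pure
gamma-variate bolus without recirculation), and the index is overridable.
The reference curve averages brain voxels outside the tumor ROI dilated by
2 voxels, excluding the partial-volume rim.

# Radiomics

Maps are discretized inside the ROI to 32 equal-width bins by default.
A fixed bin *count* is used rather than a fixed bin width: the parametric
maps carry heterogeneous physical units (s⁻¹, seconds, dimensionless
ratios), so any absolute bin width would be arbitrary per map, whereas a
fixed count adapts to each map's range.

Texture matrices follow their standard count definitions: GLCM over the 13
unique 3D offsets at distance 1, symmetrized and feature-averaged over
offsets; GLRLM runs along the same 13 directions; GLSZM zones by
26-connectivity; GLDM dependence counts over the 26-neighborhood with
similarity threshold $\alpha = 0$. Filters: a one-level separable two-tap
wavelet decomposition (averaging/differencing pairs, undecimated, replicate
edges — chosen over longer wavelets because its fixtures are exactly
verifiable: the LLL band of a constant image is the image, all other bands
are zero), Laplacian-of-Gaussian with sampled Gaussian kernels, gradient
magnitude, logarithmic/exponential intensity transforms, and slice-wise
8-neighbor LBP. Voxels just outside the ROI are padded with the in-mask
mean before neighborhood filters so undefined map values never bleed into
the ROI.

Feature names encode provenance as `map__filter__class__feature` and are
stable across runs; degenerate ROIs (too few voxels for co-occurrence)
yield NA-flagged features rather than errors. The catalogue is a defined,
configurable subset of a full radiomics library's output; exact parity
with any particular extractor's feature count is not attempted.

# Selection, balancing, classification

The selection chain is variance threshold → one-way ANOVA
($p < 0.05$; the method's threshold is a package choice, and for two groups
$F = t^2$ is asserted as a property) → L1-penalized logistic regression at
inverse regularization $C = 0.3$ (solved by `glmnet` coordinate descent
with $\lambda = 1/(nC)$, the mapping between the sum-loss and mean-loss
objective conventions), keeping coefficients with $|w| > 10^{-5}$.
Survivors are nested across steps by construction. Features are z-scored
with training-fold statistics before the L1 step and the SVM, since
penalized weights and RBF distances are scale-sensitive. The variance
threshold defaults to 0.5 — meaningful for large-magnitude raw radiomics
features — but the phantom-cohort benchmark sets it to $10^{-8}$
(drop-constants): concentration-scale parametric maps produce features
orders of magnitude smaller than raw image intensities, and an absolute 0.5
would discard nearly everything regardless of information content. If a
later step eliminates every feature in a fold, the pipeline falls back one
step rather than failing the fold.

SMOTE synthesizes minority samples as $x + \lambda(x_{nn} - x)$,
$\lambda \sim U(0,1)$, with $k = 5$ nearest minority neighbors (the
canonical choice), applied **inside training folds only**; at the 41/119
imbalance, full balancing emits exactly 78 synthetic samples, each verified
to lie on the segment between its two parents. The SVM uses an RBF kernel
with cost 1 and bandwidth $1/(p \cdot \mathrm{var}(X))$ (the "scale"
heuristic); no inner grid search, mirroring a flat scheme. One classifier
is trained per parametric map; metrics (sensitivity, specificity, F1,
accuracy, rank-based AUROC with ties at ½) are reported per fold and as
mean ± SD across the 5 stratified folds. All seeds derive from a single
global seed through fixed stream offsets.

Shapley attributions use the interventional convention: a feature outside
the coalition takes its value from a background sample. Exact mode
enumerates all $2^p$ coalitions (refused above $p = 12$); sampled mode
averages marginal contributions over feature permutations, cycling
background rows evenly. Efficiency — attributions summing to the prediction
minus the mean background prediction — is exact in enumeration mode and is
asserted to $10^{-6}$. The explanation targets the best-accuracy map's
model refit on the full selected feature set, ranked by mean |value| (the
summary-plot ordering).

# The phantom generator

`build_phantom()` lays tissue classes out as concentric blocks (trivially
verifiable masks): a brain block with leak-free kinetics and a central
tumor block whose curve is contaminated by the bidirectional forward model.
The signal is $S_0 e^{-TE \cdot C}$ with a baseline plateau and additive
Gaussian noise **on the signal**, where scanner noise enters (a Rician
option is deliberately out of scope). `make_cohort()` draws per-phantom
tumor $F_t$ and $K_2$ from class-conditional normal distributions; the
default effect places the wildtype-like majority at higher flow
($F_t$: 0.90 ± 0.12 vs 0.55 ± 0.10) and higher permeability
($K_2$: 0.022 ± 0.006 vs 0.006 ± 0.003 s⁻¹) — the direction expected for
more aggressive, angiogenic tumors, with overlapping but clearly separated
distributions. The default composition is 41 minority / 119 majority.

What the phantoms emulate: class-dependent kinetics, leakage
contamination, acquisition noise, class imbalance, and the full data flow
from 4D signal to labels. What they do not: anatomical geometry, partial
volume, motion and susceptibility artifacts, coil profiles, recirculation,
inter-site protocol differences, or realistic spatial texture (in-mask
texture arises from noise, not biology). Passing the end-to-end benchmark
therefore demonstrates that the pipeline is correct, leakage-safe and able
to recover a known class signal at realistic noise — not that any
particular accuracy would be attained on patients.

# Problem sizes and runtime choices

Validation runs use sizes chosen to make every check exhaustive yet quick:
phantom grids of 16×16×6 voxels with a 50-voxel tumor, 60 frames; 100-curve
parameter-recovery grids; 1000-curve identity checks; two full 160-phantom
cohorts (effect and null) for the end-to-end benchmark, classified on the
cheap-route maps (MSI, nrCBV, K2-unidirectional, K1-bidirectional) whose
computation needs no voxelwise nonlinear fitting — the gamma-fit maps are
validated separately by the recovery study, and `analysis/02_fit_maps.R`
demonstrates them on the demonstration phantom. MSI serves as the
designated primary endpoint of the benchmark; under the null (no class
effect) its cross-validated AUROC is required to stay near chance, which
doubles as a leakage check on the fold plumbing.

# Known limitations

* The gamma-variate transport family is an assumption; curves that deviate
  from it (e.g. non-enhancing lesions with absent bolus response) produce
  poor fits that are only flagged, not repaired. Model-independent (SVD)
  deconvolution is out of scope.
* Manual AIF input is assumed; there is no automated AIF detection.
* No T1-dominant dual-echo leakage modeling or preload correction.
* Shape features use face-counting surface area, which overestimates
  smooth-surface area relative to meshed estimators; values are internally
  consistent, not comparable across packages.
* The feature catalogue is a defined subset; no claim of numerical parity
  with any external radiomics library.
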