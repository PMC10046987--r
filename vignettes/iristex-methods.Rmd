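---
title: "Methods: iris texture analysis for coronary-artery-disease screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iris texture analysis for CAD screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Iridology charts map angular sectors of the iris to body regions; on the
left-iris chart the heart sector spans the 2 to 4 o'clock positions. `iristex`
implements a complete screening pipeline built on that premise: given a
photograph of a left eye, it isolates the heart sector of the iris, describes
its texture with a fixed 136-value descriptor, and asks shallow classifiers to
separate CAD-labelled from healthy eyes under cross-validation. The premise
itself is scientifically contested; the package treats it as the definition of
a region of interest, not as a validated clinical claim, and every stage is
testable against synthetic data with known ground truth.

The pipeline is: segmentation → polar normalization → ROI crop → contrast
enhancement → wavelet/texture features → ReliefF ranking → cross-validated
classification.

## Segmentation: the integro-differential operator

Both iris boundaries are modelled as circles. A candidate circle centred at
$(x_0, y_0)$ with radius $r$ is scored by the blurred radial derivative of the
mean intensity around its circumference,

$$\max_{r, x_0, y_0}\; \left| G_\sigma(r) * \frac{\partial}{\partial r}
\oint_{r,x_0,y_0} \frac{I(x,y)}{2\pi r}\, ds \right|,$$

which peaks where the contour jumps from dark pupil to iris (inner boundary)
or from iris to bright sclera (outer boundary, the limbus). The contour
integral is a mean of bilinearly interpolated samples at `n_angular_samples`
angles (default 128); the radial derivative uses central differences and is
blurred with a discrete Gaussian of `sigma` radius steps (default 1). Because
the score is a derivative, it is invariant to adding a constant to the image.

Searching every (centre, radius) cell at full resolution is wasteful, so
`locate_pupil()` runs coarse-to-fine: a pass over a block-averaged image
(factor 4, floored so the coarse image keeps at least 64 px on its short
side) proposes candidates, which are re-scored at full resolution before the
winner's neighbourhood is searched densely. Two details matter in practice and
are worth recording:

* **Minimum-radius texture pits.** At coarse scale, the objective is maximized
  by tiny circles sitting in dark pits of the iris texture — they are
  legitimate maxima of the coarse objective but not of the full-resolution
  one. The coarse pass therefore keeps up to 24 spatially distinct candidates
  (non-max suppression) and ranks them by a small full-resolution search
  before refining the two leaders.
* **Dark-centre prior.** The pupil is the darkest structure in an eye image,
  so coarse pupil candidates are restricted to pixels at or below the 8%
  intensity quantile (`dark_quantile`, configurable; set 1 to disable). The
  exhaustive search method never applies it.

Defaults for the radius ranges are anatomical: pupil radii in
$[\min(H,W)/40,\ \min(H,W)/8]$ and iris radii in $[1.5, 5]\times$ the found
pupil radius, with the iris centre constrained within 15 px of the pupil
centre. An `arc_mask` can exclude clock-angle intervals (e.g. ±45° around 12
and 6 o'clock) from the contour integral when eyelids occlude the limbus; the
synthetic eyes have no lids, so it is off by default. The refinement lattice
is phase-aligned with the exhaustive grid so that, with equal strides, the two
methods return identical circles.

## Normalization, ROI and enhancement

The annulus between the two circles is unwrapped with the rubber-sheet map:
output row $i$ corresponds to the radial fraction $\rho = i/(R-1)$ and column
$j$ to the clock angle $\theta$, and the sampled Cartesian point is the linear
interpolation $(1-\rho)\,p(\theta) + \rho\, l(\theta)$ between the pupil and
limbus boundary points along $\theta$ — valid for non-concentric circles. The
output is fixed at 360 rows × 720 columns. We read "360 × 720" as radial ×
angular: at 720 angular samples each column is 0.5°, which makes the
60-degree heart sector exactly 120 columns — the width of the 190 × 120 ROI.
Column 0 sits at 12 o'clock and angles grow clockwise as
displayed, the convention of clock-based iris charts.

The heart ROI is a pure sub-matrix: columns 120–239 (2 to 4 o'clock) and rows
60–249. The radial anchor is not dictated by the ROI size alone; rows 60–249
skip the innermost 60 rows (pupil-border ring, often contaminated by the
pupil edge) and the outermost 110 rows (limbus), and the anchor is exposed in
`roi_spec()`. Cropping precedes enhancement.

Contrast-limited adaptive histogram equalization (CLAHE) then spreads local
contrast: 8 × 8 tiles, clip limit 2.0 on 8-bit histograms (EBImage's
implementation with bilinear inter-tile blending; the ROI is edge-padded to a
tile multiple and cropped back). Constant inputs pass through unchanged.

## The 136-feature texture descriptor

A one-level separable 2-D wavelet transform splits the ROI into four
sub-bands `cA` (approximation), `cH`, `cV`, `cD` (horizontal, vertical,
diagonal detail). The filter bank is periodized orthogonal Haar by default
(`db2` available): periodization keeps the transform exactly orthogonal on
even-length signals, so tests can assert perfect reconstruction (max error
< 1e-9) and energy conservation (relative error < 1e-6) rather than loose
approximations. The ROI's 190 × 120 shape halves evenly to 95 × 60 per band;
odd dimensions would be edge-padded by one sample.

Per band, 34 features in a fixed order:

1. **5 first-order statistics** — mean; standard deviation ($1/(N-1)$ form);
   histogram entropy (base 2, 256-bin min–max histogram); skewness and
   kurtosis as population moment ratios $m_3/m_2^{3/2}$ and $m_4/m_2^2$.
   Constant bands yield 0 for std, entropy, skewness and kurtosis by
   convention.
2. **22 co-occurrence (Haralick-type) features**, direction-averaged over
   θ ∈ {0°, 45°, 90°, 135°} at distance 1 on the band quantized to 8 levels.
   The matrix is accumulated symmetrically (pair + reversed pair), Haralick's
   original convention, which makes the marginals equal. All entropy-like
   features use base-2 logarithms with $0\log 0 := 0$. The information
   measures of correlation use $\mathrm{IMC1} = (HXY - HXY1)/\max(HX, HY)$
   (defined as 0 when the denominator vanishes) and
   $\mathrm{IMC2} = \sqrt{\max(0,\, 1 - e^{-2(HXY2 - HXY)})}$. The maximal
   correlation coefficient is $\sqrt{\lambda_2(Q)}$ with zero-marginal levels
   removed and the eigenvalue clipped to $[0,1]$ (the raw $\lambda_2$ is
   available via `mcc_sqrt = FALSE`). Correlation is defined as 0 when a
   marginal standard deviation vanishes. The normalized inverse-difference
   features follow Clausi: $\sum p/(1+|i-j|/L)$ and $\sum p/(1+(i-j)^2/L^2)$.
3. **7 run-length features** (SRE, LRE, GLN, RP, RLN, LGRE, HGRE),
   direction-averaged over the same four directions on the band quantized to
   16 levels. Run percentage is the number of runs divided by the number of
   pixels; gray-level indices are 1-based in the LGRE/HGRE weights.

Quantization is uniform min–max binning — necessary because detail-band
coefficients are signed and unbounded; a constant band maps to level 0. Bands
are ordered `cA, cH, cV, cD`, giving 4 × 34 = 136 named values whose order
never changes.

## Feature selection and evaluation

`relieff_rank()` implements two-class ReliefF in Kononenko's k-nearest-hit /
k-nearest-miss form with every sample used once ($m = n$), $k = 10$ neighbours
per class, Manhattan distance on min–max-scaled features, and weight updates
normalized by $m\,k$ — so weights lie in $[-1, 1]$. These are the de-facto
defaults of the numeric ReliefF literature; neighbour ties break by ascending
sample index, making the ranking fully deterministic (the `seed` argument is
accepted for interface stability but can never influence the result).
`select_top()` takes prefix-consistent top-k lists; the pipeline evaluates
k = 25, 50 and 75 by default. `pointwise_correlation()` provides the
point-biserial feature–label correlations used for descriptive feature
analysis.

The classifier registry holds 22 presets in five families. Preset
hyperparameters follow what the preset names conventionally imply: trees with
split budgets 100/20/4 (mapped to `rpart` maximum depths 7/5/2, since `rpart`
has no direct split-count control); Gaussian and kernel naive Bayes (the
kernel variant uses per-class, per-feature Gaussian kernel density
estimates); SVMs with linear, quadratic, cubic (polynomial, `coef0 = 1`) and
Gaussian kernels at kernel scales $\sqrt{P}/4$, $\sqrt{P}$, $4\sqrt{P}$ for
$P$ features; kNN with k = 1/10/100 plus cosine, cubic (Minkowski $p=3$) and
squared-inverse-distance-weighted variants at k = 10; and fully connected
ReLU networks with hidden layouts 10 / 25 / 100 / 10-10 / 10-10-10 trained
full-batch with Adam (300 epochs, learning rate 0.01, L2 1e-4), seeded per
fold. The multilayer network and the kNN variants are implemented in-package
because the preset list requires two- and three-hidden-layer networks and
cosine/cubic/weighted voting. Scale-sensitive families (SVM, kNN, NN) z-score
inputs inside each training fold; trees and naive Bayes see raw features.

Evaluation is stratified 5-fold cross-validation (class ratio preserved ±1
sample per fold); stratification is used because at cohort sizes of tens of
samples unstratified folds make per-fold metrics extremely noisy. Reported
metrics are fold means of sensitivity, specificity, precision, accuracy, F1
and the geometric mean $\sqrt{SNS \cdot SPC}$, all with the 0/0 := 0
convention and CAD (label 1) as the positive class, plus AUC computed from
continuous scores (decision values for SVM, posterior-type scores otherwise)
as the tie-aware rank statistic, which equals the trapezoidal area under the
ROC curve.

## The synthetic-eye generator

Clinical iris images are not publicly deposited, so the generator is the
package's study population, not a test convenience. An eye is a bright sclera
(default 220), an iris annulus (base 110) carrying a sinusoidal angular fiber
texture (amplitude 18 gray-levels, 20–28 cycles per revolution) plus
low-amplitude smoothed noise, and a dark pupil disc (default 30) that may be
off-centre from the iris by a few pixels, as in real eyes. Those intensity
and geometry ranges are ordinary for flash-lit eye photographs scaled to
8-bit. CAD-like eyes additionally receive 10 dark elliptical lesions
(Gaussian profiles, semi-axes 2–6 px, truncated at 3σ) whose contrast is the
cohort's `effect` parameter. Lesions are placed in polar coordinates inside
the 2–4 o'clock sector (10% angular margin) at radial fractions 0.22–0.62,
which guarantees they land inside the default ROI window after unwrapping —
the class signal is reachable by the stated crop, and *only* by it.

The cohort defaults — 50 images per class at `effect = 60` gray-levels for
the separability study, 25 per class at `effect = 0` for the null check, and
360 × 360 px images — were fixed once as a realistic desk-scale study and are
the sizes the acceptance checks use. What passing tests show is that the
pipeline recovers a planted, ROI-confined texture difference and reports
chance when none exists; they cannot show that real CAD alters iris texture.
The generator does not model eyelid/eyelash occlusion, specular highlights,
defocus or photometric vignetting, and its lesion model is a stand-in — no
quantitative description of CAD-related iris texture exists to emulate.

## Numerical choices and degenerate inputs

* Bilinear interpolation everywhere (segmentation contours, rubber sheet);
  points outside the image clamp to the nearest edge pixel and are flagged in
  the normalized iris's validity mask.
* Search ties break deterministically: higher response first, then smaller
  radius, then row-major centre order; ReliefF neighbour ties by sample
  index; kNN class ties resolve to the positive class at score 0.5.
* A uniform image has zero operator response everywhere and raises a
  no-circle error (`response_floor`, default 1.5 gray-levels per radius
  step); per-image pipeline failures are logged in the run manifest and the
  image is skipped rather than aborting the cohort.
* All randomness flows from one seed; generators save and restore the
  caller's RNG state.
* The null-cohort accuracy is compared against the 95% binomial band around
  0.5 at the evaluated sample size. Cross-validated accuracy on null data is
  slightly overdispersed relative to a binomial (folds share training data),
  so occasional excursions just outside the band are expected across seeds;
  the packaged check uses the fixed study seed.

## Problem sizes used by the packaged checks

Structural and oracle checks run on 5 × 5 to 8 × 8 fixture matrices in
milliseconds. Segmentation recovery uses 40 eyes at 360 × 360 px (about a
second per eye); the end-to-end study uses 100 effect-cohort and 50
null-cohort images. The full test suite runs in roughly six minutes on one
CPU; the acceptance script in about four.

## Known limitations

* Circle-only boundary model: no ellipse fitting or active contours, no
  eyelid masking inside the normalized image.
* Single-level wavelet decomposition and co-occurrence distance 1, per the
  descriptor definition; no Gabor or multi-scale variants.
* The rpart depth mapping approximates split-count budgets; MATLAB-style
  "maximum number of splits" has no exact `rpart` equivalent.
* Kernel-scale and network-training defaults are reproducible proxies for
  the usual preset semantics, not tuned values; no hyperparameter search is
  performed anywhere.
* Real-cohort performance claims are out of reach without deposited clinical
  images; the synthetic study is the supported evidence.
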