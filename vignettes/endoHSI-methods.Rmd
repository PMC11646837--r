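---
title: "Visible-band hyperspectral conversion for endoscopic images: models and methods"
author: "endoHSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visible-band hyperspectral conversion for endoscopic images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoHSI)
```

## The problem

Conventional endoscopes record three broadband channels (RGB), yet the
reflectance differences that distinguish normal esophageal mucosa from
squamous dysplasia and squamous cell carcinoma (SCC) are spectral: they
concentrate in the 415–540 nm window where hemoglobin absorption shapes the
mucosal signal. endoHSI estimates, for every pixel of an ordinary RGB
endoscopic frame, a full visible-range reflectance spectrum — 401 bands on
the 380–780 nm grid at 1 nm — from a one-off calibration against a 24-patch
color checker measured with a spectrometer. The reconstructed cube supports
band-window analysis and a physically motivated simulation of narrow-band
imaging (NBI), and the package adds the evaluation layer used to score a
frame-level lesion detector: IoU box matching, binary and 3-class tables,
both specificity conventions, Cohen's kappa, and a standalone composite
detection loss.

## The conversion model

The chain from encoded RGB to a spectrum has four stages.

**1. Linearization and tristimulus conversion.** Encoded sRGB values in
[0, 1] are gamma-decoded with the standard IEC piecewise transfer (linear
segment below 0.04045, exponent 2.4 above; the junction mismatch of the
standard constants is ~2×10⁻⁹, far below any quantity of interest). Linear
RGB maps to XYZ on the 0–100 luminance scale through the sRGB (D65)
primaries matrix, optionally preceded by a chromatic-adaptation matrix when
the scene illuminant's white differs from D65. We use the Bradford
von-Kries transform as the default adaptation: the source method does not
name its adaptation matrix, and Bradford is the modern colorimetric
default; any linear residual it leaves is absorbed by the next stage. Both
matrices are overridable.

**2. Polynomial XYZ correction.** Real cameras deviate from the colorimetric
ideal (nonlinear response, imperfect color filters, dark current). A 3×p
correction matrix C maps a monomial expansion of camera XYZ onto
spectrometer XYZ, fitted by pseudoinverse least squares over the 24
patches: `C = XYZ_ref · pinv(V)`, where V stacks the expanded features.
The monomial set is not dictated by the method, so it is a package choice:
the default is the full order-2 expansion of (X, Y, Z) plus constant — 10
terms, comfortably determined by 24 patches — configurable from order 1
(4 terms) to order 3 (20 terms, which with 24 patches is close to
interpolation and should be used only with low-noise calibration data).
Rank-deficient designs fall back to the minimum-norm pseudoinverse solution
with a warning.

**3. Spectral basis.** Principal component analysis of the 24 measured
patch reflectances (mean-centered, via SVD) gives an orthonormal basis.
The number of retained components is the smallest k reaching 99.9 %
explained variance, capped at 12; with 24 training samples a larger k
buys noise, not signal. k can be fixed explicitly.

**4. Score transformation.** A k×q matrix M maps expanded corrected-XYZ
features to PCA scores (same pseudoinverse fit, same expansion order), so a
pixel's spectrum is `mean + components · M · expand(correct(XYZ))`. The
whole pipeline is therefore an explicit polynomial map from camera RGB to
a 401-vector; reconstruction is exactly affine in feature space, which the
test suite exploits (midpoint property).

Reconstructed reflectance is clipped to [0, 1] by default — negative
reflectance is unphysical — and the clipped-band fraction is tracked per
pixel. A pixel whose reconstruction is non-finite or whose clipped
fraction exceeds 50 % of bands is masked as a failed transformation; a
frame with more than 20 % masked pixels is flagged failed. These two
thresholds are operational definitions chosen by this package (the
phenomenon — conversions failing on out-of-gamut content — is real, but no
published criterion exists); both are configurable.

Separate models are fitted per imaging modality (WLI vs NBI), since the
illuminant, and hence the calibration, differs.

Calibration quality is quantified by three estimators computed from the
calibration data themselves: per-patch XYZ RMSE of the correction,
per-patch RMSE between each patch's simulated and measured spectrum, and
the CIEDE2000 (or CIE76) color difference of corrected vs reference
patch colors. Published values of these quantities for specific
endoscope/spectrometer pairings depend on that proprietary hardware and are
out of scope here; the package reports whatever the supplied calibration
data yield, and the acceptance suite verifies the estimators behave
correctly (near zero in the noiseless synthetic setting, growing with
camera noise).

## Band analysis and NBI simulation

`bandSlice()` restricts curves or cubes to a wavelength window; the default
415–540 nm window (126 bands on the 1 nm grid) is where the three tissue
classes separate most strongly. `regionSpectrum()` aggregates per-band mean
and SD over a pixel mask, excluding failed pixels.

`simulateNBI()` integrates each pixel's reflectance against two Gaussian
passbands and maps the responses to display channels. Defaults: centers
415 and 540 nm with 30 nm FWHM, 415 nm response shown on blue *and* green,
540 nm on red — the convention that renders superficial capillaries brown
and deeper vessels cyan in commercial NBI. Only the two band centers are
fixed by the physiology; passband shape, width and the channel map are
configurable. Display normalization is per-image min–max followed by sRGB
encoding; this makes the rendering invariant to cube-wide rescaling but is
a package choice, not a published standard, and a flat (zero-contrast)
image is rendered mid-gray rather than noise-stretched.

## Detection and classification evaluation

Boxes are 0-based, half-open pixel rectangles. A prediction matches a
ground-truth box when IoU ≥ 0.5 (threshold configurable). Matching is
greedy in descending confidence, ties broken by larger IoU then lower box
index, each truth matched at most once.

Frame-level labels must be derived from box-level outcomes, and the
tabulation convention is not uniquely determined by frame counts alone.
This package uses severity-max, the clinically conservative choice: a
frame's true class is its most severe ground-truth class (SCC > dysplasia
> normal), its predicted class the most severe class among matched
predictions; a frame with truth but no match is a miss (predicted normal),
and unmatched predictions on a truth-free frame make it a false positive
of the most severe predicted class.

Two specificity conventions are reported side by side. The *tabulation
variant* — for class c, the fraction of frames of the *other* classes that
land in their own correct cells — is the convention that reproduces the
published reference tables this package validates against; the standard
TN/(TN+FP) variant is always co-reported. Percentages are rounded
half-up to integers and kappa to two decimals *only at report
serialization*; all internals keep full precision.

The package embeds the published reference frame counts and confusion
matrices (`referenceDetectionCounts()`, `referenceConfusionMatrices()`) as
fixed validation inputs. A handful of printed cells in that source are
internally inconsistent with their own counts (two accuracy cells, one
kappa, two binary specificities); `knownInconsistencies()` lists them with
the count-consistent values this package computes. The implementation
always reproduces the arithmetic, never the typos.

## The composite detection loss

The training loss of the single-stage detector is reimplemented as a pure,
analytically testable computation over matched prediction/target pairs:

L = (1/N) Σ [ 0.5·L_cls + α(scale)·L_obj + 0.05·L_box ]

with N the number of matched positives. L_cls is cross-entropy between
target and predicted class distributions (clamped at 1e-12). L_box is
1 − CIoU with the standard center-distance and aspect-ratio penalties;
the full formula is fixed in the function documentation since the source
names but does not define CIoU. L_obj is documented as an interpretation:
binary cross-entropy between predicted objectness and the pair's IoU, the
usual soft-target reading of "confidence compares actual and predicted
boxes". The objectness gain α is piecewise constant in target area with
the small:medium:large ratio 4:1:0.4; only the ratio is published, so the
base gain defaults to 1 (α ∈ {4, 1, 0.4}) and the area thresholds default
to the common detection convention 32² and 96² px². The fourfold
aspect-ratio positive-sample rule with two-adjacent-cell assignment is
exposed as a standalone predicate, not a training loop.

## What the synthetic generator emulates — and what it does not

Every fixture is generated in code under a single seeded RNG stream per
generator, so all tests run without any external data.

**Reflectances.** Synthetic spectra are three-component Gaussian mixtures
on 380–780 nm with *fixed component shapes* (centers 430, 477, 630 nm) and
per-patch random amplitudes, over a fixed base, bounded to [0.02, 0.95]
(amplitude ranges keep the bound inactive). Fixing the shapes makes the
family exactly 3-dimensional, so tristimulus values determine a member
uniquely — no metamerism — and the noiseless calibration loop is exactly
invertible. This is the key structural property behind the closed-loop
tests: it is what "a camera within the assumed model family" means here.
Real tissue spectra are not confined to any 3-dimensional family, so the
closed-loop results certify the fitting machinery, not clinical
reconstruction accuracy.

**Tissue classes.** Each class is the same family's background plus a
class-dependent amplitude on the 477 nm component (normal 0.30, dysplasia
0.18, SCC 0.06), placing the class separation inside the 415–540 nm
analysis window by construction — mirroring why that window is analyzed —
with optional within-class amplitude variability.

**Camera.** Normalized XYZ → invertible 3×3 mixing (default: inverse sRGB
primaries plus a small fixed crosstalk) → optional additive Gaussian noise
in linear RGB → clip → sRGB encode. An optional polynomial distortion is
expressed in the camera-to-reference direction (reference XYZ as an exact
polynomial of camera XYZ) so the generating map stays inside the family
the order-2 correction assumes. Noise is the simplest model sufficient for
the monotone noise-vs-error property; no photon statistics, no specular
highlights, no shadowed-region failure mode, no mucosal texture.

**Scenes and detections.** Scenes are elliptical lesions on a normal
background with tight ground-truth boxes; overlaps resolve to the most
severe class. Detector outputs can be sampled (per-frame detection
probability, class-confusion rates, box jitter bounded at 15 % of box size
so a detected box keeps IoU ≥ 0.5 by construction) or *deterministically
allocated*: `framesFromConfusion()` emits exactly the frames whose
evaluation reproduces a target confusion matrix, which is how the
published reference tables are re-derived through the full matching
pipeline rather than by plain arithmetic.

## Numerical choices

- Quadrature over wavelength: rectangle rule at the 1 nm step. The step
  cancels between the luminance normalization k = 100/Σ S·ȳ and the
  numerators, so XYZ is step-invariant; the perfect reflector gets
  Y = 100 under any valid illuminant to ~1e-9.
- CIE 1931 2° observer curves are generated from the published multi-lobe
  Gaussian analytic representation (no runtime downloads, no binary
  tables); ȳ peaks at 554 nm. `writeCMFTables()` exports them for audit.
- The sRGB primaries matrix is the 7-digit colorimetric derivation, so
  linear white maps to (95.047, 100.000, 108.883).
- CIEDE2000 is implemented in full and verified against the published
  verification pairs to 1e-4; CIE76 is available as an option.
- Pseudoinverse fits use SVD-based `pracma::pinv`; tests cross-check
  against normal equations.
- NBI display normalization treats a contrast range below 1e-9 (relative)
  as flat to avoid stretching quadrature round-off into full-range noise.
- ENVI cubes are written as BSQ float32 with wavelengths in the text
  header; masked pixels are stored as NaN.

## Problem sizes in the test and acceptance suites

The suites use 24-patch checkers, scenes up to 32×32 pixels, frame sets of
up to ~720 records (the reference tables), 1000 random box pairs for the
IoU oracle, and 20 seeds × 3 noise levels for the noise-monotonicity
check; the full test suite and the acceptance script each complete in
well under a minute on a single CPU.

## Known limitations

- The analytic CMF representation deviates slightly from the tabulated
  1931 observer; all package guarantees are formulated to be independent
  of that choice (normalization, linearity, matrix white point).
- Published instrument-specific calibration errors and clinical detector
  performance require the original hardware, images and trained weights;
  they are out of scope and replaced by property-based synthetic suites.
- The NBI rendering is band integration only — no vessel enhancement, no
  magnification, no texture model.
- `evaluateDataset()` scores one operating point; there is deliberately no
  mAP/PR-curve machinery.
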