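---
title: "Methods: quantifying clock-protein dynamics from live imaging"
author: "circaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying clock-protein dynamics from live imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaquant)
```

# Scope

`circaquant` quantifies the intracellular behaviour of fluorescently tagged
circadian clock proteins (the motivating case is a knock-in Venus fusion of
BMAL1, the master positive regulator of the mammalian
transcriptional–translational feedback loop). Such reporters oscillate with
very low relative amplitude on a high nuclear baseline, so every number of
interest — rhythm period and robustness, protein and mRNA half-life, FRAP
mobility fractions, FCS-derived copy number, behavioural robustness — must be
extracted by explicit model fitting rather than read off the traces. The
package implements those fits, together with a synthetic-data module that
generates every input with known ground truth so that the whole pipeline is
testable without microscopy recordings.

# Rhythmicity from single-cell traces

## Pre-processing

Traces (`FluorTrace`) carry hours, intensities and a validity mask. Gaps are
repaired by forward filling (`forwardFill`), background ROI traces are
subtracted pointwise (`subtractBackground`), and noise/baseline structure is
removed with an à-trous (stationary) wavelet band-pass (`atrousBandpass`).
The à-trous transform uses the B3-spline kernel (1,4,6,4,1)/16 with mirror
boundaries; it is a partition of the signal — details plus the final smooth
reconstruct the input to machine precision, which the tests assert at 1e-10.
The retained levels default to those spanning 2–16 h structure at the trace's
sampling rate; the kernel and boundary rule are package choices, since the
transform family fixes neither.

## Classification

`classifyTrack` operationalizes "rhythmic" via the global maximum of the
one-sided periodogram (zero frequency excluded, 4x zero-padding to refine the
period grid): dominant period in [15, 30] h = circadian (closed interval, a
documented tie-break), below 15 h = ultradian, above 30 h = arrhythmic — a
dominant period longer than a few-day record can support is treated as
absence of a resolvable rhythm. Autocorrelation at 12 h (negative for
circadian cells) and 24 h (positive) is reported as supporting evidence but
does not enter the three-way call; a permutation peak-significance test is
deliberately not used either, keeping the call a pure frequency binning.

Detrending before the periodogram matters. A 24 h moving-average detrend is
the standard baseline removal for bioluminescence rhythms
(`detrendMovingAverage`, used before cosinor fitting), but as a
classification pre-filter it is harmful: its high-pass transfer function
reshapes the 1/f² spectrum of slowly wandering (random-walk-like) arrhythmic
cells into a broad bump near 20–30 h, so fragmentated cells would be read as
circadian. `classifyTrack` therefore defaults to *linear* detrending, which
removes bleaching drift exactly while leaving the low-frequency dominance of
arrhythmic cells intact. On the default synthetic cohort (45 circadian / 10
ultradian / 45 arrhythmic cells, 120 h at 0.5 h sampling, 5% oscillation
amplitude, 1% measurement noise) this classifier agrees with ground truth on
more than 90% of cells, which the acceptance tests assert.

## Cosinor fits and robustness

`fitDampedCosine` fits
$y(t) = m + A e^{-d t} \cos(2\pi (t - \phi)/P)$
by Levenberg–Marquardt least squares, initialized from the periodogram with
four phase starts to avoid phase aliasing. The relative amplitude error
RAE = SE(A)/A is the rhythm-robustness surrogate: 0 in the noiseless limit
and growing with amplitude uncertainty. It is a curvature-based (fit
covariance) quantity; bootstrap-based definitions used by some rhythm
platforms are related but not identical, and equivalence is not claimed.
Phase is reported as the fitted cosine peak time (not the raw argmax, which
is offered as a fallback for short records in `rasterMatrix`).

`phaseToCT` anchors circadian time on the PER2 expression peak, set to CT12
by convention: a reporter peaking $\Delta$ hours after PER2 at period $P$
maps to $CT = (12 + 24\,(\Delta \bmod P)/P) \bmod 24$, so a 7.9 h lag at a
24 h period is CT19.9.

# Half-life estimation

Protein decay after a translation block follows the one-phase model
$Y = (Y_0 - \text{Plateau}) e^{-KX} + \text{Plateau}$, half-life
$\ln 2 / K$. Initialization uses the observed extrema and a log-linear
regression for K; the fit is scale-equivariant, so min-max normalized and
raw traces give identical rates. When the record ends with more than 20% of
the fitted span still above the plateau, the estimate is flagged
`extrapolated`: the half-life then rests on the best-fit curve rather than an
observed plateau. The 20% cut-off is a round package convention; it
separates a ~2.5-half-life record (a fast-degrading protein over a 20 h
recording) from a ~2.3-half-life one (a slow-degrading protein in tissue
over 70 h). Because the two regimes sit close, the flag is only meaningful
when the rate is estimated precisely — for the tissue scenario the tests fit
the mean of six replicate courses, mirroring common experimental replication.

mRNA decay uses the same machinery in minutes after 2^-ddCt normalization
(`ddctNormalize`): target Ct minus the mean of two reference genes, then
relative to time zero. The mRNA fit constrains the plateau to 0 by default
(relative expression decays toward zero after a transcription block); the
constraint is toggleable since plateau-free and free-plateau fits coincide
on plateau-free data, which a nested-model test asserts.

# FRAP and FLIP photokinetics

`normalizeFrap` applies the standard double normalization
$(raw - bg)/(ref - bg)$, then scales the pre-bleach mean to 1, correcting
background and acquisition bleaching; the operation is idempotent. Recovery
is fitted as
$F(t) = \text{floor} + \sum_i A_i (1 - e^{-k_i t})$
with one or two mobile components; mobile fractions are $A_i/(1 -
\text{floor})$ and the immobile fraction the remainder. This
exponential-recovery family is used as the passive-diffusion surrogate; the
commercial acquisition software's exact functional family is unpublished, so
equivalence is limited to this parameterization, with half-times reported as
$\ln 2/k$ to match the T½ vocabulary of the field. Components are ordered
fast-first (ties broken by amplitude). Rates slower than 1/(2 × record
length) are not distinguishable from immobile material over the record and
are folded into the immobile fraction. Model order is chosen by small-sample
AIC (`selectFrapModel`); a degenerate second component makes the
two-component Jacobian singular, in which case the fit retreats to the
nested one-component model, and a curve with no recovery at all reduces to a
flat plateau with a 100% immobile fraction.

At the study operating point (floor 0.5, amplitudes 0.10/0.11, rates
0.1733/0.01733 s⁻¹, 0.5 s frames for 300 s, 1% additive noise) a single
curve estimates the fast half-time with roughly 13% sampling error, so
ensemble means over seeded replicates are the reported summary in the
acceptance script; they are unbiased at the ~1% level.

FLIP loss (`flipLoss`) background-subtracts the bleached cell's nuclear
trace, normalizes to the mean of unbleached neighbour nuclei (absorbing the
whole-field bleaching caused by the long bleach protocol), scales the
pre-bleach level to 100%, and reports the plateau shortfall as percent loss.

# FCS absolute quantification

The autocorrelation model is the standard one-component 3D-Gaussian-volume
diffusion model with a triplet state:

$$G(\tau) = 1 + \frac{1}{N}\left(1 + \frac{T e^{-\tau/\tau_T}}{1-T}\right)
\left(1 + \frac{\tau}{\tau_D}\right)^{-1}
\left(1 + \frac{\tau}{S^2 \tau_D}\right)^{-1/2}$$

with $N$ molecules in the effective volume
$V_{eff} = \pi^{3/2}\omega_0^3 S$. Calibration defaults are
$\omega_0 = 0.2\,\mu m$, $S = 5$ (typical for a 514 nm confocal line) and
are overridable — they are instrument properties, not constants of the
method. Fits are weighted least squares over the log-spaced lag grid (1 µs
to 10 s, the quasi-log binning of hardware correlators), each point weighted
inversely to local lag density so every decade contributes equally. When the
fitted triplet fraction collapses to zero, $\tau_T$ becomes unidentifiable
and the fit falls back to the nested T = 0 model.

Derived quantities: $D = \omega_0^2/(4\tau_D)$ (the invariant
$D\,\tau_D = \omega_0^2/4$ holds exactly for every fit), concentration
$C = N/(N_A V_{eff})$ in nM, and molecules per nucleus
$C \cdot V_{nucleus} \cdot N_A$ with the nuclear volume measured as a voxel
sum (1 µm³ = 1 fL). As a worked example, 1.845 molecules in a 0.300 fL
effective volume is 10.2 nM, and 10.2 nM in a 147 fL nucleus is ~900
molecules. The SD of such a product of two independently measured means is
propagated as $\sqrt{\bar{x}_A^2 SD_B^2 + \bar{x}_B^2 SD_A^2}$; the function
reports the square root (the radicand has squared units and is attached as
an attribute), consistent with the first-order Taylor expansion, which a
Monte-Carlo test verifies within 10%.

# Actigraphy

The chi-square periodogram folds the record at each candidate period P
(an integer number of bins, whole cycles only) and computes
$Q_P = N\,\mathrm{Var}(\bar{x}_h)/\mathrm{Var}(x)$, which is
$\chi^2_{K-1}$-distributed for unstructured data (K bins per period); the
significance line defaults to p = 0.001. This calibrated Sokolove–Bushell
form is used because the significance line is only meaningful when
$E[Q_P] = K - 1$ under the null.

The non-parametric robustness statistics use the field-standard hourly
rebinning: intra-daily variability
$IV = n\sum(x_i - x_{i-1})^2 / ((n-1)\sum(x_i-\bar{x})^2)$
(0 for a smooth sinusoid, 2 for i.i.d. noise, transiently above 2 for
alternation at the analysis Nyquist) and inter-daily stability
$IS = n\sum_h(\bar{x}_h-\bar{x})^2 / (p\sum_i(x_i-\bar{x})^2)$
(1 for an exactly repeating daily profile, ~1/days for noise). Both are
invariant to affine transforms of the counts.

Activity onset is the first bin where 3-bin-smoothed activity crosses 20% of
the daily maximum and stays above it for 3 bins — threshold and dwell are
package choices, exposed as parameters, since onset detection is not
standardized. The phase angle of entrainment is the circular mean across
days of (onset − lights-on), so onsets straddling midnight average
correctly.

# Imaging metrics

Manders coefficients report the fraction of one channel's intensity in
pixels positive for the other; both M1 and M2 are returned since which
direction a study reports is often ambiguous. Thresholds default to Otsu's
method on the partner channel (via EBImage), a deliberate, documented choice
where the original plug-in's thresholding is unspecified. The
nuclear:cytoplasmic ratio is a mean-intensity ratio over disjoint masks and
is gain-invariant. Percent object colocalization counts the partner-channel
objects whose footprint meets the overlap rule on the conjunction (A∧B)
image — by default at least 50% area coverage, emulating object counting on
a both-channels image, with any-pixel overlap as the alternative. Spectral
unmixing solves a per-pixel non-negative least-squares problem against
row-normalized reference spectra (Lawson–Hanson NNLS via pracma); with
orthogonal spectra the constrained and unconstrained solutions coincide,
and on noiseless stacks recovery is exact.

# The synthetic-data module

Generators emulate, with known truth: low-amplitude (~5% of baseline) damped
cosine oscillations with Gaussian noise and linear bleaching drift on a high
baseline; mixed cohorts (circadian 15–30 h, ultradian < 15 h, arrhythmic);
one-phase decays; two-component-plus-immobile FRAP recoveries with
background and bleaching reference channels; triplet-model FCS curves on a
1 µs–10 s log grid; binned activity records (sine, square, rectified-noise
and exact-repeat patterns); lambda stacks mixed from reference spectra; and
ellipsoidal nuclear voxel masks hitting a target volume within one voxel.

Deliberate realism choices: noise is additive Gaussian for intensity traces
and FRAP (detector-dominated regimes) and multiplicative on $G-1$ for FCS
(correlation noise scales with the correlation amplitude); arrhythmic cells
are reflected random walks rather than flat lines, so classification is a
real test; default measurement noise is 1% of baseline (recordings of
nuclear-localized reporters at moderate laser power are low-noise; the
magnitude is exposed as a parameter since no measured value is available).
What the generators do *not* emulate: photon statistics, point-spread
rendering, cell movement/tracking errors, or cell division. Passing tests
therefore demonstrate correctness of the estimators under the stated noise
models, not robustness to segmentation or tracking failures in real imaging
data.

Determinism: every generator takes a `seed`; a fixed seed reproduces output
bit-for-bit.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale: 100-cell
cohorts of 120 h at 0.5 h sampling; 50-replicate Monte-Carlo ensembles for
decay and FRAP recovery; 25-replicate ensembles for FCS; 50 records of 100
days for the IV/IS noise limits. Nonlinear fits use `minpack.lm::nlsLM`
(Levenberg–Marquardt with box constraints) throughout, with closed-form or
regression-based starting values as described above. Degenerate inputs fail
loudly and specifically: constant traces reject min-max normalization,
zero-variance activity records reject IV/IS, empty masks reject volume and
ratio computations, and non-convergent fits raise errors rather than
returning silent garbage.

# Known limitations

The RAE and period estimates are surrogates for platform-specific
non-linear FFT pipelines; agreement with those platforms is expected but
not certified. The FRAP model is phenomenological — reaction–diffusion
geometry corrections are out of scope. FCS assumes a single diffusing
species with a triplet state; multi-component and anomalous-diffusion
models are not provided. Copy numbers derived from FCS count mobile
molecules only and therefore underestimate total protein when an immobile
pool exists, as the FRAP analysis itself demonstrates.

```{r example}
# one worked path through the pipeline
cohort <- simCellCohort(45, 10, 45, seed = 1)
cls <- classifyCohort(cohort)
cls$counts

beam <- BeamGeometry(omega0 = 0.2, S = 5)
curve <- simFcsCurve(N = 3, tauD = 2.857e-3, T = 0.15, tauT = 5e-6,
                     beam = beam, noiseSD = 0.01, seed = 1)
fit <- fitFcs(curve, beam)
fit
moleculesPerNucleus(concentrationNM(fit), 147, round = TRUE)
```
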