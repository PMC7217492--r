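# circaquant

Quantitative analysis of circadian clock-protein dynamics from live-cell
imaging.

Core circadian clock proteins such as BMAL1 — the master positive regulator
of the mammalian transcriptional–translational feedback loop — can now be
watched in living cells through knock-in fluorescent fusions. Their signals
are awkward to quantify: the circadian oscillation rides at only a few
percent of a high nuclear baseline, protein turnover is slow relative to
recording lengths, and absolute abundance must be inferred from fluctuation
spectroscopy rather than intensity. `circaquant` provides the estimation
machinery for this kind of study, for cell biologists and chronobiologists
working with fluorescence/bioluminescence time series, photobleaching
experiments, FCS, wheel-running records and multispectral images:

- **Rhythmicity** — à-trous wavelet band-pass filtering, periodogram and
  autocorrelation classification of single-cell tracks into circadian
  (15–30 h), ultradian (< 15 h) and arrhythmic (> 30 h) classes, damped
  cosinor fits `m + A e^(-d t) cos(2π(t-φ)/P)` with relative amplitude
  error (RAE = SE(A)/A) as the robustness measure, and mapping of peak
  times to circadian time with the PER2 peak anchored at CT12.
- **Half-life** — one-phase decay fits
  `Y = (Y0 − Plateau) e^(−KX) + Plateau` (half-life = ln 2/K) for
  cycloheximide-chase protein courses, and 2^-ΔΔCt double-reference qPCR
  normalization feeding the same fit for mRNA decay.
- **Photokinetics** — FRAP double normalization and
  two-component-plus-immobile recovery fits
  `F(t) = floor + Σ A_i (1 − e^(−k_i t))` with fast/slow/immobile
  fractions and recovery half-times; FLIP nuclear-loss quantification
  against unbleached neighbours.
- **FCS** — one-component triplet-state diffusion model fitting, with
  diffusion coefficient `D = ω0²/(4 τ_D)`, concentration
  `C = N/(N_A V_eff)` (`V_eff = π^{3/2} ω0³ S`) and molecules per nucleus
  `C·V·N_A`, including SD propagation for the product of measured means.
- **Actigraphy** — Sokolove–Bushell χ² periodogram, intra-daily
  variability (IV, 0–2), inter-daily stability (IS, 0–1), activity onset
  and phase angle of entrainment.
- **Imaging** — Manders colocalization coefficients, nuclear:cytoplasmic
  ratio, percent object colocalization, per-pixel non-negative spectral
  linear unmixing of lambda stacks.
- **Synthetic data** — seeded generators for every input above with known
  ground truth, so the full pipeline is testable with no raw recordings.

Data containers are S4 (`FluorTrace`, `TraceCohort` extending
`SummarizedExperiment`, `FrapCurve`, `FcsCurve`, `ActivityRecord`,
`LambdaStack`, …) with accessors and validity checks.

## Worked example

```r
library(circaquant)

# a 100-cell synthetic cohort: 45 circadian, 10 ultradian, 45 arrhythmic
cohort <- simCellCohort(45, 10, 45, seed = 1)
classifyCohort(cohort)$counts
#>  circadian  ultradian arrhythmic
#>         43         10         47

# protein half-life from a 20 h decay course (true half-life 8 h, 2% noise)
tr <- simDecayCourse(1, 0.1, k = 0.0866, noiseSD = 0.02,
                     samplingInterval = 0.1, duration = 20, seed = 8)
fitOnePhaseDecay(tr)
#> DecayFit: half-life 7.853 hours (K = 0.08827 per hour)
#>   Y0 = 0.9991, Plateau = 0.1085, RSS = 0.0913

# FRAP: two mobile components plus an immobile pool
cv <- simFrapCurve(noiseSD = 0.01, seed = 1)
fitFrap(normalizeFrap(cv))
#> FrapFit (2-component + immobile)
#>   fractions: fast 19.9%, slow 21.6%, immobile 58.5%
#>   t_1/2: fast 4.23 s, slow 40.7 s

# FCS: absolute quantification
beam <- BeamGeometry(omega0 = 0.2, S = 5)
curve <- simFcsCurve(N = 3, tauD = 2.857e-3, T = 0.15, tauT = 5e-6,
                     beam = beam, noiseSD = 0.01, seed = 1)
fitFcs(curve, beam)
#> FcsFit (one-component + triplet)
#>   N = 2.996, tauD = 0.002854 s, T = 0.151, tauT = 4.9e-06 s
#>   D = 3.5 um^2/s, C = 22.3 nM (V_eff = 0.223 fL)
```

The cohort call recovers the programmed 45/10/45 composition with a few
cells near the 30 h class boundary exchanged; the decay fit returns the
programmed 8 h half-life within its sampling error; the FRAP fit decomposes
the recovery into ~20% fast (t½ ≈ 4 s), ~22% slow (t½ ≈ 40 s) and ~58%
immobile signal; the FCS fit recovers the particle number and diffusion
time, giving a diffusion coefficient of 3.5 µm²/s in this calibration. A
concentration of 10.2 nM in a 147 fL nucleus corresponds to
`moleculesPerNucleus(10.2, 147, round = TRUE)` = 903 molecules.

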