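# Synthetic-data module: generates every input the analysis stages consume,
# with known ground truth, so that parameter recovery is testable without any
# microscopy recording. Noise regimes follow the dominant noise of each
# modality: additive Gaussian for intensity traces and FRAP, multiplicative
# Gaussian on (G - 1) for FCS autocorrelations.

#' Simulate a damped oscillatory fluorescence trace
#'
#' Emulates the low-amplitude circadian oscillation of a nuclear clock-protein
#' reporter riding on a high baseline, with optional exponential damping,
#' linear bleaching drift and additive Gaussian noise:
#' \deqn{y(t) = b (1 + a e^{-\lambda t} \cos(2\pi (t-\phi)/P)) + s t + \epsilon}
#'
#' @param baseline baseline intensity (AU), > 0.
#' @param amplitudeFrac oscillation amplitude as a fraction of baseline
#'   (clock-protein reporters are typically ~0.05).
#' @param period oscillation period in hours, > 0.
#' @param phase peak time in hours.
#' @param dampingRate exponential damping rate, per hour.
#' @param driftSlope linear drift (bleaching), AU per hour.
#' @param noiseSD additive Gaussian noise SD as a fraction of baseline.
#' @param samplingInterval hours between samples.
#' @param duration total record length, hours.
#' @param seed optional integer seed for reproducibility.
#' @param label trace label.
#' @return A \linkS4class{FluorTrace}.
#' @examples
#' tr <- simOscillatoryTrace(100, 0.046, period = 24, noiseSD = 0, duration = 48)
#' max(traceValues(tr)) - 100   # 4.6 AU peak above baseline
#' @export
simOscillatoryTrace <- function(baseline = 100, amplitudeFrac = 0.05,
                                period = 24, phase = 0, dampingRate = 0,
                                driftSlope = 0, noiseSD = 0.01,
                                samplingInterval = 0.5, duration = 120,
                                seed = NULL, label = "sim_osc") {
  if (baseline <= 0) stop("baseline must be > 0")
  if (period <= 0) stop("period must be > 0")
  if (samplingInterval <= 0) stop("samplingInterval must be > 0")
  if (duration < 2 * samplingInterval) stop("duration too short")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = samplingInterval)
  y <- baseline * (1 + amplitudeFrac * exp(-dampingRate * t) *
                     cos(2 * pi * (t - phase) / period)) + driftSlope * t
  if (noiseSD > 0) y <- y + rnorm(length(t), sd = noiseSD * baseline)
  FluorTrace(t, y, label = label)
}

#' Noiseless oscillatory model values
#'
#' Closed-form signal of \code{\link{simOscillatoryTrace}} without noise;
#' used for residual checks against ground truth.
#'
#' @param t times, hours.
#' @inheritParams simOscillatoryTrace
#' @return Numeric model values.
#' @export
oscillatoryModel <- function(t, baseline, amplitudeFrac, period, phase = 0,
                             dampingRate = 0, driftSlope = 0) {
  baseline * (1 + amplitudeFrac * exp(-dampingRate * t) *
                cos(2 * pi * (t - phase) / period)) + driftSlope * t
}

#' Simulate a mixed cohort of circadian, ultradian and arrhythmic cells
#'
#' Circadian members carry periods drawn in 15-30 h, ultradian members below
#' 15 h; arrhythmic members are reflected random walks (AR(1) steps with a
#' floor at zero) carrying no periodic component, so that classification is a
#' non-trivial task. Ground truth (label, period, phase) is stored in
#' \code{rowData}.
#'
#' @param nCircadian,nUltradian,nArrhythmic member counts (>= 0, not all 0).
#' @param circadianRange,ultradianRange period ranges (hours) sampled
#'   uniformly for the two rhythmic classes.
#' @param baseline baseline intensity (AU).
#' @param amplitudeFrac oscillation amplitude as fraction of baseline.
#' @param dampingRate per hour.
#' @param driftSlope AU per hour (bleaching drift applied to all members).
#' @param noiseSD measurement noise SD as fraction of baseline.
#' @param walkStepSD arrhythmic random-walk step SD as fraction of baseline.
#' @param samplingInterval hours.
#' @param duration hours.
#' @param seed optional integer seed.
#' @return A \linkS4class{TraceCohort} with truth columns \code{label},
#'   \code{period}, \code{phase}.
#' @export
simCellCohort <- function(nCircadian, nUltradian, nArrhythmic,
                          circadianRange = c(15, 30),
                          ultradianRange = c(6, 12),
                          baseline = 100, amplitudeFrac = 0.05,
                          dampingRate = 0.005, driftSlope = -0.02,
                          noiseSD = 0.01, walkStepSD = 0.01,
                          samplingInterval = 0.5, duration = 120,
                          seed = NULL) {
  counts <- c(nCircadian, nUltradian, nArrhythmic)
  if (any(counts < 0)) stop("counts must be >= 0")
  nTotal <- sum(counts)
  if (nTotal == 0) stop("empty cohort")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = samplingInterval)
  labels <- rep(c("circadian", "ultradian", "arrhythmic"), counts)
  periods <- rep(NA_real_, nTotal)
  phases <- rep(NA_real_, nTotal)
  mat <- matrix(NA_real_, nrow = nTotal, ncol = length(t))
  for (i in seq_len(nTotal)) {
    if (labels[i] == "arrhythmic") {
      steps <- rnorm(length(t), sd = walkStepSD * baseline)
      walk <- baseline + cumsum(steps)
      walk <- abs(walk)                       # reflecting floor at 0
      y <- walk + rnorm(length(t), sd = noiseSD * baseline)
    } else {
      rng <- if (labels[i] == "circadian") circadianRange else ultradianRange
      periods[i] <- runif(1, rng[1], rng[2])
      phases[i] <- runif(1, 0, periods[i])
      y <- oscillatoryModel(t, baseline, amplitudeFrac, periods[i], phases[i],
                            dampingRate, driftSlope) +
        rnorm(length(t), sd = noiseSD * baseline)
    }
    mat[i, ] <- y
  }
  TraceCohort(mat, t,
              truth = data.frame(label = labels, period = periods,
                                 phase = phases))
}

#' Simulate a one-phase exponential decay course
#'
#' \eqn{Y = (Y_0 - Plateau) e^{-K X} + Plateau} with optional additive noise.
#' Time units are whatever \code{K} is expressed in (hours for protein
#' cycloheximide chases, minutes for mRNA transcription-block courses).
#'
#' @param y0 initial level, must exceed \code{plateau}.
#' @param plateau asymptote, >= 0.
#' @param k decay rate constant, > 0.
#' @param noiseSD additive Gaussian noise SD as fraction of \code{y0}.
#' @param samplingInterval,duration time grid, same units as 1/k.
#' @param seed optional integer seed.
#' @return A \linkS4class{FluorTrace} (times in the units of 1/k).
#' @export
simDecayCourse <- function(y0 = 1, plateau = 0, k, noiseSD = 0,
                           samplingInterval = 0.1, duration = 20,
                           seed = NULL) {
  if (k <= 0) stop("k must be > 0")
  if (!(y0 > plateau) || plateau < 0) stop("need y0 > plateau >= 0")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = samplingInterval)
  y <- (y0 - plateau) * exp(-k * t) + plateau
  if (noiseSD > 0) y <- y + rnorm(length(t), sd = noiseSD * y0)
  FluorTrace(t, y, label = "sim_decay")
}

#' Simulate a FRAP recovery curve
#'
#' Post-bleach recovery follows the two-component exponential model
#' \eqn{F(t) = floor + A_f (1 - e^{-k_f t}) + A_s (1 - e^{-k_s t})}, preceded
#' by \code{nPrebleach} frames at the pre-bleach level 1. Background and
#' unbleached-reference channels are included so that
#' \code{\link{normalizeFrap}} exercises the full double-normalization path;
#' the reference can decay to emulate acquisition bleaching.
#'
#' @param floor normalized post-bleach starting level, in [0, 1).
#' @param ampFast,ampSlow component amplitudes, >= 0, with
#'   \code{floor + ampFast + ampSlow <= 1}.
#' @param kFast,kSlow recovery rates, per second, > 0.
#' @param samplingInterval,duration seconds (post-bleach portion).
#' @param nPrebleach number of pre-bleach frames (default 10).
#' @param backgroundLevel constant background intensity (AU).
#' @param referenceBleachRate fractional per-second linear decay of the
#'   unbleached reference (acquisition bleaching).
#' @param intensityScale raw-intensity scale factor applied to all channels.
#' @param noiseSD additive Gaussian noise SD on the normalized scale.
#' @param seed optional integer seed.
#' @return A \linkS4class{FrapCurve}.
#' @export
simFrapCurve <- function(floor = 0.5, ampFast = 0.10, ampSlow = 0.11,
                         kFast = 0.1733, kSlow = 0.01733,
                         samplingInterval = 0.5, duration = 300,
                         nPrebleach = 10, backgroundLevel = 0,
                         referenceBleachRate = 0, intensityScale = 1,
                         noiseSD = 0, seed = NULL) {
  if (floor < 0 || floor >= 1) stop("floor must be in [0, 1)")
  if (ampFast < 0 || ampSlow < 0) stop("amplitudes must be >= 0")
  if (floor + ampFast + ampSlow > 1 + 1e-9)
    stop("floor + amplitudes must not exceed 1")
  if ((ampFast > 0 && kFast <= 0) || (ampSlow > 0 && kSlow <= 0))
    stop("recovery rates must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tPre <- -rev(seq_len(nPrebleach)) * samplingInterval
  tPost <- seq(0, duration, by = samplingInterval)
  times <- c(tPre, tPost)
  f <- c(rep(1, nPrebleach),
         floor + ampFast * (1 - exp(-kFast * tPost)) +
           ampSlow * (1 - exp(-kSlow * tPost)))
  if (noiseSD > 0) f <- f + rnorm(length(f), sd = noiseSD)
  ref <- pmax(1 - referenceBleachRate * (times - times[1]), 0.05)
  raw <- (f * ref) * intensityScale + backgroundLevel
  FrapCurve(times, raw, background = rep(backgroundLevel, length(times)),
            reference = ref * intensityScale + backgroundLevel)
}

#' Simulate an FCS autocorrelation curve
#'
#' Evaluates the one-component triplet-state diffusion model
#' (\code{\link{fcsModel}}) on a logarithmic lag grid spanning 1 us to 10 s
#' (the quasi-log binning convention of hardware correlators), with optional
#' multiplicative Gaussian noise on the correlation amplitude \eqn{G - 1}.
#'
#' @param N mean molecules in the effective volume, > 0.
#' @param tauD diffusion time, seconds.
#' @param T triplet fraction in [0, 1).
#' @param tauT triplet relaxation time, seconds (< tauD).
#' @param beam a \linkS4class{BeamGeometry}.
#' @param nLags number of log-spaced lag points.
#' @param lagRange lag range in seconds (default 1e-6 to 10).
#' @param noiseSD multiplicative noise SD on G - 1.
#' @param seed optional integer seed.
#' @return An \linkS4class{FcsCurve}.
#' @export
simFcsCurve <- function(N, tauD, T = 0, tauT = 5e-6, beam = BeamGeometry(),
                        nLags = 200, lagRange = c(1e-6, 10), noiseSD = 0,
                        seed = NULL) {
  if (N <= 0) stop("N must be > 0")
  if (T < 0 || T >= 1) stop("triplet fraction T must be in [0, 1)")
  if (T > 0 && tauT >= tauD) stop("tauT must be below tauD")
  if (!is.null(seed)) set.seed(seed)
  lags <- exp(seq(log(lagRange[1]), log(lagRange[2]), length.out = nLags))
  G <- fcsModel(lags, N = N, tauD = tauD, T = T, tauT = tauT, beam = beam)
  if (noiseSD > 0)
    G <- 1 + (G - 1) * (1 + rnorm(nLags, sd = noiseSD))
  FcsCurve(lags, G)
}

#' Simulate a binned locomotor-activity record
#'
#' Patterns: \code{"sine"} (rectified sinusoid of the given period),
#' \code{"square"} (active for half the period), \code{"noise"} (rectified
#' i.i.d. Gaussian deviates, i.e. no temporal structure), and
#' \code{"repeat_template"} (one day's template tiled exactly across days).
#'
#' @param pattern one of "sine", "square", "noise", "repeat_template".
#' @param period hours (rhythmic patterns).
#' @param binMinutes bin width in minutes; must divide 24 h evenly.
#' @param days number of days, >= 2.
#' @param amplitude mean counts scale of the active phase.
#' @param noiseSD additive Gaussian noise SD (counts) on rhythmic patterns;
#'   the SD of the deviates for pattern "noise".
#' @param template numeric vector of one day's bins (for "repeat_template").
#' @param startClock,lightsOn clock hours (see \code{\link{ActivityRecord}}).
#' @param seed optional integer seed.
#' @return An \linkS4class{ActivityRecord}.
#' @export
simActivityRecord <- function(pattern = c("sine", "square", "noise",
                                          "repeat_template"),
                              period = 24, binMinutes = 10, days = 10,
                              amplitude = 100, noiseSD = 0, template = NULL,
                              startClock = 0, lightsOn = NA_real_,
                              seed = NULL) {
  pattern <- match.arg(pattern)
  if (days < 2) stop("at least 2 days required")
  if ((24 * 60) %% binMinutes != 0) stop("bin width must divide 24 h evenly")
  if (!is.null(seed)) set.seed(seed)
  perDay <- 24 * 60 / binMinutes
  n <- perDay * days
  tHours <- (seq_len(n) - 1) * binMinutes / 60
  counts <- switch(pattern,
    sine = pmax(0, amplitude * (1 + sin(2 * pi * tHours / period)) +
                  if (noiseSD > 0) rnorm(n, sd = noiseSD) else 0),
    square = pmax(0, amplitude * ((tHours %% period) < period / 2) +
                    if (noiseSD > 0) rnorm(n, sd = noiseSD) else 0),
    noise = pmax(0, rnorm(n, sd = if (noiseSD > 0) noiseSD else 1)),
    repeat_template = {
      if (is.null(template)) stop("pattern 'repeat_template' needs a template")
      if (length(template) != perDay)
        stop("template length must equal bins per day")
      rep(as.numeric(template), days)
    })
  ActivityRecord(counts, binMinutes = binMinutes, startClock = startClock,
                 lightsOn = lightsOn)
}

#' Simulate a lambda stack from reference spectra and abundance maps
#'
#' Each pixel's spectrum is the abundance-weighted mixture of the reference
#' spectra, plus optional additive Gaussian noise. The abundance maps are the
#' unmixing ground truth.
#'
#' @param spectra a \linkS4class{SpectraMatrix} (one row per fluorophore).
#' @param abundance 3D array (rows x cols x fluorophores) of non-negative
#'   per-pixel weights.
#' @param noiseSD additive noise SD on the stack intensities.
#' @param seed optional integer seed.
#' @return A \linkS4class{LambdaStack}; the truth maps are attached as
#'   attribute \code{"truth"}.
#' @export
simLambdaStack <- function(spectra, abundance, noiseSD = 0, seed = NULL) {
  stopifnot(is(spectra, "SpectraMatrix"))
  d <- dim(abundance)
  if (length(d) != 3 || d[3] != nrow(spectra@spectra))
    stop("abundance must be rows x cols x fluorophores")
  if (any(abundance < 0)) stop("abundances must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  nw <- length(spectra@wavelengths)
  amat <- matrix(abundance, ncol = d[3])          # pixels x fluorophores
  smat <- amat %*% spectra@spectra                # pixels x wavelengths
  if (noiseSD > 0) smat <- smat + rnorm(length(smat), sd = noiseSD)
  stack <- LambdaStack(array(smat, dim = c(d[1], d[2], nw)),
                       spectra@wavelengths)
  attr(stack, "truth") <- abundance
  stack
}

#' Generate an ellipsoidal nuclear voxel mask of a target volume
#'
#' Builds a binary voxel mask approximating an ellipsoid (axis ratios
#' \code{axisRatio}) whose voxel-sum volume is within one voxel of the target,
#' by ranking voxels by scaled ellipsoidal distance and keeping exactly
#' \code{round(volume / voxelVolume)} of them.
#'
#' @param volumeFL target volume in femtolitres (= um^3), > 0.
#' @param voxelDims voxel dimensions in micrometres, length 3.
#' @param axisRatio relative semi-axis lengths (default spherical).
#' @return A logical 3D array; the achieved volume (fL) is attached as
#'   attribute \code{"volume"}.
#' @export
simNuclearMask <- function(volumeFL, voxelDims = c(0.2, 0.2, 0.5),
                           axisRatio = c(1, 1, 1)) {
  if (volumeFL <= 0) stop("volume must be > 0")
  voxVol <- prod(voxelDims)
  if (voxVol > volumeFL * (1 + 1e-9)) stop("voxel larger than target volume")
  nVox <- round(volumeFL / voxVol)
  # bounding box: sphere-equivalent radius inflated by the axis ratios
  r <- (3 * volumeFL / (4 * pi))^(1 / 3)
  ax <- axisRatio / prod(axisRatio)^(1 / 3) * r * 1.5
  dims <- pmax(3L, 2L * ceiling(ax / voxelDims) + 3L)
  centre <- (dims + 1) / 2
  gx <- (seq_len(dims[1]) - centre[1]) * voxelDims[1] / axisRatio[1]
  gy <- (seq_len(dims[2]) - centre[2]) * voxelDims[2] / axisRatio[2]
  gz <- (seq_len(dims[3]) - centre[3]) * voxelDims[3] / axisRatio[3]
  d2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
  thr <- sort(d2)[nVox]
  mask <- d2 <= thr
  # resolve ties on the shell deterministically
  if (sum(mask) > nVox) {
    excess <- sum(mask) - nVox
    shell <- which(d2 == thr)
    mask[shell[seq_len(excess)]] <- FALSE
  }
  attr(mask, "volume") <- sum(mask) * voxVol
  attr(mask, "voxelDims") <- voxelDims
  mask
}
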