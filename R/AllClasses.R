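#' @import methods
#' @importFrom stats fft coef lm nls acf qchisq sd var rnorm runif median
#'   quantile residuals setNames
#' @importFrom graphics hist
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# Physical constants used for absolute quantification.
.AVOGADRO <- 6.02214076e23   # molecules per mole

# ---------------------------------------------------------------------------
# FluorTrace: a single ROI / cell intensity time course
# ---------------------------------------------------------------------------

#' FluorTrace: a single-ROI fluorescence or bioluminescence time course
#'
#' Container for one region-of-interest (or tracked nucleus) intensity trace.
#' Times are in hours unless a function documents otherwise (FRAP/FLIP work in
#' seconds); values are arbitrary fluorescence/bioluminescence units. The
#' validity mask marks points that carry a measured value: invalid points may
#' hold \code{NA} and are repaired by \code{\link{forwardFill}}.
#'
#' @slot times numeric, strictly increasing sampling times.
#' @slot values numeric intensities, same length as \code{times}.
#' @slot mask logical validity flags; \code{values} must be finite wherever
#'   \code{mask} is \code{TRUE}.
#' @slot label character annotation, updated by processing steps.
#' @export
setClass("FluorTrace",
  representation(times = "numeric", values = "numeric",
                 mask = "logical", label = "character"))

setValidity("FluorTrace", function(object) {
  msg <- NULL
  n <- length(object@times)
  if (length(object@values) != n) msg <- c(msg, "times and values differ in length")
  if (length(object@mask) != n) msg <- c(msg, "mask and values differ in length")
  if (n > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(!is.finite(object@values[object@mask])))
    msg <- c(msg, "values must be finite where mask is TRUE")
  if (length(object@label) != 1) msg <- c(msg, "label must be a single string")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FluorTrace
#'
#' @param times numeric sampling times (hours, or seconds for photokinetics).
#' @param values numeric intensities.
#' @param mask logical validity flags; defaults to marking finite values.
#' @param label annotation string.
#' @return A \linkS4class{FluorTrace}.
#' @examples
#' tr <- FluorTrace(0:10, 100 + sin(0:10), label = "cell_1")
#' traceValues(tr)
#' @export
FluorTrace <- function(times, values, mask = NULL, label = "trace") {
  if (is.null(mask)) mask <- is.finite(values)
  new("FluorTrace", times = as.numeric(times), values = as.numeric(values),
      mask = as.logical(mask), label = as.character(label))
}

setMethod("show", "FluorTrace", function(object) {
  n <- length(object@times)
  cat("FluorTrace \"", object@label, "\": ", n, " points",
      if (n > 0) sprintf(", t = [%g, %g]", object@times[1], object@times[n]),
      ", ", sum(!object@mask), " masked\n", sep = "")
})

setMethod("length", "FluorTrace", function(x) length(x@times))

# ---------------------------------------------------------------------------
# TraceCohort: many traces on a common grid (SummarizedExperiment)
# ---------------------------------------------------------------------------

#' TraceCohort: a cohort of traces on a shared time grid
#'
#' Thin extension of \linkS4class{SummarizedExperiment}: the
#' \code{"intensity"} assay holds one row per cell/ROI and one column per time
#' point; \code{colData(x)$time} carries the common time grid (hours);
#' \code{rowData} carries per-cell annotation, including simulation ground
#' truth for cohorts built by \code{\link{simCellCohort}}.
#'
#' @export
setClass("TraceCohort", contains = "SummarizedExperiment")

setValidity("TraceCohort", function(object) {
  msg <- NULL
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  tm <- object$time
  if (is.null(tm) || !is.numeric(tm))
    msg <- c(msg, "colData must carry a numeric 'time' column")
  else if (length(tm) > 1 && any(diff(tm) <= 0))
    msg <- c(msg, "time grid must be strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TraceCohort
#'
#' @param intensity numeric matrix, cells in rows, time points in columns.
#' @param time numeric time grid in hours (length \code{ncol(intensity)}).
#' @param truth optional \code{DataFrame}/\code{data.frame} of per-cell
#'   annotation (ground truth for simulated cohorts).
#' @return A \linkS4class{TraceCohort}.
#' @export
TraceCohort <- function(intensity, time, truth = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("cell_%03d", seq_len(nrow(intensity)))
  cd <- S4Vectors::DataFrame(time = as.numeric(time))
  rd <- if (is.null(truth)) S4Vectors::DataFrame(row.names = rownames(intensity))
        else S4Vectors::DataFrame(truth, row.names = rownames(intensity))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), colData = cd, rowData = rd)
  new("TraceCohort", se)
}

#' Extract one cohort member as a FluorTrace
#'
#' @param cohort a \linkS4class{TraceCohort}.
#' @param i row index or row name.
#' @return A \linkS4class{FluorTrace}.
#' @export
getTrace <- function(cohort, i) {
  stopifnot(is(cohort, "TraceCohort"))
  v <- SummarizedExperiment::assay(cohort, "intensity")[i, , drop = TRUE]
  lbl <- if (is.character(i)) i else rownames(cohort)[i]
  FluorTrace(cohort$time, v, label = lbl)
}

# ---------------------------------------------------------------------------
# Photokinetics containers
# ---------------------------------------------------------------------------

#' FrapCurve: a photobleaching recovery record
#'
#' Times are seconds with the bleach event at t = 0; pre-bleach frames carry
#' negative times. Background and unbleached-reference channels accompany the
#' bleached-ROI signal so acquisition bleaching can be corrected
#' (\code{\link{normalizeFrap}}).
#'
#' @slot times numeric seconds, monotone increasing, 0 at bleach.
#' @slot raw numeric bleached-ROI intensities.
#' @slot background numeric background-ROI intensities.
#' @slot reference numeric unbleached-ROI intensities.
#' @slot nPrebleach integer count of pre-bleach frames (times < 0).
#' @export
setClass("FrapCurve",
  representation(times = "numeric", raw = "numeric", background = "numeric",
                 reference = "numeric", nPrebleach = "integer"))

setValidity("FrapCurve", function(object) {
  msg <- NULL
  n <- length(object@times)
  if (any(c(length(object@raw), length(object@background),
            length(object@reference)) != n))
    msg <- c(msg, "channel lengths differ")
  if (n > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (object@nPrebleach < 1L) msg <- c(msg, "at least one pre-bleach frame required")
  if (sum(object@times < 0) != object@nPrebleach)
    msg <- c(msg, "nPrebleach must equal the number of negative times")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FrapCurve
#'
#' @param times seconds (0 at bleach; pre-bleach frames negative).
#' @param raw bleached-ROI intensities.
#' @param background background-ROI intensities.
#' @param reference unbleached-ROI intensities.
#' @return A \linkS4class{FrapCurve}.
#' @export
FrapCurve <- function(times, raw, background = rep(0, length(times)),
                      reference = rep(1, length(times))) {
  new("FrapCurve", times = as.numeric(times), raw = as.numeric(raw),
      background = as.numeric(background), reference = as.numeric(reference),
      nPrebleach = as.integer(sum(times < 0)))
}

setMethod("show", "FrapCurve", function(object) {
  cat(sprintf("FrapCurve: %d frames (%d pre-bleach), t in [%g, %g] s\n",
              length(object@times), object@nPrebleach,
              min(object@times), max(object@times)))
})

#' FrapFit: decomposition of a FRAP recovery
#'
#' @slot fractions named numeric (fast, slow, immobile), summing to 1.
#' @slot tHalf named numeric recovery half-times, seconds (ln 2 / k).
#' @slot rates named numeric recovery rate constants, per second.
#' @slot amplitudes named numeric fitted amplitudes on the normalized scale.
#' @slot floor numeric first post-bleach level (fitted).
#' @slot modelOrder integer 1 or 2.
#' @slot rss numeric residual sum of squares.
#' @slot aicc numeric small-sample Akaike information criterion.
#' @slot converged logical.
#' @export
setClass("FrapFit",
  representation(fractions = "numeric", tHalf = "numeric", rates = "numeric",
                 amplitudes = "numeric", floor = "numeric",
                 modelOrder = "integer", rss = "numeric", aicc = "numeric",
                 converged = "logical"))

setValidity("FrapFit", function(object) {
  msg <- NULL
  if (any(object@fractions < -1e-6)) msg <- c(msg, "fractions must be >= 0")
  if (abs(sum(object@fractions) - 1) > 1e-6)
    msg <- c(msg, "fractions must sum to 1")
  if (!object@modelOrder %in% c(1L, 2L)) msg <- c(msg, "modelOrder must be 1 or 2")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FrapFit", function(object) {
  cat(sprintf("FrapFit (%d-component + immobile)\n", object@modelOrder))
  fr <- 100 * object@fractions
  cat(sprintf("  fractions: fast %.1f%%, slow %.1f%%, immobile %.1f%%\n",
              fr["fast"], fr["slow"], fr["immobile"]))
  cat(sprintf("  t_1/2: fast %.3g s, slow %.3g s\n",
              object@tHalf["fast"], object@tHalf["slow"]))
})

# ---------------------------------------------------------------------------
# FCS containers
# ---------------------------------------------------------------------------

#' BeamGeometry: confocal observation volume calibration
#'
#' @slot omega0 lateral 1/e^2 radius, micrometres.
#' @slot S structure parameter (axial / lateral radius ratio), > 1.
#' @export
setClass("BeamGeometry", representation(omega0 = "numeric", S = "numeric"))

setValidity("BeamGeometry", function(object) {
  msg <- NULL
  if (object@omega0 <= 0) msg <- c(msg, "omega0 must be > 0")
  if (object@S <= 1) msg <- c(msg, "structure parameter S must be > 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BeamGeometry
#'
#' Defaults reflect a typical 514 nm confocal calibration.
#'
#' @param omega0 lateral 1/e^2 beam radius in micrometres.
#' @param S structure parameter (axial/lateral ratio).
#' @return A \linkS4class{BeamGeometry}.
#' @examples
#' effectiveVolume(BeamGeometry())          # ~0.22 fL
#' @export
BeamGeometry <- function(omega0 = 0.2, S = 5) {
  new("BeamGeometry", omega0 = omega0, S = S)
}

#' Effective confocal volume
#'
#' \eqn{V_{eff} = \pi^{3/2} \omega_0^3 S} for a 3D Gaussian observation
#' profile, returned in femtolitres (1 \eqn{\mu m^3} = 1 fL).
#'
#' @param beam a \linkS4class{BeamGeometry}.
#' @return Effective volume in fL.
#' @export
effectiveVolume <- function(beam) {
  stopifnot(is(beam, "BeamGeometry"))
  pi^1.5 * beam@omega0^3 * beam@S
}

#' FcsCurve: an autocorrelation record
#'
#' @slot lags numeric lag times in seconds, increasing (log-spaced by
#'   convention of hardware correlators).
#' @slot G numeric autocorrelation amplitudes (G(tau), approaching 1 at long
#'   lags).
#' @slot runCount integer number of acquisition runs averaged into the curve.
#' @export
setClass("FcsCurve",
  representation(lags = "numeric", G = "numeric", runCount = "integer"))

setValidity("FcsCurve", function(object) {
  msg <- NULL
  if (length(object@lags) != length(object@G)) msg <- c(msg, "lags/G length mismatch")
  if (any(diff(object@lags) <= 0)) msg <- c(msg, "lags must be increasing")
  if (any(!is.finite(object@G))) msg <- c(msg, "G must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Construct an FcsCurve
#'
#' @param lags lag times, seconds.
#' @param G autocorrelation values.
#' @param runCount number of runs averaged.
#' @return An \linkS4class{FcsCurve}.
#' @export
FcsCurve <- function(lags, G, runCount = 1L) {
  new("FcsCurve", lags = as.numeric(lags), G = as.numeric(G),
      runCount = as.integer(runCount))
}

setMethod("show", "FcsCurve", function(object) {
  cat(sprintf("FcsCurve: %d lags in [%.2g, %.2g] s, %d run(s), G(0+) ~ %.4g\n",
              length(object@lags), min(object@lags), max(object@lags),
              object@runCount, object@G[1]))
})

#' FcsFit: fitted one-component triplet-state diffusion model
#'
#' @slot N mean number of molecules in the effective volume.
#' @slot tauD diffusion (dwell) time, seconds.
#' @slot T triplet fraction in [0, 1).
#' @slot tauT triplet relaxation time, seconds.
#' @slot D diffusion coefficient, um^2/s (\code{omega0^2 / (4 tauD)}).
#' @slot concNM molar concentration, nM (\code{N / (N_A V_eff)}).
#' @slot beam the \linkS4class{BeamGeometry} used.
#' @slot se named standard errors of the fitted parameters.
#' @slot residuals fit-deviation series (data minus model) over the lag grid.
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @export
setClass("FcsFit",
  representation(N = "numeric", tauD = "numeric", T = "numeric",
                 tauT = "numeric", D = "numeric", concNM = "numeric",
                 beam = "BeamGeometry", se = "numeric",
                 residuals = "numeric", rss = "numeric", converged = "logical"))

setValidity("FcsFit", function(object) {
  msg <- NULL
  if (object@N <= 0) msg <- c(msg, "N must be > 0")
  if (object@T < 0 || object@T >= 1) msg <- c(msg, "T must be in [0, 1)")
  if (abs(object@D * object@tauD - object@beam@omega0^2 / 4) >
      1e-9 * object@beam@omega0^2 / 4)
    msg <- c(msg, "D and tauD inconsistent with beam geometry")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FcsFit", function(object) {
  cat("FcsFit (one-component + triplet)\n")
  cat(sprintf("  N = %.4g, tauD = %.4g s, T = %.3f, tauT = %.3g s\n",
              object@N, object@tauD, object@T, object@tauT))
  cat(sprintf("  D = %.3g um^2/s, C = %.3g nM (V_eff = %.3g fL)\n",
              object@D, object@concNM, effectiveVolume(object@beam)))
})

# ---------------------------------------------------------------------------
# Actigraphy container
# ---------------------------------------------------------------------------

#' ActivityRecord: binned locomotor-activity counts
#'
#' @slot counts non-negative activity counts per bin.
#' @slot binMinutes bin width in minutes; must divide 24 h evenly.
#' @slot startClock clock time (hours, 0-24) of the first bin.
#' @slot lightsOn clock time of lights-on for entrained records (NA when
#'   free-running).
#' @export
setClass("ActivityRecord",
  representation(counts = "numeric", binMinutes = "numeric",
                 startClock = "numeric", lightsOn = "numeric"))

setValidity("ActivityRecord", function(object) {
  msg <- NULL
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if ((24 * 60) %% object@binMinutes != 0)
    msg <- c(msg, "bin width must divide 24 h evenly")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ActivityRecord
#'
#' @param counts non-negative counts per bin.
#' @param binMinutes bin width, minutes (must divide 24 h).
#' @param startClock clock hour of the first bin (default 0).
#' @param lightsOn clock hour of lights-on, or NA.
#' @return An \linkS4class{ActivityRecord}.
#' @export
ActivityRecord <- function(counts, binMinutes = 10, startClock = 0,
                           lightsOn = NA_real_) {
  new("ActivityRecord", counts = as.numeric(counts),
      binMinutes = as.numeric(binMinutes), startClock = as.numeric(startClock),
      lightsOn = as.numeric(lightsOn))
}

setMethod("show", "ActivityRecord", function(object) {
  days <- length(object@counts) * object@binMinutes / (24 * 60)
  cat(sprintf("ActivityRecord: %d bins of %g min (%.1f days)%s\n",
              length(object@counts), object@binMinutes, days,
              if (is.na(object@lightsOn)) ", free-running"
              else sprintf(", lights on at %02.0f:00", object@lightsOn)))
})

# ---------------------------------------------------------------------------
# Spectral imaging containers
# ---------------------------------------------------------------------------

#' SpectraMatrix: reference emission spectra for linear unmixing
#'
#' One row per fluorophore; rows are normalized to unit sum on construction.
#'
#' @slot spectra non-negative matrix, fluorophores x wavelengths, rows sum 1.
#' @slot wavelengths numeric wavelengths in nm.
#' @export
setClass("SpectraMatrix",
  representation(spectra = "matrix", wavelengths = "numeric"))

setValidity("SpectraMatrix", function(object) {
  msg <- NULL
  if (ncol(object@spectra) != length(object@wavelengths))
    msg <- c(msg, "wavelength count mismatch")
  if (any(object@spectra < 0)) msg <- c(msg, "spectra must be non-negative")
  if (any(abs(rowSums(object@spectra) - 1) > 1e-8))
    msg <- c(msg, "spectra rows must be normalized to unit sum")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SpectraMatrix
#'
#' @param spectra non-negative matrix (fluorophores in rows, wavelengths in
#'   columns); rows are renormalized to unit sum.
#' @param wavelengths wavelengths in nm (default: evenly indexed).
#' @return A \linkS4class{SpectraMatrix}.
#' @export
SpectraMatrix <- function(spectra, wavelengths = NULL) {
  spectra <- as.matrix(spectra)
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(spectra))
  rs <- rowSums(spectra)
  if (any(rs <= 0)) stop("each spectrum must have positive total intensity")
  if (is.null(rownames(spectra)))
    rownames(spectra) <- sprintf("fluor_%d", seq_len(nrow(spectra)))
  new("SpectraMatrix", spectra = spectra / rs,
      wavelengths = as.numeric(wavelengths))
}

#' LambdaStack: a wavelength-resolved image
#'
#' @slot data 3D numeric array (rows x cols x wavelengths).
#' @slot wavelengths numeric wavelengths in nm.
#' @export
setClass("LambdaStack",
  representation(data = "array", wavelengths = "numeric"))

setValidity("LambdaStack", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3) msg <- c(msg, "data must be a 3D array")
  else if (dim(object@data)[3] != length(object@wavelengths))
    msg <- c(msg, "wavelength count mismatch")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LambdaStack
#'
#' @param data 3D array, rows x cols x wavelengths.
#' @param wavelengths wavelengths in nm.
#' @return A \linkS4class{LambdaStack}.
#' @export
LambdaStack <- function(data, wavelengths = NULL) {
  if (is.null(wavelengths)) wavelengths <- seq_len(dim(data)[3])
  new("LambdaStack", data = data, wavelengths = as.numeric(wavelengths))
}

setMethod("show", "LambdaStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("LambdaStack: %d x %d pixels, %d wavelengths (%g-%g nm)\n",
              d[1], d[2], d[3], min(object@wavelengths), max(object@wavelengths)))
})

# ---------------------------------------------------------------------------
# Decay and cosine fit results
# ---------------------------------------------------------------------------

#' DecayFit: one-phase exponential decay fit
#'
#' Model \eqn{Y = (Y_0 - Plateau) e^{-K X} + Plateau}; half-life is
#' \eqn{\ln 2 / K} in the units of the time axis.
#'
#' @slot y0 fitted initial level.
#' @slot plateau fitted asymptote.
#' @slot k decay rate constant (> 0 on success).
#' @slot halfLife ln(2)/k.
#' @slot se named standard errors (y0, plateau, k, halfLife).
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @slot extrapolated logical: TRUE when the record ends before the decline is
#'   substantially complete (more than 20\% of the fitted span remaining), so
#'   the half-life rests on the fitted curve rather than an observed plateau.
#' @slot units time units of k and halfLife ("hours" or "minutes").
#' @export
setClass("DecayFit",
  representation(y0 = "numeric", plateau = "numeric", k = "numeric",
                 halfLife = "numeric", se = "numeric", rss = "numeric",
                 converged = "logical", extrapolated = "logical",
                 units = "character"))

setValidity("DecayFit", function(object) {
  msg <- NULL
  if (object@converged && object@k <= 0) msg <- c(msg, "k must be > 0 on success")
  if (object@converged && abs(object@halfLife * object@k - log(2)) > 1e-9)
    msg <- c(msg, "halfLife * k must equal ln 2")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit: half-life %.4g %s (K = %.4g per %s)%s\n",
              object@halfLife, object@units, object@k,
              sub("s$", "", object@units),
              if (object@extrapolated) " [extrapolated]" else ""))
  cat(sprintf("  Y0 = %.4g, Plateau = %.4g, RSS = %.3g\n",
              object@y0, object@plateau, object@rss))
})

#' CosineFit: damped cosinor fit of a rhythmic trace
#'
#' Model \eqn{mesor + A e^{-d t} \cos(2\pi (t - \phi)/P)}. The relative
#' amplitude error (RAE) is the standard error of the amplitude divided by the
#' amplitude: a robustness measure approaching 0 for noiseless rhythms.
#'
#' @slot period hours.
#' @slot amplitude AU (at t = 0).
#' @slot phase hours (time of the first cosine peak, in [0, period)).
#' @slot damping per hour.
#' @slot mesor AU.
#' @slot rae dimensionless robustness measure, >= 0.
#' @slot se named standard errors.
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @export
setClass("CosineFit",
  representation(period = "numeric", amplitude = "numeric", phase = "numeric",
                 damping = "numeric", mesor = "numeric", rae = "numeric",
                 se = "numeric", rss = "numeric", converged = "logical"))

setValidity("CosineFit", function(object) {
  msg <- NULL
  if (object@period <= 0) msg <- c(msg, "period must be > 0")
  if (object@converged && object@rae < 0) msg <- c(msg, "rae must be >= 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CosineFit", function(object) {
  cat(sprintf("CosineFit: period %.3f h, amplitude %.4g, phase %.2f h, RAE %.3g\n",
              object@period, object@amplitude, object@phase, object@rae))
})
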