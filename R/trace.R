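# Trace pre-processing: background subtraction, a-trous band-pass filtering,
# forward filling, moving-average detrending, min-max normalization and
# baseline-to-peak amplitude. All operations preserve the time grid and never
# reorder points.

#' Subtract a background trace
#'
#' Pointwise subtraction of a background ROI trace recorded on the same time
#' grid (background taken outside the structure of interest). The label is
#' annotated \code{"BGS"}.
#'
#' @param trace,background \linkS4class{FluorTrace}s on matching grids.
#' @return Background-subtracted \linkS4class{FluorTrace}.
#' @export
subtractBackground <- function(trace, background) {
  stopifnot(is(trace, "FluorTrace"), is(background, "FluorTrace"))
  if (length(trace@times) != length(background@times) ||
      any(abs(trace@times - background@times) > 1e-9))
    stop("time grids do not match")
  FluorTrace(trace@times, trace@values - background@values,
             mask = trace@mask & background@mask,
             label = paste(trace@label, "BGS"))
}

# Undecimated a-trous decomposition with the B3-spline kernel (1,4,6,4,1)/16
# and mirror (whole-sample symmetric) boundaries. Returns the detail levels
# and the final smooth, which sum exactly to the input.
.atrousDecompose <- function(x, nLevels) {
  n <- length(x)
  if (n < 2^nLevels)
    stop("series too short for ", nLevels, " decomposition levels")
  kernel <- c(1, 4, 6, 4, 1) / 16
  offsets <- -2:2
  reflect <- function(i) {
    # whole-sample mirror: ... 3 2 [1 2 ... n] n-1 n-2 ...
    while (any(bad <- i < 1 | i > n)) {
      i[i < 1] <- 2 - i[i < 1]
      i[i > n] <- 2 * n - i[i > n]
    }
    i
  }
  details <- matrix(0, nrow = nLevels, ncol = n)
  smooth <- x
  idx <- seq_len(n)
  for (j in seq_len(nLevels)) {
    spacing <- 2^(j - 1)
    sm <- rep(0, n)
    for (m in seq_along(kernel))
      sm <- sm + kernel[m] * smooth[reflect(idx + offsets[m] * spacing)]
    details[j, ] <- smooth - sm
    smooth <- sm
  }
  list(details = details, smooth = smooth)
}

#' Band-pass filter a trace with the a-trous (stationary) wavelet transform
#'
#' Decomposes the trace into dyadic detail levels plus a final smooth using
#' the B3-spline kernel (1,4,6,4,1)/16 with mirror boundaries, then
#' reconstructs from the retained levels only. Because the transform is a
#' partition of the signal, keeping every level and the smooth reproduces the
#' input exactly. Level \code{j} captures structure at scales of roughly
#' \code{2^j} samples; the default retains the levels spanning 2-16 h
#' structure at the trace's sampling rate, which removes both high-frequency
#' noise and the stationary background/baseline.
#'
#' @param trace a \linkS4class{FluorTrace} on a uniform grid.
#' @param keepScales integer detail levels to retain (1 = finest). Default:
#'   levels whose dyadic scale lies in \code{scaleRange}.
#' @param nLevels total decomposition depth (default: deepest level allowed
#'   by the record length, capped at 10).
#' @param scaleRange hours, the structure band retained by the default
#'   \code{keepScales}.
#' @param keepSmooth also add back the final smooth (restores the baseline).
#' @return Filtered \linkS4class{FluorTrace}.
#' @export
atrousBandpass <- function(trace, keepScales = NULL, nLevels = NULL,
                           scaleRange = c(2, 16), keepSmooth = FALSE) {
  stopifnot(is(trace, "FluorTrace"))
  dt <- diff(trace@times)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("a-trous filtering requires a uniform time grid")
  n <- length(trace@values)
  if (is.null(nLevels)) nLevels <- min(10L, floor(log2(n)))
  dec <- .atrousDecompose(trace@values, nLevels)
  if (is.null(keepScales)) {
    scaleH <- 2^seq_len(nLevels) * mean(dt)
    keepScales <- which(scaleH >= scaleRange[1] & scaleH <= scaleRange[2])
    if (length(keepScales) == 0)
      stop("no decomposition level falls in the requested scale range")
  }
  if (any(keepScales < 1 | keepScales > nLevels))
    stop("keepScales outside the decomposition depth")
  out <- colSums(dec$details[keepScales, , drop = FALSE])
  if (keepSmooth) out <- out + dec$smooth
  FluorTrace(trace@times, out, mask = trace@mask,
             label = paste(trace@label, "bandpass"))
}

#' A-trous decomposition of a trace
#'
#' Exposes the raw decomposition used by \code{\link{atrousBandpass}}.
#'
#' @param trace a \linkS4class{FluorTrace} on a uniform grid.
#' @param nLevels decomposition depth.
#' @return List with a \code{details} matrix (one row per level) and the
#'   final \code{smooth}; their column sums reconstruct the input.
#' @export
atrousDecompose <- function(trace, nLevels) {
  stopifnot(is(trace, "FluorTrace"))
  .atrousDecompose(trace@values, nLevels)
}

#' Forward-fill missing points
#'
#' Invalid (masked or NA) points take the last valid value; the mask is
#' updated to mark them as filled-valid. The first point must be valid.
#'
#' @param trace a \linkS4class{FluorTrace}.
#' @return Gap-free \linkS4class{FluorTrace}.
#' @export
forwardFill <- function(trace) {
  stopifnot(is(trace, "FluorTrace"))
  bad <- !trace@mask | !is.finite(trace@values)
  if (bad[1]) stop("first point must be valid for forward filling")
  if (!any(bad))
    return(trace)
  v <- trace@values
  idx <- cummax(ifelse(bad, 0L, seq_along(v)))
  v <- v[idx]
  FluorTrace(trace@times, v, mask = rep(TRUE, length(v)),
             label = trace@label)
}

#' Detrend a trace with a centred moving average
#'
#' Subtracts a centred moving mean of the given window (default 24 h, the
#' standard baseline-removal for circadian bioluminescence recordings). Edges
#' use truncated (shrinking) windows so the trace keeps full length.
#'
#' @param trace a \linkS4class{FluorTrace}.
#' @param window window width in hours.
#' @return Detrended \linkS4class{FluorTrace}.
#' @export
detrendMovingAverage <- function(trace, window = 24) {
  stopifnot(is(trace, "FluorTrace"))
  if (window <= 0) stop("window must be > 0")
  t <- trace@times
  if (max(t) - min(t) < window) stop("record shorter than the window")
  v <- trace@values
  half <- window / 2
  trend <- vapply(seq_along(t), function(i) {
    sel <- t >= t[i] - half & t <= t[i] + half
    mean(v[sel])
  }, numeric(1))
  FluorTrace(t, v - trend, mask = trace@mask,
             label = paste(trace@label, "detrended"))
}

#' Min-max normalize a trace to [0, 1]
#'
#' Maps the smallest value to 0 and the largest to 1, the normalization used
#' before half-life curve fitting.
#'
#' @param trace a \linkS4class{FluorTrace}.
#' @return Normalized \linkS4class{FluorTrace}.
#' @export
normalizeMinmax <- function(trace) {
  stopifnot(is(trace, "FluorTrace"))
  v <- trace@values[trace@mask]
  rng <- range(v)
  if (rng[2] <= rng[1])
    stop("degenerate input: trace is constant, min-max normalization undefined")
  FluorTrace(trace@times, (trace@values - rng[1]) / (rng[2] - rng[1]),
             mask = trace@mask, label = paste(trace@label, "minmax"))
}

#' Baseline-to-peak amplitude as a percentage of baseline
#'
#' \eqn{100 (peak - baseline) / baseline}. The baseline defaults to the mesor
#' of a damped-cosine fit (the trace's fitted trend level), with the peak
#' taken as mesor + fitted amplitude; method \code{"mean"} falls back to the
#' trace mean with the raw maximum as peak.
#'
#' @param trace a \linkS4class{FluorTrace}.
#' @param baselineMethod "cosine" (default) or "mean".
#' @return Amplitude percentage (scalar).
#' @export
amplitudePercent <- function(trace, baselineMethod = c("cosine", "mean")) {
  stopifnot(is(trace, "FluorTrace"))
  baselineMethod <- match.arg(baselineMethod)
  if (baselineMethod == "cosine") {
    fit <- tryCatch(fitDampedCosine(trace), error = function(e) NULL)
    if (!is.null(fit) && fit@converged && fit@amplitude > 0) {
      if (fit@mesor <= 0) stop("non-positive baseline estimate")
      return(100 * fit@amplitude / fit@mesor)
    }
    baselineMethod <- "mean"
  }
  b <- mean(trace@values[trace@mask])
  if (b <= 0) stop("non-positive baseline estimate")
  100 * (max(trace@values[trace@mask]) - b) / b
}
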