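# Rhythmicity: periodogram-based period estimation, autocorrelation,
# three-way rhythm classification, damped-cosine (cosinor) fitting with a
# relative-amplitude-error robustness measure, phase mapping to circadian
# time, and cohort raster matrices.

.checkUniform <- function(times) {
  dt <- diff(times)
  if (length(dt) == 0 || max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("uniform sampling required (resample first)")
  mean(dt)
}

#' One-sided power spectrum of a trace
#'
#' Periodogram on the uniform sampling grid, after removing the mean (and,
#' optionally, a linear trend). Zero-padding (default 4x) refines the
#' frequency grid so the dominant period is not quantized to the coarse
#' Fourier bins of short records. The dominant period is the reciprocal of
#' the frequency with maximum power, excluding the zero frequency.
#'
#' @param trace a \linkS4class{FluorTrace} on a uniform grid (pre-processed:
#'   gaps filled, detrended as appropriate).
#' @param detrend "linear" (default), "mean" or "none" pre-treatment.
#' @param pad zero-padding factor (>= 1).
#' @return List with \code{frequencies} (cycles/hour), \code{power},
#'   \code{dominantPeriod} (hours).
#' @export
powerSpectrum <- function(trace, detrend = c("linear", "mean", "none"),
                          pad = 4) {
  stopifnot(is(trace, "FluorTrace"))
  detrend <- match.arg(detrend)
  dt <- .checkUniform(trace@times)
  x <- trace@values
  x <- switch(detrend,
    linear = stats::residuals(lm(x ~ trace@times)),
    mean = x - mean(x),
    none = x)
  n <- length(x)
  nfft <- ceiling(pad) * n
  X <- fft(c(x, rep(0, nfft - n)))
  k <- seq_len(floor(nfft / 2))
  freq <- k / (nfft * dt)
  power <- (Mod(X[k + 1])^2) / n
  kmax <- which.max(power)
  list(frequencies = freq, power = power,
       dominantPeriod = 1 / freq[kmax])
}

#' Autocorrelation of a trace at hour lags
#'
#' Biased-normalized autocorrelation (lag 0 = 1) evaluated at the requested
#' lags in hours, rounded to the sampling grid. A circadian trace is
#' negatively correlated at half its period (12 h) and positively at one full
#' period (24 h).
#'
#' @param trace a \linkS4class{FluorTrace} on a uniform grid.
#' @param lags numeric lags in hours.
#' @param demean subtract the mean first (default TRUE).
#' @return Named numeric vector of correlations at the requested lags.
#' @export
traceAutocorrelation <- function(trace, lags = c(12, 24), demean = TRUE) {
  stopifnot(is(trace, "FluorTrace"))
  dt <- .checkUniform(trace@times)
  n <- length(trace@values)
  kl <- as.integer(round(lags / dt))
  if (any(kl >= n)) stop("lag beyond record length")
  a <- acf(trace@values, lag.max = max(kl), plot = FALSE, demean = demean)
  out <- as.numeric(a$acf)[kl + 1]
  names(out) <- sprintf("%gh", lags)
  out
}

#' Classify the rhythmicity of a single track
#'
#' Determines the dominant spectral period of the (gap-filled, detrended)
#' trace and bins it: within \code{bounds} (closed interval, default 15-30 h)
#' = circadian; below = ultradian; above = arrhythmic (a dominant period
#' longer than the record can support is taken as absence of a resolvable
#' rhythm). Autocorrelations at half and full circadian lags are reported as
#' supporting evidence.
#'
#' @param trace a \linkS4class{FluorTrace} spanning at least 48 h.
#' @param bounds circadian period bounds in hours (closed interval).
#' @param detrend detrending applied before the periodogram (see
#'   \code{\link{powerSpectrum}}). Linear detrending removes bleaching drift
#'   without reshaping low-frequency noise into the circadian band.
#' @return List with \code{label} ("circadian", "ultradian" or "arrhythmic"),
#'   \code{dominantPeriod}, \code{acf12}, \code{acf24}.
#' @export
classifyTrack <- function(trace, bounds = c(15, 30), detrend = "linear") {
  stopifnot(is(trace, "FluorTrace"))
  span <- max(trace@times) - min(trace@times)
  if (span < 48)
    stop("record too short to classify rhythmicity (need >= 48 h, got ",
         round(span, 1), " h)")
  tr <- forwardFill(trace)
  ps <- powerSpectrum(tr, detrend = detrend)
  p <- ps$dominantPeriod
  label <- if (p < bounds[1]) "ultradian"
           else if (p <= bounds[2]) "circadian"
           else "arrhythmic"
  ac <- tryCatch(traceAutocorrelation(tr, c(12, 24)),
                 error = function(e) c(`12h` = NA_real_, `24h` = NA_real_))
  list(label = label, dominantPeriod = p,
       acf12 = unname(ac[1]), acf24 = unname(ac[2]))
}

#' Classify every member of a cohort
#'
#' @param cohort a \linkS4class{TraceCohort}.
#' @param bounds,detrend passed to \code{\link{classifyTrack}}.
#' @return List with \code{calls} (per-cell data.frame: label,
#'   dominantPeriod), \code{counts} (named vector over the three labels,
#'   summing to cohort size) and \code{periodHistogram} (hist object of
#'   dominant periods).
#' @export
classifyCohort <- function(cohort, bounds = c(15, 30), detrend = "linear") {
  stopifnot(is(cohort, "TraceCohort"))
  n <- nrow(cohort)
  if (n < 1) stop("empty cohort")
  calls <- lapply(seq_len(n), function(i)
    classifyTrack(getTrace(cohort, i), bounds = bounds, detrend = detrend))
  df <- data.frame(
    label = vapply(calls, `[[`, character(1), "label"),
    dominantPeriod = vapply(calls, `[[`, numeric(1), "dominantPeriod"),
    row.names = rownames(cohort))
  counts <- c(circadian = sum(df$label == "circadian"),
              ultradian = sum(df$label == "ultradian"),
              arrhythmic = sum(df$label == "arrhythmic"))
  h <- graphics::hist(pmin(df$dominantPeriod, 48), breaks = seq(0, 48, by = 2),
                      plot = FALSE)
  list(calls = df, counts = counts, periodHistogram = h)
}

#' Fit a damped cosine (cosinor) to a trace
#'
#' Least-squares fit of
#' \eqn{mesor + A e^{-d t} \cos(2\pi (t - \phi) / P)},
#' initialized from the power spectrum, with multiple phase starts. The
#' relative amplitude error RAE = SE(A)/A is reported as a rhythm-robustness
#' measure (0 for a noiseless rhythm).
#'
#' @param trace a \linkS4class{FluorTrace} covering >= 2 cycles of the
#'   initial period estimate.
#' @param period optional fixed initial period (hours); default from
#'   \code{\link{powerSpectrum}}.
#' @return A \linkS4class{CosineFit}.
#' @export
fitDampedCosine <- function(trace, period = NULL) {
  stopifnot(is(trace, "FluorTrace"))
  t <- trace@times
  y <- trace@values
  if (is.null(period)) {
    ps <- powerSpectrum(trace, detrend = "linear")
    period <- ps$dominantPeriod
  }
  span <- max(t) - min(t)
  if (span < 2 * period)
    stop("record covers fewer than 2 cycles of the estimated period (",
         round(period, 2), " h)")
  mesor0 <- mean(y)
  amp0 <- stats::sd(y - mesor0) * sqrt(2)
  if (amp0 == 0) stop("constant trace cannot be fit")
  best <- NULL
  for (ph0 in period * (0:3) / 4) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ mesor + A * exp(-d * t) * cos(2 * pi * (t - phase) / P),
        start = list(mesor = mesor0, A = amp0, d = 0.005,
                     phase = ph0, P = period),
        lower = c(-Inf, 0, -0.5, -Inf, period / 3),
        upper = c(Inf, Inf, 0.5, Inf, period * 3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("damped-cosine fit failed to converge (initial period ",
         round(period, 2), " h); consider detrending or a period hint")
  co <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 5))
  P <- unname(co["P"]); A <- unname(co["A"])
  phase <- unname(co["phase"]) %% P
  rae <- unname(se["A"]) / A
  if (!is.finite(rae)) rae <- 0    # zero-residual limit
  new("CosineFit", period = P, amplitude = A, phase = phase,
      damping = unname(co["d"]), mesor = unname(co["mesor"]),
      rae = rae, se = se, rss = best$rss, converged = TRUE)
}

#' Map a reporter peak time to circadian time
#'
#' Circadian time is anchored by convention on the PER2 expression peak at
#' CT12. Given the peak times of the reporter of interest and of the PER2
#' reference within the same preparation, the reporter peak maps to
#' \deqn{CT = (12 + 24 ((peak - peak_{PER2}) \bmod P)/P) \bmod 24.}
#'
#' @param peakTime peak time of the reporter (hours).
#' @param peakTimePer2 peak time of the PER2 reference (hours).
#' @param period shared circadian period (hours), > 0.
#' @return Circadian time in hours, [0, 24).
#' @examples
#' phaseToCT(19.9, 12, 24)   # a peak 7.9 h after PER2 maps to CT19.9
#' @export
phaseToCT <- function(peakTime, peakTimePer2, period = 24) {
  if (period <= 0) stop("period must be > 0")
  delta <- (peakTime - peakTimePer2) %% period
  (12 + 24 * delta / period) %% 24
}

#' Phase-sorted raster matrix of a cohort
#'
#' Min-max normalizes each member trace and orders rows by fitted peak phase
#' (damped-cosine fit, falling back to the smoothed argmax for tracks the fit
#' rejects), the layout used for population raster displays.
#'
#' @param cohort a \linkS4class{TraceCohort}.
#' @param sortBy "phase" (cosine-fitted peak time) or "argmax" (raw smoothed
#'   argmax; faster, for short records).
#' @return Numeric matrix, rows in phase order and scaled to [0, 1]; row
#'   order index in attribute \code{"order"}, phases in attribute
#'   \code{"phase"}.
#' @export
rasterMatrix <- function(cohort, sortBy = c("phase", "argmax")) {
  stopifnot(is(cohort, "TraceCohort"))
  sortBy <- match.arg(sortBy)
  mat <- SummarizedExperiment::assay(cohort, "intensity")
  tm <- cohort$time
  norm <- t(apply(mat, 1, function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0, length(v))
  }))
  phases <- vapply(seq_len(nrow(mat)), function(i) {
    if (sortBy == "phase") {
      f <- tryCatch(fitDampedCosine(getTrace(cohort, i)),
                    error = function(e) NULL)
      if (!is.null(f)) return(f@phase)
    }
    sm <- stats::filter(norm[i, ], rep(1 / 5, 5), sides = 2)
    tm[which.max(ifelse(is.na(sm), -Inf, sm))]
  }, numeric(1))
  ord <- order(phases)
  out <- norm[ord, , drop = FALSE]
  attr(out, "order") <- ord
  attr(out, "phase") <- phases[ord]
  out
}
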