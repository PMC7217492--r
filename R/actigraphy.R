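# Actigraphy: chi-square (Sokolove-Bushell) periodogram, non-parametric
# circadian rhythm analysis (intra-daily variability, inter-daily stability),
# activity onset detection and phase angle of entrainment.

.recordCounts <- function(record, bin = NULL) {
  if (is(record, "ActivityRecord")) {
    x <- record@counts
    native <- record@binMinutes
  } else {
    x <- as.numeric(record)
    native <- if (is.null(bin)) 60 else bin
  }
  list(x = x, binMinutes = native)
}

.rebin <- function(x, fromMinutes, toMinutes) {
  if (toMinutes == fromMinutes) return(x)
  if (toMinutes < fromMinutes || toMinutes %% fromMinutes != 0)
    stop("target bin must be a multiple of the native bin")
  k <- toMinutes / fromMinutes
  n <- floor(length(x) / k) * k
  colSums(matrix(x[seq_len(n)], nrow = k))
}

#' Chi-square periodogram (Sokolove-Bushell)
#'
#' For each candidate period P (an integer number of bins), folds the record
#' into its K = P/bin columns and computes
#' \eqn{Q_P = N \cdot Var(\bar{x}_h) / Var(x)}, which under temporally
#' unstructured data is distributed \eqn{\chi^2_{K-1}}; the significance line
#' is the corresponding upper quantile (default p = 0.001). The best period
#' maximizes \eqn{Q_P} among candidates exceeding their significance line.
#'
#' @param record an \linkS4class{ActivityRecord} with >= 7 days of data.
#' @param periodRange candidate period range in hours (default 20-28).
#' @param alpha significance level for the chi-square line.
#' @return List with \code{periods} (hours), \code{Qp}, \code{threshold},
#'   \code{bestPeriod} (NA when nothing exceeds the line).
#' @export
chiSquarePeriodogram <- function(record, periodRange = c(20, 28),
                                 alpha = 0.001) {
  stopifnot(is(record, "ActivityRecord"))
  x <- record@counts
  binH <- record@binMinutes / 60
  nDays <- length(x) * binH / 24
  if (nDays < 7) stop("at least 7 days of data required")
  kRange <- seq(ceiling(periodRange[1] / binH), floor(periodRange[2] / binH))
  if (length(kRange) == 0 || max(kRange) * 2 > length(x))
    stop("period range outside the data support")
  res <- vapply(kRange, function(K) {
    n <- floor(length(x) / K) * K      # whole cycles only
    xx <- x[seq_len(n)]
    colMean <- colMeans(matrix(xx, nrow = n / K, byrow = TRUE))
    qp <- n * sum((colMean - mean(xx))^2) / K /
      (sum((xx - mean(xx))^2) / n)
    c(qp = qp, thr = qchisq(1 - alpha, df = K - 1))
  }, numeric(2))
  periods <- kRange * binH
  qp <- res["qp", ]; thr <- res["thr", ]
  above <- qp > thr
  best <- if (any(above)) periods[which.max(ifelse(above, qp - thr, -Inf))]
          else NA_real_
  list(periods = periods, Qp = qp, threshold = thr, bestPeriod = best)
}

#' Intra-daily variability (IV)
#'
#' Non-parametric measure of activity fragmentation: the normalized
#' first-difference variance
#' \deqn{IV = n \sum_{i=2}^n (x_i - x_{i-1})^2 /
#'      ((n-1) \sum_i (x_i - \bar{x})^2).}
#' A smooth sinusoid scores ~0; temporally unstructured (i.i.d.) data score
#' ~2. Conventionally computed on hourly-rebinned data (\code{bin = 60});
#' pass the record's native bin to evaluate the formula without rebinning.
#'
#' @param record an \linkS4class{ActivityRecord} (>= 2 days), or a numeric
#'   vector of bin values.
#' @param bin analysis bin in minutes (default 60).
#' @return IV (dimensionless, >= 0).
#' @export
intradailyVariability <- function(record, bin = 60) {
  rc <- .recordCounts(record, bin)
  x <- .rebin(rc$x, rc$binMinutes, max(bin, rc$binMinutes))
  n <- length(x)
  if (n < 2) stop("record too short")
  denom <- sum((x - mean(x))^2)
  if (denom == 0) stop("degenerate input: record has zero variance")
  n * sum(diff(x)^2) / ((n - 1) * denom)
}

#' Inter-daily stability (IS)
#'
#' Non-parametric measure of day-to-day pattern matching:
#' \deqn{IS = n \sum_h (\bar{x}_h - \bar{x})^2 /
#'       (p \sum_i (x_i - \bar{x})^2)}
#' with \eqn{p} bins per day and \eqn{\bar{x}_h} the across-day mean profile.
#' An exactly repeating daily pattern scores 1; temporally unstructured data
#' score ~1/days (approaching 0).
#'
#' @inheritParams intradailyVariability
#' @return IS in [0, 1] for non-degenerate input.
#' @export
interdailyStability <- function(record, bin = 60) {
  rc <- .recordCounts(record, bin)
  binMinutes <- max(bin, rc$binMinutes)
  x <- .rebin(rc$x, rc$binMinutes, binMinutes)
  p <- 24 * 60 / binMinutes
  days <- floor(length(x) / p)
  if (days < 2) stop("at least 2 whole days required")
  x <- x[seq_len(days * p)]
  denom <- sum((x - mean(x))^2)
  if (denom == 0) stop("degenerate input: record has zero variance")
  hourMean <- rowMeans(matrix(x, nrow = p))
  length(x) * sum((hourMean - mean(x))^2) / (p * denom)
}

#' Per-day activity onset times
#'
#' For each day, the onset is the first bin at which the (3-bin smoothed)
#' activity crosses a fraction of that day's maximum and stays above it for a
#' dwell window. Days with no activity are flagged with NA rather than
#' fabricated.
#'
#' @param record an \linkS4class{ActivityRecord}.
#' @param threshold onset threshold as a fraction of the daily maximum.
#' @param dwell number of consecutive bins required above threshold.
#' @return Numeric vector of onset clock times (hours, [0, 24)), one per
#'   day; NA where undefined.
#' @export
activityOnset <- function(record, threshold = 0.2, dwell = 3) {
  stopifnot(is(record, "ActivityRecord"))
  perDay <- 24 * 60 / record@binMinutes
  days <- floor(length(record@counts) / perDay)
  if (days < 1) stop("at least one whole day required")
  sm <- stats::filter(record@counts, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- record@counts[is.na(sm)]
  vapply(seq_len(days), function(d) {
    idx <- ((d - 1) * perDay + 1):(d * perDay)
    day <- sm[idx]
    mx <- max(day)
    if (mx <= 0) return(NA_real_)
    above <- day >= threshold * mx
    runs <- rle(as.vector(above))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    hit <- which(runs$values & runs$lengths >= dwell)
    if (length(hit) == 0) return(NA_real_)
    binIdx <- starts[hit[1]]
    (record@startClock + (binIdx - 1) * record@binMinutes / 60) %% 24
  }, numeric(1))
}

.circularMeanHours <- function(h, modulus = 24) {
  ang <- 2 * pi * h / modulus
  (atan2(mean(sin(ang)), mean(cos(ang))) * modulus / (2 * pi)) %% modulus
}

#' Phase angle of entrainment
#'
#' Circular mean, across days, of the interval from the entraining cycle
#' marker (lights-on) to the activity onset. Onsets exactly at lights-off of
#' a 12:12 schedule therefore give 12 h. Circular averaging handles onsets
#' straddling midnight correctly.
#'
#' @param record an \linkS4class{ActivityRecord} with \code{lightsOn} set and
#'   >= 10 days of data.
#' @param threshold,dwell passed to \code{\link{activityOnset}}.
#' @return Phase angle in hours after lights-on, [0, 24).
#' @export
phaseAngle <- function(record, threshold = 0.2, dwell = 3) {
  stopifnot(is(record, "ActivityRecord"))
  if (is.na(record@lightsOn)) stop("record carries no entrainment schedule")
  perDay <- 24 * 60 / record@binMinutes
  if (floor(length(record@counts) / perDay) < 10)
    stop("phase angle requires at least 10 days of data")
  onsets <- activityOnset(record, threshold = threshold, dwell = dwell)
  onsets <- onsets[!is.na(onsets)]
  if (length(onsets) == 0) stop("no defined onsets")
  .circularMeanHours((onsets - record@lightsOn) %% 24)
}
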