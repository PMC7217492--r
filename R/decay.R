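# Half-life estimation: one-phase exponential decay fits for protein
# (translation-block time courses) and mRNA (transcription-block qPCR
# courses, via 2^-ddCt double-reference normalization).

.decayFit <- function(t, y, fixPlateau = NULL, units = "hours") {
  if (length(y) < 5) stop("at least 5 points required for a decay fit")
  t <- t - t[1]
  plateau0 <- if (is.null(fixPlateau)) min(y) else fixPlateau
  y0i <- max(y)
  # rate start from log-linear regression of the positive excess over plateau
  excess <- y - plateau0
  pos <- excess > 0.05 * (y0i - plateau0)
  k0 <- if (sum(pos) >= 2) {
    sl <- coef(lm(log(excess[pos]) ~ t[pos]))[2]
    max(-unname(sl), 1e-4)
  } else 0.1
  if (is.null(fixPlateau)) {
    fit <- minpack.lm::nlsLM(
      y ~ (Y0 - Plateau) * exp(-K * t) + Plateau,
      start = list(Y0 = y0i, Plateau = plateau0, K = k0),
      lower = c(-Inf, -Inf, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ (Y0 - fixPlateau) * exp(-K * t) + fixPlateau,
      start = list(Y0 = y0i, K = k0), lower = c(-Inf, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  co <- coef(fit)
  K <- unname(co["K"])
  if (K <= 0) stop("decay fit returned a non-positive rate")
  plateau <- if (is.null(fixPlateau)) unname(co["Plateau"]) else fixPlateau
  seTab <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                    error = function(e) NULL)
  seK <- if (!is.null(seTab)) unname(seTab["K"]) else NA_real_
  halfLife <- log(2) / K
  se <- c(y0 = if (!is.null(seTab)) unname(seTab["Y0"]) else NA_real_,
          plateau = if (!is.null(seTab) && is.null(fixPlateau))
                      unname(seTab["Plateau"]) else 0,
          k = seK,
          halfLife = log(2) / K^2 * seK)   # delta method
  # decline completeness: fraction of the fitted span still remaining at the
  # final observation; more than 20% remaining means the plateau was never
  # approached and the half-life rests on extrapolation of the fitted curve
  remaining <- exp(-K * (t[length(t)] - t[1]))
  new("DecayFit", y0 = unname(co["Y0"]), plateau = plateau, k = K,
      halfLife = halfLife, se = se, rss = sum(stats::residuals(fit)^2),
      converged = TRUE, extrapolated = remaining > 0.2, units = units)
}

#' Fit a one-phase exponential decay
#'
#' Least-squares fit of \eqn{Y = (Y_0 - Plateau) e^{-K X} + Plateau} to a
#' (typically min-max normalized) fluorescence decay course after a
#' translation block; half-life = ln(2)/K. Initialization: Plateau from the
#' minimum, Y0 from the maximum, K from a log-linear regression of the excess
#' over the plateau. The fit is scale-equivariant, so raw or normalized
#' traces give the same K. When the record ends with more than 20\% of the
#' fitted span above the plateau, the estimate is flagged
#' \code{extrapolated}: the half-life then derives from the best-fit curve
#' rather than an observed plateau.
#'
#' @param trace a \linkS4class{FluorTrace} (times in hours).
#' @param fixPlateau optionally fix the plateau (e.g. 0).
#' @return A \linkS4class{DecayFit} (units hours).
#' @examples
#' tr <- simDecayCourse(1, 0, k = log(2) / 8, samplingInterval = 0.1,
#'                      duration = 20)
#' fitOnePhaseDecay(tr)   # half-life 8 h
#' @export
fitOnePhaseDecay <- function(trace, fixPlateau = NULL) {
  stopifnot(is(trace, "FluorTrace"))
  tr <- forwardFill(trace)
  .decayFit(tr@times, tr@values, fixPlateau = fixPlateau, units = "hours")
}

#' Double-reference 2^-ddCt normalization of a qPCR time course
#'
#' For each time point, the target Ct is first normalized to the mean Ct of
#' the two reference genes (dCt), then to the baseline time point (ddCt); the
#' relative expression is \eqn{2^{-\Delta\Delta Ct}}, equal to 1 at baseline
#' by construction.
#'
#' @param course data.frame with columns \code{time}, \code{gene}, \code{Ct}.
#' @param target target gene name.
#' @param referenceGenes character vector of two reference gene names.
#' @param baselineTime baseline time point (default 0).
#' @return data.frame with \code{time} and \code{relExpression}.
#' @export
ddctNormalize <- function(course, target, referenceGenes, baselineTime = 0) {
  stopifnot(all(c("time", "gene", "Ct") %in% names(course)))
  times <- sort(unique(course$time))
  if (!baselineTime %in% times) stop("baseline time point absent from course")
  dct <- vapply(times, function(tp) {
    sub <- course[course$time == tp, ]
    ctT <- sub$Ct[sub$gene == target]
    ctR <- sub$Ct[sub$gene %in% referenceGenes]
    if (length(ctT) != 1) stop("target Ct missing at time ", tp)
    if (length(ctR) != length(referenceGenes) || anyNA(ctR))
      stop("reference Ct missing at time ", tp)
    ctT - mean(ctR)
  }, numeric(1))
  ddct <- dct - dct[times == baselineTime]
  data.frame(time = times, relExpression = 2^(-ddct))
}

#' Fit mRNA decay from a relative-expression series
#'
#' One-phase exponential decay (least squares) of a 2^-ddCt series in
#' minutes. The plateau is constrained to 0 by default, since relative
#' expression after a transcription block decays toward zero; set
#' \code{fixPlateau = NULL} to free it.
#'
#' @param relSeries data.frame with columns \code{time} (minutes) and
#'   \code{relExpression} (1 at time 0), or a \linkS4class{FluorTrace}.
#' @param fixPlateau fixed plateau (default 0); NULL to estimate it.
#' @return A \linkS4class{DecayFit} (units minutes).
#' @export
fitMrnaDecay <- function(relSeries, fixPlateau = 0) {
  if (is(relSeries, "FluorTrace")) {
    t <- relSeries@times; y <- relSeries@values
  } else {
    stopifnot(all(c("time", "relExpression") %in% names(relSeries)))
    t <- relSeries$time; y <- relSeries$relExpression
  }
  .decayFit(t, y, fixPlateau = fixPlateau, units = "minutes")
}
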