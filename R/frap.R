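# Photokinetics: FRAP double normalization, exponential-recovery fitting
# (1 or 2 mobile components + immobile fraction), small-sample model
# selection, and FLIP nuclear-loss quantification.

#' Double-normalize a FRAP curve
#'
#' Corrects for background and acquisition bleaching:
#' \eqn{(raw - bg) / (ref - bg)}, then divides by the pre-bleach mean so the
#' pre-bleach level is exactly 1. Applying the function to an
#' already-normalized curve is the identity.
#'
#' @param curve a \linkS4class{FrapCurve}.
#' @return A \linkS4class{FluorTrace} (times in seconds, 0 at bleach) whose
#'   pre-bleach mean is 1.
#' @export
normalizeFrap <- function(curve) {
  stopifnot(is(curve, "FrapCurve"))
  denom <- curve@reference - curve@background
  if (any(denom <= 0))
    stop("unbleached reference must exceed background everywhere")
  corrected <- (curve@raw - curve@background) / denom
  pre <- curve@times < 0
  preMean <- mean(corrected[pre])
  if (preMean <= 0) stop("non-positive pre-bleach level")
  FluorTrace(curve@times, corrected / preMean, label = "FRAP normalized")
}

.frapModel <- function(t, floor, amps, ks) {
  out <- rep(floor, length(t))
  for (i in seq_along(amps)) out <- out + amps[i] * (1 - exp(-ks[i] * t))
  out
}

.aicc <- function(rss, n, p) {
  # p model parameters + 1 for the error variance
  k <- p + 1
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

.fitFrapOrder <- function(t, f, order, kMin) {
  span <- max(t)
  total <- max(stats::quantile(f, 0.95) - f[1], 0.01)
  floor0 <- f[1]
  if (order == 1) {
    start <- list(fl = floor0, A1 = total, k1 = 5 / span)
    lower <- c(0, 0, kMin); upper <- c(1, 1, Inf)
    form <- f ~ fl + A1 * (1 - exp(-k1 * t))
  } else {
    start <- list(fl = floor0, A1 = total / 2, k1 = 50 / span,
                  A2 = total / 2, k2 = 2 / span)
    lower <- c(0, 0, kMin, 0, kMin); upper <- c(1, 1, Inf, 1, Inf)
    form <- f ~ fl + A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t))
  }
  fit <- minpack.lm::nlsLM(form, start = start, lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 300))
  co <- coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  list(coef = co, rss = rss,
       aicc = .aicc(rss, length(t), length(co)))
}

#' Fit the exponential FRAP recovery model
#'
#' Fits \eqn{F(t) = floor + \sum_i A_i (1 - e^{-k_i t})} to the post-bleach
#' portion of a normalized recovery. Mobile fractions are
#' \eqn{f_i = A_i / (1 - floor)}, the immobile fraction is
#' \eqn{1 - \sum f_i}, and recovery half-times are \eqn{\ln 2 / k_i}.
#' Components are ordered fast-first. Rates slower than
#' \eqn{1 / (2 \times record length)} cannot be distinguished from immobile
#' material over the record and their amplitude is folded into the immobile
#' fraction. With \code{autoReduce = TRUE} a requested 2-component model is
#' dropped to 1 component when the small-sample AIC prefers it (degenerate
#' second component).
#'
#' @param normalized a \linkS4class{FluorTrace} from
#'   \code{\link{normalizeFrap}} (pre-bleach level 1, bleach at t = 0).
#' @param modelOrder 1 or 2 mobile components.
#' @param autoReduce drop degenerate components by AICc (default TRUE).
#' @return A \linkS4class{FrapFit}.
#' @export
fitFrap <- function(normalized, modelOrder = 2, autoReduce = TRUE) {
  stopifnot(is(normalized, "FluorTrace"))
  post <- normalized@times >= 0
  t <- normalized@times[post]
  f <- normalized@values[post]
  if (length(t) < 20) stop("at least 20 post-bleach points required")
  kMin <- 1 / (2 * max(t))
  fit <- tryCatch(.fitFrapOrder(t, f, modelOrder, kMin),
                  error = function(e) NULL)
  if (is.null(fit) && modelOrder == 2) {
    # a second component with no amplitude makes the 2-component Jacobian
    # degenerate; retreat to the nested 1-component model
    fit <- tryCatch(.fitFrapOrder(t, f, 1, kMin), error = function(e) NULL)
    if (!is.null(fit)) modelOrder <- 1
  }
  if (is.null(fit)) {
    # no resolvable recovery at all: a flat post-bleach plateau
    fl <- mean(f)
    rss <- sum((f - fl)^2)
    fit <- list(coef = c(fl = fl), rss = rss,
                aicc = .aicc(rss, length(t), 1))
    modelOrder <- 1
  } else if (modelOrder == 2 && autoReduce) {
    fit1 <- tryCatch(.fitFrapOrder(t, f, 1, kMin), error = function(e) NULL)
    if (!is.null(fit1) && fit1$aicc < fit$aicc) {
      fit <- fit1
      modelOrder <- 1
    }
  }
  co <- fit$coef
  fl <- unname(co["fl"])
  amps <- unname(co[grep("^A", names(co))])
  ks <- unname(co[grep("^k", names(co))])
  # fold unresolvably slow components into the immobile fraction
  resolvable <- ks > kMin * (1 + 1e-9) | amps < 1e-9
  amps <- amps[resolvable]; ks <- ks[resolvable]
  ord <- order(-ks, -amps)       # fast first; ties broken by amplitude
  amps <- amps[ord]; ks <- ks[ord]
  bleachDepth <- 1 - fl
  if (bleachDepth <= 0) stop("no bleach depth: floor at or above pre-bleach level")
  fFast <- if (length(amps) >= 1) amps[1] / bleachDepth else 0
  fSlow <- if (length(amps) >= 2) amps[2] / bleachDepth else 0
  fractions <- c(fast = fFast, slow = fSlow,
                 immobile = max(1 - fFast - fSlow, 0))
  fractions <- fractions / sum(fractions)
  tHalf <- c(fast = if (length(ks) >= 1) log(2) / ks[1] else NA_real_,
             slow = if (length(ks) >= 2) log(2) / ks[2] else NA_real_)
  new("FrapFit", fractions = fractions, tHalf = tHalf,
      rates = c(fast = if (length(ks) >= 1) ks[1] else NA_real_,
                slow = if (length(ks) >= 2) ks[2] else NA_real_),
      amplitudes = c(fast = if (length(amps) >= 1) amps[1] else 0,
                     slow = if (length(amps) >= 2) amps[2] else 0),
      floor = fl, modelOrder = as.integer(modelOrder), rss = fit$rss,
      aicc = fit$aicc, converged = TRUE)
}

#' Select the FRAP model order by small-sample AIC
#'
#' Fits 1- and 2-component recoveries and returns the order minimizing the
#' corrected Akaike information criterion. A curve with no appreciable
#' recovery (pure noise around the floor) yields order 1 with near-zero
#' mobile amplitude.
#'
#' @param normalized a normalized recovery (see \code{\link{fitFrap}}).
#' @return Integer model order (1 or 2).
#' @export
selectFrapModel <- function(normalized) {
  stopifnot(is(normalized, "FluorTrace"))
  post <- normalized@times >= 0
  t <- normalized@times[post]
  f <- normalized@values[post]
  kMin <- 1 / (2 * max(t))
  a1 <- tryCatch(.fitFrapOrder(t, f, 1, kMin)$aicc, error = function(e) Inf)
  a2 <- tryCatch(.fitFrapOrder(t, f, 2, kMin)$aicc, error = function(e) Inf)
  if (a2 < a1) 2L else 1L
}

#' Quantify FLIP nuclear signal loss
#'
#' Background-subtracts the bleached cell's nuclear trace, normalizes to the
#' mean of the nuclei of adjacent non-bleached cells (correcting the gradual
#' whole-field bleaching caused by the long bleach protocol), scales the
#' pre-bleach level to 100\%, and reports the percentage loss at the final
#' plateau (mean of the last \code{tailFraction} of post-bleach points).
#'
#' @param nuclear \linkS4class{FluorTrace} of the bleached cell's nucleus
#'   (times in seconds, bleaching starts at t = 0).
#' @param controls list of \linkS4class{FluorTrace}s from unbleached
#'   neighbour nuclei on the same grid (>= 1).
#' @param background optional background \linkS4class{FluorTrace}.
#' @param tailFraction fraction of post-bleach points defining the plateau.
#' @return List with \code{percentLoss}, \code{normalized}
#'   (\linkS4class{FluorTrace}, percent scale) and \code{controlCount}.
#' @export
flipLoss <- function(nuclear, controls, background = NULL,
                     tailFraction = 0.1) {
  stopifnot(is(nuclear, "FluorTrace"))
  if (is(controls, "FluorTrace")) controls <- list(controls)
  if (length(controls) < 1) stop("at least one unbleached control required")
  bg <- if (is.null(background)) 0 else background@values
  nuc <- nuclear@values - bg
  ctrl <- rowMeans(vapply(controls, function(cc) {
    if (length(cc@times) != length(nuclear@times))
      stop("control grid mismatch")
    cc@values - bg
  }, numeric(length(nuclear@times))))
  if (any(ctrl <= 0)) stop("control signal must stay positive")
  norm <- nuc / ctrl
  pre <- nuclear@times < 0
  if (!any(pre)) stop("no pre-bleach frames (times < 0)")
  norm <- 100 * norm / mean(norm[pre])
  post <- which(nuclear@times >= 0)
  tail <- post[post >= post[length(post)] -
                 max(ceiling(length(post) * tailFraction), 3) + 1]
  list(percentLoss = 100 - mean(norm[tail]),
       normalized = FluorTrace(nuclear@times, norm, label = "FLIP normalized"),
       controlCount = length(controls))
}
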