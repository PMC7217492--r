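# Fluorescence correlation spectroscopy: the one-component triplet-state 3D
# diffusion model, curve averaging, weighted fitting, and conversion of the
# fitted particle number into diffusion coefficient, molar concentration and
# molecules per nucleus with propagated uncertainty.

#' One-component triplet-state diffusion autocorrelation model
#'
#' For a single species diffusing through a 3D Gaussian observation volume
#' with a triplet (dark-state) term:
#' \deqn{G(\tau) = 1 + \frac{1}{N}
#'   \left(1 + \frac{T e^{-\tau/\tau_T}}{1 - T}\right)
#'   \left(1 + \frac{\tau}{\tau_D}\right)^{-1}
#'   \left(1 + \frac{\tau}{S^2 \tau_D}\right)^{-1/2}}
#'
#' @param lag lag time(s) in seconds.
#' @param N mean molecules in the effective volume, > 0.
#' @param tauD diffusion time, seconds, > 0.
#' @param T triplet fraction in [0, 1).
#' @param tauT triplet relaxation time, seconds.
#' @param beam a \linkS4class{BeamGeometry} (supplies the structure
#'   parameter S).
#' @return G values, same length as \code{lag}.
#' @examples
#' fcsModel(1e-6, N = 2, tauD = 1e-3, T = 0)   # ~ 1 + 1/2
#' @export
fcsModel <- function(lag, N, tauD, T = 0, tauT = 5e-6, beam = BeamGeometry()) {
  if (N <= 0) stop("N must be > 0")
  if (tauD <= 0) stop("tauD must be > 0")
  if (T < 0 || T >= 1) stop("triplet fraction T must be in [0, 1)")
  S <- beam@S
  triplet <- if (T > 0) 1 + T * exp(-lag / tauT) / (1 - T) else rep(1, length(lag))
  1 + (1 / N) * triplet * (1 + lag / tauD)^(-1) *
    (1 + lag / (S^2 * tauD))^(-0.5)
}

#' Average repeated FCS runs
#'
#' Pointwise mean of autocorrelation curves recorded on identical lag grids
#' (e.g. 5 runs of 5 s per cell); run counts accumulate.
#'
#' @param curves list of \linkS4class{FcsCurve}s (or a single curve).
#' @return An \linkS4class{FcsCurve}.
#' @export
averageRuns <- function(curves) {
  if (is(curves, "FcsCurve")) return(curves)
  stopifnot(length(curves) >= 1, all(vapply(curves, is, logical(1), "FcsCurve")))
  lags <- curves[[1]]@lags
  for (cc in curves)
    if (length(cc@lags) != length(lags) ||
        any(abs(cc@lags - lags) > 1e-12 * lags))
      stop("lag grids do not match")
  G <- rowMeans(vapply(curves, slot, numeric(length(lags)), "G"))
  FcsCurve(lags, G, runCount = sum(vapply(curves, slot, integer(1), "runCount")))
}

#' Fit the triplet-state diffusion model to an autocorrelation curve
#'
#' Weighted least squares over the (log-spaced) lag grid; by default each
#' point is weighted inversely to the local lag-bin density so every decade
#' of lag contributes equally, mimicking hardware-correlator binning. Reports
#' the fitted (N, tauD, T, tauT) with the derived diffusion coefficient
#' \eqn{D = \omega_0^2 / (4 \tau_D)} and concentration
#' \eqn{C = N / (N_A V_{eff})}, plus the fit-deviation (residual) series.
#'
#' @param curve an \linkS4class{FcsCurve} whose lags span at least ~3 decades
#'   around the diffusion time.
#' @param beam a \linkS4class{BeamGeometry}.
#' @param fitTriplet estimate the triplet term (default TRUE); when FALSE, T
#'   is fixed at 0.
#' @param weights optional per-point weights; default uniform per decade.
#' @return An \linkS4class{FcsFit}.
#' @export
fitFcs <- function(curve, beam = BeamGeometry(), fitTriplet = TRUE,
                   weights = NULL) {
  stopifnot(is(curve, "FcsCurve"), is(beam, "BeamGeometry"))
  lag <- curve@lags
  G <- curve@G
  if (log10(max(lag) / min(lag)) < 3)
    stop("lag grid must span at least 3 decades")
  if (is.null(weights)) {
    # inverse local density on the log-lag axis
    dl <- diff(log(lag))
    weights <- c(dl[1], (dl[-length(dl)] + dl[-1]) / 2, dl[length(dl)])
    weights <- weights / mean(weights)
  }
  amp0 <- max(G[1] - 1, 1e-6)
  N0 <- 1 / amp0
  # diffusion-time start: lag where the decay reaches half its amplitude
  half <- which(G - 1 <= amp0 / 2)
  tauD0 <- if (length(half)) lag[half[1]] else stats::median(lag)
  if (fitTriplet) {
    # a vanishing triplet fraction makes tauT unidentifiable; fall back to
    # the nested T = 0 model when the full fit degenerates
    fit <- tryCatch(
      minpack.lm::nlsLM(
        G ~ fcsModel(lag, N, tauD, T, tauT, beam),
        start = list(N = N0, tauD = tauD0, T = 0.1, tauT = 5e-6),
        lower = c(1e-6, min(lag), 0, min(lag) / 10),
        upper = c(Inf, max(lag), 0.8, tauD0),
        weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit))
      return(fitFcs(curve, beam, fitTriplet = FALSE, weights = weights))
  } else {
    fit <- minpack.lm::nlsLM(
      G ~ fcsModel(lag, N, tauD, T = 0, beam = beam),
      start = list(N = N0, tauD = tauD0),
      lower = c(1e-6, min(lag)), upper = c(Inf, max(lag)),
      weights = weights,
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  co <- coef(fit)
  N <- unname(co["N"]); tauD <- unname(co["tauD"])
  Tfrac <- if (fitTriplet) unname(co["T"]) else 0
  tauT <- if (fitTriplet) unname(co["tauT"]) else 0
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(co)),
                                                    names(co)))
  new("FcsFit", N = N, tauD = tauD, T = Tfrac, tauT = tauT,
      D = beam@omega0^2 / (4 * tauD),
      concNM = fcsConcentration(N, beam), beam = beam, se = se,
      residuals = G - fcsModel(lag, N, tauD, Tfrac,
                               if (fitTriplet) tauT else 5e-6, beam),
      rss = sum(stats::residuals(fit)^2), converged = TRUE)
}

#' Convert a particle number to molar concentration
#'
#' \eqn{C = N / (N_A V_{eff})} with
#' \eqn{V_{eff} = \pi^{3/2} \omega_0^3 S}, reported in nM.
#'
#' @param N mean molecules in the effective volume, > 0.
#' @param beam a \linkS4class{BeamGeometry}, or a numeric effective volume
#'   in fL.
#' @return Concentration in nM.
#' @examples
#' fcsConcentration(1.845, beam = 0.300)   # ~10.2 nM
#' @export
fcsConcentration <- function(N, beam = BeamGeometry()) {
  if (any(N <= 0)) stop("N must be > 0")
  veffFL <- if (is.numeric(beam)) beam else effectiveVolume(beam)
  molar <- N / (.AVOGADRO * veffFL * 1e-15)   # fL -> L
  molar * 1e9
}

#' Molecules per nucleus from concentration and nuclear volume
#'
#' \eqn{count = C \cdot V \cdot N_A} with C in nM and V in fL.
#'
#' @param concentrationNM concentration, nM.
#' @param volumeFL nuclear volume, fL.
#' @param round round to an integer for reporting (default FALSE).
#' @return Molecule count (sub-unity values allowed when \code{round} is
#'   FALSE).
#' @examples
#' moleculesPerNucleus(10.2, 147)   # ~900 molecules
#' @export
moleculesPerNucleus <- function(concentrationNM, volumeFL, round = FALSE) {
  if (any(concentrationNM < 0) || any(volumeFL < 0)) stop("inputs must be >= 0")
  count <- concentrationNM * 1e-9 * volumeFL * 1e-15 * .AVOGADRO
  if (round) base::round(count) else count
}

#' Propagated standard deviation of a product of two measured means
#'
#' For a product \eqn{\bar{x}_A \bar{x}_B} of independently measured
#' quantities, the first-order propagated SD is
#' \eqn{\sqrt{\bar{x}_A^2 SD_B^2 + \bar{x}_B^2 SD_A^2}}. The raw radicand is
#' attached as attribute \code{"radicand"}.
#'
#' @param meanA,sdA mean and SD of the first factor.
#' @param meanB,sdB mean and SD of the second factor.
#' @return Propagated SD (numeric, with attribute \code{"radicand"}).
#' @export
propagateSD <- function(meanA, sdA, meanB, sdB) {
  if (any(c(sdA, sdB) < 0)) stop("SDs must be non-negative")
  radicand <- meanA^2 * sdB^2 + meanB^2 * sdA^2
  out <- sqrt(radicand)
  attr(out, "radicand") <- radicand
  out
}

#' Nuclear volume from a voxel mask
#'
#' Voxel count times voxel volume, in femtolitres (1 um^3 = 1 fL).
#'
#' @param mask logical/0-1 voxel array.
#' @param voxelDims voxel dimensions in micrometres (length 3); defaults to
#'   the \code{"voxelDims"} attribute of masks built by
#'   \code{\link{simNuclearMask}}.
#' @return Volume in fL.
#' @export
nuclearVolume <- function(mask, voxelDims = attr(mask, "voxelDims")) {
  if (is.null(voxelDims)) stop("voxel dimensions required")
  if (sum(mask) == 0) stop("empty mask")
  sum(mask) * prod(voxelDims)
}
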