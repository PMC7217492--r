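# Image-level quantification: Manders colocalization coefficients,
# nuclear:cytoplasmic intensity ratio, percent object colocalization, and
# per-pixel spectral linear unmixing.

#' Manders colocalization coefficients
#'
#' \eqn{M_1} is the fraction of channel-A intensity residing in pixels where
#' channel B exceeds its threshold; \eqn{M_2} is the symmetric quantity for B
#' over A-positive pixels. Thresholds default to Otsu's method on the
#' respective channel.
#'
#' @param channelA,channelB numeric matrices of identical shape.
#' @param thresholdB,thresholdA intensity thresholds; NULL for Otsu.
#' @return Named numeric \code{c(M1, M2)}, each in [0, 1].
#' @export
mandersCoefficient <- function(channelA, channelB, thresholdB = NULL,
                               thresholdA = NULL) {
  if (!all(dim(channelA) == dim(channelB)))
    stop("channel shapes differ")
  if (is.null(thresholdB)) thresholdB <- .otsuThreshold(channelB)
  if (is.null(thresholdA)) thresholdA <- .otsuThreshold(channelA)
  sumA <- sum(channelA)
  sumB <- sum(channelB)
  if (sumA == 0) stop("channel A carries no intensity; M1 undefined")
  if (sumB == 0) stop("channel B carries no intensity; M2 undefined")
  c(M1 = sum(channelA[channelB > thresholdB]) / sumA,
    M2 = sum(channelB[channelA > thresholdA]) / sumB)
}

.otsuThreshold <- function(img) {
  r <- range(img)
  if (r[2] <= r[1]) return(r[1])
  scaled <- (img - r[1]) / (r[2] - r[1])
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  thr * (r[2] - r[1]) + r[1]
}

#' Nuclear:cytoplasmic intensity ratio
#'
#' Mean intensity inside the nuclear mask divided by the mean intensity
#' inside the cytoplasmic mask; invariant to multiplicative gain.
#'
#' @param image numeric matrix.
#' @param nuclearMask,cytoplasmMask logical matrices, disjoint, non-empty.
#' @return Scalar ratio.
#' @export
ncRatio <- function(image, nuclearMask, cytoplasmMask) {
  if (!all(dim(image) == dim(nuclearMask)) ||
      !all(dim(image) == dim(cytoplasmMask)))
    stop("mask shapes differ from the image")
  if (!any(nuclearMask) || !any(cytoplasmMask)) stop("empty mask")
  if (any(nuclearMask & cytoplasmMask)) stop("masks must be disjoint")
  mean(image[nuclearMask]) / mean(image[cytoplasmMask])
}

#' Percentage of objects colocalizing across channels
#'
#' Builds the A-and-B coincidence channel (pixels positive in both label
#' masks) and reports the percentage of B objects whose footprint meets the
#' overlap rule: either at least half of the object's area covered by the
#' coincidence channel (\code{"half_area"}, the default, emulating
#' nucleus-counting on the conjunction image) or any coincident pixel
#' (\code{"any_pixel"}).
#'
#' @param objectsA,objectsB integer label masks (0 = background, positive
#'   integers label objects).
#' @param overlapRule "half_area" or "any_pixel".
#' @return Percentage in [0, 100].
#' @export
percentColocalized <- function(objectsA, objectsB,
                               overlapRule = c("half_area", "any_pixel")) {
  overlapRule <- match.arg(overlapRule)
  if (!all(dim(objectsA) == dim(objectsB))) stop("mask shapes differ")
  labs <- setdiff(unique(as.vector(objectsB)), 0)
  if (length(labs) == 0) stop("no objects in channel B")
  both <- objectsA > 0 & objectsB > 0
  hit <- vapply(labs, function(l) {
    foot <- objectsB == l
    frac <- sum(both & foot) / sum(foot)
    if (overlapRule == "half_area") frac >= 0.5 else frac > 0
  }, logical(1))
  100 * sum(hit) / length(labs)
}

#' Spectral linear unmixing of a lambda stack
#'
#' Solves, per pixel, the (non-negative) least-squares problem
#' \eqn{\min_a \|S^T a - y\|^2} where the rows of S are the reference
#' emission spectra and y is the pixel's recorded spectrum, yielding one
#' abundance map per fluorophore plus a residual map. With linearly
#' independent spectra and a noiseless stack the recovery is exact; with
#' orthogonal spectra the constrained and unconstrained solutions coincide.
#'
#' @param stack a \linkS4class{LambdaStack}.
#' @param spectra a \linkS4class{SpectraMatrix}; wavelength grids must match.
#' @param nonneg constrain abundances to be non-negative (default TRUE).
#' @return List with \code{abundance} (rows x cols x fluorophores array) and
#'   \code{residual} (rows x cols matrix of residual norms).
#' @export
linearUnmix <- function(stack, spectra, nonneg = TRUE) {
  stopifnot(is(stack, "LambdaStack"), is(spectra, "SpectraMatrix"))
  if (length(stack@wavelengths) != length(spectra@wavelengths) ||
      any(abs(stack@wavelengths - spectra@wavelengths) > 1e-9))
    stop("wavelength grids do not match")
  S <- spectra@spectra                     # F x W
  nf <- nrow(S); nw <- ncol(S)
  if (nw < nf) stop("need at least as many wavelengths as fluorophores")
  if (qr(S)$rank < nf) stop("reference spectra are rank deficient")
  d <- dim(stack@data)
  Y <- matrix(stack@data, ncol = nw)       # pixels x W
  A <- t(S)                                # W x F design matrix
  if (nonneg) {
    ab <- t(apply(Y, 1, function(y) pracma::lsqnonneg(A, y)$x))
  } else {
    ab <- t(qr.coef(qr(A), t(Y)))
  }
  fitted <- ab %*% S
  res <- sqrt(rowSums((Y - fitted)^2))
  dimnames(ab) <- NULL
  list(abundance = array(ab, dim = c(d[1], d[2], nf)),
       residual = matrix(res, nrow = d[1], ncol = d[2]))
}
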