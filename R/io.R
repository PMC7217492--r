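# Plain-text and TIFF input/output for the containers the analysis consumes.

#' Read a delimited trace table
#'
#' Expects columns \code{time} and \code{value}, with an optional logical
#' \code{mask} column.
#'
#' @param path file path (CSV/TSV; delimiter auto-detected by
#'   \code{\link[utils]{read.table}} rules via \code{sep}).
#' @param sep field separator (default comma).
#' @return A \linkS4class{FluorTrace}.
#' @export
readTraceTable <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  stopifnot(all(c("time", "value") %in% names(df)))
  FluorTrace(df$time, df$value,
             mask = if ("mask" %in% names(df)) as.logical(df$mask) else NULL,
             label = basename(path))
}

#' Write a trace as a delimited table
#'
#' @param trace a \linkS4class{FluorTrace}.
#' @param path destination file.
#' @param sep field separator.
#' @return Invisibly, \code{path}.
#' @export
writeTraceTable <- function(trace, path, sep = ",") {
  stopifnot(is(trace, "FluorTrace"))
  utils::write.table(
    data.frame(time = trace@times, value = trace@values, mask = trace@mask),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an FCS autocorrelation table
#'
#' Expects columns \code{lag_s} and \code{G}.
#'
#' @param path file path.
#' @param sep field separator.
#' @return An \linkS4class{FcsCurve}.
#' @export
readFcsTable <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  stopifnot(all(c("lag_s", "G") %in% names(df)))
  FcsCurve(df$lag_s, df$G)
}

#' Read a lambda stack from a multi-page TIFF
#'
#' Each TIFF page is one wavelength plane.
#'
#' @param path TIFF file.
#' @param wavelengths optional wavelength vector (nm).
#' @return A \linkS4class{LambdaStack}.
#' @export
readLambdaStack <- function(path, wavelengths = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(pages)
  LambdaStack(arr, wavelengths)
}

#' Write a lambda stack to a multi-page TIFF
#'
#' Intensities are rescaled to [0, 1] for storage; the scale factor is
#' returned invisibly.
#'
#' @param stack a \linkS4class{LambdaStack}.
#' @param path destination TIFF.
#' @return Invisibly, the scale factor applied.
#' @export
writeLambdaStack <- function(stack, path) {
  stopifnot(is(stack, "LambdaStack"))
  mx <- max(stack@data)
  scale <- if (mx > 0) mx else 1
  planes <- lapply(seq_len(dim(stack@data)[3]),
                   function(k) stack@data[, , k] / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  invisible(scale)
}
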