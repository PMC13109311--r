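## Spectral preprocessing. All three transforms are fit-free (nothing is
## learned from the calibration set), preserve the band count, and are
## applied per spectrum, so they can be applied before or after sample
## splitting without leakage and band-selection indices keep their
## meaning across the combination grid.

#' Centered moving-average (boxcar) smoothing
#'
#' At the spectrum edges the window shrinks to the available bands; no
#' padding values are invented.
#'
#' @param x numeric spectrum, or an n x B matrix (rows smoothed
#'   independently).
#' @param window odd window width in bands (default 5, narrow enough to
#'   keep pigment troughs distinct at ~2.4 nm sampling).
#' @return Smoothed spectrum/matrix, same shape as `x`.
#' @examples
#' movingAverage(c(0, 3, 0, 3, 0), window = 3)
#' @export
movingAverage <- function(x, window = 5L) {
  window <- .assertCount(window, "window")
  if (window %% 2L == 0L) stop("window must be odd")
  if (is.matrix(x))
    return(t(apply(x, 1, movingAverage, window = window)))
  B <- length(x)
  if (window > B) stop("window exceeds band count")
  h <- (window - 1L) %/% 2L
  ## cumulative-sum boxcar with shrinking edge windows
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(B) - h, 1L)
  hi <- pmin(seq_len(B) + h, B)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Standard normal variate transform
#'
#' Per-spectrum standardization to mean 0 and unit standard deviation
#' (sample sd, `n - 1` denominator, used consistently package-wide).
#' Removes additive offsets and multiplicative scatter: any positive
#' affine map of a spectrum has the same SNV transform.
#'
#' @param x numeric spectrum (>= 2 bands, non-constant), or an n x B
#'   matrix.
#' @return Transformed spectrum/matrix.
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
    if (any(sdv == 0)) stop("zero-variance spectrum: SNV undefined")
    return((x - mu) / sdv)
  }
  if (length(x) < 2L) stop("SNV needs at least 2 bands")
  sdv <- stats::sd(x)
  if (sdv == 0) stop("zero-variance spectrum: SNV undefined")
  (x - mean(x)) / sdv
}

#' First derivative with respect to wavelength
#'
#' Central differences on interior bands, one-sided differences at the
#' ends, each divided by the local wavelength spacing. Exact for affine
#' spectra (constant output) and, on interior bands, for quadratics.
#'
#' @param x numeric spectrum (>= 3 bands), or an n x B matrix.
#' @param wavelengths strictly increasing wavelength axis (nm).
#' @return Derivative spectrum/matrix (reflectance per nm), same length.
#' @export
firstDerivative <- function(x, wavelengths) {
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (is.matrix(x)) {
    if (ncol(x) != length(wavelengths))
      stop("ncol(x) must match wavelengths")
    return(t(apply(x, 1, firstDerivative, wavelengths = wavelengths)))
  }
  B <- length(x)
  if (B < 3L) stop("first derivative needs at least 3 bands")
  d <- numeric(B)
  i <- 2:(B - 1L)
  d[i] <- (x[i + 1L] - x[i - 1L]) / (wavelengths[i + 1L] - wavelengths[i - 1L])
  d[1L] <- (x[2L] - x[1L]) / (wavelengths[2L] - wavelengths[1L])
  d[B] <- (x[B] - x[B - 1L]) / (wavelengths[B] - wavelengths[B - 1L])
  d
}

#' Preprocessing specification and application
#'
#' @param method `"none"`, `"MA"`, `"SNV"` or `"D1"`.
#' @param window odd moving-average window (MA only).
#' @return `prepSpec`: a list of class `prepSpec`; `applyPrep`: the
#'   preprocessed matrix (band count preserved).
#' @export
prepSpec <- function(method = c("none", "MA", "SNV", "D1"), window = 5L) {
  method <- match.arg(method)
  if (method == "MA") window <- .assertCount(window, "window")
  structure(list(method = method, window = window), class = "prepSpec")
}

#' @rdname prepSpec
#' @param X n x B spectra matrix.
#' @param spec a [prepSpec()].
#' @param wavelengths wavelength axis (required for D1).
#' @export
applyPrep <- function(X, spec, wavelengths = NULL) {
  stopifnot(inherits(spec, "prepSpec"))
  X <- as.matrix(X)
  switch(spec$method,
         none = X,
         MA = movingAverage(X, spec$window),
         SNV = snv(X),
         D1 = {
           if (is.null(wavelengths))
             stop("D1 preprocessing needs the wavelength axis")
           firstDerivative(X, wavelengths)
         })
}
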