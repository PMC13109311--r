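## Cube calibration, canopy segmentation and spectral extraction.

## Reduce a white/dark reference to a per-band vector. Push-broom systems
## record reference cubes; averaging over the spatial dims gives the
## per-band reference level.
.refVector <- function(ref, B) {
  if (is(ref, "HyperCube")) ref <- cubeData(ref)
  if (is.array(ref) && length(dim(ref)) == 3L)
    ref <- apply(ref, 3, mean)
  ref <- as.numeric(ref)
  if (length(ref) == 1L) ref <- rep(ref, B)
  if (length(ref) != B)
    stop(sprintf("reference has %d bands, cube has %d", length(ref), B))
  ref
}

#' White/dark reference reflectance calibration
#'
#' Converts raw sensor counts to reflectance per band:
#' `R = (R_raw - R_dark) / (R_white - R_dark)`, the standard black/white
#' plate correction that removes illumination non-uniformity and dark
#' current.
#'
#' @param raw a [HyperCube-class] with `kind = "raw"`.
#' @param white,dark white (high-reflectance plate) and dark
#'   (shutter-closed) references: per-band vectors, scalars, or full
#'   reference cubes (reduced by spatial mean).
#' @return A reflectance [HyperCube-class].
#' @details Bands where `white <= dark` make the formula meaningless and
#'   raise an error naming the offending band, rather than being
#'   silently clamped.
#' @export
calibrateReflectance <- function(raw, white, dark) {
  stopifnot(is(raw, "HyperCube"))
  if (cubeKind(raw) != "raw")
    stop("cube is already calibrated (kind != 'raw')")
  d <- dim(cubeData(raw))
  B <- d[3L]
  w <- .refVector(white, B)
  k <- .refVector(dark, B)
  bad <- which(w <= k)
  if (length(bad))
    stop(sprintf("white <= dark at band(s) %s (%.2f nm ...)",
                 paste(utils::head(bad, 5), collapse = ","),
                 wavelengths(raw)[bad[1L]]))
  x <- cubeData(raw)
  denom <- w - k
  for (b in seq_len(B)) x[, , b] <- (x[, , b] - k[b]) / denom[b]
  HyperCube(x, wavelengths(raw), kind = "reflectance")
}

## Otsu's threshold on a numeric matrix: the cut maximizing between-class
## variance over a 256-bin histogram of the value range.
.otsuThreshold <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  muT <- mu1[nbins]
  sb <- (muT * w1 - mu1)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- -Inf
  ## with an empty gap between modes the criterion plateaus; take the
  ## plateau midpoint so the cut sits centrally in the gap
  best <- which(sb >= max(sb) - 1e-12)
  mids[best[ceiling(length(best) / 2)]]
}

#' Segment the canopy from the background
#'
#' Thresholds the grayscale image of the band nearest `band_nm`
#' (default 748.76 nm, on the NIR plateau where vegetation/background
#' contrast is maximal). By default the cut is chosen by Otsu's method;
#' a fixed `threshold` can be supplied instead for reproducible fixed-cut
#' workflows. Foreground is the high-reflectance side.
#'
#' @param cube a reflectance [HyperCube-class].
#' @param band_nm wavelength (nm) of the segmentation band; the nearest
#'   grid band is used.
#' @param threshold optional fixed threshold overriding Otsu.
#' @return H x W logical mask with attribute `provenance`: a list with
#'   the threshold used, the requested and actual band wavelengths, and
#'   the band index. An empty (or full) foreground raises a warning but
#'   the mask is still returned.
#' @export
segmentCanopy <- function(cube, band_nm = 748.76, threshold = NULL) {
  stopifnot(is(cube, "HyperCube"))
  wl <- wavelengths(cube)
  if (band_nm < min(wl) || band_nm > max(wl))
    stop("band_nm outside the cube's wavelength range")
  b <- .nearestBand(wl, band_nm)
  img <- cubeData(cube)[, , b]
  thr <- if (is.null(threshold)) .otsuThreshold(img) else threshold
  mask <- img > thr
  if (all(mask) || !any(mask))
    warning("degenerate segmentation: foreground is empty or full-frame")
  attr(mask, "provenance") <- list(threshold = thr, band_nm = band_nm,
                                   band_wavelength = wl[b], band_index = b,
                                   method = if (is.null(threshold)) "otsu"
                                            else "fixed")
  mask
}

#' Mean spectrum over a pixel selection
#'
#' Per-band arithmetic mean of all selected pixels, the standard
#' ROI/mask spectral-extraction step.
#'
#' @param cube a [HyperCube-class].
#' @param pixels an H x W logical mask, or a 2-column (row, col) index
#'   matrix, or a vector of linear pixel indices into the H x W frame.
#' @return Numeric length-B mean spectrum.
#' @export
meanSpectrum <- function(cube, pixels) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cubeData(cube))
  idx <- if (is.logical(pixels)) {
    if (!identical(dim(pixels), d[1:2]))
      stop("mask shape does not match the cube")
    which(pixels)
  } else if (is.matrix(pixels) && ncol(pixels) == 2L) {
    if (any(pixels[, 1] < 1 | pixels[, 1] > d[1] |
            pixels[, 2] < 1 | pixels[, 2] > d[2]))
      stop("pixel indices outside the frame")
    (pixels[, 2] - 1L) * d[1L] + pixels[, 1L]
  } else {
    as.integer(pixels)
  }
  if (!length(idx)) stop("empty pixel selection")
  X <- matrix(cubeData(cube), d[1L] * d[2L], d[3L])
  colMeans(X[idx, , drop = FALSE])
}

#' Extract the pixel-spectra matrix for a selection
#'
#' @inheritParams meanSpectrum
#' @return n_pixels x B matrix of spectra (row order follows the linear
#'   index order of the selection).
#' @export
pixelSpectra <- function(cube, pixels) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cubeData(cube))
  idx <- if (is.logical(pixels)) which(pixels) else as.integer(pixels)
  if (!length(idx)) stop("empty pixel selection")
  X <- matrix(cubeData(cube), d[1L] * d[2L], d[3L])
  X[idx, , drop = FALSE]
}

#' Write a mask as a PNG with a JSON provenance sidecar
#'
#' @param mask logical matrix (as from [segmentCanopy()]).
#' @param path output PNG path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  prov <- attr(mask, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
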