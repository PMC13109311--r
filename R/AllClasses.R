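#' @include AllGenerics.R
NULL

#' HyperCube: a hyperspectral image stack
#'
#' An H x W x B array of per-pixel spectra together with its wavelength
#' axis. `kind` records whether values are raw sensor counts ("raw") or
#' calibrated reflectance ("reflectance"); [calibrateReflectance()] converts
#' the former into the latter using white/dark references.
#'
#' @slot data numeric array, height x width x bands.
#' @slot wavelengths numeric vector of band-centre wavelengths (nm),
#'   strictly increasing, length equal to `dim(data)[3]`.
#' @slot kind `"raw"` or `"reflectance"`.
#'
#' @seealso [calibrateReflectance()], [segmentCanopy()], [meanSpectrum()],
#'   [readENVI()]
#' @export
setClass("HyperCube",
  representation(data = "array", wavelengths = "numeric", kind = "character"))

setValidity("HyperCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-dimensional (H x W x B) array")
  if (length(object@wavelengths) != d[3L])
    return(sprintf("wavelength length (%d) != band count (%d)",
                   length(object@wavelengths), d[3L]))
  if (any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (!(object@kind %in% c("raw", "reflectance")))
    return("kind must be 'raw' or 'reflectance'")
  TRUE
})

#' Construct a HyperCube
#'
#' @param data H x W x B numeric array.
#' @param wavelengths length-B wavelength axis (nm), strictly increasing.
#' @param kind `"raw"` (sensor counts) or `"reflectance"`.
#' @return A [HyperCube-class] object.
#' @examples
#' cube <- HyperCube(array(runif(4 * 4 * 5), c(4, 4, 5)),
#'                   wavelengths = seq(400, 800, length.out = 5),
#'                   kind = "reflectance")
#' dim(cubeData(cube))
#' @export
HyperCube <- function(data, wavelengths, kind = c("reflectance", "raw")) {
  kind <- match.arg(kind)
  new("HyperCube", data = data, wavelengths = as.numeric(wavelengths),
      kind = kind)
}

#' @describeIn HyperCube the raw H x W x B array.
#' @param x a `HyperCube`.
#' @aliases cubeData cubeKind
#' @name cubeData
#' @export
setMethod("cubeData", "HyperCube", function(x) x@data)

#' @describeIn HyperCube `"raw"` or `"reflectance"`.
#' @export
setMethod("cubeKind", "HyperCube", function(x) x@kind)

#' @export
setMethod("wavelengths", "HyperCube", function(x) x@wavelengths)

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube: %d x %d pixels, %d bands (%.1f-%.1f nm), kind=%s\n",
              d[1L], d[2L], d[3L], min(object@wavelengths),
              max(object@wavelengths), object@kind))
})

#' SpectraSet: per-sample spectra with pigment targets
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding one
#' reflectance spectrum per sample (assay `"reflectance"`, bands in rows,
#' samples in columns), the wavelength axis in `rowData(x)$wavelength`, and
#' measured or simulated pigment targets (chla, chlb, car, tpc; mg/g) in
#' `colData`. Synthetic batches additionally record the generator's
#' causally informative band indices in `metadata(x)$truth_bands`.
#'
#' Chemometric code works with samples-in-rows matrices; use
#' [spectraMatrix()] for that orientation.
#'
#' @seealso [simulateLeafSpectra()], [spectraMatrix()], [pigments()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

#' Construct a SpectraSet
#'
#' @param spectra n x B matrix, one spectrum per row.
#' @param wavelengths length-B wavelength axis (nm).
#' @param pigments optional n x 4 matrix or data.frame with columns
#'   chla, chlb, car, tpc (mg/g).
#' @param truthBands optional integer vector of informative band indices.
#' @return A [SpectraSet-class].
#' @export
SpectraSet <- function(spectra, wavelengths, pigments = NULL,
                       truthBands = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths))
    stop("ncol(spectra) must equal length(wavelengths)")
  if (is.null(rownames(spectra)))
    rownames(spectra) <- sprintf("sample_%03d", seq_len(nrow(spectra)))
  cd <- S4Vectors::DataFrame(row.names = rownames(spectra))
  if (!is.null(pigments)) {
    pigments <- as.data.frame(pigments)
    stopifnot(all(c("chla", "chlb", "car", "tpc") %in% colnames(pigments)))
    cd <- S4Vectors::DataFrame(pigments[, c("chla", "chlb", "car", "tpc")],
                               row.names = rownames(spectra))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = t(spectra)),
    rowData = S4Vectors::DataFrame(wavelength = as.numeric(wavelengths)),
    colData = cd)
  S4Vectors::metadata(se)$truth_bands <- truthBands
  new("SpectraSet", se)
}

#' Accessors for SpectraSet
#'
#' `spectraMatrix` returns the n x B samples-in-rows reflectance matrix;
#' `pigments` the n x 4 target matrix (or NULL); `truthBands` the
#' generator's informative band indices (or NULL).
#'
#' @param x a [SpectraSet-class].
#' @aliases pigments truthBands
#' @name spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x)
  t(SummarizedExperiment::assay(x, "reflectance")))

#' @export
setMethod("wavelengths", "SpectraSet", function(x)
  SummarizedExperiment::rowData(x)$wavelength)

#' @export
setMethod("pigments", "SpectraSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("chla", "chlb", "car", "tpc") %in% colnames(cd))) return(NULL)
  as.matrix(as.data.frame(cd)[, c("chla", "chlb", "car", "tpc")])
})

#' @export
setMethod("truthBands", "SpectraSet", function(x, pigment = NULL) {
  if (is.null(pigment)) return(S4Vectors::metadata(x)$truth_bands)
  S4Vectors::metadata(x)$truth_bands_by_pigment[[pigment]]
})

#' PigmentMap: per-pixel canopy pigment estimates
#'
#' Four H x W planes (chla, chlb, car, tpc; mg/g) predicted pixelwise from
#' a calibrated cube, plus the foreground mask used. Background pixels
#' carry the `sentinel` value (default `NA`). Negative predictions are
#' preserved (and counted in `provenance$n_negative`) rather than clipped,
#' so downstream distribution statistics stay unbiased.
#'
#' @slot planes H x W x 4 array, dimnames chla/chlb/car/tpc.
#' @slot mask H x W logical foreground map.
#' @slot sentinel background fill value.
#' @slot provenance list: model description, preprocessing, band selection,
#'   negative-prediction count.
#' @seealso [invertCanopy()], [summarizeByType()], [renderMap()]
#' @export
setClass("PigmentMap",
  representation(planes = "array", mask = "matrix", sentinel = "numeric",
                 provenance = "list"))

setValidity("PigmentMap", function(object) {
  d <- dim(object@planes)
  if (length(d) != 3L || d[3L] != 4L)
    return("planes must be H x W x 4")
  if (!identical(dim(object@mask), d[1:2]))
    return("mask shape must match planes")
  if (!is.logical(object@mask))
    return("mask must be logical")
  TRUE
})

#' @describeIn PigmentMap extract one plane ("chla", "chlb", "car", "tpc").
#' @param x a `PigmentMap`.
#' @param plane one of `"chla"`, `"chlb"`, `"car"`, `"tpc"`.
#' @export
setMethod("mapPlane", "PigmentMap", function(x, plane) {
  plane <- match.arg(plane, c("chla", "chlb", "car", "tpc"))
  x@planes[, , plane]
})

#' @describeIn PigmentMap the foreground mask.
#' @export
setMethod("mapMask", "PigmentMap", function(x) x@mask)

setMethod("show", "PigmentMap", function(object) {
  d <- dim(object@planes)
  cat(sprintf("PigmentMap: %d x %d pixels, %d foreground (%.1f%%)\n",
              d[1L], d[2L], sum(object@mask),
              100 * mean(object@mask)))
  fg <- object@planes[, , "chla"][object@mask]
  if (length(fg))
    cat(sprintf("  chla foreground range: %.3f-%.3f mg/g\n",
                min(fg), max(fg)))
})
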