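#' @import methods
NULL

#' Wavelength axis of a spectral object
#'
#' Returns the wavelength grid (nm) attached to a [HyperCube-class] or
#' [SpectraSet-class].
#'
#' @param x a `HyperCube` or `SpectraSet`.
#' @return Numeric vector of wavelengths in nanometres, strictly increasing.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname cubeData
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname cubeData
#' @export
setGeneric("cubeKind", function(x) standardGeneric("cubeKind"))

#' @rdname spectraMatrix
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname spectraMatrix
#' @export
setGeneric("pigments", function(x) standardGeneric("pigments"))

#' @rdname spectraMatrix
#' @export
setGeneric("truthBands", function(x, pigment = NULL)
  standardGeneric("truthBands"))

#' @rdname PigmentMap-class
#' @export
setGeneric("mapPlane", function(x, plane) standardGeneric("mapPlane"))

#' @rdname PigmentMap-class
#' @export
setGeneric("mapMask", function(x) standardGeneric("mapMask"))
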