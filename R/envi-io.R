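## Minimal ENVI header/binary cube I/O.
##
## Supports the common dialect: BSQ/BIL/BIP interleaves, data types 4
## (float32) and 12 (uint16), little/big endian, and a mandatory
## `wavelength = { ... }` block. No ENVI reader ships with the installed
## R stack, so the format is parsed here directly.

.enviDataType <- list(`4` = list(what = "numeric", size = 4L),
                      `12` = list(what = "integer", size = 2L))

.parseEnviHeader <- function(hdrPath) {
  txt <- readLines(hdrPath, warn = FALSE)
  txt <- paste(txt, collapse = "\n")
  getScalar <- function(key) {
    m <- regmatches(txt, regexec(sprintf("(?mi)^%s\\s*=\\s*([^\\{\\n]+)$",
                                         key), txt, perl = TRUE))[[1]]
    if (length(m) < 2L) return(NULL)
    trimws(m[2L])
  }
  getBlock <- function(key) {
    m <- regmatches(txt, regexec(sprintf("(?si)%s\\s*=\\s*\\{([^}]*)\\}",
                                         key), txt, perl = TRUE))[[1]]
    if (length(m) < 2L) return(NULL)
    as.numeric(strsplit(gsub("[\n ]", "", m[2L]), ",")[[1]])
  }
  hdr <- list(samples = as.integer(getScalar("samples")),
              lines = as.integer(getScalar("lines")),
              bands = as.integer(getScalar("bands")),
              dataType = as.integer(getScalar("data type")),
              interleave = tolower(getScalar("interleave")),
              byteOrder = as.integer(getScalar("byte order") %||% "0"),
              wavelength = getBlock("wavelength"))
  for (k in c("samples", "lines", "bands", "dataType", "interleave"))
    if (is.null(hdr[[k]]) || is.na(hdr[[k]][1]))
      stop("ENVI header missing required field: ", k)
  if (is.null(hdr$wavelength))
    stop("ENVI header missing the wavelength block")
  if (length(hdr$wavelength) != hdr$bands)
    stop(sprintf("header declares %d bands but lists %d wavelengths",
                 hdr$bands, length(hdr$wavelength)))
  if (!hdr$interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported ENVI interleave dialect: ", hdr$interleave)
  if (!as.character(hdr$dataType) %in% names(.enviDataType))
    stop("unsupported ENVI data type: ", hdr$dataType,
         " (supported: 4 = float32, 12 = uint16)")
  hdr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write ENVI hyperspectral cubes
#'
#' `readENVI` reads a `<path>.hdr` + binary pair into a
#' [HyperCube-class]; `writeENVI` is its inverse. A written cube reads
#' back bitwise-identical (float32 storage) with wavelengths preserved.
#' Supported dialect: BSQ/BIL/BIP interleave, data types 4 (float32) and
#' 12 (uint16); the `wavelength` block is required.
#'
#' @param path path of the binary file; the header is `<path>.hdr`.
#' @param kind `"reflectance"` or `"raw"` for the returned cube.
#' @return `readENVI`: a [HyperCube-class]. `writeENVI`: `path`,
#'   invisibly.
#' @export
readENVI <- function(path, kind = c("reflectance", "raw")) {
  kind <- match.arg(kind)
  hdr <- .parseEnviHeader(paste0(path, ".hdr"))
  dt <- .enviDataType[[as.character(hdr$dataType)]]
  n <- hdr$samples * hdr$lines * hdr$bands
  endian <- if (hdr$byteOrder == 0L) "little" else "big"
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
               signed = dt$size > 2L)
  if (length(v) != n) stop("ENVI binary shorter than header declares")
  ## ENVI order within the file (fastest first):
  ##   BSQ: sample, line, band;  BIL: sample, band, line;
  ##   BIP: band, sample, line
  a <- switch(hdr$interleave,
    bsq = aperm(array(v, c(hdr$samples, hdr$lines, hdr$bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(hdr$samples, hdr$bands, hdr$lines)), c(3, 1, 2)),
    bip = aperm(array(v, c(hdr$bands, hdr$samples, hdr$lines)), c(3, 2, 1)))
  HyperCube(a, hdr$wavelength, kind = kind)
}

#' @rdname readENVI
#' @param cube a [HyperCube-class] to write.
#' @param interleave `"bsq"` (default), `"bil"` or `"bip"`.
#' @export
writeENVI <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(is(cube, "HyperCube"))
  interleave <- match.arg(interleave)
  d <- dim(cubeData(cube))   # lines (H), samples (W), bands
  a <- cubeData(cube)
  v <- switch(interleave,
    bsq = as.vector(aperm(a, c(2, 1, 3))),
    bil = as.vector(aperm(a, c(2, 3, 1))),
    bip = as.vector(aperm(a, c(3, 2, 1))))
  con <- file(path, "wb")
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  close(con)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2L]),
           sprintf("lines = %d", d[1L]),
           sprintf("bands = %d", d[3L]),
           "header offset = 0",
           "data type = 4",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("wavelength = { %s }",
                   paste(format(wavelengths(cube), trim = TRUE),
                         collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}
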