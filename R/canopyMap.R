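## Leaf-to-canopy inversion: apply a leaf-trained predictor to every
## foreground pixel of a calibrated cube. Strictly pixelwise -- no
## spatial smoothing -- so vein-scale texture survives in the maps.

#' Per-pixel canopy pigment inversion
#'
#' Each foreground pixel's spectrum is preprocessed exactly as the
#' training spectra were, reduced to the training band selection, and
#' scored by the predictor. Background pixels carry the sentinel value.
#' Out-of-range (negative) predictions are preserved and counted in the
#' provenance rather than clipped.
#'
#' @param cube a calibrated reflectance [HyperCube-class] on the
#'   training wavelength grid.
#' @param mask H x W logical foreground mask (an empty mask yields an
#'   all-sentinel map, without error).
#' @param predictors a single fitted model (scored into every plane it
#'   is named for) or a named list with entries among chla, chlb, car,
#'   tpc; each must expose `predict(model, X)`. Planes without a model
#'   stay at the sentinel. If all of chla, chlb and car are predicted
#'   but tpc is not, tpc is completed as their sum.
#' @param prep the [prepSpec()] the predictors were trained with
#'   (default none).
#' @param selection optional `selectionResult` (or integer band
#'   indices); pixels are reduced to these bands after preprocessing.
#' @param sentinel background value (default `NA`).
#' @param tile_rows pixels are scored in row-tiles of this many mask
#'   pixels so full-frame cubes fit modest memory.
#' @return A [PigmentMap-class].
#' @export
invertCanopy <- function(cube, mask, predictors, prep = prepSpec("none"),
                         selection = NULL, sentinel = NA_real_,
                         tile_rows = 20000L) {
  stopifnot(is(cube, "HyperCube"))
  if (cubeKind(cube) != "reflectance")
    stop("cube must be calibrated to reflectance first")
  d <- dim(cubeData(cube))
  if (!identical(dim(mask), d[1:2])) stop("mask shape mismatch")
  ## a bare fitted model (anything with a class and a predict method)
  ## is treated as a chla-only predictor
  if (!is.null(attr(predictors, "class")) || !is.list(predictors) ||
      is.null(names(predictors)))
    predictors <- list(chla = predictors)
  bad <- setdiff(names(predictors), .pigmentNames)
  if (length(bad)) stop("unknown plane(s): ", paste(bad, collapse = ", "))
  sel <- if (is.null(selection)) NULL
         else if (inherits(selection, "selectionResult")) selection$selected
         else as.integer(selection)
  planes <- array(sentinel, c(d[1L], d[2L], 4L),
                  dimnames = list(NULL, NULL, .pigmentNames))
  idx <- which(mask)
  nNeg <- 0L
  if (length(idx)) {
    wl <- wavelengths(cube)
    Xall <- matrix(cubeData(cube), d[1L] * d[2L], d[3L])
    tiles <- split(idx, ceiling(seq_along(idx) / tile_rows))
    for (tile in tiles) {
      P <- applyPrep(Xall[tile, , drop = FALSE], prep, wavelengths = wl)
      if (!is.null(sel)) P <- P[, sel, drop = FALSE]
      for (p in names(predictors)) {
        v <- as.numeric(stats::predict(predictors[[p]], P))
        nNeg <- nNeg + sum(v < 0)
        plane <- planes[, , p]; plane[tile] <- v; planes[, , p] <- plane
      }
    }
    if (all(c("chla", "chlb", "car") %in% names(predictors)) &&
        !("tpc" %in% names(predictors))) {
      plane <- planes[, , "chla"] + planes[, , "chlb"] + planes[, , "car"]
      bg <- !mask
      plane[bg] <- sentinel
      planes[, , "tpc"] <- plane
    }
  }
  new("PigmentMap", planes = planes, mask = mask,
      sentinel = as.numeric(sentinel),
      provenance = list(
        model = paste(vapply(predictors, function(m) class(m)[1L], ""),
                      collapse = ","),
        planes_modeled = names(predictors),
        prep = prep$method, n_selected = if (is.null(sel)) d[3L]
                                          else length(sel),
        n_negative = nNeg))
}

#' Pixel-pooled distribution statistics per canopy type
#'
#' @param maps list of [PigmentMap-class] objects.
#' @param labels character vector of type labels, one per map (maps of
#'   the same type are pooled).
#' @return Data.frame of class `typeSummary`: one row per type x
#'   pigment with n_pixels, mean, sd, quartiles and the coefficient of
#'   variation (`sd/mean`).
#' @export
summarizeByType <- function(maps, labels) {
  if (length(maps) == 0L) stop("no maps supplied")
  if (length(labels) != length(maps) || anyNA(labels))
    stop("every map needs a type label")
  rows <- list()
  for (type in unique(labels)) {
    sub <- maps[labels == type]
    for (p in .pigmentNames) {
      v <- unlist(lapply(sub, function(m) {
        pl <- mapPlane(m, p)
        pl[mapMask(m)]
      }))
      v <- v[is.finite(v)]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[paste(type, p)]] <- data.frame(
        type = type, pigment = p, n_pixels = length(v),
        mean = mean(v), sd = stats::sd(v),
        q25 = q[1L], median = q[2L], q75 = q[3L],
        cv = stats::sd(v) / mean(v))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("typeSummary", "data.frame")
  out
}

#' Render a pigment plane as a false-color PNG
#'
#' Background (sentinel) pixels are black; foreground values are mapped
#' through a perceptual colormap. The value range and colormap are
#' written to a JSON sidecar (`<path>.json`).
#'
#' @param map a [PigmentMap-class].
#' @param plane `"chla"`, `"chlb"`, `"car"` or `"tpc"`.
#' @param path output PNG path.
#' @param colormap a `grDevices::hcl.colors` palette name (default
#'   "viridis").
#' @return `path`, invisibly.
#' @export
renderMap <- function(map, plane, path, colormap = "viridis") {
  stopifnot(is(map, "PigmentMap"))
  v <- mapPlane(map, plane)
  fg <- mapMask(map) & is.finite(v)
  if (!any(fg)) stop("plane holds no finite foreground values")
  rng <- range(v[fg])
  pal <- grDevices::hcl.colors(256L, colormap)
  rgbPal <- grDevices::col2rgb(pal) / 255
  img <- array(0, c(nrow(v), ncol(v), 3L))
  lev <- if (diff(rng) > 0)
    pmin(255L, pmax(0L, floor((v[fg] - rng[1L]) / diff(rng) * 255))) + 1L
  else rep(128L, sum(fg))
  for (ch in 1:3) {
    plane2 <- img[, , ch]
    plane2[fg] <- rgbPal[ch, lev]
    img[, , ch] <- plane2
  }
  png::writePNG(img, path)
  jsonlite::write_json(list(plane = plane, min = rng[1L], max = rng[2L],
                            colormap = colormap,
                            n_negative = sum(v[fg] < 0)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
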