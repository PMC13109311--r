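## End-to-end demonstration pipeline: simulate -> calibrate -> segment ->
## extract -> model -> map, with a JSON manifest (paths, seeds, md5
## checksums) enabling verification of deterministic reruns. Every
## stochastic stage derives its own seed from the global seed and the
## stage name. A thin command-line wrapper over these functions ships in
## `inst/scripts/leafspec.R`.

.manifestEntry <- function(stage, path)
  list(stage = stage, path = path,
       md5 = unname(tools::md5sum(path)))

#' Run the leaf-to-canopy demonstration pipeline
#'
#' Stages: (1) simulate leaf spectra with pigment truth and write them
#' as CSV; (2) simulate a canopy scene, fold it back to raw counts with
#' synthetic white/dark references, write the raw cube as ENVI and
#' re-calibrate it; (3) segment the canopy at 748.76 nm and write the
#' mask; (4) extract the canopy mean spectrum; (5) fit a PLSR per
#' pigment on the leaf spectra; (6) invert the canopy per pixel and
#' render the four pigment maps. A failure in any stage halts with the
#' stage name after persisting the partial manifest.
#'
#' @param out_dir output root; all artifacts land below it.
#' @param seed global seed.
#' @param n_samples leaf spectra count (default 150).
#' @param canopy_size canopy frame edge in pixels (default 48).
#' @param config optional [generatorConfig()] overriding the defaults.
#' @return The manifest (invisibly): list of stage entries with paths
#'   and md5 checksums, written to `<out_dir>/manifest.json`.
#' @export
runPipeline <- function(out_dir, seed = 1L, n_samples = 150L,
                        canopy_size = 48L, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, artifacts = list())
  manifestPath <- file.path(out_dir, "manifest.json")
  push <- function(stage, path)
    manifest$artifacts[[length(manifest$artifacts) + 1L]] <<-
      .manifestEntry(stage, path)
  persist <- function()
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA)
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      persist()
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  base <- if (is.null(config)) generatorConfig() else config

  leaves <- NULL
  runStage("simulate_leaves", {
    cfgL <- base
    cfgL$n_samples <- as.integer(n_samples)
    cfgL$seed <- deriveSeed(seed, "simulate_leaves")
    leaves <- simulateLeafSpectra(cfgL)
    p <- file.path(out_dir, "leaf_spectra.csv")
    writeSpectraCSV(leaves, p)
    push("simulate_leaves", p)
  })

  canopy <- NULL; cube <- NULL
  runStage("simulate_canopy", {
    cfgC <- base
    cfgC$seed <- deriveSeed(seed, "simulate_canopy")
    canopy <- simulateCanopyCube(cfgC, canopy_size, canopy_size,
                                  gradient = c(chla = 0.15, chlb = -0.05,
                                               car = 0.03))
    ## fold reflectance back to raw counts and recover it by calibration
    wl <- wavelengths(canopy$cube)
    white <- 900 + 0.05 * wl
    dark <- rep(60, length(wl))
    raw <- cubeData(canopy$cube)
    for (b in seq_along(wl))
      raw[, , b] <- raw[, , b] * (white[b] - dark[b]) + dark[b]
    rawCube <- HyperCube(raw, wl, kind = "raw")
    p <- file.path(out_dir, "canopy_raw")
    writeENVI(rawCube, p)
    push("simulate_canopy", p)
    push("simulate_canopy", paste0(p, ".hdr"))
    cube <- calibrateReflectance(readENVI(p, kind = "raw"), white, dark)
  })

  mask <- NULL
  runStage("segment", {
    mask <- segmentCanopy(cube)
    p <- file.path(out_dir, "canopy_mask.png")
    writeMaskPNG(mask, p)
    push("segment", p)
  })

  runStage("extract", {
    sp <- meanSpectrum(cube, mask)
    p <- file.path(out_dir, "canopy_mean_spectrum.csv")
    utils::write.csv(data.frame(wavelength = wavelengths(cube),
                                reflectance = sp), p, row.names = FALSE)
    push("extract", p)
  })

  models <- NULL
  runStage("model", {
    X <- spectraMatrix(leaves)
    pg <- pigments(leaves)
    models <- lapply(c(chla = "chla", chlb = "chlb", car = "car"),
                      function(p) fitPLSR(X, pg[, p],
                                          seed = deriveSeed(seed, "fit", p)))
  })

  runStage("map", {
    pm <- invertCanopy(cube, mask, models)
    for (p in .pigmentNames) {
      f <- file.path(out_dir, sprintf("map_%s.png", p))
      renderMap(pm, p, f)
      push("map", f)
      push("map", paste0(f, ".json"))
    }
  })

  persist()
  invisible(manifest)
}

#' Verify a pipeline manifest against the files on disk
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [runPipeline()].
#' @return Data.frame with one row per artifact: path, stored and
#'   current md5, and whether they match. Any corrupted or missing
#'   artifact has `ok = FALSE`.
#' @export
verifyManifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  rows <- lapply(man$artifacts, function(a) {
    cur <- if (file.exists(a$path)) unname(tools::md5sum(a$path))
           else NA_character_
    data.frame(stage = a$stage, path = a$path, stored = a$md5,
               current = cur, ok = identical(cur, a$md5))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
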