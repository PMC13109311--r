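## A PLSR at the generator's truth bands with ncomp = 3 (the rank of the
## pigment-to-reflectance map) is an exact linear inverse of the
## noise-free linear generator.
exactLinearPredictor <- function(target = "chla") {
  ss <- cleanLeafBatch(n = 150, seed = 55)
  X <- spectraMatrix(ss)[, truthBands(ss)]
  fitPLSR(X, pigments(ss)[, target], ncomp = 3L, seed = 1)
}

test_that("gradient-0 canopy with an exact linear model inverts to the known vector", {
  cc <- simulateCanopyCube(generatorConfig(noise_sd = 0, seed = 55), 24, 24)
  ss <- cleanLeafBatch(n = 150, seed = 55)
  tb <- truthBands(ss)
  preds <- lapply(c(chla = "chla", chlb = "chlb", car = "car"),
                  exactLinearPredictor)
  pm <- invertCanopy(cc$cube, cc$mask, preds, selection = tb)
  for (p in c("chla", "chlb", "car", "tpc")) {
    plane <- mapPlane(pm, p)
    expect_lt(max(abs(plane[cc$mask] - cc$truth[[p]][cc$mask])), 1e-8)
    expect_true(all(is.na(plane[!cc$mask])))
  }
})

test_that("radial-gradient canopy: PLSR inversion correlates with truth pixelwise", {
  cfg <- generatorConfig(noise_sd = 0, seed = 42)
  cc <- simulateCanopyCube(cfg, 32, 32,
                           gradient = c(chla = 0.2, chlb = -0.04,
                                        car = 0.02))
  ss <- cleanLeafBatch(n = 150, seed = 42)
  fit <- fitPLSR(spectraMatrix(ss), pigments(ss)[, "chla"], seed = 1)
  pm <- invertCanopy(cc$cube, cc$mask, list(chla = fit))
  r <- cor(mapPlane(pm, "chla")[cc$mask], cc$truth$chla[cc$mask])
  expect_gte(r, 0.99)
})

test_that("empty mask gives an all-sentinel map without error", {
  cc <- simulateCanopyCube(generatorConfig(noise_sd = 0, seed = 5), 16, 16)
  none <- matrix(FALSE, 16, 16)
  pm <- invertCanopy(cc$cube, none, exactLinearPredictor())
  expect_true(all(is.na(mapPlane(pm, "chla"))))
})

test_that("inversion is strictly pixelwise (no spatial mixing)", {
  cc <- simulateCanopyCube(generatorConfig(noise_sd = 0.01, seed = 9), 16, 16)
  fitp <- exactLinearPredictor()
  ss <- cleanLeafBatch(n = 10, seed = 55)
  tb <- truthBands(ss)
  pm <- invertCanopy(cc$cube, cc$mask, list(chla = fitp), selection = tb)
  idx <- which(cc$mask)[c(1, 5, 9)]
  P <- pixelSpectra(cc$cube, idx)[, tb]
  expect_equal(mapPlane(pm, "chla")[idx], predict(fitp, P),
               tolerance = 1e-12)
})

test_that("map statistics are invariant to frame rotation", {
  cc <- simulateCanopyCube(generatorConfig(noise_sd = 0, seed = 31), 20, 20,
                           gradient = c(chla = 0.15, chlb = 0, car = 0))
  pred <- exactLinearPredictor()
  ss <- cleanLeafBatch(n = 10, seed = 55)
  tb <- truthBands(ss)
  pm1 <- invertCanopy(cc$cube, cc$mask, pred, selection = tb)
  rot <- function(m) t(m[nrow(m):1, ])
  d <- cubeData(cc$cube)
  dr <- array(0, c(dim(d)[2], dim(d)[1], dim(d)[3]))
  for (b in seq_len(dim(d)[3])) dr[, , b] <- rot(d[, , b])
  cubeR <- HyperCube(dr, wavelengths(cc$cube))
  pm2 <- invertCanopy(cubeR, rot(cc$mask), pred, selection = tb)
  expect_equal(sort(mapPlane(pm1, "chla")[mapMask(pm1)]),
               sort(mapPlane(pm2, "chla")[mapMask(pm2)]),
               tolerance = 1e-12)
})

test_that("type summaries pool pixels and report CV correctly", {
  cfgA <- generatorConfig(noise_sd = 0, seed = 1,
                          pigment_ranges = list(chla = c(0.70, 0.72),
                                                chlb = c(0.30, 0.32),
                                                car = c(0.15, 0.16)))
  cfgB <- generatorConfig(noise_sd = 0, seed = 2,
                          pigment_ranges = list(chla = c(0.95, 0.97),
                                                chlb = c(0.30, 0.32),
                                                car = c(0.15, 0.16)))
  mk <- function(cfg) {
    cc <- simulateCanopyCube(cfg, 16, 16)
    planes <- array(NA_real_, c(16, 16, 4),
                    dimnames = list(NULL, NULL,
                                    c("chla", "chlb", "car", "tpc")))
    for (p in c("chla", "chlb", "car", "tpc"))
      planes[, , p] <- cc$truth[[p]]
    new("PigmentMap", planes = planes, mask = cc$mask,
        sentinel = NA_real_, provenance = list(model = "truth"))
  }
  mapA <- mk(cfgA); mapB <- mk(cfgB)
  ## gradient 0: sd and CV are exactly 0
  s1 <- summarizeByType(list(mapA), labels = "low")
  expect_equal(s1$sd[s1$pigment == "chla"], 0)
  expect_equal(s1$cv[s1$pigment == "chla"], 0)
  ## two types with disjoint chla ranges order as generated
  s2 <- summarizeByType(list(mapA, mapB), labels = c("low", "high"))
  mLow <- s2$mean[s2$type == "low" & s2$pigment == "chla"]
  mHigh <- s2$mean[s2$type == "high" & s2$pigment == "chla"]
  expect_lt(mLow, mHigh)
  ## duplicating a map leaves the type's statistics unchanged
  s3 <- summarizeByType(list(mapA, mapA), labels = c("low", "low"))
  expect_equal(s3$mean, s1$mean)
  expect_equal(s3$cv, s1$cv)
  expect_identical(s3$n_pixels, 2L * s1$n_pixels)
  expect_error(summarizeByType(list(mapA), labels = NA), "label")
})

test_that("map rendering writes a false-color PNG with annotated range", {
  cc <- simulateCanopyCube(generatorConfig(noise_sd = 0, seed = 3), 16, 16,
                           gradient = c(chla = 0.2, chlb = 0, car = 0))
  pred <- exactLinearPredictor()
  ss <- cleanLeafBatch(n = 10, seed = 55)
  pm <- invertCanopy(cc$cube, cc$mask, pred, selection = truthBands(ss))
  f <- tempfile(fileext = ".png")
  renderMap(pm, "chla", f)
  img <- png::readPNG(f)
  ## background black
  expect_equal(max(img[1, 1, ]), 0)
  side <- jsonlite::read_json(paste0(f, ".json"))
  v <- mapPlane(pm, "chla")[cc$mask]
  expect_equal(side$min, min(v), tolerance = 1e-12)
  expect_equal(side$max, max(v), tolerance = 1e-12)
  ## a plane that was never modeled holds no finite values
  expect_error(renderMap(pm, "chlb", f), "no finite foreground")
  unlink(c(f, paste0(f, ".json")))
})
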