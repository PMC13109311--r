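test_that("wavelength axis is evenly spaced with exact endpoints", {
  wl <- makeWavelengthAxis(generatorConfig())
  expect_length(wl, 256)
  expect_equal(wl[1], 366)
  expect_equal(wl[256], 976)
  expect_equal(diff(wl), rep((976 - 366) / 255, 255))

  expect_equal(makeWavelengthAxis(list(wl_min = 0, wl_max = 10,
                                       n_bands = 11)), 0:10)
  expect_equal(makeWavelengthAxis(list(wl_min = 366, wl_max = 976,
                                       n_bands = 2)), c(366, 976))
  expect_error(generatorConfig(n_bands = 1), "n_bands")
})

test_that("generator is deterministic and respects the zero-absorber limit", {
  cfg <- generatorConfig(n_samples = 5, noise_sd = 0, seed = 42)
  a <- simulateLeafSpectra(cfg)
  b <- simulateLeafSpectra(cfg)
  expect_identical(spectraMatrix(a), spectraMatrix(b))
  expect_identical(pigments(a), pigments(b))

  ## near-zero pigment: spectrum approaches the base curve; the deep
  ## 430-470 nm troughs of pigmented leaves must vanish
  tiny <- generatorConfig(n_samples = 2, noise_sd = 0, seed = 1,
                          pigment_ranges = list(chla = c(1e-9, 2e-9),
                                                chlb = c(1e-9, 2e-9),
                                                car = c(1e-9, 2e-9)))
  s <- spectraMatrix(simulateLeafSpectra(tiny))[1, ]
  wl <- makeWavelengthAxis(tiny)
  base <- hsiPigments:::.baseCurve(wl)
  expect_lt(max(abs(s - base)), 1e-8)
})

test_that("TPC column is exactly the sum of the three pigments", {
  for (seed in c(1, 2, 3)) {
    pg <- pigments(cleanLeafBatch(n = 40, seed = seed, noise = 0.01))
    expect_identical(pg[, "tpc"],
                     pg[, "chla"] + pg[, "chlb"] + pg[, "car"])
  }
})

test_that("linear noise-free mode is affine: regression on truth bands is exact", {
  ss <- cleanLeafBatch(n = 200, seed = 3)
  X <- spectraMatrix(ss)
  tb <- truthBands(ss)
  pg <- pigments(ss)
  for (p in c("chla", "chlb", "car")) {
    fit <- lm(pg[, p] ~ X[, tb])
    relRes <- sqrt(sum(residuals(fit)^2)) / sqrt(sum(pg[, p]^2))
    expect_lt(relRes, 1e-8)
  }
})

test_that("mean spectrum shows the pigment landmarks", {
  ss <- cleanLeafBatch(n = 300, seed = 9, noise = 0.002)
  m <- colMeans(spectraMatrix(ss))
  wl <- wavelengths(ss)
  vis <- wl >= 400 & wl <= 760
  blueMin <- wl[vis][which.min(replace(m[vis], wl[vis] > 500, Inf))]
  redMin <- wl[vis][which.min(replace(m[vis], wl[vis] < 600, Inf))]
  greenMax <- wl[vis][which.max(replace(m[vis],
                                        wl[vis] < 530 | wl[vis] > 580,
                                        -Inf))]
  expect_gte(blueMin, 430); expect_lte(blueMin, 470)
  expect_gte(redMin, 670); expect_lte(redMin, 690)
  expect_gte(greenMax, 530); expect_lte(greenMax, 580)
})

test_that("reflectance stays within [0, 1.05]", {
  ss <- cleanLeafBatch(n = 50, seed = 5, noise = 0.05)
  X <- spectraMatrix(ss)
  expect_gte(min(X), 0)
  expect_lte(max(X), 1.05)
})

test_that("canopy cube: gradient 0 gives one shared pigment vector and true NIR contrast", {
  cfg <- generatorConfig(noise_sd = 0, seed = 15)
  cc <- simulateCanopyCube(cfg, 32, 32, gradient = c(chla = 0, chlb = 0,
                                                     car = 0))
  expect_s4_class(cc$cube, "HyperCube")
  fg <- cc$truth$chla[cc$mask]
  expect_equal(max(fg) - min(fg), 0)
  ## all foreground pixels share one spectrum
  P <- pixelSpectra(cc$cube, cc$mask)
  expect_lt(max(abs(sweep(P, 2, P[1, ]))), 1e-12)
  ## NIR contrast at 748.76 nm
  b <- which.min(abs(wavelengths(cc$cube) - 748.76))
  expect_gt(mean(P[, b]) - hsiPigments:::.SOIL_REFLECTANCE, 0.3)
})

test_that("canopy truth maps are the exact radial function in linear mode", {
  cfg <- generatorConfig(noise_sd = 0, seed = 8)
  grad <- c(chla = 0.2, chlb = -0.05, car = 0.02)
  cc <- simulateCanopyCube(cfg, 40, 40, gradient = grad)
  h <- 40; cy <- (h + 1) / 2
  rr <- outer(seq_len(h) - cy, seq_len(h) - cy, function(a, b) sqrt(a^2 + b^2))
  Rmax <- 0.8 * (h - 1) / 2
  idx <- which(cc$mask)
  rho <- rr[idx] / Rmax
  ## chla truth is exactly affine in relative radius with slope = gradient
  fit <- lm(cc$truth$chla[idx] ~ rho)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_equal(unname(coef(fit)[2]), unname(grad["chla"]),
               tolerance = 1e-10)
  expect_true(all(is.na(cc$truth$chla[!cc$mask])))
  expect_identical(cc$truth$tpc,
                   cc$truth$chla + cc$truth$chlb + cc$truth$car)
})

test_that("spectra CSV round-trips", {
  ss <- cleanLeafBatch(n = 8, seed = 2, noise = 0.001)
  f <- tempfile(fileext = ".csv")
  writeSpectraCSV(ss, f)
  back <- readSpectraCSV(f)
  expect_equal(spectraMatrix(back), spectraMatrix(ss), tolerance = 1e-12)
  expect_equal(pigments(back), pigments(ss), tolerance = 1e-12)
  expect_equal(wavelengths(back), wavelengths(ss), tolerance = 1e-6)
  unlink(f)
})
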