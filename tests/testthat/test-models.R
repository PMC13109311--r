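test_that("metrics match hand arithmetic", {
  y <- c(0, 1, 2)
  m <- regMetrics(y, c(0, 2, 2))
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-15)
  expect_equal(m$r2, 0.5, tolerance = 1e-15)
  expect_equal(m$mae, 1 / 3, tolerance = 1e-15)
  perfect <- regMetrics(y, y)
  expect_identical(c(perfect$rmse, perfect$r2, perfect$mae), c(0, 1, 0))
  off <- regMetrics(y, y + 1)
  expect_equal(off$rmse, 1); expect_equal(off$mae, 1)
  expect_error(regMetrics(c(1, 1), c(1, 2)), "constant")
  expect_error(regMetrics(1:3, 1:2), "length")
})

test_that("r2 of a least-squares linear fit on its own data is non-negative", {
  set.seed(40)
  X <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  fit <- lm(y ~ X)
  expect_gte(regMetrics(y, fitted(fit))$r2, 0)
})

test_that("PLSR recovers a noise-free linear map", {
  ss <- cleanLeafBatch(n = 120, seed = 71)
  X <- spectraMatrix(ss)
  y <- pigments(ss)[, "chla"]
  sp <- kennardStone(X, 0.75)
  fit <- fitPLSR(X[sp$calib_idx, ], y[sp$calib_idx], seed = 1)
  pred <- predict(fit, X[sp$pred_idx, ])
  expect_gte(regMetrics(y[sp$pred_idx], pred)$r2, 0.999)
})

test_that("ELM with hidden units >= n interpolates its calibration set", {
  set.seed(9)
  n <- 40
  X <- matrix(runif(n * 12), n, 12)
  y <- rnorm(n)
  fit <- fitELM(X, y, n_hidden = 60L, seed = 3)
  expect_gte(regMetrics(y, predict(fit, X))$r2, 1 - 1e-6)
  ## ELM is seeded: same seed, same predictions
  fit2 <- fitELM(X, y, n_hidden = 60L, seed = 3)
  expect_identical(predict(fit, X), predict(fit2, X))
})

test_that("RF predicts a constant for constant targets; SVR learns a smooth map", {
  set.seed(14)
  X <- matrix(runif(200), 50, 4)
  ## constant response: randomForest warns about degenerate regression
  rf <- suppressWarnings(fitRF(X, rep(2.5, 50), ntree = 50L, seed = 1))
  expect_equal(predict(rf, X), rep(2.5, 50), tolerance = 1e-10)
  y <- sin(2 * pi * X[, 1]) + 0.1 * rnorm(50)
  sv <- fitSVR(X, y, seed = 2)
  expect_gte(regMetrics(y, predict(sv, X))$r2, 0.7)
})

test_that("combination grid on clean linear data: PLSR combos approach exactness", {
  ss <- cleanLeafBatch(n = 90, seed = 81)
  res <- runGrid(ss, preps = c("none", "SNV"), selectors = c("LARS"),
                 splitters = c("Random", "KS"), models = c("PLSR"),
                 targets = c("chla"), seed = 7)
  expect_identical(length(res$errors), 0L)
  expect_true(all(res$table$rp2 >= 0.99))
  ## best row is the argmax over rp2
  expect_equal(res$best$rp2[1], max(res$table$rp2))
  ## grid rerun is deterministic
  res2 <- runGrid(ss, preps = c("none", "SNV"), selectors = c("LARS"),
                  splitters = c("Random", "KS"), models = c("PLSR"),
                  targets = c("chla"), seed = 7)
  expect_equal(res$table$rp2, res2$table$rp2, tolerance = 1e-10)
  expect_identical(res$table$selected_bands, res2$table$selected_bands)
})

test_that("grid export writes tidy CSV and best-combo JSON", {
  ss <- cleanLeafBatch(n = 60, seed = 91)
  res <- runGrid(ss, preps = "none", selectors = "LARS",
                 splitters = "Random", models = c("PLSR", "ELM"),
                 targets = c("chla", "tpc"), seed = 3)
  d <- tempfile()
  writeGridResult(res, d)
  tab <- utils::read.csv(file.path(d, "grid_results.csv"))
  expect_setequal(tab$pigment, c("chla", "tpc"))
  best <- jsonlite::read_json(file.path(d, "best_combos.json"),
                              simplifyVector = TRUE)
  expect_identical(nrow(best), 2L)
  unlink(d, recursive = TRUE)
})

test_that("no leakage: permuting prediction-set targets changes nothing calibrated", {
  ss <- cleanLeafBatch(n = 80, seed = 95, noise = 0.003)
  X <- spectraMatrix(ss)
  y <- pigments(ss)[, "chla"]
  sp <- randomSplit(80, 0.75, seed = 11)
  yPerm <- y
  yPerm[sp$pred_idx] <- sample(y[sp$pred_idx])
  selA <- carsSelect(X[sp$calib_idx, ], y[sp$calib_idx], runs = 20L,
                     seed = 5)
  selB <- carsSelect(X[sp$calib_idx, ], yPerm[sp$calib_idx], runs = 20L,
                     seed = 5)
  expect_identical(selA$selected, selB$selected)
  fitA <- fitPLSR(X[sp$calib_idx, selA$selected], y[sp$calib_idx], seed = 2)
  mA <- regMetrics(y[sp$calib_idx],
                   predict(fitA, X[sp$calib_idx, selA$selected]))
  fitB <- fitPLSR(X[sp$calib_idx, selB$selected], yPerm[sp$calib_idx],
                  seed = 2)
  mB <- regMetrics(yPerm[sp$calib_idx],
                   predict(fitB, X[sp$calib_idx, selB$selected]))
  expect_equal(mA$rmse, mB$rmse, tolerance = 1e-12)
})

test_that("internal PLS engine agrees with a reference PLS fit", {
  ## cross-check the wrapper against mixOmics called directly
  set.seed(6)
  n <- 40; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("b%d", 1:p)
  y <- X[, 2] - 0.5 * X[, 9] + rnorm(n, 0, 0.05)
  fit <- hsiPigments:::.plsFit(X, y, 5L)
  ref <- mixOmics::pls(X, y, ncomp = 5, mode = "regression", scale = FALSE)
  refPred <- predict(ref, X)$predict[, 1, 5]
  expect_equal(hsiPigments:::.plsPredict(fit, X), as.numeric(refPred),
               tolerance = 1e-10)
})
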