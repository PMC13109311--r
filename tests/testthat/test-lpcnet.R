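test_that("MHSA forward matches the independent six-step reference", {
  set.seed(2)
  for (scale in c(TRUE, FALSE)) {
    for (rep in 1:5) {
      T <- sample(2:6, 1); D <- sample(4:10, 1)
      heads <- sample(1:3, 1)
      p <- mhsaParams(D, heads, seed = 1000 + rep)
      h <- matrix(rnorm(T * D), T, D)
      got <- mhsaForward(h, p, scale = scale)
      ref <- referenceMHSA(h, p, scale = scale)
      expect_equal(got$output, ref, tolerance = 1e-6, ignore_attr = TRUE)
      ## weights: non-negative, rows sum to 1 for every head
      expect_true(all(got$weights >= 0))
      sums <- apply(got$weights, c(1, 2, 3), sum)
      expect_lt(max(abs(sums - 1)), 1e-6)
    }
  }
})

test_that("MHSA degenerate cases: equal tokens and length-1 sequences", {
  D <- 6
  p <- mhsaParams(D, 2L, seed = 4)
  ## identical tokens -> all scores equal -> uniform attention rows
  h <- matrix(rep(rnorm(D), each = 4), 4, D)
  got <- mhsaForward(h, p)
  expect_lt(max(abs(got$weights - 0.25)), 1e-12)
  ## sequence length 1 -> weight [[1]], output = v Wo path
  h1 <- matrix(rnorm(D), 1, D)
  g1 <- mhsaForward(h1, p)
  expect_equal(dim(g1$weights), c(1L, 2L, 1L, 1L))
  expect_equal(as.numeric(g1$weights), c(1, 1))
  v <- cbind(h1 %*% p$heads[[1]]$Wv, h1 %*% p$heads[[2]]$Wv)
  expect_equal(g1$output, v %*% p$Wo, tolerance = 1e-12)
})

test_that("builder: shape contract, parameter count, batch-permutation equivariance", {
  cfg <- lpcnetConfig(conv_kernels = c(3L, 3L), conv_channels = c(4L, 6L),
                      lstm_hidden = 5L, heads = 2L, seed = 11)
  m <- buildLPCNet(32L, cfg)
  ## closed-form parameter count:
  ## conv1: 3*1*4 + 4; conv2: 3*4*6 + 6; bilstm: 2*(6*20 + 5*20 + 20);
  ## mhsa: D = 10, dh = 5 -> 2 heads * 3 * (10*5) + Wo 10*10;
  ## head: 10 + 1
  expect_equal(lpcnetParamCount(m),
               (3 * 4 + 4) + (3 * 4 * 6 + 6) +
               2 * (6 * 20 + 5 * 20 + 20) +
               (2 * 3 * 50 + 100) + 11)
  X <- matrix(rnorm(4 * 32), 4, 32)
  out <- hsiPigments:::.lpcnetForward(m, X)$out
  expect_length(out, 4)
  expect_true(all(is.finite(out)))
  ## permuting the batch permutes outputs identically
  prm <- c(3, 1, 4, 2)
  out2 <- hsiPigments:::.lpcnetForward(m, X[prm, ])$out
  expect_equal(out2, out[prm], tolerance = 1e-12)
  expect_error(buildLPCNet(4L, cfg), "too small")
})

test_that("analytic gradients agree with finite differences through every block", {
  cfg <- lpcnetConfig(conv_kernels = c(3L, 3L), conv_channels = c(2L, 3L),
                      lstm_hidden = 4L, heads = 2L, seed = 2)
  m <- buildLPCNet(16L, cfg, variant = "LPCNet")
  set.seed(1)
  X <- matrix(rnorm(3 * 16), 3, 16)
  y <- rnorm(3)
  fw <- hsiPigments:::.lpcnetForward(m, X, keep = TRUE)
  grads <- hsiPigments:::.lpcnetBackward(m, fw$caches,
                                         2 * (fw$out - y) / 3)
  skel <- utils::as.relistable(m$params)
  pv <- unlist(skel)
  gv <- unlist(grads)
  loss <- function(v) {
    m2 <- m
    m2$params <- utils::relist(v, skel)
    mean((hsiPigments:::.lpcnetForward(m2, X, keep = TRUE)$out - y)^2)
  }
  eps <- 1e-5
  idx <- unique(round(seq(1, length(pv), length.out = 60)))
  for (i in idx) {
    v1 <- pv; v1[i] <- v1[i] + eps
    v2 <- pv; v2[i] <- v2[i] - eps
    num <- (loss(v1) - loss(v2)) / (2 * eps)
    expect_lt(abs(num - gv[i]) / max(1e-6, abs(num) + abs(gv[i])), 1e-4)
  }
})

test_that("fused training step equals the per-layer path on every variant", {
  cfg <- lpcnetConfig(conv_kernels = c(3L, 3L), conv_channels = c(2L, 3L),
                      lstm_hidden = 4L, heads = 2L, seed = 2)
  set.seed(3)
  X <- matrix(rnorm(5 * 16), 5, 16)
  y <- rnorm(5)
  for (v in c("CNN", "CNN-BiLSTM", "CNN-MHSA", "LPCNet")) {
    m <- buildLPCNet(16L, cfg, variant = v)
    fwR <- hsiPigments:::.lpcnetForward(m, X, keep = TRUE)
    gR <- hsiPigments:::.lpcnetBackward(m, fwR$caches,
                                        2 * (fwR$out - y) / 5)
    st <- hsiPigments:::.lpcnetStepCpp(X, y, m$params, TRUE)
    expect_equal(st$out, fwR$out, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unlist(st$grads), unlist(gR), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("training contracts: zero-epoch report, determinism, loss decrease", {
  ss <- cleanLeafBatch(n = 80, seed = 77, noise = 0.002, n_bands = 64)
  X <- spectraMatrix(ss)
  y <- pigments(ss)[, "chla"]
  sp <- randomSplit(80, 0.75, seed = 2)
  small <- lpcnetConfig(conv_channels = c(4L, 8L, 8L), lstm_hidden = 8L,
                        epochs = 0L, seed = 5)
  ## zero-epoch train equals untrained-model evaluation
  fit0 <- trainLPCNet(X, y, sp, small)
  m0 <- buildLPCNet(64L, small)
  m0$xScale <- fit0$model$xScale
  m0$yScale <- fit0$model$yScale
  predU <- predict(m0, X[sp$pred_idx, ])
  expect_equal(regMetrics(y[sp$pred_idx], predU)$r2, fit0$report$rp2,
               tolerance = 1e-12)
  ## two runs with the same seed give identical loss curves
  small$epochs <- 8L
  fitA <- trainLPCNet(X, y, sp, small)
  fitB <- trainLPCNet(X, y, sp, small)
  expect_identical(fitA$curves$loss, fitB$curves$loss)
  expect_identical(fitA$curves$pred_r2, fitB$curves$pred_r2)
  ## calibration loss trends down (median of late window < early window)
  small$epochs <- 30L
  fitC <- trainLPCNet(X, y, sp, small)
  expect_lt(median(tail(fitC$curves$loss, 10)),
            median(head(fitC$curves$loss, 10)))
  ## the reported epoch maximizes prediction R^2
  expect_equal(max(fitC$curves$pred_r2),
               fitC$curves$pred_r2[fitC$report$best_epoch])
})

test_that("ablation harness: fixed variant order, shared split", {
  ss <- cleanLeafBatch(n = 60, seed = 88, noise = 0.002, n_bands = 64,
                       nonlinear = TRUE)
  X <- spectraMatrix(ss)
  y <- pigments(ss)[, "chla"]
  sp <- randomSplit(60, 0.75, seed = 3)
  cfg <- lpcnetConfig(conv_channels = c(4L, 8L, 8L), lstm_hidden = 8L,
                      epochs = 3L, seed = 6)
  ab <- ablateLPCNet(X, y, sp, cfg)
  expect_identical(ab$reports$model,
                   c("CNN", "CNN-BiLSTM", "CNN-MHSA", "LPCNet"))
  expect_identical(names(ab$fits),
                   c("CNN", "CNN-BiLSTM", "CNN-MHSA", "LPCNet"))
  ## all four variants trained and evaluated on the same indices
  expect_true(all(is.finite(ab$reports$rp2)))
})
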