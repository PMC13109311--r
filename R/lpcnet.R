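## LPCNet: a 1-D CNN -> BiLSTM -> multi-head self-attention -> regression
## head for spectral pigment regression, with the ablation variants that
## drop the recurrent and/or attention blocks. One scalar model is
## trained per pigment.

#' LPCNet configuration
#'
#' Defaults: three convolution blocks (kernel sizes 7/5/3, channels
#' 16/32/64, stride 1, max-pool 2 after each), a bidirectional LSTM with
#' 64 hidden units per direction (sequence width 128), six attention
#' heads of dimension `floor(width / heads)`, mean pooling and a dense
#' scalar head. Trained with Adam (learning rate 1e-3), batch size 32,
#' 200 epochs, mean-squared-error loss.
#'
#' @param conv_kernels,conv_channels integer vectors, one entry per
#'   convolution block.
#' @param lstm_hidden hidden units per LSTM direction.
#' @param heads attention heads (default 6).
#' @param head_dim per-head dimension; `NULL` means
#'   `floor(width / heads)`.
#' @param scale_scores if `TRUE` (default) attention scores are scaled
#'   by `1/sqrt(d_k)`; `FALSE` gives the unscaled dot-product literal
#'   form.
#' @param epochs,learning_rate,batch_size optimizer settings.
#' @param select_best if `TRUE` (default) the reported epoch is the one
#'   with the best prediction-set R^2; otherwise the last epoch.
#' @param seed RNG seed for initialization and batch order.
#' @return A list of class `lpcnetConfig`.
#' @export
lpcnetConfig <- function(conv_kernels = c(7L, 5L, 3L),
                         conv_channels = c(16L, 32L, 64L),
                         lstm_hidden = 64L, heads = 6L, head_dim = NULL,
                         scale_scores = TRUE, epochs = 200L,
                         learning_rate = 1e-3, batch_size = 32L,
                         select_best = TRUE, seed = 1L) {
  stopifnot(length(conv_kernels) == length(conv_channels),
            all(conv_kernels %% 2 == 1), heads >= 1L, epochs >= 0L)
  structure(list(conv_kernels = as.integer(conv_kernels),
                 conv_channels = as.integer(conv_channels),
                 lstm_hidden = as.integer(lstm_hidden),
                 heads = as.integer(heads), head_dim = head_dim,
                 scale_scores = isTRUE(scale_scores),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 select_best = isTRUE(select_best),
                 seed = as.integer(seed)),
            class = "lpcnetConfig")
}

.lpcnetVariants <- c("CNN", "CNN-BiLSTM", "CNN-MHSA", "LPCNet")

#' Build an LPCNet model (or an ablation variant)
#'
#' @param n_bands input spectrum length.
#' @param config an [lpcnetConfig()].
#' @param variant `"LPCNet"` (full model), or `"CNN"`, `"CNN-BiLSTM"`,
#'   `"CNN-MHSA"` with the named blocks dropped (the head attaches
#'   directly to the remaining stack).
#' @return A list of class `lpcnetModel` with untrained, seeded
#'   parameters.
#' @export
buildLPCNet <- function(n_bands, config = lpcnetConfig(),
                        variant = "LPCNet") {
  variant <- match.arg(variant, .lpcnetVariants)
  nBlocks <- length(config$conv_kernels)
  L <- n_bands
  for (i in seq_len(nBlocks)) L <- L %/% 2L
  if (L < 2L)
    stop("band count too small for the convolution/pooling stack")
  .withSeed(config$seed, {
    params <- list()
    Cin <- 1L
    for (i in seq_len(nBlocks)) {
      params[[paste0("conv", i)]] <-
        .convInit(config$conv_kernels[i], Cin, config$conv_channels[i])
      Cin <- config$conv_channels[i]
    }
    D <- Cin
    if (variant %in% c("CNN-BiLSTM", "LPCNet")) {
      params$bilstm <- .bilstmInit(Cin, config$lstm_hidden)
      D <- 2L * config$lstm_hidden
    }
    if (variant %in% c("CNN-MHSA", "LPCNet")) {
      dh <- config$head_dim
      if (is.null(dh)) dh <- max(1L, D %/% config$heads)
      params$mhsa <- .mhsaInit(D, config$heads, dh)
    }
    params$head <- .denseInit(D, 1L)
    structure(list(params = params, variant = variant, config = config,
                   n_bands = n_bands, seq_len = L, width = D,
                   xScale = NULL, yScale = NULL),
              class = "lpcnetModel")
  })
}

#' @export
print.lpcnetModel <- function(x, ...) {
  cat(sprintf("lpcnetModel[%s]: %d bands -> %d tokens x width %d, %d parameters\n",
              x$variant, x$n_bands, x$seq_len, x$width,
              lpcnetParamCount(x)))
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param model an `lpcnetModel`.
#' @return Integer: sum of the lengths of every weight and bias array.
#' @export
lpcnetParamCount <- function(model) {
  count <- function(p) if (is.list(p)) sum(vapply(p, count, 1)) else length(p)
  as.integer(count(model$params))
}

## Full forward pass. x: n x B matrix (already input-scaled).
## Returns the scalar outputs and, if `keep = TRUE`, every layer cache;
## `attention = TRUE` additionally materializes the attention weights.
.lpcnetForward <- function(model, x, keep = FALSE, attention = FALSE) {
  cfg <- model$config
  p <- model$params
  if (!keep && !attention)
    return(list(out = as.numeric(.lpcnetPredictCpp(x, p,
                                                   cfg$scale_scores)),
                caches = NULL, attention = NULL))
  n <- nrow(x)
  a <- array(x, c(n, 1L, ncol(x)))     # (batch, channel, position)
  caches <- list()
  for (i in seq_along(cfg$conv_kernels)) {
    cv <- .convBlockFwd(p[[paste0("conv", i)]], a)
    a <- cv$y
    if (keep) caches[[paste0("conv", i)]] <- cv$cache
  }
  if (!is.null(p$bilstm)) {
    bl <- .bilstmFwd(p$bilstm, a)
    a <- bl$y
    if (keep) caches$bilstm <- bl$cache
  }
  att <- NULL
  if (!is.null(p$mhsa)) {
    mh <- .mhsaFwd(p$mhsa, a, scale = cfg$scale_scores,
                   buildWeights = attention)
    a <- mh$y
    att <- mh$weights
    if (keep) caches$mhsa <- mh$cache
  }
  mp <- .meanPoolFwd(a)
  hd <- .denseFwd(p$head, mp$y)
  if (keep) { caches$meanPool <- mp$cache; caches$head <- hd$cache }
  list(out = drop(hd$y), caches = caches, attention = att)
}

## Backward pass for MSE loss gradient gOut (n-vector d loss / d output).
.lpcnetBackward <- function(model, caches, gOut) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  hb <- .denseBwd(p$head, caches$head, matrix(gOut, ncol = 1L))
  grads$head <- hb$grads
  ga <- .meanPoolBwd(caches$meanPool, hb$gx)
  if (!is.null(p$mhsa)) {
    mb <- .mhsaBwd(p$mhsa, caches$mhsa, ga)
    grads$mhsa <- mb$grads
    ga <- mb$gx
  }
  if (!is.null(p$bilstm)) {
    bb <- .bilstmBwd(p$bilstm, caches$bilstm, ga)
    grads$bilstm <- bb$grads
    ga <- bb$gx
  }
  for (i in rev(seq_along(cfg$conv_kernels))) {
    cb <- .convBlockBwd(p[[paste0("conv", i)]], caches[[paste0("conv", i)]],
                        ga)
    grads[[paste0("conv", i)]] <- cb$grads
    ga <- cb$gx
  }
  ## order grads to match the parameter list
  grads[names(model$params)]
}

#' Predict pigment content with a trained LPCNet
#'
#' @param object a trained `lpcnetModel`.
#' @param newdata n x B spectra matrix on the training wavelength grid.
#' @param ... unused.
#' @return Numeric predictions on the original target scale.
#' @export
predict.lpcnetModel <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$xScale))
    X <- sweep(sweep(X, 2, object$xScale$mu), 2, object$xScale$sd, `/`)
  out <- .lpcnetForward(object, X)$out
  if (!is.null(object$yScale))
    out <- out * object$yScale$sd + object$yScale$mu
  as.numeric(out)
}

#' Train an LPCNet on a calibration/prediction split
#'
#' Minimizes mean-squared error on the calibration rows with Adam for
#' `config$epochs` epochs, tracking per-epoch calibration loss and
#' prediction-set R^2. Inputs are standardized per band and the target
#' z-scored using calibration statistics only (stored in the model, so
#' `predict` works on raw spectra). The returned report corresponds to
#' the epoch with the best prediction-set R^2 (or the last epoch if
#' `select_best = FALSE`); the returned model carries that epoch's
#' weights. Fully seeded: equal seeds give identical loss curves.
#'
#' @param X n x B spectra matrix (raw reflectance).
#' @param y length-n pigment target (mg/g).
#' @param split a `splitResult` with disjoint calibration/prediction
#'   indices.
#' @param config an [lpcnetConfig()].
#' @param variant model variant (see [buildLPCNet()]).
#' @return List of class `lpcnetFit`: `model`, `report` (one-row
#'   data.frame: rc2, rmsec, rp2, rmsep, mae, best_epoch), `curves`
#'   (epoch, loss, pred_r2).
#' @export
trainLPCNet <- function(X, y, split, config = lpcnetConfig(),
                        variant = "LPCNet") {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(inherits(split, "splitResult"),
            length(intersect(split$calib_idx, split$pred_idx)) == 0L)
  model <- buildLPCNet(ncol(X), config, variant)
  mu <- colMeans(X[split$calib_idx, , drop = FALSE])
  sdv <- apply(X[split$calib_idx, , drop = FALSE], 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  model$xScale <- list(mu = mu, sd = sdv)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  yMu <- mean(y[split$calib_idx]); ySd <- stats::sd(y[split$calib_idx])
  if (ySd == 0) stop("constant calibration target")
  model$yScale <- list(mu = yMu, sd = ySd)
  ys <- (y - yMu) / ySd
  Xc <- Xs[split$calib_idx, , drop = FALSE]; yc <- ys[split$calib_idx]
  Xp <- Xs[split$pred_idx, , drop = FALSE]
  yPredTrue <- y[split$pred_idx]
  nc <- nrow(Xc)
  state <- .adamInit(model$params)
  curves <- data.frame(epoch = integer(0), loss = numeric(0),
                       pred_r2 = numeric(0))
  evalEpoch <- function(epoch) {
    predP <- .lpcnetForward(model, Xp)$out * ySd + yMu
    r2 <- regMetrics(yPredTrue, predP)$r2
    r2
  }
  best <- list(r2 = -Inf, params = model$params, epoch = 0L)
  if (config$epochs == 0L) {
    r2 <- evalEpoch(0L)
    best <- list(r2 = r2, params = model$params, epoch = 0L)
  }
  .withSeed(deriveSeed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nc)
      starts <- seq(1L, nc, by = config$batch_size)
      epochLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, nc)]
        step <- .lpcnetStepCpp(Xc[idx, , drop = FALSE], yc[idx],
                               model$params, config$scale_scores)
        if (!is.finite(step$loss))
          stop("non-finite loss at epoch ", epoch,
               "; try a lower learning rate")
        if (step$rowSumDev > 1e-6)
          stop("attention rows do not sum to 1")
        epochLoss <- epochLoss + step$loss * length(idx)
        up <- .adamStep(model$params, step$grads, state,
                        lr = config$learning_rate)
        model$params <- up$params
        state <- up$state
      }
      r2 <- evalEpoch(epoch)
      curves <- rbind(curves, data.frame(epoch = epoch,
                                         loss = epochLoss / nc,
                                         pred_r2 = r2))
      if (r2 > best$r2) best <- list(r2 = r2, params = model$params,
                                     epoch = epoch)
    }
  })
  if (config$select_best) {
    model$params <- best$params
    bestEpoch <- best$epoch
  } else {
    bestEpoch <- config$epochs
  }
  predC <- predict(model, X[split$calib_idx, , drop = FALSE])
  predP <- predict(model, X[split$pred_idx, , drop = FALSE])
  mc <- regMetrics(y[split$calib_idx], predC)
  mp <- regMetrics(yPredTrue, predP)
  report <- data.frame(model = model$variant,
                       rc2 = mc$r2, rmsec = mc$rmse,
                       rp2 = mp$r2, rmsep = mp$rmse, mae = mp$mae,
                       best_epoch = bestEpoch)
  structure(list(model = model, report = report, curves = curves),
            class = "lpcnetFit")
}

#' @export
print.lpcnetFit <- function(x, ...) {
  print(x$report, digits = 4)
  invisible(x)
}

#' Ablation harness: CNN, CNN-BiLSTM, CNN-MHSA, LPCNet
#'
#' Trains the four module combinations under identical hyperparameters,
#' seeds and split, and returns comparable reports.
#'
#' @inheritParams trainLPCNet
#' @return List of class `lpcnetAblation`: `reports` (4-row data.frame
#'   in the fixed variant order) and `fits` (named list of `lpcnetFit`).
#' @export
ablateLPCNet <- function(X, y, split, config = lpcnetConfig()) {
  fits <- lapply(.lpcnetVariants, function(v)
    trainLPCNet(X, y, split, config, variant = v))
  names(fits) <- .lpcnetVariants
  reports <- do.call(rbind, lapply(fits, `[[`, "report"))
  rownames(reports) <- NULL
  structure(list(reports = reports, fits = fits), class = "lpcnetAblation")
}

#' Multi-head self-attention forward pass
#'
#' The six-step attention computation as a standalone operation: linear
#' Q/K/V projections per head, dot-product scores (optionally scaled by
#' `1/sqrt(d_k)`), row-softmax to non-negative weights summing to 1,
#' value-weighted sums, head concatenation and output projection by
#' `W_O`.
#'
#' @param h input sequence: a T x D matrix, or an n x T x D array.
#' @param params list with `heads` (list per head of `Wq`, `Wk`, `Wv`,
#'   each D x d_h) and `Wo` ((heads * d_h) x D), as produced by
#'   [mhsaParams()].
#' @param scale logical: apply `1/sqrt(d_k)` score scaling (default
#'   `TRUE`).
#' @return List with `output` (same shape as `h`) and `weights`
#'   (n x heads x T x T attention matrices; rows sum to 1).
#' @export
mhsaForward <- function(h, params, scale = TRUE) {
  single <- is.matrix(h)
  if (single) h <- array(h, c(1L, nrow(h), ncol(h)))
  fw <- .mhsaFwd(params, aperm(h, c(1, 3, 2)), scale = scale,
                 buildWeights = TRUE)
  out <- aperm(fw$y, c(1, 3, 2))
  if (single) out <- matrix(out[1L, , ], dim(h)[2], dim(h)[3])
  list(output = out, weights = fw$weights)
}

#' Seeded multi-head attention parameters
#'
#' @param D model width.
#' @param heads number of heads.
#' @param head_dim per-head dimension (default `floor(D / heads)`).
#' @param seed RNG seed.
#' @return Parameter list for [mhsaForward()].
#' @export
mhsaParams <- function(D, heads, head_dim = NULL, seed = 1L) {
  if (is.null(head_dim)) head_dim <- max(1L, D %/% heads)
  .withSeed(seed, .mhsaInit(D, heads, head_dim))
}
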