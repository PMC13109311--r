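## Thin internal wrapper around mixOmics' PLS regression, used both by
## the PLSR model and inside the CARS/UVE/SPA selectors (coefficient
## ranking and cross-validated RMSE). Centering only, no per-column
## scaling (the chemometric convention for reflectance spectra).

.plsSafeNcomp <- function(ncomp, n, p) max(1L, min(ncomp, n - 1L, p))

## mixOmics warns via cor() when a band has zero variance (routine on
## noise-free synthetic spectra whose plateaus are constant); that
## specific warning is muffled, everything else propagates.
.quietPls <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("standard deviation is zero", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

## Effective rank of the centered predictor matrix; latent components
## beyond it make the PLS normal equations singular (exactly collinear
## spectra, e.g. noise-free synthetic data).
.plsRankCap <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  d <- svd(Xc, nu = 0, nv = 0)$d
  max(1L, sum(d > max(d, 0) * 1e-8))
}

.plsFit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("b%d", seq_len(ncol(X)))
  ncomp <- min(.plsSafeNcomp(ncomp, nrow(X), ncol(X)), .plsRankCap(X))
  if (ncol(X) == 1L) {
    ## univariate fall-back: mixOmics needs >= 2 predictors
    fit <- stats::lm.fit(cbind(1, X), y)
    return(structure(list(kind = "lm", coefs = fit$coefficients,
                          cols = colnames(X), ncomp = 1L),
                     class = "plsEngineFit"))
  }
  fit <- .quietPls(mixOmics::pls(X, y, ncomp = ncomp, mode = "regression",
                                 scale = FALSE))
  pr <- .quietPls(stats::predict(fit, X))
  structure(list(kind = "pls", fit = fit, ncomp = ncomp,
                 cols = colnames(X),
                 coef = pr$B.hat[, 1L, ncomp]),
            class = "plsEngineFit")
}

.plsPredict <- function(object, X) {
  X <- as.matrix(X)
  colnames(X) <- object$cols
  if (object$kind == "lm")
    return(as.numeric(cbind(1, X) %*% object$coefs))
  pr <- .quietPls(stats::predict(object$fit, X))
  as.numeric(pr$predict[, 1L, object$ncomp])
}

## Regression coefficients on the original column scale (no intercept).
.plsCoef <- function(object) {
  if (object$kind == "lm") return(object$coefs[-1L])
  object$coef
}

## k-fold cross-validated RMSE of a PLS model with `ncomp` components.
## Fold assignment is deterministic given `seed`.
.plsCVRMSE <- function(X, y, ncomp, folds = 5L, seed = 1L) {
  n <- nrow(X)
  folds <- min(folds, n)
  fold <- .withSeed(seed, sample(rep_len(seq_len(folds), n)))
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- .plsFit(X[tr, , drop = FALSE], y[tr], ncomp)
    press <- press + sum((y[!tr] - .plsPredict(fit, X[!tr, , drop = FALSE]))^2)
  }
  sqrt(press / n)
}

## Choose the PLS component count by k-fold CV over 1..ncomp_max.
## One fit per fold at ncomp_max; mixOmics predicts all component counts
## at once, so PRESS for every candidate falls out of the same fit.
.plsChooseNcomp <- function(X, y, ncomp_max = 15L, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("b%d", seq_len(ncol(X)))
  n <- nrow(X)
  folds <- min(folds, n)
  ncomp_max <- min(.plsSafeNcomp(ncomp_max, n - ceiling(n / folds),
                                 ncol(X)),
                   .plsRankCap(X))
  if (ncol(X) == 1L) return(1L)
  fold <- .withSeed(seed, sample(rep_len(seq_len(folds), n)))
  press <- numeric(ncomp_max)
  for (f in seq_len(folds)) {
    tr <- fold != f
    ncf <- min(ncomp_max, .plsRankCap(X[tr, , drop = FALSE]))
    fit <- .quietPls(mixOmics::pls(X[tr, , drop = FALSE], y[tr],
                                   ncomp = ncf, mode = "regression",
                                   scale = FALSE))
    pr <- .quietPls(stats::predict(fit, X[!tr, , drop = FALSE]))$predict
    pm <- matrix(pr, nrow = sum(!tr), ncol = ncf)
    if (ncf < ncomp_max)                 # reuse the deepest fitted comp
      pm <- cbind(pm, matrix(pm[, ncf], sum(!tr), ncomp_max - ncf))
    press <- press + colSums((y[!tr] - pm)^2)
  }
  which.min(press)
}
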