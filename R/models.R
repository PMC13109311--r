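## The four classical multivariate regressors and the evaluation metrics.
## Each fit* function returns an object with a predict() method; all are
## trained per pigment (one scalar model per target).

#' Regression evaluation metrics
#'
#' `rmse = sqrt(mean((y - yhat)^2))`,
#' `r2 = 1 - SSres/SStot` (SStot about the mean of `y_true`), and
#' `mae = mean(|y - yhat|)`.
#'
#' @param y_true observed values.
#' @param y_pred predicted values (same nonzero length).
#' @return Named list `rmse`, `r2`, `mae`.
#' @examples
#' regMetrics(c(0, 1, 2), c(0, 2, 2))  # rmse sqrt(1/3), r2 0.5, mae 1/3
#' @export
regMetrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal nonzero length")
  res <- y_true - y_pred
  sstot <- sum((y_true - mean(y_true))^2)
  if (sstot == 0) stop("constant y_true: r2 undefined")
  list(rmse = sqrt(mean(res^2)),
       r2 = 1 - sum(res^2) / sstot,
       mae = mean(abs(res)))
}

#' Fit the classical regressors
#'
#' @param X calibration predictor matrix (n x p).
#' @param y calibration response.
#' @param ncomp PLSR components; `NULL` chooses by 5-fold CV up to
#'   `ncomp_max`.
#' @param ncomp_max PLSR component ceiling for CV choice (default 15).
#' @param seed seed for stochastic fits (RF, ELM, CV folds).
#' @return A fitted model object with a `predict(object, X)` method
#'   returning a numeric vector.
#' @name fitModels
NULL

#' @rdname fitModels
#' @export
fitPLSR <- function(X, y, ncomp = NULL, ncomp_max = 15L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(ncomp))
    ncomp <- .plsChooseNcomp(X, y, ncomp_max = ncomp_max, seed = seed)
  fit <- .plsFit(X, y, ncomp)
  structure(list(fit = fit, ncomp = fit$ncomp), class = "plsrModel")
}

#' @export
predict.plsrModel <- function(object, newdata, ...)
  .plsPredict(object$fit, as.matrix(newdata))

#' @rdname fitModels
#' @param ntree random-forest tree count (default 500).
#' @export
fitRF <- function(X, y, ntree = 500L, seed = 1L) {
  X <- as.matrix(X)
  colnames(X) <- sprintf("b%d", seq_len(ncol(X)))
  rf <- .withSeed(seed, randomForest::randomForest(X, y, ntree = ntree))
  structure(list(rf = rf, cols = colnames(X)), class = "rfModel")
}

#' @export
predict.rfModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$cols
  as.numeric(stats::predict(object$rf, newdata))
}

#' @rdname fitModels
#' @param cost_grid,gamma_factors RBF-SVR hyperparameter grid: `C` values
#'   and multipliers of the `1/p` gamma heuristic, tuned by 5-fold CV on
#'   the calibration set.
#' @export
fitSVR <- function(X, y, cost_grid = c(1, 10, 100),
                   gamma_factors = c(0.1, 1, 10), seed = 1L) {
  X <- as.matrix(X)
  ## standardize with calibration statistics only
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  gamma0 <- 1 / ncol(X)
  best <- NULL; bestErr <- Inf
  folds <- .withSeed(seed, sample(rep_len(1:5, nrow(X))))
  for (C in cost_grid) for (gf in gamma_factors) {
    err <- 0
    for (f in 1:5) {
      tr <- folds != f
      if (all(tr) || !any(tr)) next
      m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "radial", cost = C, gamma = gamma0 * gf)
      err <- err + sum((y[!tr] - stats::predict(m, Xs[!tr, , drop = FALSE]))^2)
    }
    if (err < bestErr) { bestErr <- err; best <- c(C = C, gamma = gamma0 * gf) }
  }
  m <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                  cost = best["C"], gamma = best["gamma"])
  structure(list(svm = m, mu = mu, sd = sdv, pars = best), class = "svrModel")
}

#' @export
predict.svrModel <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$mu), 2, object$sd, `/`)
  as.numeric(stats::predict(object$svm, Xs))
}

#' @rdname fitModels
#' @param n_hidden hidden sigmoid units for the extreme learning machine
#'   (default 200).
#' @details The extreme learning machine draws hidden weights and biases
#'   from the seeded generator (uniform on \[-1, 1\] over standardized
#'   inputs), computes the sigmoid hidden activation matrix `H`, and
#'   solves the output weights by Moore-Penrose pseudoinverse of `H`.
#'   With at least `n` hidden units on distinct inputs it interpolates
#'   its calibration set.
#' @export
fitELM <- function(X, y, n_hidden = 200L, seed = 1L) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  p <- ncol(X)
  .withSeed(seed, {
    W <- matrix(stats::runif(p * n_hidden, -1, 1), p, n_hidden)
    b <- stats::runif(n_hidden, -1, 1)
    H <- stats::plogis(Xs %*% W + matrix(b, nrow(Xs), n_hidden, byrow = TRUE))
    beta <- drop(MASS::ginv(H) %*% y)
    structure(list(W = W, b = b, beta = beta, mu = mu, sd = sdv),
              class = "elmModel")
  })
}

#' @export
predict.elmModel <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$mu), 2, object$sd, `/`)
  H <- stats::plogis(Xs %*% object$W +
                       matrix(object$b, nrow(Xs), length(object$b),
                              byrow = TRUE))
  drop(H %*% object$beta)
}

## Evaluate one fitted model on calibration and prediction sets.
.fitReport <- function(model, Xc, yc, Xp, yp, modelTag, comboTag) {
  mc <- regMetrics(yc, stats::predict(model, Xc))
  mp <- regMetrics(yp, stats::predict(model, Xp))
  data.frame(combo = comboTag, model = modelTag,
             rc2 = mc$r2, rmsec = mc$rmse,
             rp2 = mp$r2, rmsep = mp$rmse, mae = mp$mae)
}
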