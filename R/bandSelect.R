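## Wavelength (variable) selection: CARS, SPA, UVE and LARS.
##
## All four are pure functions of (X, y, config, seed): equal seeds give
## identical results, and every ranking tie is broken by the lower band
## index. Selected indices always refer to the matrix handed in, so
## selection composes cleanly with any fit-free preprocessing.

.selectionResult <- function(selected, trace, method, config, seed = NULL) {
  structure(list(selected = sort(unique(as.integer(selected))),
                 trace = trace, method = method, config = config,
                 seed = seed),
            class = "selectionResult")
}

#' @export
print.selectionResult <- function(x, ...) {
  cat(sprintf("selectionResult[%s]: %d bands selected\n", x$method,
              length(x$selected)))
  invisible(x)
}

#' Write a selection result as JSON
#'
#' @param x a `selectionResult`.
#' @param path output path.
#' @export
writeSelectionJSON <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo PLS-based selection. Each iteration fits PLS on a random
#' row subset, ranks bands by absolute regression coefficient, keeps the
#' top fraction dictated by an exponentially decreasing function
#' (`r_i = a exp(-k i)` calibrated so `r_1 = 1` and `r_runs = 2/B`), then
#' performs adaptive reweighted sampling (with replacement, probability
#' proportional to |coefficient|) among the survivors. The returned
#' subset is the iteration minimizing k-fold cross-validated RMSE.
#'
#' @param X n x B predictor matrix (calibration rows only).
#' @param y response vector.
#' @param runs Monte-Carlo iterations (default 50).
#' @param subsampling row fraction fitted per iteration (default 0.8).
#' @param cv_folds folds for the per-iteration RMSE (default 5).
#' @param ncomp_max PLS component ceiling (default 10).
#' @param seed RNG seed.
#' @return A `selectionResult`; `trace` has one row per iteration with
#'   the exponential-decrease target count (`edf_count`), the retained
#'   count after reweighted sampling, and the cross-validated RMSE.
#' @export
carsSelect <- function(X, y, runs = 50L, subsampling = 0.8, cv_folds = 5L,
                       ncomp_max = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); B <- ncol(X)
  if (stats::var(y) == 0) stop("degenerate y: zero variance")
  if (runs < 2L) stop("runs must be >= 2")
  if (n < 2L * cv_folds) stop("need n >= 2 * cv_folds")
  ## EDF constants: r_1 = 1, r_runs = 2/B
  k <- log(B / 2) / (runs - 1L)
  a <- exp(k)
  .withSeed(seed, {
    S <- seq_len(B)
    trace <- data.frame(iteration = seq_len(runs), edf_count = NA_integer_,
                        retained = NA_integer_, rmse_cv = NA_real_)
    subsets <- vector("list", runs)
    for (i in seq_len(runs)) {
      rows <- sample.int(n, max(2L, round(subsampling * n)))
      fit <- .plsFit(X[rows, S, drop = FALSE], y[rows], ncomp_max)
      w <- abs(.plsCoef(fit))
      edf_n <- as.integer(max(2, round(a * exp(-k * i) * B)))
      if (edf_n < length(S)) {
        keep <- order(-w, seq_along(S))[seq_len(edf_n)]
        S <- S[keep]; w <- w[keep]
      }
      ## adaptive reweighted sampling among the survivors
      if (any(w > 0)) {
        draw <- sample(seq_along(S), size = length(S), replace = TRUE,
                       prob = w)
        S <- sort(unique(S[draw]))
      }
      trace$edf_count[i] <- edf_n
      trace$retained[i] <- length(S)
      trace$rmse_cv[i] <- .plsCVRMSE(X[, S, drop = FALSE], y, ncomp_max,
                                     cv_folds, seed = sample.int(2^30, 1))
      subsets[[i]] <- S
      if (length(S) <= 2L) {
        trace <- trace[seq_len(i), ]; subsets <- subsets[seq_len(i)]
        break
      }
    }
    best <- which.min(trace$rmse_cv)
    .selectionResult(subsets[[best]], trace, "CARS",
                     list(runs = runs, subsampling = subsampling,
                          cv_folds = cv_folds, ncomp_max = ncomp_max,
                          best_iteration = best),
                     as.integer(seed))
  })
}

#' Successive projections algorithm (SPA)
#'
#' Greedy forward selection that minimizes collinearity: starting from
#' `first_band`, repeatedly adds the band whose column has the largest
#' norm after orthogonal projection onto the complement of the span of
#' the already-selected columns. Deterministic given `first_band`;
#' `first_band = "auto"` tries every start and keeps the chain with the
#' best PLS cross-validated RMSE (the same criterion CARS uses).
#'
#' @param X n x B predictor matrix.
#' @param k_max chain length (must not exceed `min(n - 1, B)`).
#' @param first_band starting band index, or `"auto"`.
#' @param y response, required for `"auto"` scoring.
#' @param cv_folds,seed cross-validation controls for `"auto"`.
#' @return A `selectionResult`; `trace` holds the projected norm at each
#'   step. Collinear duplicates of already-selected columns have zero
#'   projected norm and are never selected.
#' @export
spaSelect <- function(X, k_max, first_band = 1L, y = NULL, cv_folds = 5L,
                      seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); B <- ncol(X)
  k_max <- .assertCount(k_max, "k_max")
  if (k_max > min(n - 1L, B))
    stop("k_max exceeds min(n - 1, B)")
  chainFrom <- function(start) {
    R <- scale(X, center = TRUE, scale = FALSE)   # work on centered columns
    sel <- integer(0)
    norms <- numeric(0)
    cand <- start
    for (step in seq_len(k_max)) {
      v <- R[, cand]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-10) break                        # collinear: stop chain
      sel <- c(sel, cand)
      norms <- c(norms, nv)
      u <- v / nv
      R <- R - u %*% crossprod(u, R)               # project out the span
      rn <- sqrt(colSums(R^2))
      rn[sel] <- -Inf
      if (length(sel) == k_max || max(rn) < 1e-10) break
      cand <- which.max(rn)                        # ties -> lowest index
    }
    list(sel = sel, norms = norms)
  }
  chainTrace <- function(ch)
    data.frame(step = seq_along(ch$norms), band = ch$sel,
               projected_norm = ch$norms)
  if (identical(first_band, "auto")) {
    if (is.null(y)) stop("first_band = 'auto' needs y for CV scoring")
    best <- NULL; bestRMSE <- Inf; bestStart <- NA_integer_
    for (s in seq_len(B)) {
      ch <- chainFrom(s)
      if (length(ch$sel) < 1L) next
      r <- .plsCVRMSE(X[, ch$sel, drop = FALSE], as.numeric(y),
                      ncomp = min(10L, length(ch$sel)), folds = cv_folds,
                      seed = seed)
      if (r < bestRMSE) { bestRMSE <- r; best <- ch; bestStart <- s }
    }
    return(.selectionResult(best$sel, chainTrace(best), "SPA",
                            list(k_max = k_max, first_band = bestStart,
                                 auto = TRUE, cv_rmse = bestRMSE),
                            as.integer(seed)))
  }
  first_band <- .assertCount(first_band, "first_band")
  ch <- chainFrom(first_band)
  .selectionResult(ch$sel, chainTrace(ch), "SPA",
                   list(k_max = k_max, first_band = first_band,
                        auto = FALSE))
}

#' Uninformative variable elimination (UVE)
#'
#' Appends `n_noise` artificial uniform-noise columns (magnitude
#' `1e-3 * max|X|`), runs leave-one-out PLS, and scores every column by
#' its coefficient stability `c_j = mean(b_j) / sd(b_j)` across folds.
#' Real bands are kept only when `|c_j|` exceeds the `cutoff_quantile`
#' quantile of the noise columns' `|c|` -- i.e. when they are more stable
#' than noise.
#'
#' @param X n x B predictor matrix (n >= 10).
#' @param y response vector.
#' @param n_noise number of appended noise columns (default `ncol(X)`).
#' @param cutoff_quantile noise-stability quantile (default 0.99).
#' @param ncomp_max PLS component ceiling (default 10).
#' @param seed RNG seed (noise draw only; the LOO loop is deterministic).
#' @return A `selectionResult`; `trace` holds per-band stability and the
#'   cutoff.
#' @export
uveSelect <- function(X, y, n_noise = NULL, cutoff_quantile = 0.99,
                      ncomp_max = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); B <- ncol(X)
  if (n < 10L) stop("UVE needs n >= 10")
  if (is.null(n_noise)) n_noise <- B
  .withSeed(seed, {
    noise <- matrix(stats::runif(n * n_noise, 0, 1e-3 * max(abs(X))),
                    n, n_noise)
    XA <- cbind(X, noise)
    colnames(XA) <- sprintf("b%d", seq_len(ncol(XA)))
    ncomp <- .plsSafeNcomp(ncomp_max, n - 1L, ncol(XA))
    b <- matrix(NA_real_, n, ncol(XA))
    for (i in seq_len(n)) {
      fit <- .plsFit(XA[-i, , drop = FALSE], y[-i], ncomp)
      b[i, ] <- .plsCoef(fit)
    }
    sdv <- apply(b, 2, stats::sd)
    sdv[sdv == 0] <- .Machine$double.eps
    stab <- colMeans(b) / sdv
    cutoff <- stats::quantile(abs(stab[(B + 1):(B + n_noise)]),
                              cutoff_quantile, names = FALSE)
    keep <- which(abs(stab[seq_len(B)]) > cutoff)
    if (!length(keep))
      stop("UVE eliminated every band; lower cutoff_quantile")
    .selectionResult(keep,
                     list(stability = stab[seq_len(B)], cutoff = cutoff,
                          noise_stability = stab[(B + 1):(B + n_noise)]),
                     "UVE",
                     list(n_noise = n_noise,
                          cutoff_quantile = cutoff_quantile,
                          ncomp_max = ncomp_max),
                     as.integer(seed))
  })
}

#' Least angle regression (LARS) band ranking
#'
#' Runs the LARS path on internally standardized columns and returns the
#' first `k` bands to enter the active set, in entry order. On an
#' orthogonal design the entry order equals the ranking of absolute
#' correlation with `y`.
#'
#' @param X n x B predictor matrix.
#' @param y response vector.
#' @param k number of bands to return (k <= B).
#' @return A `selectionResult`; `selected` is sorted, `trace$entry_order`
#'   preserves the path order.
#' @export
larsSelect <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); B <- ncol(X)
  k <- .assertCount(k, "k")
  if (k > B) stop("k exceeds the number of bands")
  ## standardize columns; constant columns get zero weight and never enter
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  yc <- y - mean(y)
  mu <- rep(0, n)
  active <- integer(0)
  kEff <- min(k, n - 1L, sum(attr(Xs, "scaled:scale") > 0))
  while (length(active) < kEff) {
    cvec <- drop(crossprod(Xs, yc - mu))
    if (length(active) == 0L)
      active <- unname(which.max(abs(cvec)))
    s <- sign(cvec[active])
    s[s == 0] <- 1
    Xa <- sweep(Xs[, active, drop = FALSE], 2, s, `*`)
    G <- crossprod(Xa)
    Ginv1 <- tryCatch(solve(G, rep(1, length(active))),
                      error = function(e)
                        drop(MASS::ginv(G) %*% rep(1, length(active))))
    AA <- 1 / sqrt(sum(Ginv1))
    u <- drop(Xa %*% (AA * Ginv1))                 # equiangular direction
    a <- drop(crossprod(Xs, u))
    Cmax <- max(abs(cvec[active]))
    if (length(active) >= kEff) break
    inactive <- setdiff(seq_len(B), active)
    g1 <- (Cmax - cvec[inactive]) / (AA - a[inactive])
    g2 <- (Cmax + cvec[inactive]) / (AA + a[inactive])
    g1[!is.finite(g1) | g1 <= 1e-12] <- Inf
    g2[!is.finite(g2) | g2 <= 1e-12] <- Inf
    gam <- pmin(g1, g2)
    if (all(!is.finite(gam))) break
    jstar <- which.min(gam)                        # ties -> lowest index
    mu <- mu + gam[jstar] * u
    active <- c(active, unname(inactive[jstar]))
  }
  .selectionResult(active,
                   list(entry_order = active),
                   "LARS", list(k = k))
}

#' Fraction of truth bands recovered by a selection
#'
#' A truth band counts as recovered when a selected band lies within
#' `tol` band indices of it. On a ~2.4 nm grid the default `tol = 3`
#' (~7 nm) sits well inside an 18 nm-wide absorption feature, where
#' neighbouring bands carry essentially the same signal and exact-index
#' identifiability is physically impossible.
#'
#' @param selected integer band indices (or a `selectionResult`).
#' @param truth integer truth-band indices.
#' @param tol neighbourhood half-width in band indices (default 3).
#' @return Fraction of `truth` recovered, in `[0, 1]`.
#' @export
bandRecovery <- function(selected, truth, tol = 3L) {
  if (inherits(selected, "selectionResult")) selected <- selected$selected
  if (!length(truth)) stop("empty truth set")
  mean(vapply(truth, function(b) any(abs(selected - b) <= tol), TRUE))
}
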