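## Calibration/prediction partitioning. KS and SPXY are deterministic
## max-min greedy selections; Random depends only on its seed. Default
## ratio 0.75 (3:1 calibration:prediction), standard chemometrics
## practice.

.splitResult <- function(calib, pred, method, ratio, seed = NULL) {
  structure(list(calib_idx = sort(unname(as.integer(calib))),
                 pred_idx = sort(unname(as.integer(pred))),
                 method = method, ratio = ratio, seed = seed),
            class = "splitResult")
}

#' @export
print.splitResult <- function(x, ...) {
  cat(sprintf("splitResult[%s]: %d calibration / %d prediction (ratio %.2f)\n",
              x$method, length(x$calib_idx), length(x$pred_idx), x$ratio))
  invisible(x)
}

#' Random calibration/prediction split
#'
#' Uniform draw without replacement; reproducible per seed.
#'
#' @param n number of samples.
#' @param ratio calibration fraction in (0, 1); calibration size is
#'   `round(ratio * n)`.
#' @param seed RNG seed.
#' @return A `splitResult`: list with `calib_idx`, `pred_idx`, `method`,
#'   `ratio`, `seed`.
#' @export
randomSplit <- function(n, ratio = 0.75, seed = 1L) {
  n <- .assertCount(n, "n", 2L)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  nc <- round(ratio * n)
  if (nc < 1L || nc >= n) stop("split leaves one side empty")
  calib <- .withSeed(seed, sample.int(n, nc))
  .splitResult(calib, setdiff(seq_len(n), calib), "Random", ratio,
               as.integer(seed))
}

## Greedy max-min selection given a full distance matrix. Seeded with the
## global farthest pair; then repeatedly adds the sample whose minimum
## distance to the chosen set is largest. All ties broken by smallest
## index, so runs are bitwise reproducible.
.maxminSelect <- function(D, nc) {
  n <- nrow(D)
  Dd <- D
  diag(Dd) <- -Inf
  far <- which(Dd == max(Dd), arr.ind = TRUE)[1L, ] # earliest max pair
  sel <- sort(c(far[1L], far[2L]))
  if (nc <= 2L) return(sel[seq_len(nc)])
  mind <- pmin(D[, sel[1L]], D[, sel[2L]])
  mind[sel] <- -Inf
  while (length(sel) < nc) {
    nxt <- which.max(mind)                          # ties -> lowest index
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  sel
}

#' Kennard-Stone split
#'
#' Deterministic max-min selection in predictor space: the calibration
#' set starts from the farthest Euclidean pair, then grows by always
#' adding the sample farthest (in min-distance sense) from the current
#' set. The most extreme samples therefore always land in calibration.
#'
#' @param X n x B predictor matrix.
#' @inheritParams randomSplit
#' @return A `splitResult`.
#' @export
kennardStone <- function(X, ratio = 0.75) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  nc <- round(ratio * n)
  if (nc < 2L) nc <- 2L
  if (nc >= n) stop("split leaves one side empty")
  D <- as.matrix(stats::dist(X))
  sel <- .maxminSelect(D, nc)
  .splitResult(sel, setdiff(seq_len(n), sel), "KS", ratio)
}

#' SPXY split (joint X-Y distances)
#'
#' Kennard-Stone greedy max-min on the joint distance
#' `d(i,j) = d_x(i,j)/max(d_x) + d_y(i,j)/max(d_y)` with Euclidean
#' distance in X and `|y_i - y_j|` in y (each matrix normalized by its
#' own maximum), so the calibration set is representative in both
#' predictor and response space. With constant `y` the response term
#' vanishes and the result equals [kennardStone()].
#'
#' @param X n x B predictor matrix.
#' @param y response vector (the model's own target).
#' @inheritParams randomSplit
#' @return A `splitResult`.
#' @export
spxySplit <- function(X, y, ratio = 0.75) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (any(!is.finite(y))) stop("y must be finite")
  n <- nrow(X)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  nc <- round(ratio * n)
  if (nc < 2L) nc <- 2L
  if (nc >= n) stop("split leaves one side empty")
  Dx <- as.matrix(stats::dist(X))
  Dy <- abs(outer(y, y, `-`))
  D <- if (max(Dx) > 0) Dx / max(Dx) else Dx   # constant X: y decides
  if (max(Dy) > 0) D <- D + Dy / max(Dy)       # constant y falls back to KS
  sel <- .maxminSelect(D, nc)
  .splitResult(sel, setdiff(seq_len(n), sel), "SPXY", ratio)
}
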