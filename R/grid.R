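## The combination-grid runner: {none, MA, SNV, D1} preprocessing x
## {CARS, SPA, LARS, UVE} band selection x {Random, KS, SPXY} splitting x
## {PLSR, RF, SVR, ELM} regression, per pigment. The full grid is
## 4 x 4 x 3 x 4 = 192 combinations per pigment.
##
## Leakage discipline: preprocessing is fit-free and applied to all
## spectra; band selection and every fitted statistic use calibration
## rows only. Prediction-set responses influence nothing but the final
## prediction metrics (KS uses X only; SPXY consults the full response
## by construction of the splitting method itself).

.gridSelect <- function(method, Xc, yc, seed) {
  switch(method,
    none = .selectionResult(seq_len(ncol(Xc)), NULL, "none", list()),
    CARS = carsSelect(Xc, yc, seed = seed),
    SPA = spaSelect(Xc, k_max = min(25L, nrow(Xc) - 2L, ncol(Xc)),
                    first_band = "auto", y = yc, seed = seed),
    LARS = larsSelect(Xc, yc, k = min(25L, ncol(Xc))),
    UVE = uveSelect(Xc, yc, seed = seed),
    stop("unknown selector: ", method))
}

.gridFit <- function(method, Xc, yc, seed) {
  switch(method,
    PLSR = fitPLSR(Xc, yc, seed = seed),
    RF = fitRF(Xc, yc, seed = seed),
    SVR = fitSVR(Xc, yc, seed = seed),
    ELM = fitELM(Xc, yc, n_hidden = min(200L, 4L * nrow(Xc)), seed = seed),
    stop("unknown model: ", method))
}

.gridSplit <- function(method, X, y, ratio, seed) {
  switch(method,
    Random = randomSplit(nrow(X), ratio, seed = seed),
    KS = kennardStone(X, ratio),
    SPXY = spxySplit(X, y, ratio),
    stop("unknown splitter: ", method))
}

#' Run the preprocessing x selection x splitting x model grid
#'
#' For every combination and pigment: preprocess all spectra (fit-free),
#' split into calibration/prediction sets, select bands on the
#' calibration rows only, fit on calibration, and evaluate both sets.
#' Stage failures are recorded per combination and the grid continues.
#'
#' @param dataset a [SpectraSet-class] with all four pigment targets.
#' @param preps,selectors,splitters,models character vectors naming the
#'   grid axes (defaults: the full grid).
#' @param targets pigment columns to model (default all four).
#' @param ratio calibration fraction (default 0.75).
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it and the combination label, so reruns reproduce every report.
#' @return A list of class `gridResult`: `table` (one row per
#'   combo x pigment with rc2/rmsec/rp2/rmsep/mae and the selected
#'   bands), `best` (per-pigment row maximizing rp2), `errors`.
#' @export
runGrid <- function(dataset,
                    preps = c("none", "MA", "SNV", "D1"),
                    selectors = c("CARS", "SPA", "LARS", "UVE"),
                    splitters = c("Random", "KS", "SPXY"),
                    models = c("PLSR", "RF", "SVR", "ELM"),
                    targets = .pigmentNames,
                    ratio = 0.75, seed = 1L) {
  stopifnot(is(dataset, "SpectraSet"))
  pg <- pigments(dataset)
  if (is.null(pg)) stop("dataset has no pigment targets")
  X0 <- spectraMatrix(dataset)
  wl <- wavelengths(dataset)
  rows <- list(); errors <- list()
  for (prep in preps) {
    X <- applyPrep(X0, prepSpec(prep), wavelengths = wl)
    for (target in targets) {
      y <- pg[, target]
      for (splitter in splitters) {
        for (selector in selectors) {
          for (model in models) {
            combo <- paste(prep, selector, splitter, model, sep = "-")
            tag <- paste(combo, target, sep = ":")
            res <- tryCatch({
              sd1 <- deriveSeed(seed, tag, "split")
              sp <- .gridSplit(splitter, X, y, ratio, sd1)
              Xc <- X[sp$calib_idx, , drop = FALSE]
              yc <- y[sp$calib_idx]
              sel <- .gridSelect(selector, Xc, yc,
                                 deriveSeed(seed, tag, "select"))
              Xcs <- Xc[, sel$selected, drop = FALSE]
              fit <- .gridFit(model, Xcs, yc, deriveSeed(seed, tag, "fit"))
              Xps <- X[sp$pred_idx, sel$selected, drop = FALSE]
              rep <- .fitReport(fit, Xcs, yc, Xps, y[sp$pred_idx],
                                model, combo)
              rep$pigment <- target
              rep$selected_bands <- paste(sel$selected, collapse = ",")
              rep
            }, error = function(e) e)
            if (inherits(res, "error")) {
              errors[[tag]] <- conditionMessage(res)
            } else {
              rows[[tag]] <- res
            }
          }
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- NULL
  if (!is.null(tab)) {
    best <- do.call(rbind, lapply(split(tab, tab$pigment), function(d)
      d[which.max(d$rp2), ]))
    rownames(best) <- NULL
  }
  structure(list(table = tab, best = best, errors = errors, seed = seed,
                 ratio = ratio),
            class = "gridResult")
}

#' @export
print.gridResult <- function(x, ...) {
  cat(sprintf("gridResult: %d combo evaluations, %d failures\n",
              if (is.null(x$table)) 0L else nrow(x$table),
              length(x$errors)))
  if (!is.null(x$best)) {
    cat("best combination per pigment (by rp2):\n")
    print(x$best[, c("pigment", "combo", "rc2", "rmsec", "rp2", "rmsep",
                     "mae")], digits = 4)
  }
  invisible(x)
}

#' Write a gridResult as tidy CSV + JSON best-combo summary
#'
#' @param x a `gridResult`.
#' @param dir output directory.
#' @export
writeGridResult <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$table[, c("combo", "pigment", "rc2", "rmsec", "rp2",
                               "rmsep", "mae")],
                   file.path(dir, "grid_results.csv"), row.names = FALSE)
  jsonlite::write_json(x$best, file.path(dir, "best_combos.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
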