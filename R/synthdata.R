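## Synthetic leaf/canopy spectra with known pigment -> reflectance physics.
##
## The generator emulates the qualitative physiognomy of a green-leaf
## Vis-NIR reflectance spectrum: a low visible plateau, a green reflectance
## peak near 550 nm, a sigmoid red edge rising over 690-750 nm to a NIR
## plateau, and pigment-weighted Gaussian absorption troughs. Blue-region
## absorption centres follow the in vivo pigment maxima (Chl a 430 nm,
## Chl b 450 nm, carotenoids 470 nm); the red chlorophyll features sit at
## 680 nm (Chl a) and 650 nm (Chl b), the in vivo positions, so the mean
## spectrum shows its red trough inside 670-690 nm as real leaves do.

.ABS_CENTERS <- list(chla = c(430, 680), chlb = c(450, 650), car = 470)
.ABS_WIDTH <- 18        # nm, Gaussian sd of each absorption band
.ABS_STRENGTH <- c(chla = 0.05, chlb = 0.05, car = 0.10)  # reflectance per mg/g
.SOIL_REFLECTANCE <- 0.15

.gauss <- function(x, mu, sd) exp(-0.5 * ((x - mu) / sd)^2)

## B x 3 matrix of unit-concentration absorption loadings per pigment.
.pigmentLoadings <- function(wl) {
  L <- sapply(c("chla", "chlb", "car"), function(p) {
    rowSums(sapply(.ABS_CENTERS[[p]], function(mu) .gauss(wl, mu, .ABS_WIDTH)))
  })
  colnames(L) <- c("chla", "chlb", "car")
  L
}

## Pigment-free base reflectance curve.
.baseCurve <- function(wl) {
  0.10 +                                        # visible plateau
    0.45 / (1 + exp(-(wl - 720) / 10)) +        # red edge -> NIR plateau
    0.08 * .gauss(wl, 550, 20)                  # green reflectance peak
}

## Evaluate reflectance for an n x 3 concentration matrix (no noise).
.leafReflectance <- function(wl, conc, nonlinearity = FALSE) {
  L <- .pigmentLoadings(wl)                     # B x 3
  alpha <- .ABS_STRENGTH
  if (nonlinearity) {
    ## Beer-Lambert-style saturation: depth = amp * (1 - exp(-k c)),
    ## with k set so the top of each pigment's biological range reaches
    ## ~80% of saturation, and amp matched to the linear-mode depth there.
    cmax <- c(chla = 0.99, chlb = 0.45, car = 0.23)
    k <- log(5) / cmax
    amp <- alpha * cmax / 0.8
    depth <- sapply(seq_len(3), function(p)
      amp[p] * (1 - exp(-k[p] * conc[, p])))
  } else {
    depth <- sweep(conc, 2, alpha, `*`)         # n x 3, linear mixing
  }
  base <- .baseCurve(wl)
  R <- matrix(base, nrow(conc), length(wl), byrow = TRUE) -
    depth %*% t(L)
  R
}

.defaultRanges <- function() {
  list(chla = c(0.68, 0.99), chlb = c(0.29, 0.45), car = c(0.14, 0.23))
}

#' Configuration for the synthetic spectra generator
#'
#' Defaults mirror the study conditions this package targets: 256 spectral
#' channels over 366-976 nm and leaf pigment concentrations of
#' Chl a 0.68-0.99, Chl b 0.29-0.45 and carotenoids 0.14-0.23 mg/g.
#'
#' @param n_samples number of leaf spectra to simulate.
#' @param n_bands number of spectral channels (default 256).
#' @param wl_min,wl_max wavelength range in nm (defaults 366, 976).
#' @param pigment_ranges named list of `c(low, high)` mg/g ranges for
#'   `chla`, `chlb`, `car` (TPC is always their sum).
#' @param noise_sd additive Gaussian noise, reflectance units (default
#'   0.002, roughly 0.5% of the visible-plateau signal).
#' @param nonlinearity if `TRUE`, absorption depth saturates
#'   Beer-Lambert-style as `1 - exp(-k c)`; if `FALSE` (default) the
#'   pigment-to-spectrum map is affine.
#' @param seed integer RNG seed; equal seeds give bitwise-equal batches.
#' @return A list of class `generatorConfig`.
#' @export
generatorConfig <- function(n_samples = 100L, n_bands = 256L,
                            wl_min = 366, wl_max = 976,
                            pigment_ranges = .defaultRanges(),
                            noise_sd = 0.002, nonlinearity = FALSE,
                            seed = 1L) {
  n_samples <- .assertCount(n_samples, "n_samples")
  n_bands <- .assertCount(n_bands, "n_bands", min = 2L)
  if (wl_min >= wl_max) stop("wl_min must be < wl_max")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (p in c("chla", "chlb", "car")) {
    r <- pigment_ranges[[p]]
    if (is.null(r) || length(r) != 2L || r[1] >= r[2] || r[1] <= 0)
      stop(sprintf("pigment_ranges$%s must be c(low, high) with 0 < low < high", p))
  }
  structure(list(n_samples = n_samples, n_bands = n_bands,
                 wl_min = wl_min, wl_max = wl_max,
                 pigment_ranges = pigment_ranges[c("chla", "chlb", "car")],
                 noise_sd = noise_sd, nonlinearity = isTRUE(nonlinearity),
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

#' Evenly spaced wavelength axis
#'
#' @param config a [generatorConfig()] (or anything with `wl_min`,
#'   `wl_max`, `n_bands`).
#' @return Strictly increasing numeric vector of length `n_bands` with
#'   endpoints `wl_min` and `wl_max`.
#' @examples
#' wl <- makeWavelengthAxis(generatorConfig())
#' range(wl); diff(wl)[1]
#' @export
makeWavelengthAxis <- function(config) {
  n <- .assertCount(config$n_bands, "n_bands", min = 2L)
  seq(config$wl_min, config$wl_max, length.out = n)
}

## Run expr under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

## Indices of bands causally tied to the pigments: the band nearest each
## absorption centre. Kept minimal so the set is identifiable by design.
.truthBands <- function(wl) {
  centers <- sort(unique(unlist(.ABS_CENTERS)))
  sort(unique(vapply(centers, function(mu) .nearestBand(wl, mu), 1L)))
}

## Same, split by pigment: the bands causally tied to one target.
.truthBandsByPigment <- function(wl) {
  lapply(.ABS_CENTERS, function(mus)
    sort(unique(vapply(mus, function(mu) .nearestBand(wl, mu), 1L))))
}

#' Simulate a batch of leaf spectra with known pigment truth
#'
#' Draws pigment concentrations uniformly within the configured ranges
#' (TPC computed as their exact sum), evaluates the pigment-to-reflectance
#' model, adds Gaussian noise, and clips to `[0, 1.05]` (admitting slight
#' white-reference overshoot as real calibrated cubes do).
#'
#' @param config a [generatorConfig()].
#' @return A [SpectraSet-class] with pigment targets in `colData` and the
#'   informative band indices in `metadata(x)$truth_bands`.
#' @examples
#' ss <- simulateLeafSpectra(generatorConfig(n_samples = 10, seed = 7))
#' dim(spectraMatrix(ss))
#' head(pigments(ss))
#' @export
simulateLeafSpectra <- function(config) {
  stopifnot(inherits(config, "generatorConfig"))
  wl <- makeWavelengthAxis(config)
  .withSeed(config$seed, {
    n <- config$n_samples
    conc <- sapply(config$pigment_ranges, function(r) runif(n, r[1], r[2]))
    conc <- matrix(conc, nrow = n,
                   dimnames = list(NULL, c("chla", "chlb", "car")))
    R <- .leafReflectance(wl, conc, config$nonlinearity)
    if (config$noise_sd > 0)
      R <- R + matrix(rnorm(length(R), 0, config$noise_sd), nrow(R))
    R <- pmin(pmax(R, 0), 1.05)
    targets <- cbind(conc,
                     tpc = conc[, "chla"] + conc[, "chlb"] + conc[, "car"])
    ss <- SpectraSet(R, wl, pigments = as.data.frame(targets),
                     truthBands = .truthBands(wl))
    S4Vectors::metadata(ss)$truth_bands_by_pigment <-
      .truthBandsByPigment(wl)
    ss
  })
}

#' Simulate a canopy hyperspectral cube with per-pixel pigment truth
#'
#' Foreground pixels form a centred disk carrying leaf spectra whose
#' pigment concentrations vary radially (`conc = centre value +
#' gradient * r/R`, with `r/R` the relative radius), emulating the
#' centre-to-periphery trends seen in real canopies. Background pixels
#' carry a flat low-NIR soil spectrum, giving strong foreground contrast
#' on the NIR plateau.
#'
#' @param config a [generatorConfig()]; `n_samples` is ignored.
#' @param height,width frame size in pixels (>= 8).
#' @param gradient named numeric (chla, chlb, car): mg/g change from disk
#'   centre to rim. Zero means all foreground pixels share one pigment
#'   vector.
#' @param radius_frac disk radius as a fraction of `min(height, width)/2`
#'   (default 0.8); the disk must fit inside the frame.
#' @return A list with `cube` ([HyperCube-class], kind `"reflectance"`),
#'   `mask` (true foreground), and `truth` (list of H x W maps chla, chlb,
#'   car, tpc; `NA` on background).
#' @export
simulateCanopyCube <- function(config, height = 64L, width = 64L,
                               gradient = c(chla = 0, chlb = 0, car = 0),
                               radius_frac = 0.8) {
  stopifnot(inherits(config, "generatorConfig"))
  height <- .assertCount(height, "height", 8L)
  width <- .assertCount(width, "width", 8L)
  if (radius_frac <= 0 || radius_frac > 1)
    stop("disk does not fit the frame: radius_frac must be in (0, 1]")
  gradient <- gradient[c("chla", "chlb", "car")]
  gradient[is.na(gradient)] <- 0
  wl <- makeWavelengthAxis(config)
  B <- length(wl)
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  Rmax <- radius_frac * (min(height, width) - 1) / 2
  rr <- outer(seq_len(height) - cy, seq_len(width) - cx,
              function(a, b) sqrt(a^2 + b^2))
  mask <- rr <= Rmax

  .withSeed(config$seed, {
    c0 <- vapply(config$pigment_ranges, function(r) runif(1, r[1], r[2]), 1)
    names(c0) <- c("chla", "chlb", "car")
    data <- array(.SOIL_REFLECTANCE, c(height, width, B))
    truth <- lapply(.pigmentNames, function(p) {
      m <- matrix(NA_real_, height, width); m
    })
    names(truth) <- .pigmentNames
    if (any(mask)) {
      rho <- rr[mask] / Rmax                      # relative radius in [0,1]
      conc <- cbind(chla = c0["chla"] + gradient["chla"] * rho,
                    chlb = c0["chlb"] + gradient["chlb"] * rho,
                    car = c0["car"] + gradient["car"] * rho)
      R <- .leafReflectance(wl, conc, config$nonlinearity)
      if (config$noise_sd > 0)
        R <- R + matrix(rnorm(length(R), 0, config$noise_sd), nrow(R))
      R <- pmin(pmax(R, 0), 1.05)
      idx <- which(mask)
      for (b in seq_len(B)) {
        plane <- data[, , b]; plane[idx] <- R[, b]; data[, , b] <- plane
      }
      for (p in c("chla", "chlb", "car")) truth[[p]][idx] <- conc[, p]
      truth$tpc[idx] <- conc[, "chla"] + conc[, "chlb"] + conc[, "car"]
    }
    list(cube = HyperCube(data, wl, kind = "reflectance"),
         mask = mask, truth = truth)
  })
}

#' Write / read a SpectraSet as CSV
#'
#' Columns: `sample_id`, one `wl_<nm>` column per band, then any pigment
#' targets (`chla`, `chlb`, `car`, `tpc`).
#'
#' @param x a [SpectraSet-class].
#' @param path output CSV path.
#' @return `writeSpectraCSV` returns `path` invisibly; `readSpectraCSV`
#'   returns a [SpectraSet-class].
#' @export
writeSpectraCSV <- function(x, path) {
  X <- spectraMatrix(x)
  colnames(X) <- sprintf("wl_%.4f", wavelengths(x))
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  pg <- pigments(x)
  if (!is.null(pg)) df <- cbind(df, as.data.frame(pg))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wlCols <- grep("^wl_", colnames(df))
  wl <- as.numeric(sub("^wl_", "", colnames(df)[wlCols]))
  X <- as.matrix(df[, wlCols])
  dimnames(X) <- list(df$sample_id, NULL)
  pg <- NULL
  if (all(.pigmentNames %in% colnames(df))) pg <- df[, .pigmentNames]
  SpectraSet(X, wl, pigments = pg)
}
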