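## Spectrophotometric pigment assay (Lichtenthaler-style, 96% ethanol).
##
## Concentrations are first obtained in ug/mL from the absorbance triplet:
##   Ca   = 13.95 dA665 - 6.88 dA649
##   Cb   = 24.96 dA649 - 7.32 dA665
##   Ccar = (1000 dA470 - 2.05 Ca - 114.8 Cb) / 245
## (the Ca/Cb inside the carotenoid line are the ug/mL concentrations --
## the only reading that keeps the units consistent), then converted to
## mg per g fresh mass via V / (1000 W), with V the extract volume in mL
## and W the sample mass in g. TPC is the exact sum of the three.

#' Pigment content from an absorbance reading
#'
#' @param dA665,dA649,dA470 background-corrected absorbances at 665, 649
#'   and 470 nm (vectors recycle together).
#' @param V total extract volume (mL), > 0.
#' @param W sample fresh mass (g), > 0.
#' @return A data.frame with columns `chla`, `chlb`, `car`, `tpc` (mg/g)
#'   and `flag`: `TRUE` where any component came out negative (possible
#'   with noisy absorbances; preserved, never clipped, so downstream
#'   statistics stay unbiased).
#' @examples
#' pigmentFromAbsorbance(0.8, 0.4, 0.5, V = 10, W = 0.1)
#' @export
pigmentFromAbsorbance <- function(dA665, dA649, dA470, V, W) {
  n <- max(length(dA665), length(dA649), length(dA470), length(V), length(W))
  dA665 <- rep_len(dA665, n); dA649 <- rep_len(dA649, n)
  dA470 <- rep_len(dA470, n); V <- rep_len(V, n); W <- rep_len(W, n)
  if (any(V <= 0)) stop("extract volume V must be > 0 (mL)")
  if (any(W <= 0)) stop("sample mass W must be > 0 (g)")
  if (any(c(dA665, dA649, dA470) < 0))
    stop("absorbances must be >= 0")
  ca <- 13.95 * dA665 - 6.88 * dA649          # ug/mL
  cb <- 24.96 * dA649 - 7.32 * dA665
  ccar <- (1000 * dA470 - 2.05 * ca - 114.8 * cb) / 245
  conv <- V / (1000 * W)                      # ug/mL -> mg/g
  out <- data.frame(chla = ca * conv, chlb = cb * conv, car = ccar * conv)
  out$tpc <- totalPigment(out$chla, out$chlb, out$car)
  out$flag <- out$chla < 0 | out$chlb < 0 | out$car < 0
  out
}

#' Total pigment content
#'
#' Exact sum of chlorophyll a, chlorophyll b and carotenoid content.
#'
#' @param chla,chlb,car pigment contents (mg/g).
#' @return `chla + chlb + car`.
#' @export
totalPigment <- function(chla, chlb, car) chla + chlb + car

#' Run the pigment assay over a readings table
#'
#' @param readings data.frame (or CSV path) with columns `sample_id`,
#'   `dA665`, `dA649`, `dA470`, `V_ml`, `W_g`.
#' @param out optional CSV path to write the augmented table to.
#' @return The readings with `chla`, `chlb`, `car`, `tpc`, `flag` appended.
#' @export
assayTable <- function(readings, out = NULL) {
  if (is.character(readings)) readings <- utils::read.csv(readings)
  need <- c("sample_id", "dA665", "dA649", "dA470", "V_ml", "W_g")
  if (!all(need %in% colnames(readings)))
    stop("readings must have columns: ", paste(need, collapse = ", "))
  res <- cbind(readings,
               pigmentFromAbsorbance(readings$dA665, readings$dA649,
                                     readings$dA470, readings$V_ml,
                                     readings$W_g))
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
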