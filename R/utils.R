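## Internal helpers shared across modules.

## Deterministic 32-bit FNV-1a hash of a character string, reduced to a
## valid R seed. Used to derive independent per-stage seeds from one
## global seed without seed collisions across stages.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    ## xor on the low 16 bits (b < 2^16); h may exceed .Machine$integer.max
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b)
    ## 32-bit modular multiply by the FNV prime 16777619, split into
    ## 16-bit halves so every intermediate stays below 2^53
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

#' Derive a stage seed from a global seed
#'
#' Hashes the global seed together with a stage label so that every
#' stochastic stage of a pipeline gets its own reproducible stream.
#'
#' @param seed integer global seed.
#' @param ... character labels identifying the stage (concatenated).
#' @return An integer in `[0, 2^31 - 1)` suitable for `set.seed()`.
#' @export
deriveSeed <- function(seed, ...) {
  as.integer(.fnv1a(paste(c(as.character(seed), ...), collapse = "/")) %%
               2147483647)
}

## Index of the band whose wavelength is closest to `nm`.
.nearestBand <- function(wavelengths, nm) which.min(abs(wavelengths - nm))

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("%s must be a single integer >= %d", name, min))
  as.integer(x)
}

.pigmentNames <- c("chla", "chlb", "car", "tpc")
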