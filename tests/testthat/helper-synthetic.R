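## Shared fixture builders. Everything is generated in code at test time.

## Small linear, noise-free leaf batch with known truth bands.
cleanLeafBatch <- function(n = 60, seed = 101, noise = 0, nonlinear = FALSE,
                           n_bands = 256) {
  simulateLeafSpectra(generatorConfig(n_samples = n, n_bands = n_bands,
                                      noise_sd = noise,
                                      nonlinearity = nonlinear,
                                      seed = seed))
}

## Tiny reflectance cube with known values.
tinyCube <- function(h = 4, w = 4, b = 5, seed = 7, kind = "reflectance") {
  set.seed(seed)
  HyperCube(array(runif(h * w * b), c(h, w, b)),
            wavelengths = seq(400, 800, length.out = b), kind = kind)
}

## Step-by-step brute-force max-min selection oracle (Kennard-Stone
## greedy on an arbitrary distance matrix), written independently of the
## package implementation: at every step it recomputes each candidate's
## minimum distance to the selected set by direct enumeration.
bruteMaxmin <- function(D, nc) {
  n <- nrow(D)
  Dd <- D
  diag(Dd) <- -Inf
  best <- -Inf
  pair <- c(1L, 2L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (Dd[i, j] > best) { best <- Dd[i, j]; pair <- c(i, j) }
  }
  sel <- sort(pair)
  while (length(sel) < nc) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(i) min(D[i, sel]), 1)
    sel <- c(sel, cand[which.max(score)])
  }
  sel[seq_len(nc)]
}

## SPXY joint distance matrix, by direct formula.
bruteSpxyDist <- function(X, y) {
  Dx <- as.matrix(stats::dist(X))
  Dy <- abs(outer(y, y, `-`))
  D <- Dx / max(Dx)
  if (max(Dy) > 0) D <- D + Dy / max(Dy)
  D
}

## Straight-line multi-head self-attention reference: project, score,
## softmax, weight, concatenate, project -- one step at a time, loops
## only, no shared code with the package implementation.
referenceMHSA <- function(h, params, scale = TRUE) {
  T <- nrow(h); D <- ncol(h)
  outHeads <- list()
  for (hd in params$heads) {
    Q <- h %*% hd$Wq                          # step 1: projections
    K <- h %*% hd$Wk
    V <- h %*% hd$Wv
    dh <- ncol(Q)
    O <- matrix(0, T, dh)
    for (i in seq_len(T)) {
      s <- numeric(T)
      for (j in seq_len(T))                   # step 2: dot products
        s[j] <- sum(Q[i, ] * K[j, ])
      if (scale) s <- s / sqrt(dh)
      w <- exp(s - max(s)); w <- w / sum(w)   # step 3: softmax
      acc <- numeric(dh)
      for (j in seq_len(T))                   # step 4: weighted values
        acc <- acc + w[j] * V[j, ]
      O[i, ] <- acc
    }
    outHeads[[length(outHeads) + 1L]] <- O
  }
  concat <- do.call(cbind, outHeads)          # step 6: stack heads
  concat %*% params$Wo                        # Eq: Concat(...) W_O
}
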