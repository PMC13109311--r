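## Modular neural-network layers: fused 1-D convolution blocks
## (conv -> ReLU -> max-pool), (bi)directional LSTM, multi-head
## self-attention, mean pooling and a dense head, each with an analytic
## backward pass, plus an Adam optimizer over nested parameter lists.
## Inter-layer activations are (batch, channel, position) arrays; the
## numerical kernels live in src/nn_kernels.cpp. The training loop uses
## the fused whole-network C++ step; this per-layer path backs the
## exported attention op, inspection, and the gradient tests, and is
## asserted to agree with the fused path. Gradient correctness is pinned
## by finite-difference tests.

.sigm <- function(x) 1 / (1 + exp(-x))

## ---- fused convolution block: conv1d -> ReLU -> max-pool(2) ----
## (stride 1, zero 'same' padding, odd kernel; pooling drops a trailing
## odd position)

.convInit <- function(K, Cin, Cout) {
  s <- sqrt(2 / (K * Cin))
  list(W = matrix(stats::rnorm(K * Cin * Cout, 0, s), K * Cin, Cout),
       b = numeric(Cout))
}

.convBlockFwd <- function(p, x) {
  d <- dim(x)
  res <- .convBlockFwdCpp(x, p$W, p$b)
  list(y = res$Y,
       cache = list(cols = res$cols, M = res$M, P = res$P, dims = d))
}

.convBlockBwd <- function(p, cache, gy) {
  d <- cache$dims                      # (n, Cin, L)
  out <- .convBlockBwdCpp(gy, p$W, cache$cols, cache$M, cache$P,
                          d[1L], d[2L], d[3L])
  g <- out$grads
  g$b <- as.numeric(g$b)
  list(gx = out$gX, grads = g)
}

## ---- LSTM (one direction) ----

.lstmInit <- function(C, H) {
  s <- 1 / sqrt(H)
  b <- numeric(4 * H)
  b[(H + 1L):(2L * H)] <- 1            # forget-gate bias
  list(Wx = matrix(stats::runif(C * 4 * H, -s, s), C, 4 * H),
       Wh = matrix(stats::runif(H * 4 * H, -s, s), H, 4 * H),
       b = b)
}

.lstmFwd <- function(p, x, reverse = FALSE) {
  res <- .lstmFwdCpp(x, p$Wx, p$Wh, p$b, reverse)
  list(y = res$H, cache = list(x = x, res = res, reverse = reverse))
}

.lstmBwd <- function(p, cache, gy) {
  out <- .lstmBwdCpp(cache$x, p$Wx, p$Wh, cache$res, gy, cache$reverse)
  g <- out$grads
  g$b <- as.numeric(g$b)
  list(gx = out$gX, grads = g)
}

## Bidirectional wrapper: a forward-time pass and a reversed-time pass
## over the same input, channel-concatenated ("capture dependencies in
## both directions").

.bilstmInit <- function(C, H)
  list(fwd = .lstmInit(C, H), bwd = .lstmInit(C, H))

.bilstmFwd <- function(p, x) {
  a <- .lstmFwd(p$fwd, x, reverse = FALSE)
  b <- .lstmFwd(p$bwd, x, reverse = TRUE)
  d <- dim(a$y)                        # (n, H, T)
  y <- array(0, c(d[1], 2 * d[2], d[3]))
  y[, seq_len(d[2]), ] <- a$y
  y[, d[2] + seq_len(d[2]), ] <- b$y
  list(y = y, cache = list(a = a$cache, b = b$cache, H = d[2]))
}

.bilstmBwd <- function(p, cache, gy) {
  H <- cache$H
  ga <- .lstmBwd(p$fwd, cache$a, gy[, seq_len(H), , drop = FALSE])
  gb <- .lstmBwd(p$bwd, cache$b, gy[, H + seq_len(H), , drop = FALSE])
  list(gx = ga$gx + gb$gx,
       grads = list(fwd = ga$grads, bwd = gb$grads))
}

## ---- multi-head self-attention ----

.mhsaInit <- function(D, heads, headDim) {
  s <- sqrt(2 / (D + headDim))
  onehead <- function()
    list(Wq = matrix(stats::rnorm(D * headDim, 0, s), D, headDim),
         Wk = matrix(stats::rnorm(D * headDim, 0, s), D, headDim),
         Wv = matrix(stats::rnorm(D * headDim, 0, s), D, headDim))
  list(heads = replicate(heads, onehead(), simplify = FALSE),
       Wo = matrix(stats::rnorm(heads * headDim * D, 0,
                                sqrt(2 / (heads * headDim + D))),
                   heads * headDim, D))
}

## x: (n, D, T) cube of token features. Per head: S = Q K' (scaled by
## 1/sqrt(d_k) unless `scale = FALSE`), A = row-softmax(S), head = A V;
## heads concatenated then projected by Wo. Every attention row sums to
## 1 (asserted inside the kernel and checked here).
.mhsaFwd <- function(p, x, scale = TRUE, buildWeights = FALSE) {
  d <- dim(x)                              # (n, D, T)
  Xc <- aperm(x, c(3, 2, 1))               # (T, D, n) for the kernel
  res <- .mhsaFwdCpp(Xc, p$heads, p$Wo, scale)
  if (res$rowSumDev > 1e-6)
    stop("attention rows do not sum to 1")
  W <- NULL
  if (buildWeights) {
    nh <- length(p$heads)
    W <- aperm(array(res$A, c(d[3], d[3], d[1], nh)), c(3, 4, 1, 2))
  }
  list(y = aperm(res$Y, c(3, 2, 1)), weights = W,
       cache = list(Xc = Xc, res = res, scale = scale))
}

.mhsaBwd <- function(p, cache, gy) {
  res <- cache$res
  out <- .mhsaBwdCpp(cache$Xc, aperm(gy, c(3, 2, 1)), p$heads, p$Wo,
                     res$Q, res$K, res$V, res$A, res$concat, cache$scale)
  list(gx = aperm(out$gX, c(3, 2, 1)), grads = out$grads)
}

## ---- mean pooling over positions, dense head ----

.meanPoolFwd <- function(x) {
  d <- dim(x)                          # (n, D, T)
  list(y = rowSums(x, dims = 2L) / d[3], cache = d)
}

.meanPoolBwd <- function(cache, gy) {
  d <- cache
  array(gy / d[3], d)                  # replicate across positions
}

.denseInit <- function(Din, Dout) {
  s <- sqrt(2 / Din)
  list(W = matrix(stats::rnorm(Din * Dout, 0, s), Din, Dout),
       b = numeric(Dout))
}

.denseFwd <- function(p, x)
  list(y = sweep(x %*% p$W, 2, p$b, `+`), cache = x)

.denseBwd <- function(p, cache, gy)
  list(gx = gy %*% t(p$W),
       grads = list(W = crossprod(cache, gy), b = colSums(gy)))

## ---- Adam over an arbitrarily nested parameter list ----

.adamInit <- function(params) {
  zeros <- function(p) if (is.list(p)) lapply(p, zeros) else p * 0
  list(m = zeros(params), v = zeros(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
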