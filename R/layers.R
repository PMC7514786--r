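# Forward primitives of the S1/S2 networks. Exported functions operate on a
# single instance with time in rows; the *Batch internals operate on flat
# matrices of shape (N*B) x C — batch b and time n are folded into the row
# index with n fastest — which keeps every layer a plain matrix op (no
# array permutations between layers).
#
# Temporal convolution is implemented as cross-correlation (the sign of the
# time index is immaterial for a learned kernel); "valid" mode only, so an
# input of N samples and a kernel of L taps yield N - L + 1 outputs (the
# first L - 1 lags are discarded).

#' Convolutional layer forward pass
#'
#' Valid (no padding) temporal cross-correlation with one bias per output
#' kernel followed by a linear rectifier `max(0, x)`.
#'
#' @param x numeric matrix, `N` time samples x `C` input channels.
#' @param weights numeric array `L x C x M` (taps x input channels x
#'   kernels).
#' @param biases numeric vector of length `M`, one bias per kernel.
#' @return matrix `(N - L + 1) x M`.
#' @export
convForward <- function(x, weights, biases) {
  x <- as.matrix(x)
  if (length(dim(weights)) == 2) dim(weights) <- c(dim(weights), 1L)
  L <- dim(weights)[1]; C <- dim(weights)[2]; M <- dim(weights)[3]
  if (ncol(x) != C) stop("input channels do not match the kernel array")
  out <- convForwardBatch(x, nrow(x), 1L, matrix(weights, L * C, M), biases)
  out$y
}

# X: (N*B) x C flat batch; Wmat: (C*L) x M with channel-c/tap-i at row
# (c-1)*L + i. The convolution is evaluated tap by tap as a sum of shifted
# row-block products, Y = sum_i X[rows + i - 1, ] %*% W_i, which avoids
# materializing the full im2col matrix. Returns y (Nout*B) x M plus the
# caches backprop needs (withCache = FALSE skips them for inference).
convForwardBatch <- function(X, N, B, Wmat, b, withCache = TRUE) {
  C <- ncol(X)
  L <- nrow(Wmat) / C
  Nout <- N - L + 1L
  if (Nout < 1L) stop("input shorter than the kernel length")
  baseNb <- as.vector(outer(seq_len(Nout), (seq_len(B) - 1L) * N, "+"))
  tapRows <- (seq_len(C) - 1L) * L
  A <- matrix(rep(b, each = Nout * B), Nout * B, ncol(Wmat))
  for (i in seq_len(L)) {
    A <- A + X[baseNb + (i - 1L), , drop = FALSE] %*%
      Wmat[tapRows + i, , drop = FALSE]
  }
  pos <- A > 0
  y <- A * pos
  if (!withCache) return(list(y = y, Nout = Nout))
  list(y = y, X = X, pos = pos, N = N, B = B, C = C, L = L,
       Nout = Nout, baseNb = baseNb, tapRows = tapRows)
}

convBackwardBatch <- function(cache, Wmat, dy) {
  dYmat <- dy * cache$pos
  db <- colSums(dYmat)
  dW <- matrix(0, nrow(Wmat), ncol(Wmat))
  dX <- matrix(0, cache$N * cache$B, cache$C)
  for (i in seq_len(cache$L)) {
    rows <- cache$baseNb + (i - 1L)
    Xi <- cache$X[rows, , drop = FALSE]
    dW[cache$tapRows + i, ] <- crossprod(Xi, dYmat)
    dX[rows, ] <- dX[rows, , drop = FALSE] +
      dYmat %*% t(Wmat[cache$tapRows + i, , drop = FALSE])
  }
  list(dx = dX, dW = dW, db = db)
}

#' Max-pooling over non-overlapping windows
#'
#' Per-channel maximum over consecutive non-overlapping windows of `K`
#' samples; a trailing remainder shorter than `K` is discarded.
#'
#' @param x numeric matrix `N x M` (time x channels) or numeric vector.
#' @param K pool size.
#' @return matrix `floor(N / K) x M` (or vector for vector input).
#' @export
maxPool <- function(x, K = 2L) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  out <- maxPoolBatch(x, nrow(x), 1L, K)$y
  if (vec) drop(out) else out
}

maxPoolBatch <- function(X, N, B, K = 2L, withCache = TRUE) {
  Np <- N %/% K
  if (Np < 1L) stop("input shorter than the pool size")
  offs <- (seq_len(B) - 1L) * N
  idx1 <- as.vector(outer((seq_len(Np) - 1L) * K + 1L, offs, "+"))
  y <- X[idx1, , drop = FALSE]
  if (!withCache) {
    if (K > 1L) {
      for (k in 2:K) y <- pmax(y, X[idx1 + (k - 1L), , drop = FALSE])
    }
    return(list(y = y, Np = Np))
  }
  arg <- matrix(1L, nrow(y), ncol(y))
  if (K > 1L) {
    for (k in 2:K) {
      cand <- X[idx1 + (k - 1L), , drop = FALSE]
      upd <- cand > y
      y[upd] <- cand[upd]
      arg[upd] <- k
    }
  }
  list(y = y, arg = arg, idx1 = idx1, inRows = N * B, K = K, Np = Np)
}

maxPoolBackwardBatch <- function(cache, dy) {
  dX <- matrix(0, cache$inRows, ncol(dy))
  for (k in seq_len(cache$K)) {
    dX[cache$idx1 + (k - 1L), ] <- dy * (cache$arg == k)
  }
  dX
}

#' Global max pooling
#'
#' Temporal maximum of each channel, producing the `M`-element feature
#' vector fed to the classification layer of the fully convolutional
#' network.
#'
#' @param x numeric matrix `N x M` (time x channels).
#' @return numeric vector of length `M`.
#' @export
globalMaxPool <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("empty time axis")
  apply(x, 2, max)
}

# X: (N*B) x M -> v: M x B with per-(channel, segment) argmax rows kept for
# the backward scatter.
globalMaxPoolBatch <- function(X, N, B) {
  M <- ncol(X)
  v <- matrix(0, M, B)
  arg <- matrix(0L, M, B)
  for (m in seq_len(M)) {
    xm <- matrix(X[, m], N, B)
    j <- max.col(t(xm), ties.method = "first")
    arg[m, ] <- j + (seq_len(B) - 1L) * N
    v[m, ] <- xm[cbind(j, seq_len(B))]
  }
  list(v = v, arg = arg, N = N, B = B)
}

globalMaxPoolBackwardBatch <- function(cache, dv) {
  dX <- matrix(0, cache$N * cache$B, nrow(dv))
  for (m in seq_len(nrow(dv))) {
    dX[cache$arg[m, ], m] <- dv[m, ]
  }
  dX
}

# Inverted dropout: units are zeroed with probability alpha and the rest
# scaled by 1/(1-alpha), so expectation is preserved and inference needs no
# rescaling. Draws from the current RNG stream.
dropoutMask <- function(nr, nc, alpha) {
  if (alpha <= 0) return(NULL)
  matrix((runif(nr * nc) >= alpha) / (1 - alpha), nr, nc)
}

#' GRU forward pass (final hidden state)
#'
#' Iterates the gated-recurrent-unit equations
#' `z = sigma(Wz d + Uz h + bz)`, `r = sigma(Wr d + Ur h + br)`,
#' `h' = tanh(Wh d + r * (Uh h) + bh)`, `h <- z * h + (1 - z) * h'`
#' from `h = 0`, and returns the hidden state after the last step. For the
#' backward direction the input sequence is time-reversed first.
#'
#' @param x numeric matrix `N x M` (time steps x input channels).
#' @param params list with matrices `Wz, Wr, Wh` (`theta x M`),
#'   `Uz, Ur, Uh` (`theta x theta`) and bias vectors `bz, br, bh`
#'   (one bias vector per gate).
#' @param direction `"forward"` or `"backward"`.
#' @return numeric vector of length `theta`.
#' @export
gruForward <- function(x, params, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("empty sequence")
  if (ncol(x) != ncol(params$Wz)) stop("input channels do not match Wz")
  res <- gruForwardBatch(x, nrow(x), 1L, params,
                         backward = direction == "backward")
  drop(res$h)
}

# X: (N*B) x M flat batch. Runs the GRU over time (reversed if backward),
# returning the final state (theta x B) and per-step caches for BPTT.
# recMask, if given, is a (theta x B) dropout mask applied to the recurrent
# state inside the gate equations (recurrent dropout, fixed across steps).
gruForwardBatch <- function(X, N, B, params, backward = FALSE,
                            recMask = NULL) {
  M <- ncol(X)
  steps <- if (backward) rev(seq_len(N)) else seq_len(N)
  theta <- nrow(params$Wz)
  offs <- (seq_len(B) - 1L) * N
  h <- matrix(0, theta, B)
  cache <- vector("list", N)
  for (s in seq_len(N)) {
    Dn <- t(X[steps[s] + offs, , drop = FALSE])      # M x B
    hd <- if (is.null(recMask)) h else h * recMask
    z <- matrix(sigmoid(params$Wz %*% Dn + params$Uz %*% hd + params$bz),
                theta, B)
    r <- matrix(sigmoid(params$Wr %*% Dn + params$Ur %*% hd + params$br),
                theta, B)
    Uhhd <- params$Uh %*% hd
    hp <- tanh(params$Wh %*% Dn + r * Uhhd + params$bh)
    hNew <- z * h + (1 - z) * hp
    cache[[s]] <- list(Dn = Dn, hPrev = h, hd = hd, z = z, r = r,
                       hp = hp, Uhhd = Uhhd)
    h <- hNew
  }
  list(h = h, cache = cache, steps = steps, N = N, B = B, M = M,
       recMask = recMask)
}

gruBackwardBatch <- function(fwd, params, dh) {
  N <- fwd$N; B <- fwd$B; M <- fwd$M
  theta <- nrow(params$Wz)
  offs <- (seq_len(B) - 1L) * N
  g <- list(Wz = matrix(0, theta, M), Wr = matrix(0, theta, M),
            Wh = matrix(0, theta, M), Uz = matrix(0, theta, theta),
            Ur = matrix(0, theta, theta), Uh = matrix(0, theta, theta),
            bz = numeric(theta), br = numeric(theta), bh = numeric(theta))
  dX <- matrix(0, N * B, M)
  for (s in rev(seq_len(N))) {
    cc <- fwd$cache[[s]]
    dz <- dh * (cc$hPrev - cc$hp)
    dhp <- dh * (1 - cc$z)
    dhPrev <- dh * cc$z
    daH <- dhp * (1 - cc$hp^2)
    g$Wh <- g$Wh + daH %*% t(cc$Dn)
    g$bh <- g$bh + rowSums(daH)
    dr <- daH * cc$Uhhd
    dUhhd <- daH * cc$r
    g$Uh <- g$Uh + dUhhd %*% t(cc$hd)
    dhd <- t(params$Uh) %*% dUhhd
    daZ <- dz * cc$z * (1 - cc$z)
    g$Wz <- g$Wz + daZ %*% t(cc$Dn)
    g$bz <- g$bz + rowSums(daZ)
    g$Uz <- g$Uz + daZ %*% t(cc$hd)
    dhd <- dhd + t(params$Uz) %*% daZ
    daR <- dr * cc$r * (1 - cc$r)
    g$Wr <- g$Wr + daR %*% t(cc$Dn)
    g$br <- g$br + rowSums(daR)
    g$Ur <- g$Ur + daR %*% t(cc$hd)
    dhd <- dhd + t(params$Ur) %*% daR
    dDn <- t(params$Wz) %*% daZ + t(params$Wr) %*% daR + t(params$Wh) %*% daH
    dX[fwd$steps[s] + offs, ] <- t(dDn)
    if (!is.null(fwd$recMask)) dhd <- dhd * fwd$recMask
    dh <- dhPrev + dhd
  }
  list(dx = dX, grads = g)
}

#' Bidirectional GRU forward pass
#'
#' Runs a forward-direction and a backward-direction GRU over the same
#' sequence and concatenates their final hidden states into a `2 * theta`
#' feature vector.
#'
#' @param x numeric matrix `N x M`.
#' @param paramsFwd,paramsBwd GRU parameter lists as in [gruForward()].
#' @return numeric vector of length `2 * theta`.
#' @export
bgruForward <- function(x, paramsFwd, paramsBwd) {
  c(gruForward(x, paramsFwd, "forward"),
    gruForward(x, paramsBwd, "backward"))
}

#' Sigmoid classification unit
#'
#' Numerically stable evaluation of `1 / (1 + exp(-(w . v + b)))`, the PR
#' likelihood produced by the final fully connected layer.
#'
#' @param v feature vector.
#' @param w weight vector of the same length.
#' @param b scalar bias.
#' @return probability strictly inside (0, 1).
#' @export
denseSigmoid <- function(v, w, b) {
  if (length(v) != length(w)) stop("feature and weight dimensions differ")
  clampProb(sigmoid(sum(w * v) + b), 1e-12)
}
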