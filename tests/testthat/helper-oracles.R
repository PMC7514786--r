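# Independent loop-based reference implementations used to verify the
# vectorized layer code, plus a naive beat counter for the generator tests.

# Valid cross-correlation + bias + ReLU, element by element.
oracleConv <- function(x, W, b) {
  L <- dim(W)[1]; C <- dim(W)[2]; M <- dim(W)[3]
  Nout <- nrow(x) - L + 1
  out <- matrix(0, Nout, M)
  for (m in seq_len(M)) {
    for (n in seq_len(Nout)) {
      acc <- b[m]
      for (c in seq_len(C)) {
        for (i in seq_len(L)) {
          acc <- acc + W[i, c, m] * x[n + i - 1, c]
        }
      }
      out[n, m] <- max(0, acc)
    }
  }
  out
}

oracleMaxPool <- function(x, K) {
  Np <- nrow(x) %/% K
  out <- matrix(0, Np, ncol(x))
  for (m in seq_len(ncol(x))) {
    for (n in seq_len(Np)) {
      out[n, m] <- max(x[((n - 1) * K + 1):(n * K), m])
    }
  }
  out
}

# Step-by-step scalar GRU following the gate equations directly.
oracleGru <- function(x, params, backward = FALSE) {
  theta <- nrow(params$Wz)
  steps <- if (backward) rev(seq_len(nrow(x))) else seq_len(nrow(x))
  h <- numeric(theta)
  sig <- function(u) 1 / (1 + exp(-u))
  for (n in steps) {
    d <- x[n, ]
    z <- sig(params$Wz %*% d + params$Uz %*% h + params$bz)
    r <- sig(params$Wr %*% d + params$Ur %*% h + params$br)
    hp <- tanh(params$Wh %*% d + r * (params$Uh %*% h) + params$bh)
    h <- as.numeric(z * h + (1 - z) * hp)
  }
  h
}

randomGruParams <- function(M, theta) {
  rm <- function(r, c) matrix(rnorm(r * c, sd = 0.5), r, c)
  list(Wz = rm(theta, M), Wr = rm(theta, M), Wh = rm(theta, M),
       Uz = rm(theta, theta), Ur = rm(theta, theta), Uh = rm(theta, theta),
       bz = rnorm(theta), br = rnorm(theta), bh = rnorm(theta))
}

# Naive beat counter: upward crossings of half the maximum rectified
# amplitude (independent of the package's detector).
oracleCountBeats <- function(s) {
  a <- abs(s - stats::median(s))
  thr <- 0.5 * max(a)
  above <- a > thr
  sum(diff(c(FALSE, above)) == 1)
}
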