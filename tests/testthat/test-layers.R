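# Each forward primitive is checked against an independent nested-loop
# evaluation of its defining equation on random instances.

test_that("convolution matches the loop-based oracle on random instances", {
  set.seed(1)
  for (rep in 1:30) {
    N <- sample(8:30, 1); C <- sample(1:3, 1)
    L <- sample(2:5, 1); M <- sample(1:4, 1)
    x <- matrix(rnorm(N * C), N, C)
    W <- array(rnorm(L * C * M), c(L, C, M))
    b <- rnorm(M)
    expect_equal(convForward(x, W, b), oracleConv(x, W, b),
                 tolerance = 1e-6)
  }
})

test_that("convolution edge behaviour follows the valid-mode contract", {
  W <- array(rnorm(7), c(7, 1, 1))
  x <- matrix(rnorm(500), ncol = 1)
  expect_equal(nrow(convForward(x, W, 0)), 494L)       # N - L + 1
  expect_equal(convForward(matrix(0, 20, 1), W, 0),
               matrix(0, 14, 1))                       # phi(0) = 0
  expect_error(convForward(matrix(1, 3, 1), W, 0), "shorter")
})

test_that("max pooling matches per-window maxima and drops remainders", {
  expect_equal(maxPool(c(1, 3, 2, 0)), c(3, 2))
  expect_equal(maxPool(c(5, 5, 5, 5, 5)), c(5, 5))  # odd tail dropped
  expect_error(maxPool(c(1), K = 2), "shorter")
  set.seed(2)
  for (rep in 1:20) {
    N <- sample(4:25, 1); M <- sample(1:4, 1); K <- sample(2:3, 1)
    x <- matrix(rnorm(N * M), N, M)
    if (N < K) next
    expect_equal(maxPool(x, K), oracleMaxPool(x, K), tolerance = 1e-12)
  }
})

test_that("global max pooling takes per-channel maxima, order-invariantly", {
  expect_equal(globalMaxPool(matrix(c(1, 5, 3), ncol = 1)), 5)
  expect_equal(globalMaxPool(matrix(rep(c(2, -1), each = 4), 4, 2)),
               c(2, -1))
  set.seed(3)
  for (rep in 1:10) {
    x <- matrix(rnorm(8 * 25), 25, 8)
    expect_equal(globalMaxPool(x), apply(x, 2, max))
    perm <- sample(nrow(x))
    expect_equal(globalMaxPool(x[perm, ]), globalMaxPool(x))
  }
})

test_that("GRU forward matches the step-by-step oracle in both directions", {
  set.seed(4)
  for (rep in 1:25) {
    N <- sample(2:8, 1); M <- sample(1:4, 1); theta <- sample(2:4, 1)
    x <- matrix(rnorm(N * M), N, M)
    params <- randomGruParams(M, theta)
    expect_equal(gruForward(x, params, "forward"),
                 oracleGru(x, params, backward = FALSE), tolerance = 1e-6)
    expect_equal(gruForward(x, params, "backward"),
                 oracleGru(x, params, backward = TRUE), tolerance = 1e-6)
  }
})

test_that("GRU degenerate parameter settings behave as the equations dictate", {
  M <- 3; theta <- 2
  x <- matrix(rnorm(18), 6, M)
  # update gate saturated at 1: the zero initial state is copied through
  p <- randomGruParams(M, theta)
  p$bz <- rep(1e4, theta)
  expect_equal(gruForward(x, p), rep(0, theta), tolerance = 1e-9)
  # all-zero parameters: h' = tanh(0) = 0 and the state stays 0
  z <- lapply(randomGruParams(M, theta), function(m) m * 0)
  expect_equal(gruForward(x, z), rep(0, theta))
})

test_that("bidirectional GRU concatenates both directions", {
  set.seed(5)
  M <- 3; theta <- 6
  x <- matrix(rnorm(5 * M), 5, M)
  pf <- randomGruParams(M, theta); pb <- randomGruParams(M, theta)
  v <- bgruForward(x, pf, pb)
  expect_length(v, 2 * theta)
  expect_equal(v, c(oracleGru(x, pf), oracleGru(x, pb, backward = TRUE)),
               tolerance = 1e-6)
  # palindromic input with shared parameters: both halves agree
  xs <- rbind(x, x[nrow(x):1, ])  # reversal-invariant sequence
  vs <- bgruForward(xs, pf, pf)
  expect_equal(vs[1:theta], vs[theta + 1:theta], tolerance = 1e-9)
})

test_that("the sigmoid unit evaluates the affine score stably", {
  expect_equal(denseSigmoid(c(1, -1), c(1, 1), 0), 0.5)
  expect_equal(denseSigmoid(c(1, 2), c(0.5, -0.25), 0.1),
               1 / (1 + exp(-0.1)), tolerance = 1e-9)
  expect_lt(denseSigmoid(1, 1e6, 0), 1)       # clamped inside (0, 1)
  expect_gt(denseSigmoid(1, -1e6, 0), 0)
  expect_error(denseSigmoid(c(1, 2), c(1, 2, 3), 0), "dimensions")
  set.seed(6)
  for (rep in 1:20) {
    v <- rnorm(5); w <- rnorm(5); b <- rnorm(1)
    expect_equal(denseSigmoid(v, w, b), 1 / (1 + exp(-(sum(w * v) + b))),
                 tolerance = 1e-9)
  }
})
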