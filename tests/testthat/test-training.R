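test_that("sample weights equalize patients", {
  expect_equal(computeSampleWeights(rep("a", 4)), rep(0.25, 4))
  w <- computeSampleWeights(c("a", "b", "b", "b"))
  expect_equal(w, c(1, 1/3, 1/3, 1/3))
  expect_equal(sum(w), 2)  # number of patients

  set.seed(1)
  pid <- rep(sprintf("p%02d", 1:10), times = sample(1:6, 10, replace = TRUE))
  w <- computeSampleWeights(pid)
  sums <- vapply(split(w, pid), sum, numeric(1))
  expect_equal(unname(sums), rep(1, 10), tolerance = 1e-9)
  expect_error(computeSampleWeights(character(0)), "empty")
})

test_that("augmentation draws the documented noise and jitter", {
  x <- matrix(rnorm(500 * 4), 500, 4)
  expect_identical(augmentBatch(x, noiseSd = 0, amplitudeJitter = 0), x)

  z <- augmentBatch(matrix(0, 500, 2), noiseSd = 1e-4,
                    amplitudeJitter = 0.02, seed = 1)
  expect_equal(sd(z), 1e-4, tolerance = 0.2)

  scales <- replicate(200, {
    y <- augmentBatch(matrix(1, 10, 1), noiseSd = 0,
                      amplitudeJitter = 0.02)
    mean(y)
  })
  expect_true(all(scales >= 0.98 & scales <= 1.02))
  expect_equal(mean(scales), 1.0, tolerance = 0.005)
})

test_that("the weighted cross-entropy matches its formula", {
  expect_equal(weightedBce(0.5, 1, 1), log(2), tolerance = 1e-9)
  expect_equal(weightedBce(c(1, 0), c(1, 0)), 0, tolerance = 1e-5)
  p <- c(0.2, 0.9, 0.6); y <- c(0, 1, 1); eta <- c(0.5, 1, 2)
  expect_equal(weightedBce(p, y, 2 * eta), 2 * weightedBce(p, y, eta))
  expect_equal(weightedBce(p, y, eta),
               -sum(eta * (y * log(p) + (1 - y) * log(1 - p))),
               tolerance = 1e-9)
  # clamping keeps the loss finite at degenerate probabilities
  expect_true(is.finite(weightedBce(c(0, 1), c(1, 0))))
})

test_that("max-norm projection rescales only over-norm vectors", {
  w <- c(3, 6, 2) / sqrt(49) * 7          # norm 7
  expect_equal(sqrt(sum(applyMaxNorm(w, 3.5)^2)), 3.5)
  expect_identical(applyMaxNorm(c(0.6, 0.8), 3.5), c(0.6, 0.8))
  expect_identical(applyMaxNorm(numeric(3), 3.5), numeric(3))
  # matrix: per-column kernels
  W <- cbind(c(10, 0), c(1, 0))
  Wc <- applyMaxNorm(W, 3.5)
  expect_equal(sqrt(colSums(Wc^2)), c(3.5, 1))
})

test_that("training reduces the loss and respects its contracts", {
  model <- smallTrainedModel()
  h <- model@history
  expect_lt(mean(tail(h, 3)), h[1])
  # constraint holds for every conv kernel
  for (nm in grep("^conv[0-9]+\\.W$", names(model@params), value = TRUE)) {
    expect_true(all(sqrt(colSums(model@params[[nm]]^2)) <= 3.5 + 1e-6))
  }
})

test_that("training is bit-reproducible for a fixed seed", {
  d <- preprocessSegments(generateDataset(3, 3, c(2, 3), seed = 21))
  base <- buildS1(s1Config(1, 4, 5, dropout = 0.2), 500, seed = 8)
  cfg <- trainingConfig(epochs = 3)
  f1 <- trainModel(base, d, cfg, seed = 9)
  f2 <- trainModel(base, d, cfg, seed = 9)
  expect_identical(f1@params, f2@params)
  expect_identical(f1@history, f2@history)
  f3 <- trainModel(base, d, cfg, seed = 10)
  expect_false(identical(f1@params, f3@params))
})

test_that("a small S2 trains on a separable toy problem", {
  d <- preprocessSegments(generateDataset(4, 4, c(2, 3), seed = 31))
  model <- buildS2(s2Config(1, 4, 5, 4, dropout = 0.1), 500, seed = 11)
  fit <- trainModel(model, d, trainingConfig(epochs = 8), seed = 11)
  expect_lt(tail(fit@history, 1), fit@history[1])
  # recurrent kernels are constrained too (per-unit row vectors)
  for (nm in grep("^gru[FB]\\.(W|U)[zrh]$", names(fit@params), value = TRUE)) {
    expect_true(all(sqrt(rowSums(fit@params[[nm]]^2)) <= 3.5 + 1e-6))
  }
})
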