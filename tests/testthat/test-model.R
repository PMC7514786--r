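test_that("layer-length arithmetic matches the block recursion", {
  ll <- layerLengths(s1Config(4, 8, 7, dropout = 0.2), 500)
  expect_equal(ll$afterConv, c(494L, 241L, 114L, 51L))
  expect_equal(ll$afterPool, c(247L, 120L, 57L, 25L))

  ll2 <- layerLengths(s2Config(2, 24, 6, 6, dropout = 0.4), 500)
  expect_equal(ll2$afterConv, c(495L, 242L))
  expect_equal(ll2$afterPool, c(247L, 121L))

  expect_equal(layerLengths(s1Config(1, 1, 1, dropout = 0.05), 10)$afterConv,
               10L)  # L = 1 preserves length
  expect_error(layerLengths(s1Config(5, 8, 8, dropout = 0.1), 12),
               "underflow")
  expect_error(buildS1(s1Config(5, 8, 8, dropout = 0.1), 12), "underflow")
})

test_that("closed-form parameter counts agree with enumeration on the search grid", {
  for (lam in 1:5) {
    for (M in c(8L, 16L, 24L)) {
      for (L in 5:8) {
        c1 <- s1Config(lam, M, L, dropout = 0.1)
        m1 <- buildS1(c1, 600)
        expect_identical(countParameters(m1),
                         countParametersClosedForm(c1))
        for (theta in 4:8) {
          c2 <- s2Config(lam, M, L, theta, dropout = 0.1)
          expect_identical(countParameters(buildS2(c2, 600)),
                           countParametersClosedForm(c2))
        }
      }
    }
  }
  # degenerate closed-form check: single 1-tap kernel plus dense unit
  expect_identical(countParameters(buildS1(s1Config(1, 1, 1, dropout = 0.05),
                                           10)), 4L)
})

test_that("predictions are deterministic probabilities with a 0.5 decision rule", {
  model <- buildS1(s1Config(2, 8, 5, dropout = 0.3), 500, seed = 2)
  x <- matrix(rnorm(500 * 6), 500, 6)
  p1 <- predictPulse(model, x)
  p2 <- predictPulse(model, x)
  expect_identical(p1, p2)  # dropout off => pure function
  expect_true(all(p1$p_pr > 0 & p1$p_pr < 1))
  expect_identical(as.character(p1$label),
                   ifelse(p1$p_pr >= 0.5, "PR", "PEA"))
  expect_error(predictPulse(model, matrix(rnorm(10), 10, 1)), "shorter")
})

test_that("with zero biases the pre-sigmoid score is positively homogeneous", {
  model <- buildS1(s1Config(2, 8, 5, dropout = 0), 500, seed = 3)
  model@params[["dense.b"]] <- 0
  for (i in 1:2) model@params[[paste0("conv", i, ".b")]][] <- 0
  x <- matrix(abs(rnorm(500)), 500, 1)
  p1 <- predictPulse(model, x)$p_pr
  p2 <- predictPulse(model, 1.02 * x)$p_pr
  score <- function(p) log(p / (1 - p))
  expect_equal(score(p2), 1.02 * score(p1), tolerance = 1e-6)
})

test_that("variable input lengths are accepted down to the model minimum", {
  model <- buildS2(s2Config(2, 8, 5, 4, dropout = 0.1), 500, seed = 4)
  for (len in c(500, 350, 200, model@minLength)) {
    p <- predictPulse(model, matrix(rnorm(len * 2), len, 2))
    expect_equal(nrow(p), 2L)
  }
  expect_error(predictPulse(model, matrix(rnorm(model@minLength - 1))),
               "shorter")
})

test_that("network feature vectors have the documented dimensions", {
  x <- matrix(rnorm(500 * 3), 500, 3)
  f1 <- dnnFeatures(buildS1(s1Config(1, 8, 5, dropout = 0.1), 500), x)
  expect_equal(dim(f1), c(3L, 8L))       # M features
  f2 <- dnnFeatures(buildS2(s2Config(1, 8, 5, 6, dropout = 0.1), 500), x)
  expect_equal(dim(f2), c(3L, 12L))      # 2 theta features
})

test_that("models survive a JSON round trip", {
  model <- smallTrainedModel()
  path <- withr::local_tempfile(fileext = ".json")
  writePulseNet(model, path)
  back <- readPulseNet(path)
  x <- matrix(rnorm(500 * 3), 500, 3)
  expect_equal(predictPulse(back, x)$p_pr, predictPulse(model, x)$p_pr,
               tolerance = 1e-12)
  expect_equal(back@history, model@history)

  m2 <- buildS2(s2Config(1, 4, 5, 4, dropout = 0.2), 300, seed = 9)
  writePulseNet(m2, path)
  b2 <- readPulseNet(path)
  x2 <- matrix(rnorm(300 * 2), 300, 2)
  expect_equal(predictPulse(b2, x2)$p_pr, predictPulse(m2, x2)$p_pr,
               tolerance = 1e-12)
})
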