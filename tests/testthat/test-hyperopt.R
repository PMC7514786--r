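test_that("patient-wise folds are balanced, stratified and exhaustive", {
  d <- generateDataset(4, 4, c(1, 2), seed = 71)
  folds <- makePatientFolds(d, k = 4, seed = 1)
  expect_equal(as.integer(sort(table(folds))), rep(2L, 4))
  expect_setequal(names(folds), unique(patientIds(d)))

  # 223 patients in 4 folds: sizes 56/56/56/55 in some order
  pats <- sprintf("p%03d", 1:223)
  labs <- rep(c("PR", "PEA"), length.out = 223)
  f223 <- makePatientFolds(pats, k = 4, seed = 2, labels = labs)
  expect_equal(as.integer(sort(table(f223), decreasing = TRUE)),
               c(56L, 56L, 56L, 55L))
  # stratification: each fold holds both classes
  byFold <- split(labs[match(names(f223), pats)], f223)
  expect_true(all(vapply(byFold, function(l) length(unique(l)) == 2,
                         logical(1))))
  expect_error(makePatientFolds(pats[1:3], k = 4, labels = labs[1:3]),
               "fewer patients")
})

test_that("the cross-validated objective scores injected classifiers correctly", {
  d <- preprocessSegments(generateDataset(6, 6, c(1, 2), seed = 72))
  folds <- makePatientFolds(d, k = 3, seed = 1)
  oracle <- function(train, test, config, seed) segmentLabels(test)
  expect_equal(cvObjective(oracle, list(), d, folds), 0)
  alwaysPr <- function(train, test, config, seed)
    factor(rep("PR", nSegments(test)), levels = c("PEA", "PR"))
  expect_equal(cvObjective(alwaysPr, list(), d, folds), 0.5)
  broken <- function(...) stop("boom")
  expect_error(cvObjective(broken, list(), d, folds), "fold 1")
})

test_that("a small S1 reaches a low cross-validated BER on separable data", {
  d <- preprocessSegments(generateDataset(8, 8, c(2, 3), seed = 73))
  folds <- makePatientFolds(d, k = 4, seed = 1)
  ber <- cvObjective("s1", list(lambda = 1, M = 8, L = 5, alpha = 0.1),
                     d, folds, seed = 1, epochs = 25)
  expect_lt(ber, 0.2)
})

test_that("both optimizers minimize a known 1-D function", {
  sp <- list(x = list(type = "uniform", min = -2, max = 2))
  quad <- function(cfg) (cfg$x - 0.7)^2
  for (method in c("tpe", "gp")) {
    res <- tuneModel(sp, quad, nTrials = 50, method = method, seed = 3)
    expect_lt(res$best$objective, 0.1 * (2.7^2))  # within 10% of the range
    expect_equal(nrow(res$history), 50L)
    expect_equal(res$best$objective, min(res$history$objective))
    expect_true(all(res$history$x >= -2 & res$history$x <= 2))
  }
})

test_that("optimization handles mixed spaces, trial bounds, and determinism", {
  sp <- list(
    k = list(type = "choice", values = c(2L, 4L, 8L)),
    x = list(type = "uniform", min = 0, max = 1)
  )
  f <- function(cfg) abs(cfg$k - 4) + (cfg$x - 0.5)^2
  one <- tuneModel(sp, f, nTrials = 1, method = "tpe", seed = 1)
  expect_equal(nrow(one$history), 1L)
  expect_equal(one$best$objective, one$history$objective[1])

  a <- tuneModel(sp, f, nTrials = 20, method = "tpe", seed = 5)
  b <- tuneModel(sp, f, nTrials = 20, method = "tpe", seed = 5)
  expect_identical(a$history, b$history)
  expect_true(all(a$history$k %in% c(2L, 4L, 8L)))
  expect_true(all(a$history$x >= 0 & a$history$x <= 1))
  expect_equal(a$best$config$k, 4L)

  g <- tuneModel(sp, f, nTrials = 25, method = "gp", seed = 6)
  expect_equal(g$best$config$k, 4L)
  expect_error(tuneModel(list(), f, 5), "invalid search space")
})

test_that("the end-to-end tuner returns configs inside the family space", {
  d <- preprocessSegments(generateDataset(6, 6, c(1, 2), seed = 74))
  res <- tunePulseDetector("rf", d, nTrials = 6, k = 3, seed = 2)
  expect_equal(nrow(res$history), 6L)
  expect_true(all(res$history$phi >= 0.5 & res$history$phi <= 1))
  expect_true(all(res$history$psi %in% 1:9))
  expect_true(all(res$history$objective >= 0 & res$history$objective <= 1))
})
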