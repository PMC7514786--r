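test_that("patient-weighted metrics follow their definitions", {
  # one-class inputs leave the other class's metric undefined
  expect_error(patientWeightedMetrics("PR", "PR", "A"), "specificity")
  expect_error(patientWeightedMetrics("PEA", "PEA", "A"), "sensitivity")

  pred <- c("PR", "PEA", "PR", "PEA")
  truth <- c("PR", "PR", "PEA", "PEA")
  m2 <- patientWeightedMetrics(pred, truth, c("a", "a", "b", "b"))
  expect_equal(m2[["se_pct"]], 50)
  expect_equal(m2[["sp_pct"]], 50)
  expect_equal(m2[["bac_pct"]], 50)
})

test_that("mixed-per-patient accuracy averages patient-wise", {
  m <- patientWeightedMetrics(
    predicted = c("PR", "PEA", "PR", "PEA"),
    truth = c("PR", "PR", "PR", "PEA"),
    patientId = c("A", "A", "B", "C"))
  expect_equal(m[["se_pct"]], 75)   # mean(0.5, 1.0)
  expect_equal(m[["sp_pct"]], 100)
})

test_that("metric identities hold and perfect prediction scores 100", {
  truth <- rep(c("PR", "PEA"), each = 6)
  pid <- rep(letters[1:4], each = 3)
  m <- patientWeightedMetrics(truth, truth, pid)
  expect_equal(unname(m), c(100, 100, 100, 0))
  set.seed(2)
  for (rep in 1:20) {
    pred <- sample(c("PR", "PEA"), 12, replace = TRUE)
    m <- patientWeightedMetrics(pred, truth, pid)
    expect_equal(m[["bac_pct"]], (m[["se_pct"]] + m[["sp_pct"]]) / 2,
                 tolerance = 1e-9)
    expect_equal(m[["ber_pct"]], 100 - m[["bac_pct"]], tolerance = 1e-9)
  }
})

test_that("duplicating one patient's segments leaves metrics unchanged", {
  set.seed(3)
  truth <- sample(c("PR", "PEA"), 20, replace = TRUE)
  pid <- rep(sprintf("p%d", 1:5), each = 4)
  pred <- ifelse(runif(20) < 0.8, truth, ifelse(truth == "PR", "PEA", "PR"))
  m1 <- patientWeightedMetrics(pred, truth, pid)
  dup <- pid == "p1"
  m2 <- patientWeightedMetrics(c(pred, pred[dup]), c(truth, truth[dup]),
                               c(pid, pid[dup]))
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("swapping class labels swaps sensitivity and specificity", {
  set.seed(4)
  truth <- sample(c("PR", "PEA"), 30, replace = TRUE)
  pid <- sample(letters[1:6], 30, replace = TRUE)
  pred <- sample(c("PR", "PEA"), 30, replace = TRUE)
  flip <- function(x) ifelse(x == "PR", "PEA", "PR")
  m <- patientWeightedMetrics(pred, truth, pid)
  mf <- patientWeightedMetrics(flip(pred), flip(truth), pid)
  expect_equal(m[["se_pct"]], mf[["sp_pct"]], tolerance = 1e-9)
  expect_equal(m[["sp_pct"]], mf[["se_pct"]], tolerance = 1e-9)
})

test_that("the duration sweep evaluates every model at every duration", {
  test <- preprocessSegments(generateDataset(5, 5, seed = 61))
  model <- smallTrainedModel()
  ftr <- extractFeatures(smallTrainSet())
  rf <- rfFit(ftr, segmentLabels(smallTrainSet()), seed = 1)
  sweep <- durationSweep(list(s1 = model, rf = rf), test,
                         durations = c(2, 3.5, 5))
  expect_equal(nrow(sweep), 6L)
  expect_true(all(is.finite(sweep$bac_pct)))
  # duration 5 equals the plain evaluation
  full <- patientWeightedMetrics(predictPulse(model, test)$label,
                                 segmentLabels(test), patientIds(test))
  expect_equal(sweep$bac_pct[sweep$model == "s1" & sweep$duration_s == 5],
               full[["bac_pct"]])
})

test_that("trained S1 keeps its accuracy down to 2-s segments", {
  deltas <- vapply(1:10, function(seed) {
    model <- endToEndModel(seed)
    sw <- durationSweep(list(s1 = model), endToEndTestSet(seed),
                        durations = c(2, 5))
    diff(sw$bac_pct)  # BAC(5 s) - BAC(2 s)
  }, numeric(1))
  expect_lte(mean(abs(deltas)), 10)
})

test_that("feature AUC is the rank statistic", {
  vals <- c(1, 2, 3, 10, 11, 12)
  labs <- c("PEA", "PEA", "PEA", "PR", "PR", "PR")
  expect_equal(featureAuc(vals, labs), 1)
  expect_equal(featureAuc(-vals, labs), 0)
  expect_equal(featureAuc(c(1, 2, 1, 2), c("PEA", "PR", "PR", "PEA")), 0.5)
})
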