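test_that("generatePatient returns fixed-length labelled segments, reproducibly", {
  x <- generatePatient(rhythmParams("PR"), nSegments = 3, seed = 7)
  expect_s4_class(x, "EcgSegmentSet")
  expect_equal(dim(ecgSignals(x)), c(1250L, 3L))
  expect_equal(samplingRate(x), 250)
  expect_true(all(segmentLabels(x) == "PR"))
  expect_equal(length(unique(patientIds(x))), 1L)

  y <- generatePatient(rhythmParams("PR"), nSegments = 3, seed = 7)
  expect_identical(ecgSignals(x), ecgSignals(y))

  z <- generatePatient(rhythmParams("PR"), nSegments = 3, seed = 8)
  expect_false(identical(ecgSignals(x), ecgSignals(z)))

  expect_error(generatePatient(rhythmParams("PR"), 0, seed = 1), "positive")
})

test_that("clean 80-bpm rhythm yields the expected beat count in 5 s", {
  p <- rhythmParams("PR", heartRateBpm = 80, rateCv = 0, ectopyProb = 0,
                    noiseSdMv = 0)
  for (seed in 1:10) {
    x <- generatePatient(p, nSegments = 1, seed = seed)
    nb <- oracleCountBeats(ecgSignals(x)[, 1])
    expect_true(nb %in% c(6L, 7L), label = sprintf("seed %d: %d beats", seed, nb))
  }
})

test_that("generateDataset respects patient structure and segment ranges", {
  expect_equal(nSegments(generateDataset(0, 0, c(1, 1), seed = 1)), 0L)
  expect_error(generateDataset(2, 2, c(4, 2), seed = 1), "range")

  d <- generateDataset(10, 10, segmentsPerPatient = c(2, 6), seed = 1)
  counts <- table(patientIds(d))
  expect_equal(length(counts), 20L)
  expect_true(all(counts >= 2 & counts <= 6))
  # labels constant within patient
  lab <- split(as.character(segmentLabels(d)), patientIds(d))
  expect_true(all(vapply(lab, function(l) length(unique(l)) == 1, logical(1))))
  # deterministic
  d2 <- generateDataset(10, 10, segmentsPerPatient = c(2, 6), seed = 1)
  expect_identical(ecgSignals(d), ecgSignals(d2))
})

test_that("PR patients beat faster than PEA patients on average", {
  d <- generateDataset(50, 50, seed = 1)
  lab <- as.character(segmentLabels(d))
  rates <- apply(ecgSignals(d), 2, function(s) oracleCountBeats(s) / 5 * 60)
  byPatient <- vapply(split(seq_along(lab), patientIds(d)),
                      function(i) mean(rates[i]), numeric(1))
  patLab <- vapply(split(lab, patientIds(d)), `[`, character(1), 1)
  expect_gt(mean(byPatient[patLab == "PR"]), mean(byPatient[patLab == "PEA"]))
})

test_that("segments are finite and bounded by amplitude + 6 noise SD", {
  for (cls in c("PR", "PEA")) {
    p <- rhythmParams(cls, amplitudeMv = 0.8, noiseSdMv = 0.05)
    x <- ecgSignals(generatePatient(p, nSegments = 10, seed = 3))
    expect_true(all(is.finite(x)))
    expect_lt(max(abs(x)), 0.8 + 6 * 0.05)
  }
})

test_that("a rate-threshold classifier separates the classes (BAC > 0.7)", {
  d <- generateDataset(40, 40, seed = 11)
  rates <- apply(ecgSignals(d), 2, function(s) oracleCountBeats(s) / 5 * 60)
  pred <- ifelse(rates >= 70, "PR", "PEA")
  m <- patientWeightedMetrics(pred, segmentLabels(d), patientIds(d))
  expect_gt(m[["bac_pct"]], 70)
})

test_that("segment tables survive a CSV round trip", {
  d <- generateDataset(3, 2, segmentsPerPatient = c(1, 3), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSegmentCsv(d, path)
  d2 <- readSegmentCsv(path)
  expect_equal(ecgSignals(d2), ecgSignals(d), tolerance = 1e-12)
  expect_identical(patientIds(d2), patientIds(d))
  expect_identical(as.character(segmentLabels(d2)),
                   as.character(segmentLabels(d)))
  expect_equal(samplingRate(d2), 250)
})

test_that("patient-wise splitting keeps patients whole", {
  d <- generateDataset(10, 10, seed = 2)
  sp <- splitByPatient(d, fraction = 0.7, seed = 3)
  expect_length(intersect(patientIds(sp$train), patientIds(sp$test)), 0)
  expect_equal(nSegments(sp$train) + nSegments(sp$test), nSegments(d))
})
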