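# Memoised fixtures shared across test files. The end-to-end study
# conditions are: 100 training patients (50 PR / 50 PEA) and 40 disjoint
# test patients (20/20), 2-6 segments per patient, S1 with lambda = 2,
# M = 8, L = 5, alpha = 0.1 trained for 75 epochs in batches of 8.

.pgCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .pgCache)) assign(key, expr, envir = .pgCache)
  get(key, envir = .pgCache)
}

endToEndTrainSet <- function(seed) {
  memo(paste0("train", seed),
       preprocessSegments(generateDataset(50, 50, seed = 1000 + seed)))
}

endToEndTestSet <- function(seed) {
  memo(paste0("test", seed),
       preprocessSegments(generateDataset(20, 20, seed = 2000 + seed)))
}

endToEndModel <- function(seed) {
  memo(paste0("model", seed), {
    model <- buildS1(s1Config(2, 8, 5, dropout = 0.1), 500, seed = seed)
    trainModel(model, endToEndTrainSet(seed), trainingConfig(), seed = seed)
  })
}

endToEndBac <- function(seed) {
  memo(paste0("bac", seed), {
    te <- endToEndTestSet(seed)
    pred <- predictPulse(endToEndModel(seed), te)
    patientWeightedMetrics(pred$label, segmentLabels(te),
                           patientIds(te))[["bac_pct"]]
  })
}

# One MC-dropout run per set and seed; thresholds for all feedback
# fractions are calibrated from the same uncertainties.
endToEndMc <- function(seed) {
  memo(paste0("mc", seed), {
    model <- endToEndModel(seed)
    list(
      train = mcPredict(model, endToEndTrainSet(seed), nRepeats = 100,
                        seed = 3000 + seed),
      test = mcPredict(model, endToEndTestSet(seed), nRepeats = 100,
                       seed = 4000 + seed)
    )
  })
}

# A small quick dataset + model for unit tests that need a trained network
# but not the full study conditions.
smallTrainSet <- function() {
  memo("smallTrain",
       preprocessSegments(generateDataset(6, 6, seed = 77)))
}

smallTrainedModel <- function() {
  memo("smallModel", {
    model <- buildS1(s1Config(2, 4, 5, dropout = 0.1), 500, seed = 5)
    trainModel(model, smallTrainSet(),
               trainingConfig(epochs = 10), seed = 5)
  })
}
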