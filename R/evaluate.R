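#' Patient-weighted performance metrics
#'
#' Sensitivity (correct PR detection), specificity (correct PEA detection),
#' balanced accuracy and balanced error rate, weighting every patient
#' equally: each patient's per-class accuracy is computed over that
#' patient's segments, then averaged over the patients that have segments of
#' the class. Reported in percent.
#'
#' @param predicted predicted labels (PR/PEA factor or character).
#' @param truth true labels.
#' @param patientId patient identifier per segment.
#' @return named numeric vector `se_pct`, `sp_pct`, `bac_pct`, `ber_pct`.
#' @examples
#' patientWeightedMetrics(c("PR", "PEA", "PR"), c("PR", "PR", "PR"),
#'                        c("A", "A", "B"))["se_pct"]  # mean(0.5, 1) = 75
#' @export
patientWeightedMetrics <- function(predicted, truth, patientId) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  patientId <- as.character(patientId)
  stopifnot(length(predicted) == length(truth),
            length(truth) == length(patientId))
  perPatient <- function(class) {
    sel <- truth == class
    if (!any(sel))
      stop("no ", class, " segments: ",
           if (class == "PR") "sensitivity" else "specificity",
           " is undefined")
    correct <- (predicted == truth)[sel]
    vapply(split(correct, patientId[sel]), mean, numeric(1))
  }
  se <- 100 * mean(perPatient("PR"))
  sp <- 100 * mean(perPatient("PEA"))
  bac <- (se + sp) / 2
  c(se_pct = se, sp_pct = sp, bac_pct = bac, ber_pct = 100 - bac)
}

#' Segment-duration sweep
#'
#' Evaluates models trained on 5-s segments at shorter durations: each test
#' signal is truncated to its first seconds, predictions are recomputed, and
#' patient-weighted metrics reported per model and duration. Networks accept
#' any duration at or above their minimum length; a duration below it yields
#' an `NA` row. Baseline classifiers recompute their hand-crafted features
#' on the truncated signals.
#'
#' @param models named list of [PulseNet-class] models and/or baseline
#'   models from [rfFit()], [svmFit()], [klrFit()].
#' @param data an [EcgSegmentSet-class] of processed (100 Hz) test segments.
#' @param durations durations in seconds.
#' @return data.frame with `model`, `duration_s`, `se_pct`, `sp_pct`,
#'   `bac_pct`, `ber_pct`.
#' @export
durationSweep <- function(models, data, durations = c(2, 3, 4, 5)) {
  stopifnot(length(names(models)) == length(models))
  fs <- samplingRate(data)
  truth <- segmentLabels(data)
  pid <- patientIds(data)
  rows <- list()
  for (nm in names(models)) {
    model <- models[[nm]]
    for (d in durations) {
      k <- floor(d * fs)
      met <- rep(NA_real_, 4)
      if (k <= nrow(data)) {
        xd <- ecgSignals(data)[seq_len(k), , drop = FALSE]
        lab <- tryCatch({
          if (methods::is(model, "PulseNet")) {
            if (k < model@minLength) NULL else predictPulse(model, xd)$label
          } else {
            predictBaseline(model, t(apply(xd, 2, extractFeatures, fs = fs)))
          }
        }, error = function(e) NULL)
        if (!is.null(lab))
          met <- patientWeightedMetrics(lab, truth, pid)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, duration_s = d, se_pct = met[1], sp_pct = met[2],
        bac_pct = met[3], ber_pct = met[4], row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Per-feature AUC screen
#'
#' Rank-based area under the ROC curve of a single feature for PR (positive
#' class) versus PEA, equivalent to the Wilcoxon statistic.
#'
#' @param values numeric feature values, one per segment.
#' @param labels PR/PEA labels.
#' @return AUC in \[0, 1\].
#' @export
featureAuc <- function(values, labels) {
  y <- labelToBinary(labels)
  if (!any(y == 1) || !any(y == 0)) stop("both classes are required")
  r <- rank(values)
  n1 <- sum(y == 1)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * sum(y == 0))
}
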