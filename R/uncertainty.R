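#' Selective-prediction policy constructor
#'
#' @param nRepeats Monte-Carlo repetitions (default 100).
#' @param threshold uncertainty threshold; leave `NA` and fill with
#'   [calibrateThreshold()].
#' @param targetFeedbackFraction intended feedback proportion in (0, 1].
#' @param noiseSd SD of the white noise added to the input at each pass
#'   (the training augmentation scale).
#' @return an [UncertaintyPolicy-class].
#' @export
uncertaintyPolicy <- function(nRepeats = 100L, threshold = NA_real_,
                              targetFeedbackFraction = 1.0, noiseSd = 1e-4) {
  methods::new("UncertaintyPolicy", nRepeats = as.integer(nRepeats),
               threshold = threshold,
               targetFeedbackFraction = targetFeedbackFraction,
               noiseSd = noiseSd)
}

#' Monte-Carlo-dropout prediction
#'
#' Repeats the forward pass `nRepeats` times with dropout active and fresh
#' white noise added to the input, and summarizes the PR likelihoods by
#' their sample mean and population variance. The variance is the
#' uncertainty of the decision.
#'
#' @param model a trained [PulseNet-class].
#' @param x processed signals (vector, matrix, or [EcgSegmentSet-class]).
#' @param nRepeats number of stochastic passes (>= 1).
#' @param seed integer seed.
#' @param noiseSd SD of the additive input noise per pass.
#' @return data.frame with `p_pr` (mean), `uncertainty` (variance) and
#'   `label` per segment.
#' @export
mcPredict <- function(model, x, nRepeats = 100L, seed = 1L, noiseSd = 1e-4) {
  if (nRepeats < 1) stop("nRepeats must be >= 1")
  x <- asSignalMatrix(x)
  P <- withSeed(seed, {
    vapply(seq_len(nRepeats), function(i) {
      xi <- if (noiseSd > 0) x + rnorm(length(x), 0, noiseSd) else x
      forwardNet(model, xi, mcDropout = TRUE)$p
    }, numeric(ncol(x)))
  })
  P <- matrix(P, ncol(x), nRepeats)
  pm <- rowMeans(P)
  pv <- rowMeans(P^2) - pm^2        # population (1/n) variance
  pv[pv < 0] <- 0
  data.frame(
    p_pr = pm, uncertainty = pv,
    label = factor(ifelse(pm >= 0.5, "PR", "PEA"), levels = RHYTHM_LEVELS)
  )
}

#' Calibrate the feedback threshold
#'
#' Nearest-rank quantile of the training-set uncertainties: the threshold is
#' the `ceiling(fraction * n)`-th smallest uncertainty, so decisions with
#' uncertainty at or below it (ties included) receive feedback.
#'
#' @param uncertainties nonnegative uncertainties from the training set.
#' @param feedbackFraction target fraction of emitted decisions in (0, 1].
#' @return the threshold.
#' @examples
#' calibrateThreshold(1:10, 0.8)  # 8
#' @export
calibrateThreshold <- function(uncertainties, feedbackFraction = 1.0) {
  if (length(uncertainties) == 0) stop("empty uncertainty list")
  if (feedbackFraction <= 0 || feedbackFraction > 1)
    stop("feedbackFraction must be in (0, 1]")
  sort(uncertainties)[ceiling(feedbackFraction * length(uncertainties))]
}

#' Selective evaluation under an uncertainty policy
#'
#' Runs Monte-Carlo-dropout prediction on a test set, withholds decisions
#' whose uncertainty exceeds the calibrated threshold, and computes
#' patient-weighted metrics on the retained decisions.
#'
#' @param model a trained [PulseNet-class].
#' @param data an [EcgSegmentSet-class] of processed segments.
#' @param policy a calibrated [UncertaintyPolicy-class].
#' @param seed integer seed for the MC passes.
#' @return list with `metrics` (see [patientWeightedMetrics()]; `NULL` when
#'   nothing is retained), `feedbackFraction` (realized), `nRetained`, and
#'   the per-segment `predictions`.
#' @export
selectiveEvaluate <- function(model, data, policy, seed = 1L) {
  methods::validObject(policy)
  if (is.na(policy@threshold)) stop("policy threshold is not calibrated")
  pred <- mcPredict(model, data, nRepeats = policy@nRepeats, seed = seed,
                    noiseSd = policy@noiseSd)
  keep <- pred$uncertainty <= policy@threshold
  frac <- mean(keep)
  if (!any(keep)) {
    return(list(metrics = NULL, feedbackFraction = 0, nRetained = 0L,
                predictions = pred))
  }
  m <- patientWeightedMetrics(pred$label[keep],
                              segmentLabels(data)[keep],
                              patientIds(data)[keep])
  list(metrics = m, feedbackFraction = frac, nRetained = sum(keep),
       predictions = pred)
}
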