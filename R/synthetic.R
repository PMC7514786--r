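#' Rhythm parameter constructor
#'
#' Builds a [RhythmParams-class] with class-specific defaults. PR defaults
#' are faster, narrower and more regular than PEA, reflecting the clinical
#' contrast between perfusing rhythms and pulseless electrical activity.
#'
#' @param rhythmClass `"PR"` or `"PEA"`.
#' @param heartRateBpm mean heart rate (bpm).
#' @param rateCv RR-interval coefficient of variation.
#' @param qrsWidthMs QRS width (ms).
#' @param ectopyProb per-beat ectopic probability.
#' @param amplitudeMv peak QRS amplitude (mV).
#' @param noiseSdMv additive noise SD (mV).
#' @return a [RhythmParams-class].
#' @examples
#' rhythmParams("PR", heartRateBpm = 80, rateCv = 0)
#' @export
rhythmParams <- function(rhythmClass = c("PR", "PEA"),
                         heartRateBpm = NULL, rateCv = NULL,
                         qrsWidthMs = NULL, ectopyProb = NULL,
                         amplitudeMv = 1.0, noiseSdMv = 0.02) {
  rhythmClass <- match.arg(rhythmClass)
  def <- if (rhythmClass == "PR") {
    list(rate = 100, cv = 0.03, width = 80, ect = 0.02)
  } else {
    list(rate = 45, cv = 0.15, width = 170, ect = 0.10)
  }
  methods::new("RhythmParams",
    rhythmClass = rhythmClass,
    heartRateBpm = if (is.null(heartRateBpm)) def$rate else heartRateBpm,
    rateCv = if (is.null(rateCv)) def$cv else rateCv,
    qrsWidthMs = if (is.null(qrsWidthMs)) def$width else qrsWidthMs,
    ectopyProb = if (is.null(ectopyProb)) def$ect else ectopyProb,
    amplitudeMv = amplitudeMv,
    noiseSdMv = noiseSdMv
  )
}

# Class-conditional priors for per-patient parameters. PR rates dominate PEA
# rates stochastically; PEA dominates in QRS width and RR variability.
samplePatientParams <- function(rhythmClass) {
  if (rhythmClass == "PR") {
    rhythmParams("PR",
      heartRateBpm = runif(1, 70, 130),
      rateCv = runif(1, 0.01, 0.05),
      qrsWidthMs = runif(1, 60, 100),
      ectopyProb = runif(1, 0, 0.05),
      amplitudeMv = runif(1, 0.5, 1.5),
      noiseSdMv = runif(1, 0.01, 0.03)
    )
  } else {
    rhythmParams("PEA",
      heartRateBpm = runif(1, 20, 70),
      rateCv = runif(1, 0.08, 0.25),
      qrsWidthMs = runif(1, 120, 220),
      ectopyProb = runif(1, 0, 0.2),
      amplitudeMv = runif(1, 0.5, 1.5),
      noiseSdMv = runif(1, 0.01, 0.03)
    )
  }
}

# Synthesize one 5-s segment at 250 Hz from rhythm parameters using the
# current RNG stream. The waveform is a train of Gaussian-shaped QRS pulses
# at jittered RR intervals plus slow baseline wander and truncated white
# noise; peak budget keeps |x| <= amplitudeMv + 6 * noiseSdMv.
synthesizeSegment <- function(params, fs = 250, durationS = 5,
                              rateScale = 1) {
  n <- round(fs * durationS)
  t <- (seq_len(n) - 1) / fs
  rate <- params@heartRateBpm * rateScale
  meanRR <- 60 / rate
  sigmaQrs <- params@qrsWidthMs / 1000 / 6  # +-3 sigma spans the QRS

  # beat times: jittered RR intervals, strictly positive
  beats <- numeric(0)
  tb <- runif(1, 0, meanRR)
  while (tb < durationS + 3 * sigmaQrs) {
    beats <- c(beats, tb)
    rr <- rnorm(1, meanRR, params@rateCv * meanRR)
    rr <- max(rr, 0.25 * meanRR, 0.2)
    tb <- tb + rr
  }

  qrsAmp <- 0.88 * params@amplitudeMv
  wanderAmp <- 0.05 * params@amplitudeMv
  x <- wanderAmp * sin(2 * pi * runif(1, 0.15, 0.35) * t + runif(1, 0, 2 * pi))
  for (tb in beats) {
    ect <- runif(1) < params@ectopyProb
    a <- qrsAmp * runif(1, 0.95, 1.05) * if (ect) -0.9 else 1
    s <- sigmaQrs * if (ect) 1.8 else 1
    win <- abs(t - tb) < 4 * s
    x[win] <- x[win] + a * exp(-(t[win] - tb)^2 / (2 * s^2))
  }
  if (params@noiseSdMv > 0) {
    eps <- rnorm(n, 0, params@noiseSdMv)
    bound <- 6 * params@noiseSdMv
    x <- x + pmin(pmax(eps, -bound), bound)
  }
  x
}

#' Generate synthetic ECG segments for one patient
#'
#' Synthesizes `nSegments` labelled 5-s segments at 250 Hz for a single
#' patient. The waveform model is a train of Gaussian-shaped QRS pulses at
#' jittered RR intervals, optional wide inverted ectopic beats, slow
#' baseline wander, and white noise. Output is bit-reproducible for a given
#' seed.
#'
#' @param params a [RhythmParams-class].
#' @param nSegments number of segments (>= 1).
#' @param seed integer seed.
#' @param patientId identifier stored with every segment.
#' @param durationS segment duration in seconds.
#' @return an [EcgSegmentSet-class] with `nSegments` columns.
#' @examples
#' x <- generatePatient(rhythmParams("PR"), nSegments = 3, seed = 7)
#' dim(ecgSignals(x))  # 1250 x 3
#' @export
generatePatient <- function(params, nSegments, seed,
                            patientId = "patient_1", durationS = 5) {
  methods::validObject(params)
  if (length(nSegments) != 1 || nSegments < 1)
    stop("nSegments must be a positive integer")
  fs <- 250
  withSeed(seed, {
    # Within-patient variability: the per-segment mean rate wanders in
    # proportion to the RR variability, twice as strongly for PEA, so PEA
    # segments of one patient differ more among themselves than PR segments.
    scaleSd <- params@rateCv * if (params@rhythmClass == "PR") 1 else 2
    sig <- vapply(seq_len(nSegments), function(i) {
      synthesizeSegment(params, fs = fs, durationS = durationS,
                        rateScale = max(0.5, rnorm(1, 1, scaleSd)))
    }, numeric(round(fs * durationS)))
    EcgSegmentSet(sig,
                  patientId = rep(patientId, nSegments),
                  label = rep(params@rhythmClass, nSegments),
                  fs = fs)
  })
}

#' Generate a patient-structured synthetic dataset
#'
#' Draws per-patient rhythm parameters from class-conditional priors
#' (PR: rate U(70,130) bpm, RR CV U(0.01,0.05), QRS width U(60,100) ms;
#' PEA: rate U(20,70) bpm, RR CV U(0.08,0.25), QRS width U(120,220) ms,
#' ectopy up to 0.2) and a variable number of segments per patient.
#'
#' @param nPrPatients,nPeaPatients number of patients per class (>= 0).
#' @param segmentsPerPatient integer range `c(min, max)` of segments drawn
#'   per patient.
#' @param seed integer seed; the result is fully reproducible.
#' @return an [EcgSegmentSet-class] (possibly with zero segments).
#' @examples
#' d <- generateDataset(5, 5, segmentsPerPatient = c(2, 6), seed = 1)
#' table(patientIds(d))
#' @export
generateDataset <- function(nPrPatients, nPeaPatients,
                            segmentsPerPatient = c(2L, 6L), seed = 1L) {
  if (nPrPatients < 0 || nPeaPatients < 0)
    stop("patient counts must be nonnegative")
  if (length(segmentsPerPatient) != 2 ||
      any(segmentsPerPatient < 1) ||
      segmentsPerPatient[2] < segmentsPerPatient[1])
    stop("segmentsPerPatient must be a valid range c(min, max) with min >= 1")
  classes <- c(rep("PR", nPrPatients), rep("PEA", nPeaPatients))
  if (length(classes) == 0) {
    return(EcgSegmentSet(matrix(numeric(0), 1250, 0),
                         patientId = character(0), label = character(0),
                         fs = 250))
  }
  withSeed(seed, {
    sets <- lapply(seq_along(classes), function(i) {
      params <- samplePatientParams(classes[i])
      k <- sample(seq(segmentsPerPatient[1], segmentsPerPatient[2]), 1)
      pid <- sprintf("%s_%03d", classes[i],
                     if (classes[i] == "PR") i else i - nPrPatients)
      generatePatient(params, k, seed = sample.int(.Machine$integer.max, 1),
                      patientId = pid)
    })
    sig <- do.call(cbind, lapply(sets, ecgSignals))
    EcgSegmentSet(sig,
                  patientId = unlist(lapply(sets, patientIds)),
                  label = unlist(lapply(sets, function(s)
                    as.character(segmentLabels(s)))),
                  fs = 250)
  })
}
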