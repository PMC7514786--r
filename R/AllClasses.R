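#' Rhythm synthesis parameters
#'
#' Parameters controlling the synthetic waveform of one patient's rhythm.
#' PR (pulse-generating rhythm) is characterized by faster, narrower, more
#' regular QRS complexes than PEA (pulseless electrical activity).
#'
#' @slot rhythmClass `"PR"` or `"PEA"`.
#' @slot heartRateBpm mean heart rate in beats per minute (> 0).
#' @slot rateCv coefficient of variation of RR intervals (>= 0, unitless).
#' @slot qrsWidthMs QRS complex width in milliseconds (> 0).
#' @slot ectopyProb per-beat probability of an ectopic (wide, inverted) beat.
#' @slot amplitudeMv peak QRS amplitude in mV (> 0).
#' @slot noiseSdMv standard deviation of additive noise in mV (>= 0).
#'
#' @seealso [rhythmParams()], [generatePatient()]
#' @export
setClass("RhythmParams",
  representation(
    rhythmClass = "character",
    heartRateBpm = "numeric",
    rateCv = "numeric",
    qrsWidthMs = "numeric",
    ectopyProb = "numeric",
    amplitudeMv = "numeric",
    noiseSdMv = "numeric"
  )
)

setValidity("RhythmParams", function(object) {
  msg <- character(0)
  if (!object@rhythmClass %in% RHYTHM_LEVELS)
    msg <- c(msg, "rhythmClass must be 'PR' or 'PEA'")
  if (object@heartRateBpm <= 0) msg <- c(msg, "heartRateBpm must be positive")
  if (object@rateCv < 0) msg <- c(msg, "rateCv must be nonnegative")
  if (object@qrsWidthMs <= 0) msg <- c(msg, "qrsWidthMs must be positive")
  if (object@ectopyProb < 0 || object@ectopyProb > 1)
    msg <- c(msg, "ectopyProb must be in [0, 1]")
  if (object@amplitudeMv <= 0) msg <- c(msg, "amplitudeMv must be positive")
  if (object@noiseSdMv < 0) msg <- c(msg, "noiseSdMv must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Labelled ECG segment collection
#'
#' Container for a set of fixed-length single-lead ECG segments with patient
#' identity and PR/PEA labels. Extends
#' [SummarizedExperiment::SummarizedExperiment]: the `"ecg"` assay holds one
#' segment per column (rows are time samples), `colData` carries
#' `patient_id` and `label`, and the sampling frequency in Hz is stored in
#' `metadata(x)$fs`.
#'
#' @seealso [EcgSegmentSet()], [generateDataset()], [preprocessSegments()]
#' @export
setClass("EcgSegmentSet", contains = "SummarizedExperiment")

setValidity("EcgSegmentSet", function(object) {
  msg <- character(0)
  if (!"ecg" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'ecg' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("patient_id", "label") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'patient_id' and 'label'")
  else if (!all(as.character(cd$label) %in% RHYTHM_LEVELS))
    msg <- c(msg, "labels must be 'PR' or 'PEA'")
  fs <- S4Vectors::metadata(object)$fs
  if (is.null(fs) || !is.numeric(fs) || fs <= 0)
    msg <- c(msg, "metadata(x)$fs must be a positive sampling frequency")
  if (length(msg)) msg else TRUE
})

#' Network hyper-parameter configurations
#'
#' `S1Config` describes the fully convolutional architecture: `nBlocks`
#' convolutional blocks (conv -> max-pool -> dropout), each with `nKernels`
#' kernels of length `kernelLength`, followed by global max pooling and a
#' single sigmoid unit. `S2Config` extends it with a bidirectional GRU of
#' `gruUnits` units per direction replacing the global pooling stage.
#'
#' @slot nBlocks number of convolutional blocks (lambda).
#' @slot nKernels kernels per convolutional layer (M).
#' @slot kernelLength kernel length in samples (L).
#' @slot dropout dropout probability alpha in [0, 1).
#' @slot poolSize max-pooling size K (fixed to 2 in the reference design).
#' @slot maxNorm max-norm bound gamma on constrained weight vectors.
#'
#' @aliases S2Config-class
#' @seealso [s1Config()], [s2Config()], [buildS1()], [buildS2()]
#' @export
setClass("S1Config",
  representation(
    nBlocks = "integer",
    nKernels = "integer",
    kernelLength = "integer",
    dropout = "numeric",
    poolSize = "integer",
    maxNorm = "numeric"
  ),
  prototype(poolSize = 2L, maxNorm = 3.5, dropout = 0.1)
)

setValidity("S1Config", function(object) {
  msg <- character(0)
  if (object@nBlocks < 1L) msg <- c(msg, "nBlocks must be >= 1")
  if (object@nKernels < 1L) msg <- c(msg, "nKernels must be >= 1")
  if (object@kernelLength < 1L) msg <- c(msg, "kernelLength must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (object@poolSize < 1L) msg <- c(msg, "poolSize must be >= 1")
  if (object@maxNorm <= 0) msg <- c(msg, "maxNorm must be positive")
  if (length(msg)) msg else TRUE
})

#' @slot gruUnits GRU units per direction (theta).
#' @slot recurrentDropout dropout fraction on recurrent connections.
#' @rdname S1Config-class
#' @export
setClass("S2Config",
  contains = "S1Config",
  representation(
    gruUnits = "integer",
    recurrentDropout = "numeric"
  ),
  prototype(recurrentDropout = 0.15)
)

setValidity("S2Config", function(object) {
  msg <- character(0)
  if (object@gruUnits < 1L) msg <- c(msg, "gruUnits must be >= 1")
  if (object@recurrentDropout < 0 || object@recurrentDropout >= 1)
    msg <- c(msg, "recurrentDropout must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Pulse-detection network
#'
#' A built (optionally trained) S1 or S2 network. Parameters are stored as a
#' named list of numeric arrays; convolution weights use the flattened
#' (channel x tap) layout described in [convForward()].
#'
#' @slot arch `"s1"` or `"s2"`.
#' @slot config the [S1Config-class] or [S2Config-class] used to build it.
#' @slot inputLength nominal input length in samples (500 for 5 s at 100 Hz).
#' @slot minLength shortest input the layer stack accepts.
#' @slot params named list of parameter arrays.
#' @slot history per-epoch training loss (empty until trained).
#'
#' @seealso [buildS1()], [buildS2()], [trainModel()], [predictPulse()]
#' @export
setClass("PulseNet",
  representation(
    arch = "character",
    config = "S1Config",
    inputLength = "integer",
    minLength = "integer",
    params = "list",
    history = "numeric"
  )
)

#' Training configuration
#'
#' Optimization recipe used by [trainModel()]: ADAM with fixed learning rate,
#' mini-batches, per-mini-batch augmentation (additive Gaussian noise and
#' uniform amplitude jitter), and a max-norm constraint applied after every
#' update.
#'
#' @slot learningRate ADAM step size.
#' @slot beta1,beta2 ADAM exponential decay rates.
#' @slot batchSize mini-batch size.
#' @slot epochs number of passes over the training data.
#' @slot noiseSd standard deviation of additive augmentation noise.
#' @slot amplitudeJitter half-width of the uniform amplitude scaling
#'   (0.02 means factors in \[0.98, 1.02\]).
#' @slot maxNorm max-norm bound applied to constrained weight vectors.
#'
#' @seealso [trainingConfig()], [trainModel()]
#' @export
setClass("TrainingConfig",
  representation(
    learningRate = "numeric",
    beta1 = "numeric",
    beta2 = "numeric",
    batchSize = "integer",
    epochs = "integer",
    noiseSd = "numeric",
    amplitudeJitter = "numeric",
    maxNorm = "numeric"
  )
)

setValidity("TrainingConfig", function(object) {
  ok <- object@learningRate > 0 && object@beta1 > 0 && object@beta2 > 0 &&
    object@batchSize >= 1L && object@epochs >= 1L && object@noiseSd >= 0 &&
    object@amplitudeJitter >= 0 && object@amplitudeJitter < 1 &&
    object@maxNorm > 0
  if (ok) TRUE else "all fields must be positive (jitter in [0, 1))"
})

#' Selective-prediction policy
#'
#' Monte-Carlo-dropout uncertainty gating: predictions whose MC variance
#' exceeds `threshold` are withheld (no feedback). The threshold is
#' calibrated on training-set uncertainties so that a target fraction of
#' decisions receives feedback.
#'
#' @slot nRepeats number of stochastic forward passes.
#' @slot threshold uncertainty threshold (`NA` until calibrated).
#' @slot targetFeedbackFraction intended fraction of emitted decisions.
#' @slot noiseSd SD of the white noise added to the input at each pass.
#'
#' @seealso [uncertaintyPolicy()], [calibrateThreshold()],
#'   [selectiveEvaluate()]
#' @export
setClass("UncertaintyPolicy",
  representation(
    nRepeats = "integer",
    threshold = "numeric",
    targetFeedbackFraction = "numeric",
    noiseSd = "numeric"
  ),
  prototype(nRepeats = 100L, threshold = NA_real_,
            targetFeedbackFraction = 1.0, noiseSd = 1e-4)
)

setValidity("UncertaintyPolicy", function(object) {
  msg <- character(0)
  if (object@nRepeats < 1L) msg <- c(msg, "nRepeats must be >= 1")
  if (object@targetFeedbackFraction <= 0 || object@targetFeedbackFraction > 1)
    msg <- c(msg, "targetFeedbackFraction must be in (0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})
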