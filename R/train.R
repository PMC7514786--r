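#' Training configuration constructor
#'
#' Defaults follow the reference recipe: ADAM (learning rate 0.001, decay
#' rates 0.9 / 0.999), mini-batches of 8 for 75 epochs, per-mini-batch
#' augmentation with Gaussian noise (SD 1e-4) and +-2% amplitude jitter, and
#' a max-norm bound of 3.5 on the convolution (and recurrent) kernels.
#'
#' @param learningRate,beta1,beta2 ADAM settings.
#' @param batchSize,epochs mini-batch size and number of epochs.
#' @param noiseSd,amplitudeJitter augmentation parameters.
#' @param maxNorm max-norm bound gamma.
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(learningRate = 0.001, beta1 = 0.9, beta2 = 0.999,
                           batchSize = 8L, epochs = 75L, noiseSd = 1e-4,
                           amplitudeJitter = 0.02, maxNorm = 3.5) {
  methods::new("TrainingConfig",
    learningRate = learningRate, beta1 = beta1, beta2 = beta2,
    batchSize = as.integer(batchSize), epochs = as.integer(epochs),
    noiseSd = noiseSd, amplitudeJitter = amplitudeJitter, maxNorm = maxNorm)
}

#' Patient-equalizing sample weights
#'
#' Every patient contributes equally to the loss: each segment of a patient
#' with `k` segments receives weight `1/k`, so per-patient weights sum to 1
#' and the total equals the number of patients.
#'
#' @param x an [EcgSegmentSet-class] or a character vector of patient ids.
#' @return numeric weight per segment.
#' @examples
#' computeSampleWeights(c("a", "b", "b", "b"))  # 1, 1/3, 1/3, 1/3
#' @export
computeSampleWeights <- function(x) {
  pid <- if (methods::is(x, "EcgSegmentSet")) patientIds(x) else
    as.character(x)
  if (length(pid) == 0) stop("empty dataset")
  1 / as.numeric(table(pid)[pid])
}

#' Mini-batch augmentation
#'
#' Each signal `x` is replaced by `a * x + eps` with a fresh amplitude
#' factor `a ~ U(1 - jitter, 1 + jitter)` per segment and i.i.d. Gaussian
#' noise `eps ~ N(0, noiseSd^2)` per sample, drawn anew at every mini-batch.
#'
#' @param x numeric matrix, samples x segments.
#' @param noiseSd additive noise standard deviation.
#' @param amplitudeJitter half-width of the uniform scaling.
#' @param seed optional seed (when used standalone; [trainModel()] drives
#'   the stream itself).
#' @return matrix of the same shape.
#' @export
augmentBatch <- function(x, noiseSd = 1e-4, amplitudeJitter = 0.02,
                         seed = NULL) {
  stopifnot(is.matrix(x), ncol(x) >= 1)
  withSeed(seed, {
    a <- if (amplitudeJitter > 0)
      runif(ncol(x), 1 - amplitudeJitter, 1 + amplitudeJitter)
    else rep(1, ncol(x))
    out <- sweep(x, 2, a, `*`)
    if (noiseSd > 0) out <- out + rnorm(length(out), 0, noiseSd)
    out
  })
}

#' Patient-weighted binary cross-entropy
#'
#' `-sum(eta * (y * log(p) + (1 - y) * log(1 - p)))` with probabilities
#' clamped to `[1e-7, 1 - 1e-7]`. With patient-equalizing weights this is
#' the training loss; it weights every patient equally regardless of how
#' many segments the patient contributed.
#'
#' @param p predicted PR likelihoods in (0, 1).
#' @param y binary labels (1 = PR, 0 = PEA) or a PR/PEA factor.
#' @param eta sample weights (default 1).
#' @return nonnegative scalar loss.
#' @examples
#' weightedBce(0.5, 1)  # log(2)
#' @export
weightedBce <- function(p, y, eta = rep(1, length(p))) {
  if (is.factor(y) || is.character(y)) y <- labelToBinary(y)
  pc <- clampProb(p)
  -sum(eta * (y * log(pc) + (1 - y) * log(1 - pc)))
}

#' Max-norm constraint
#'
#' Projects weight vectors onto the Euclidean ball of radius `gamma`: a
#' vector with norm above the bound is rescaled to norm `gamma`, otherwise
#' left unchanged. For a matrix the constraint applies column-wise (each
#' column is one kernel's weight vector).
#'
#' @param w numeric vector or matrix.
#' @param gamma max-norm bound.
#' @return constrained vector/matrix.
#' @export
applyMaxNorm <- function(w, gamma = 3.5) {
  if (is.matrix(w)) {
    nrm <- sqrt(colSums(w^2))
    scl <- ifelse(nrm > gamma, gamma / nrm, 1)
    return(sweep(w, 2, scl, `*`))
  }
  nrm <- sqrt(sum(w^2))
  if (nrm > gamma) w * (gamma / nrm) else w
}

# Constrained parameter names: convolution kernels column-wise; GRU input
# and recurrent matrices row-wise (one weight vector per unit and gate).
# The dense layer is left unconstrained.
applyConstraints <- function(params, gamma) {
  for (nm in names(params)) {
    if (grepl("^conv[0-9]+\\.W$", nm)) {
      params[[nm]] <- applyMaxNorm(params[[nm]], gamma)
    } else if (grepl("^gru[FB]\\.(W|U)[zrh]?$", nm)) {
      params[[nm]] <- t(applyMaxNorm(t(params[[nm]]), gamma))
    }
  }
  params
}

#' Train a pulse-detection network
#'
#' Stochastic training with ADAM on the patient-weighted binary
#' cross-entropy. Data are shuffled at each epoch and fed in mini-batches;
#' every mini-batch is augmented (noise + amplitude jitter), dropout is
#' active, and the max-norm constraint is re-applied after every update.
#' The run is bit-reproducible for a fixed seed.
#'
#' @param model an untrained (or previously trained) [PulseNet-class].
#' @param data an [EcgSegmentSet-class] of processed (100 Hz) segments, or a
#'   numeric `N x B` matrix when `labels`/`patients` are given explicitly.
#' @param config a [TrainingConfig-class].
#' @param seed integer seed controlling shuffling, augmentation and dropout.
#' @param labels,patients per-segment labels and patient ids (only when
#'   `data` is a plain matrix).
#' @return the trained [PulseNet-class]; `@history` holds the per-epoch mean
#'   loss per patient.
#' @export
trainModel <- function(model, data, config = trainingConfig(), seed = 1L,
                       labels = NULL, patients = NULL) {
  methods::validObject(config)
  if (methods::is(data, "EcgSegmentSet")) {
    labels <- segmentLabels(data)
    patients <- patientIds(data)
    data <- ecgSignals(data)
  }
  if (is.null(labels) || is.null(patients))
    stop("labels and patients are required for matrix input")
  nSeg <- ncol(data)
  if (nSeg == 0) stop("empty dataset")
  y <- labelToBinary(labels)
  eta <- computeSampleWeights(patients)
  nPat <- length(unique(patients))

  params <- model@params
  mState <- lapply(params, function(p)
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p)))
  vState <- mState
  t0 <- 0L
  history <- numeric(config@epochs)

  withSeed(seed, {
    for (epoch in seq_len(config@epochs)) {
      perm <- sample.int(nSeg)
      epochLoss <- 0
      for (start in seq(1L, nSeg, by = config@batchSize)) {
        idx <- perm[start:min(start + config@batchSize - 1L, nSeg)]
        xb <- augmentBatch(data[, idx, drop = FALSE],
                           config@noiseSd, config@amplitudeJitter)
        model@params <- params
        fwd <- forwardNet(model, xb, training = TRUE, withCache = TRUE)
        pb <- clampProb(fwd$p)
        epochLoss <- epochLoss + weightedBce(pb, y[idx], eta[idx])
        dscore <- eta[idx] * (pb - y[idx])
        grads <- backwardNet(model, fwd, dscore)
        t0 <- t0 + 1L
        lrT <- config@learningRate *
          sqrt(1 - config@beta2^t0) / (1 - config@beta1^t0)
        for (nm in names(params)) {
          g <- grads[[nm]]
          mState[[nm]] <- config@beta1 * mState[[nm]] + (1 - config@beta1) * g
          vState[[nm]] <- config@beta2 * vState[[nm]] +
            (1 - config@beta2) * g^2
          params[[nm]] <- params[[nm]] -
            lrT * mState[[nm]] / (sqrt(vState[[nm]]) + 1e-8)
        }
        params <- applyConstraints(params, config@maxNorm)
      }
      history[epoch] <- epochLoss / nPat
    }
  })
  model@params <- params
  model@history <- c(model@history, history)
  model
}
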