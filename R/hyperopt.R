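# Bayesian hyper-parameter optimization: 4-fold patient-wise
# cross-validated balanced error rate as the objective, minimized with a
# tree-structured Parzen estimator (networks) or a Gaussian-process
# surrogate with expected improvement (classical baselines). Both
# optimizers are compact self-contained implementations behind a common
# `tuneModel` interface.

#' Reference search spaces
#'
#' The hyper-parameter search space of each model family: S1
#' (`lambda` 1..5, `M` {8,16,24}, `L` 5..8, `alpha` U(0.05, 0.5)), S2 (adds
#' `theta` 4..8), RF (`phi` U(0.5, 1), `psi` 1..9), SVM (`C`, `gammaS`
#' U(0.001, 10000)), KLR (`lambdaL` U(0.0001, 0.2), `gammaS` U(0.0001, 15)).
#'
#' @param family `"s1"`, `"s2"`, `"rf"`, `"svm"` or `"klr"`.
#' @return named list of dimensions, each
#'   `list(type = "choice", values = ...)` or
#'   `list(type = "uniform", min = ..., max = ...)`.
#' @export
pulseSearchSpace <- function(family = c("s1", "s2", "rf", "svm", "klr")) {
  family <- match.arg(family)
  ch <- function(v) list(type = "choice", values = v)
  un <- function(lo, hi) list(type = "uniform", min = lo, max = hi)
  switch(family,
    s1 = list(lambda = ch(1:5), M = ch(c(8L, 16L, 24L)), L = ch(5:8),
              alpha = un(0.05, 0.5)),
    s2 = list(lambda = ch(1:5), M = ch(c(8L, 16L, 24L)), L = ch(5:8),
              alpha = un(0.05, 0.5), theta = ch(4:8)),
    rf = list(phi = un(0.5, 1), psi = ch(1:9)),
    svm = list(C = un(0.001, 10000), gammaS = un(0.001, 10000)),
    klr = list(lambdaL = un(0.0001, 0.2), gammaS = un(0.0001, 15))
  )
}

#' Patient-wise cross-validation folds
#'
#' Assigns whole patients to `k` folds, stratified by patient label, with
#' fold sizes differing by at most one patient.
#'
#' @param x an [EcgSegmentSet-class], or a character vector of patient ids
#'   (with `labels` per entry).
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @param labels patient labels when `x` is a plain vector.
#' @return named integer vector mapping each patient id to a fold in 1..k.
#' @export
makePatientFolds <- function(x, k = 4L, seed = 1L, labels = NULL) {
  if (methods::is(x, "EcgSegmentSet")) {
    labels <- segmentLabels(x)
    x <- patientIds(x)
  }
  pats <- unique(as.character(x))
  if (length(pats) < k) stop("fewer patients than folds")
  patLab <- as.character(labels)[match(pats, as.character(x))]
  withSeed(seed, {
    fold <- integer(length(pats))
    names(fold) <- pats
    slot <- 0L
    for (cl in unique(patLab)) {
      members <- sample(pats[patLab == cl])
      for (p in members) {
        fold[p] <- (slot %% k) + 1L
        slot <- slot + 1L
      }
    }
    fold
  })
}

# Build/train/predict for one family and config on a train/test pair of
# EcgSegmentSets of processed signals. Returns predicted labels for test.
fitPredictFamily <- function(family, config, train, test, seed,
                             epochs = 75L, batchSize = 8L) {
  if (is.function(family)) return(family(train, test, config, seed))
  if (family %in% c("s1", "s2")) {
    cfg <- if (family == "s1")
      s1Config(config$lambda, config$M, config$L, dropout = config$alpha)
    else
      s2Config(config$lambda, config$M, config$L, config$theta,
               dropout = config$alpha)
    model <- if (family == "s1") buildS1(cfg, nrow(train), seed = seed)
             else buildS2(cfg, nrow(train), seed = seed)
    tc <- trainingConfig(epochs = epochs, batchSize = batchSize)
    model <- trainModel(model, train, tc, seed = seed)
    return(predictPulse(model, test)$label)
  }
  ftr <- extractFeatures(train)
  fte <- extractFeatures(test)
  lab <- segmentLabels(train)
  fit <- switch(family,
    rf = rfFit(ftr, lab, phi = config$phi, psi = config$psi, seed = seed),
    svm = svmFit(ftr, lab, C = config$C, gammaS = config$gammaS),
    klr = klrFit(ftr, lab, lambdaL = config$lambdaL, gammaS = config$gammaS),
    stop("unknown model family: ", family)
  )
  predictBaseline(fit, fte)
}

#' Cross-validated balanced error rate
#'
#' Trains a model family with the given hyper-parameters on `k - 1` folds,
#' evaluates patient-weighted metrics on the held-out fold, and averages
#' the balanced error rate (fraction scale) over folds.
#'
#' @param family `"s1"`, `"s2"`, `"rf"`, `"svm"`, `"klr"`, or a function
#'   `f(train, test, config, seed)` returning predicted labels for `test`
#'   (useful for testing the protocol with known classifiers).
#' @param config named list of hyper-parameters (see [pulseSearchSpace()]).
#' @param data an [EcgSegmentSet-class] of processed segments.
#' @param folds patient-to-fold assignment from [makePatientFolds()].
#' @param seed integer seed.
#' @param epochs,batchSize training settings for the network families.
#' @return mean BER over folds, in \[0, 1\].
#' @export
cvObjective <- function(family, config, data, folds, seed = 1L,
                        epochs = 75L, batchSize = 8L) {
  pid <- patientIds(data)
  bers <- vapply(sort(unique(folds)), function(f) {
    inTest <- pid %in% names(folds)[folds == f]
    pred <- tryCatch(
      fitPredictFamily(family, config, data[, !inTest], data[, inTest],
                       seed = seed, epochs = epochs, batchSize = batchSize),
      error = function(e) stop("training failed in fold ", f, ": ",
                               conditionMessage(e)))
    m <- patientWeightedMetrics(pred, segmentLabels(data)[inTest],
                                pid[inTest])
    m[["ber_pct"]] / 100
  }, numeric(1))
  mean(bers)
}

sampleUniformConfig <- function(space) {
  lapply(space, function(dim) {
    if (dim$type == "choice") sample(dim$values, 1)
    else runif(1, dim$min, dim$max)
  })
}

configToRow <- function(config, value) {
  as.data.frame(c(config, list(objective = value)))
}

# --- tree-structured Parzen estimator ------------------------------------

tpePropose <- function(space, history, values, nCandidates = 24L,
                       gammaFrac = 0.25) {
  n <- length(values)
  ng <- max(1L, ceiling(gammaFrac * n))
  ord <- order(values)
  goodIdx <- ord[seq_len(ng)]
  badIdx <- ord[-seq_len(ng)]
  if (length(badIdx) == 0) badIdx <- ord
  dimLogRatio <- function(dim, vals, x) {
    g <- vals[goodIdx]; b <- vals[badIdx]
    if (dim$type == "choice") {
      k <- length(dim$values)
      pg <- (tabulate(match(g, dim$values), k) + 1) / (length(g) + k)
      pb <- (tabulate(match(b, dim$values), k) + 1) / (length(b) + k)
      i <- match(x, dim$values)
      log(pg[i]) - log(pb[i])
    } else {
      rng <- dim$max - dim$min
      dens <- function(pts, x) {
        bw <- max(rng / max(sqrt(length(pts)), 1), 0.05 * rng)
        prior <- 1 / rng
        (sum(dnorm(x, pts, bw)) + prior) / (length(pts) + 1)
      }
      log(dens(g, x)) - log(dens(b, x))
    }
  }
  sampleGood <- function(dim, vals) {
    g <- vals[goodIdx]
    if (dim$type == "choice") {
      k <- length(dim$values)
      pg <- (tabulate(match(g, dim$values), k) + 1) / (length(g) + k)
      dim$values[sample.int(k, 1, prob = pg)]
    } else {
      rng <- dim$max - dim$min
      bw <- max(rng / max(sqrt(length(g)), 1), 0.05 * rng)
      x <- rnorm(1, g[sample.int(length(g), 1)], bw)
      min(max(x, dim$min), dim$max)
    }
  }
  best <- NULL; bestScore <- -Inf
  for (cand in seq_len(nCandidates)) {
    config <- list()
    score <- 0
    for (nm in names(space)) {
      vals <- vapply(history, function(h) h[[nm]], numeric(1))
      x <- sampleGood(space[[nm]], vals)
      config[[nm]] <- x
      score <- score + dimLogRatio(space[[nm]], vals, x)
    }
    if (score > bestScore) { bestScore <- score; best <- config }
  }
  best
}

# --- Gaussian-process surrogate with expected improvement -----------------

encodeConfig <- function(space, config) {
  vapply(names(space), function(nm) {
    dim <- space[[nm]]
    if (dim$type == "choice") {
      k <- length(dim$values)
      if (k == 1) 0.5 else (match(config[[nm]], dim$values) - 1) / (k - 1)
    } else {
      (config[[nm]] - dim$min) / (dim$max - dim$min)
    }
  }, numeric(1))
}

decodePoint <- function(space, u) {
  config <- list()
  for (j in seq_along(space)) {
    dim <- space[[j]]
    config[[names(space)[j]]] <- if (dim$type == "choice") {
      k <- length(dim$values)
      dim$values[1 + round(u[j] * (k - 1))]
    } else {
      dim$min + u[j] * (dim$max - dim$min)
    }
  }
  config
}

gpPropose <- function(space, history, values, nCandidates = 256L,
                      lengthscale = 0.25) {
  X <- vapply(history, function(h) encodeConfig(space, h),
              numeric(length(space)))
  X <- if (is.matrix(X)) t(X) else matrix(X, ncol = 1)
  ym <- mean(values); ys <- max(sd(values), 1e-9)
  y <- (values - ym) / ys
  k2 <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / (2 * lengthscale^2))
  }
  K <- k2(X, X) + diag(1e-4, nrow(X))
  Kinv_y <- solve(K, y)
  U <- matrix(runif(nCandidates * ncol(X)), nCandidates)
  Ks <- k2(U, X)
  mu <- as.numeric(Ks %*% Kinv_y)
  s2 <- pmax(1 - rowSums(Ks * t(solve(K, t(Ks)))), 1e-12)
  sdev <- sqrt(s2)
  fBest <- min(y)
  imp <- fBest - mu
  zq <- imp / sdev
  ei <- imp * stats::pnorm(zq) + sdev * dnorm(zq)
  decodePoint(space, U[which.max(ei), ])
}

#' Sequential model-based hyper-parameter optimization
#'
#' Minimizes an objective over a mixed discrete/continuous search space
#' using either a tree-structured Parzen estimator (`"tpe"`) or a
#' Gaussian-process surrogate with expected improvement (`"gp"`). The first
#' trials are random/space-filling; each later trial is proposed by the
#' surrogate. Deterministic for a fixed seed.
#'
#' @param space search space as returned by [pulseSearchSpace()].
#' @param objective function taking a named config list, returning the
#'   value to minimize (e.g. a closure over [cvObjective()]).
#' @param nTrials total number of trials (>= 1).
#' @param method `"tpe"` or `"gp"`.
#' @param seed integer seed.
#' @param nStartup number of initial random trials.
#' @return list with `best` (`config`, `objective`) and `history` (one row
#'   per trial: config columns plus `objective`).
#' @examples
#' sp <- list(x = list(type = "uniform", min = -2, max = 2))
#' res <- tuneModel(sp, function(cfg) (cfg$x - 1)^2, nTrials = 20,
#'                  method = "gp", seed = 1)
#' res$best$config$x
#' @export
tuneModel <- function(space, objective, nTrials = 50L,
                      method = c("tpe", "gp"), seed = 1L,
                      nStartup = NULL) {
  method <- match.arg(method)
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (!length(space) || !all(vapply(space, function(d)
    d$type %in% c("choice", "uniform"), logical(1))))
    stop("invalid search space")
  nStartup <- if (is.null(nStartup)) min(10L, max(3L, nTrials %/% 3L))
              else as.integer(nStartup)
  withSeed(seed, {
    history <- list()
    values <- numeric(0)
    startGrid <- if (method == "gp")
      lhs::randomLHS(max(nStartup, 1L), length(space))
    for (trial in seq_len(nTrials)) {
      config <- if (trial <= nStartup) {
        if (method == "gp") decodePoint(space, startGrid[trial, ])
        else sampleUniformConfig(space)
      } else if (method == "tpe") {
        tpePropose(space, history, values)
      } else {
        gpPropose(space, history, values)
      }
      values <- c(values, objective(config))
      history[[trial]] <- config
    }
    best <- which.min(values)
    list(
      best = list(config = history[[best]], objective = values[best]),
      history = do.call(rbind, lapply(seq_len(nTrials), function(i)
        configToRow(history[[i]], values[i])))
    )
  })
}

#' Tune a pulse classifier by patient-wise cross-validation
#'
#' Convenience wrapper tying [pulseSearchSpace()], [makePatientFolds()],
#' [cvObjective()] and [tuneModel()] together: TPE for the network families,
#' GP for the classical baselines.
#'
#' @param family `"s1"`, `"s2"`, `"rf"`, `"svm"` or `"klr"`.
#' @param data an [EcgSegmentSet-class] of processed segments.
#' @param nTrials number of optimization trials.
#' @param k number of patient-wise folds.
#' @param seed integer seed.
#' @param epochs,batchSize training settings for the network families.
#' @return as [tuneModel()].
#' @export
tunePulseDetector <- function(family, data, nTrials = 50L, k = 4L,
                              seed = 1L, epochs = 75L, batchSize = 8L) {
  space <- pulseSearchSpace(family)
  folds <- makePatientFolds(data, k = k, seed = seed)
  objective <- function(config)
    cvObjective(family, config, data, folds, seed = seed, epochs = epochs,
                batchSize = batchSize)
  tuneModel(space, objective, nTrials = nTrials,
            method = if (family %in% c("s1", "s2")) "tpe" else "gp",
            seed = seed + 1L)
}
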