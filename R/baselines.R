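# Classical machine-learning baselines over feature vectors (hand-crafted
# or network-derived). Labels are the usual PR/PEA factor; PR is the
# positive class. Random forest and SVM wrap the established
# implementations; kernel logistic regression is solved here by penalized
# IRLS since no packaged implementation is available.

featureMatrix <- function(features) {
  f <- as.matrix(features)
  storage.mode(f) <- "double"
  if (!all(is.finite(f))) stop("features must be finite")
  f
}

checkTwoClasses <- function(labels) {
  labels <- asRhythmFactor(labels)
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes")
  labels
}

#' Random-forest baseline
#'
#' 300 trees by default, each grown on a with-replacement resample of
#' `phi * n` segments using `psi` candidate features per node, final label
#' by majority vote. Wraps [randomForest::randomForest()].
#'
#' @param features numeric matrix, one row per segment.
#' @param labels PR/PEA labels.
#' @param phi resample fraction in \[0.5, 1\].
#' @param psi features considered at each node.
#' @param nTrees number of trees.
#' @param seed integer seed.
#' @return a baseline model for [predictBaseline()] / [rfPredict()].
#' @export
rfFit <- function(features, labels, phi = 0.58, psi = 1L, nTrees = 300L,
                  seed = 1L) {
  f <- featureMatrix(features)
  labels <- checkTwoClasses(labels)
  if (psi > ncol(f)) stop("psi exceeds the feature dimension")
  fit <- withSeed(seed, randomForest::randomForest(
    x = f, y = labels, ntree = nTrees, mtry = psi, replace = TRUE,
    sampsize = max(1L, ceiling(phi * nrow(f)))))
  structure(list(fit = fit), class = c("rfBaseline", "pulseBaseline"))
}

#' @rdname rfFit
#' @param model a fitted baseline model.
#' @export
rfPredict <- function(model, features) predictBaseline(model, features)

#' Support-vector-machine baseline
#'
#' Soft-margin SVM with the Gaussian kernel
#' `K(v, vi) = exp(-gammaS ||v - vi||^2)`; the label is the sign of the
#' kernel expansion plus intercept. Wraps [e1071::svm()]. Features are
#' standardized with training-set statistics.
#'
#' @param features numeric matrix, one row per segment.
#' @param labels PR/PEA labels.
#' @param C soft-margin cost.
#' @param gammaS kernel width.
#' @param scale standardize features before fitting.
#' @return a baseline model for [predictBaseline()] / [svmPredict()].
#' @export
svmFit <- function(features, labels, C = 1, gammaS = 1, scale = TRUE) {
  f <- featureMatrix(features)
  labels <- checkTwoClasses(labels)
  fit <- e1071::svm(x = f, y = labels, kernel = "radial", gamma = gammaS,
                    cost = C, scale = scale)
  structure(list(fit = fit), class = c("svmBaseline", "pulseBaseline"))
}

#' @rdname svmFit
#' @param model a fitted baseline model.
#' @export
svmPredict <- function(model, features) predictBaseline(model, features)

#' Kernel logistic regression baseline
#'
#' Logistic regression in the Gaussian-kernel feature space: the logit is
#' `b + sum_i a_i K(v, v_i)` over the training points, fitted by iteratively
#' reweighted least squares with a ridge penalty `lambdaL * a' K a`
#' (tolerance 1e-8, at most 100 iterations). Features are standardized with
#' training-set statistics before the kernel is evaluated.
#'
#' @param features numeric matrix, one row per segment.
#' @param labels PR/PEA labels.
#' @param lambdaL ridge regularization weight.
#' @param gammaS kernel width.
#' @return a baseline model for [predictBaseline()] / [klrPredict()].
#' @export
klrFit <- function(features, labels, lambdaL = 0.01, gammaS = 1) {
  f <- featureMatrix(features)
  labels <- checkTwoClasses(labels)
  y <- labelToBinary(labels)
  ctr <- colMeans(f)
  scl <- apply(f, 2, sd); scl[scl == 0] <- 1
  fz <- sweep(sweep(f, 2, ctr), 2, scl, "/")
  n <- nrow(fz)
  K <- rbfKernelMatrix(fz, fz, gammaS)
  a <- numeric(n); b <- 0
  for (iter in seq_len(100L)) {
    eta <- as.numeric(K %*% a) + b
    p <- clampProb(sigmoid(eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    # weighted penalized normal equations over [K, 1]
    A <- cbind(K, 1)
    H <- crossprod(A, A * w)
    H[seq_len(n), seq_len(n)] <- H[seq_len(n), seq_len(n)] + lambdaL * K
    H <- H + diag(1e-10, n + 1L)
    theta <- solve(H, crossprod(A, w * z))
    aNew <- theta[seq_len(n)]; bNew <- theta[n + 1L]
    delta <- max(abs(c(aNew - a, bNew - b)))
    a <- aNew; b <- bNew
    if (delta < 1e-8) break
  }
  structure(list(a = a, b = b, X = fz, gammaS = gammaS, center = ctr,
                 scale = scl),
            class = c("klrBaseline", "pulseBaseline"))
}

rbfKernelMatrix <- function(X, Y, gammaS) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gammaS * pmax(d2, 0))
}

#' @rdname klrFit
#' @param model a fitted baseline model.
#' @param type `"label"` or `"prob"`.
#' @export
klrPredict <- function(model, features, type = c("label", "prob")) {
  type <- match.arg(type)
  f <- featureMatrix(features)
  fz <- sweep(sweep(f, 2, model$center), 2, model$scale, "/")
  p <- clampProb(sigmoid(
    as.numeric(rbfKernelMatrix(fz, model$X, model$gammaS) %*% model$a) +
      model$b))
  if (type == "prob") return(p)
  factor(ifelse(p >= 0.5, "PR", "PEA"), levels = RHYTHM_LEVELS)
}

#' Predict labels with a fitted baseline model
#'
#' @param model a model from [rfFit()], [svmFit()] or [klrFit()].
#' @param features numeric matrix, one row per segment.
#' @return PR/PEA factor.
#' @export
predictBaseline <- function(model, features) {
  f <- featureMatrix(features)
  if (inherits(model, "klrBaseline")) return(klrPredict(model, f))
  p <- stats::predict(model$fit, f)
  factor(as.character(p), levels = RHYTHM_LEVELS)
}
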