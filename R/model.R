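#' Configuration constructors
#'
#' Convenience constructors for [S1Config-class] and [S2Config-class]. The
#' reference search space is `nBlocks` in 1..5, `nKernels` in {8, 16, 24},
#' `kernelLength` in 5..8, `dropout` in \[0.05, 0.5\] and, for S2,
#' `gruUnits` in 4..8; values outside it are allowed (useful for toy
#' models) as long as the layer arithmetic stays valid.
#'
#' @param nBlocks number of convolutional blocks (lambda).
#' @param nKernels kernels per layer (M).
#' @param kernelLength kernel length (L).
#' @param dropout dropout probability (alpha).
#' @param poolSize max-pool size (K).
#' @param maxNorm max-norm bound (gamma).
#' @return an [S1Config-class] / [S2Config-class].
#' @examples
#' s1Config(nBlocks = 4, nKernels = 8, kernelLength = 7, dropout = 0.2)
#' @export
s1Config <- function(nBlocks, nKernels, kernelLength, dropout = 0.1,
                     poolSize = 2L, maxNorm = 3.5) {
  methods::new("S1Config",
    nBlocks = as.integer(nBlocks), nKernels = as.integer(nKernels),
    kernelLength = as.integer(kernelLength), dropout = dropout,
    poolSize = as.integer(poolSize), maxNorm = maxNorm)
}

#' @param gruUnits GRU units per direction (theta).
#' @param recurrentDropout recurrent dropout fraction.
#' @rdname s1Config
#' @export
s2Config <- function(nBlocks, nKernels, kernelLength, gruUnits,
                     dropout = 0.1, poolSize = 2L, maxNorm = 3.5,
                     recurrentDropout = 0.15) {
  methods::new("S2Config",
    nBlocks = as.integer(nBlocks), nKernels = as.integer(nKernels),
    kernelLength = as.integer(kernelLength), dropout = dropout,
    poolSize = as.integer(poolSize), maxNorm = maxNorm,
    gruUnits = as.integer(gruUnits), recurrentDropout = recurrentDropout)
}

#' Per-block signal lengths
#'
#' Time-axis length after each convolution (`N - L + 1`) and each
#' max-pooling (`floor(N / K)`) of the block stack, for a given input
#' length. Errors if any length underflows.
#'
#' @param config an [S1Config-class] (or [S2Config-class]).
#' @param inputLength input length in samples.
#' @return data.frame with columns `block`, `afterConv`, `afterPool`.
#' @export
layerLengths <- function(config, inputLength) {
  n <- as.integer(inputLength)
  L <- config@kernelLength; K <- config@poolSize
  out <- data.frame(block = seq_len(config@nBlocks),
                    afterConv = NA_integer_, afterPool = NA_integer_)
  for (i in seq_len(config@nBlocks)) {
    if (n < L)
      stop("input too short for ", config@nBlocks, " blocks of kernel length ",
           L, " (underflow at block ", i, ")")
    n <- n - L + 1L
    out$afterConv[i] <- n
    n <- n %/% K
    if (n < 1L)
      stop("input too short for ", config@nBlocks, " blocks (pooling ",
           "underflow at block ", i, ")")
    out$afterPool[i] <- n
  }
  out
}

# Shortest input length the stack accepts (all conv inputs >= L, all pooled
# lengths >= 1), obtained by inverting the length arithmetic block by block.
minInputLength <- function(config) {
  n <- 1L
  for (i in seq_len(config@nBlocks)) {
    n <- n * config@poolSize          # floor(N/K) >= n  =>  N >= K*n
    n <- n + config@kernelLength - 1L # conv input
  }
  n
}

# Glorot-uniform weight initialization.
glorot <- function(fanIn, fanOut, dims) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(runif(prod(dims), -lim, lim), dims)
}

orthogonalInit <- function(n) {
  q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  q
}

initGruParams <- function(M, theta) {
  list(Wz = glorot(M, theta, c(theta, M)),
       Wr = glorot(M, theta, c(theta, M)),
       Wh = glorot(M, theta, c(theta, M)),
       Uz = orthogonalInit(theta), Ur = orthogonalInit(theta),
       Uh = orthogonalInit(theta),
       bz = numeric(theta), br = numeric(theta), bh = numeric(theta))
}

initParams <- function(config, arch) {
  M <- config@nKernels; L <- config@kernelLength
  params <- list()
  for (i in seq_len(config@nBlocks)) {
    Cin <- if (i == 1L) 1L else M
    params[[paste0("conv", i, ".W")]] <- glorot(L * Cin, M, c(L * Cin, M))
    params[[paste0("conv", i, ".b")]] <- numeric(M)
  }
  if (arch == "s2") {
    theta <- config@gruUnits
    for (nm in names(gf <- initGruParams(M, theta)))
      params[[paste0("gruF.", nm)]] <- gf[[nm]]
    for (nm in names(gb <- initGruParams(M, theta)))
      params[[paste0("gruB.", nm)]] <- gb[[nm]]
    featDim <- 2L * theta
  } else {
    featDim <- M
  }
  params[["dense.w"]] <- as.numeric(glorot(featDim, 1, featDim))
  params[["dense.b"]] <- 0
  params
}

buildNet <- function(config, inputLength, arch, seed) {
  methods::validObject(config)
  layerLengths(config, inputLength)  # errors on underflow
  params <- withSeed(seed, initParams(config, arch))
  methods::new("PulseNet",
    arch = arch, config = config,
    inputLength = as.integer(inputLength),
    minLength = minInputLength(config),
    params = params, history = numeric(0))
}

#' Build the pulse-detection networks
#'
#' `buildS1` composes `nBlocks` x (convolution, max-pool, dropout), global
#' max pooling and a single sigmoid unit. `buildS2` replaces the global
#' pooling with a bidirectional GRU (plus an extra dropout layer before the
#' classifier). Weights are Glorot-uniform initialized (orthogonal recurrent
#' matrices), biases zero.
#'
#' @param config an [S1Config-class] (`buildS1`) or [S2Config-class]
#'   (`buildS2`).
#' @param inputLength nominal input length in samples (500 = 5 s at 100 Hz).
#'   Built models accept any input of at least `minLength(model)` samples.
#' @param seed integer seed for weight initialization.
#' @return a [PulseNet-class].
#' @examples
#' m <- buildS1(s1Config(4, 8, 7, dropout = 0.2), inputLength = 500)
#' countParameters(m)  # 1441
#' @export
buildS1 <- function(config, inputLength = 500L, seed = 1L) {
  stopifnot(methods::is(config, "S1Config"),
            !methods::is(config, "S2Config"))
  buildNet(config, inputLength, "s1", seed)
}

#' @rdname buildS1
#' @export
buildS2 <- function(config, inputLength = 500L, seed = 1L) {
  stopifnot(methods::is(config, "S2Config"))
  buildNet(config, inputLength, "s2", seed)
}

setMethod("show", "PulseNet", function(object) {
  cfg <- object@config
  cat(sprintf("PulseNet %s: lambda=%d M=%d L=%d alpha=%.2f",
              toupper(object@arch), cfg@nBlocks, cfg@nKernels,
              cfg@kernelLength, cfg@dropout))
  if (object@arch == "s2") cat(sprintf(" theta=%d", cfg@gruUnits))
  cat("\n  input length:", object@inputLength,
      "(min", paste0(object@minLength, ")"),
      "| parameters:", countParameters(object),
      "|", if (length(object@history)) "trained" else "untrained", "\n")
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "PulseNet", function(object, ...) {
  sum(vapply(object@params, length, integer(1)))
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "S1Config", function(object, ...) {
  countParametersClosedForm(object)
})

#' Closed-form trainable-parameter count
#'
#' For S1: `M(L + 1) + (lambda - 1) M(ML + 1) + (M + 1)` (first conv, deeper
#' convs, dense unit). For S2 the dense and pooling terms are replaced by
#' the bidirectional GRU, `2 * 3(M theta + theta^2 + theta)`, plus a dense
#' unit over `2 theta` features. One bias per convolution kernel and one
#' bias vector per GRU gate.
#'
#' @param config an [S1Config-class] or [S2Config-class].
#' @return integer parameter count.
#' @export
countParametersClosedForm <- function(config) {
  M <- config@nKernels; L <- config@kernelLength; lam <- config@nBlocks
  conv <- M * (L + 1) + (lam - 1) * M * (M * L + 1)
  n <- if (methods::is(config, "S2Config")) {
    th <- config@gruUnits
    conv + 2 * 3 * (M * th + th^2 + th) + (2 * th + 1)
  } else {
    conv + (M + 1)
  }
  as.integer(n)
}

# Full network forward pass on a batch. x: N x B matrix (single channel).
# Dropout is active when training or mcDropout; caches are collected when
# withCache. Uses the current RNG stream for dropout masks.
forwardNet <- function(model, x, training = FALSE, mcDropout = FALSE,
                       withCache = FALSE) {
  cfg <- model@config
  stochastic <- training || mcDropout
  alpha <- if (stochastic) cfg@dropout else 0
  N <- nrow(x); B <- ncol(x)
  if (N < model@minLength)
    stop("input of ", N, " samples is shorter than the model minimum of ",
         model@minLength)
  a <- matrix(as.vector(x), N * B, 1L)   # flat (N*B) x C layout, n fastest
  caches <- list()
  for (i in seq_len(cfg@nBlocks)) {
    cv <- convForwardBatch(a, N, B, model@params[[paste0("conv", i, ".W")]],
                           model@params[[paste0("conv", i, ".b")]],
                           withCache = withCache)
    pl <- maxPoolBatch(cv$y, cv$Nout, B, cfg@poolSize,
                       withCache = withCache)
    N <- pl$Np
    mask <- if (stochastic) dropoutMask(nrow(pl$y), ncol(pl$y), alpha)
            else NULL
    a <- if (is.null(mask)) pl$y else pl$y * mask
    if (withCache) caches[[i]] <- list(conv = cv, pool = pl, mask = mask)
  }
  if (model@arch == "s1") {
    gmp <- globalMaxPoolBatch(a, N, B)
    v <- gmp$v
    topCache <- list(gmp = gmp)
  } else {
    theta <- cfg@gruUnits
    recMask <- if (stochastic && cfg@recurrentDropout > 0)
      list(f = dropoutMask(theta, B, cfg@recurrentDropout),
           b = dropoutMask(theta, B, cfg@recurrentDropout))
    else list(f = NULL, b = NULL)
    gf <- gruForwardBatch(a, N, B, gruParamSet(model@params, "gruF"),
                          backward = FALSE, recMask = recMask$f)
    gb <- gruForwardBatch(a, N, B, gruParamSet(model@params, "gruB"),
                          backward = TRUE, recMask = recMask$b)
    v <- rbind(gf$h, gb$h)
    topCache <- list(gf = gf, gb = gb)
  }
  vMask <- if (stochastic) dropoutMask(nrow(v), ncol(v), alpha) else NULL
  vd <- if (is.null(vMask)) v else v * vMask
  w <- model@params[["dense.w"]]
  score <- colSums(vd * w) + model@params[["dense.b"]]
  p <- clampProb(sigmoid(score), 1e-12)
  if (!withCache) return(list(p = p, v = v))
  topCache$vMask <- vMask
  topCache$vd <- vd
  list(p = p, v = v, blocks = caches, top = topCache, x = x)
}

gruParamSet <- function(params, prefix) {
  nm <- c("Wz", "Wr", "Wh", "Uz", "Ur", "Uh", "bz", "br", "bh")
  stats::setNames(lapply(nm, function(k) params[[paste0(prefix, ".", k)]]), nm)
}

# Backward pass; dscore is dLoss/dscore per batch element (length B).
# Returns gradients as a flat named list matching model@params.
backwardNet <- function(model, fwd, dscore) {
  cfg <- model@config
  grads <- list()
  vd <- fwd$top$vd
  grads[["dense.w"]] <- as.numeric(vd %*% dscore)
  grads[["dense.b"]] <- sum(dscore)
  dv <- outer(model@params[["dense.w"]], dscore)
  if (!is.null(fwd$top$vMask)) dv <- dv * fwd$top$vMask
  if (model@arch == "s1") {
    da <- globalMaxPoolBackwardBatch(fwd$top$gmp, dv)
  } else {
    theta <- cfg@gruUnits
    bf <- gruBackwardBatch(fwd$top$gf, gruParamSet(model@params, "gruF"),
                           dv[seq_len(theta), , drop = FALSE])
    bb <- gruBackwardBatch(fwd$top$gb, gruParamSet(model@params, "gruB"),
                           dv[theta + seq_len(theta), , drop = FALSE])
    for (nm in names(bf$grads)) {
      grads[[paste0("gruF.", nm)]] <- bf$grads[[nm]]
      grads[[paste0("gruB.", nm)]] <- bb$grads[[nm]]
    }
    da <- bf$dx + bb$dx
  }
  for (i in rev(seq_len(cfg@nBlocks))) {
    blk <- fwd$blocks[[i]]
    if (!is.null(blk$mask)) da <- da * blk$mask
    da <- maxPoolBackwardBatch(blk$pool, da)
    cb <- convBackwardBatch(blk$conv, model@params[[paste0("conv", i, ".W")]],
                            da)
    grads[[paste0("conv", i, ".W")]] <- cb$dW
    grads[[paste0("conv", i, ".b")]] <- cb$db
    da <- cb$dx
  }
  grads
}

#' Classify processed ECG segments
#'
#' Runs the network on preprocessed (100 Hz) segments and returns the PR
#' likelihood and the hard label (PR when `p_pr >= 0.5`). With dropout
#' disabled (the default) the prediction is a deterministic function of the
#' input.
#'
#' @param model a [PulseNet-class].
#' @param x numeric vector, `N x B` matrix, or [EcgSegmentSet-class] of
#'   processed signals (any length `>= minLength`).
#' @param dropout if `TRUE`, dropout stays active (stochastic forward pass;
#'   used by Monte-Carlo uncertainty estimation).
#' @param seed optional seed for the stochastic mode.
#' @return data.frame with columns `p_pr` and `label`.
#' @export
predictPulse <- function(model, x, dropout = FALSE, seed = NULL) {
  x <- asSignalMatrix(x)
  res <- withSeed(seed, forwardNet(model, x, mcDropout = dropout))
  data.frame(
    p_pr = res$p,
    label = factor(ifelse(res$p >= 0.5, "PR", "PEA"), levels = RHYTHM_LEVELS)
  )
}

#' Network-derived feature vectors
#'
#' Deterministic features the trained networks feed to their classification
#' layer: the global-max-pooled channel maxima for S1 (`M` values) or the
#' concatenated bidirectional GRU states for S2 (`2 * theta` values). These
#' can be used as inputs to the classical classifiers.
#'
#' @param model a [PulseNet-class].
#' @param x processed signals (vector, matrix or [EcgSegmentSet-class]).
#' @return matrix, one row per segment.
#' @export
dnnFeatures <- function(model, x) {
  x <- asSignalMatrix(x)
  t(forwardNet(model, x)$v)
}

asSignalMatrix <- function(x) {
  if (methods::is(x, "EcgSegmentSet")) return(ecgSignals(x))
  if (is.matrix(x)) x else matrix(x, ncol = 1)
}

#' Model serialization
#'
#' Writes/reads a [PulseNet-class] as a self-describing JSON container
#' holding the architecture, configuration, and named parameter arrays.
#'
#' @param model a [PulseNet-class].
#' @param path file path.
#' @return `readPulseNet` returns the reconstructed [PulseNet-class].
#' @export
writePulseNet <- function(model, path) {
  cfg <- model@config
  cfgList <- list(nBlocks = cfg@nBlocks, nKernels = cfg@nKernels,
                  kernelLength = cfg@kernelLength, dropout = cfg@dropout,
                  poolSize = cfg@poolSize, maxNorm = cfg@maxNorm)
  if (model@arch == "s2") {
    cfgList$gruUnits <- cfg@gruUnits
    cfgList$recurrentDropout <- cfg@recurrentDropout
  }
  obj <- list(
    arch = model@arch, config = cfgList,
    inputLength = model@inputLength, history = model@history,
    params = lapply(model@params, function(p)
      list(dim = dim(p) %||% length(p), data = as.numeric(p)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname writePulseNet
#' @export
readPulseNet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- obj$config
  cfg <- if (identical(obj$arch, "s2")) {
    s2Config(cl$nBlocks, cl$nKernels, cl$kernelLength, cl$gruUnits,
             dropout = cl$dropout, poolSize = cl$poolSize,
             maxNorm = cl$maxNorm, recurrentDropout = cl$recurrentDropout)
  } else {
    s1Config(cl$nBlocks, cl$nKernels, cl$kernelLength, dropout = cl$dropout,
             poolSize = cl$poolSize, maxNorm = cl$maxNorm)
  }
  params <- lapply(obj$params, function(p) {
    d <- as.integer(p$dim)
    if (length(d) > 1) array(as.numeric(p$data), d) else as.numeric(p$data)
  })
  methods::new("PulseNet", arch = obj$arch, config = cfg,
               inputLength = as.integer(obj$inputLength),
               minLength = minInputLength(cfg), params = params,
               history = as.numeric(obj$history))
}
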