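# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. If seed is NULL the current stream is used
# (and advanced), which lets outer routines own determinism.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Numerically stable logistic function.
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

clampProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Rhythm labels are stored as a factor with fixed level order; PR is the
# positive class (y = 1) throughout.
RHYTHM_LEVELS <- c("PEA", "PR")

asRhythmFactor <- function(label) {
  f <- factor(as.character(label), levels = RHYTHM_LEVELS)
  if (anyNA(f)) stop("labels must be 'PR' or 'PEA'")
  f
}

labelToBinary <- function(label) as.integer(as.character(label) == "PR")
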