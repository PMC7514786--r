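# Hand-crafted ECG features. The nine features cover the classical PR/PEA
# contrast domains: QRS rate and narrowness, slope steepness, spectral
# energy distribution, and signal regularity. Formulas follow standard
# definitions from the ECG rhythm-analysis literature; they are
# reimplementations in spirit, not bit-exact replicas of any specific
# published feature set.

#' Simple threshold beat detector
#'
#' Detects QRS complexes as local maxima of the rectified signal above a
#' fraction of its peak amplitude, with a refractory period. Intended for
#' the band-limited 100-Hz network input; returns an empty vector on flat
#' signals.
#'
#' @param s numeric signal.
#' @param fs sampling frequency in Hz.
#' @param thresholdFrac detection threshold as a fraction of the maximum
#'   rectified amplitude.
#' @param refractoryS minimum spacing between detected beats (seconds).
#' @return integer sample indices of detected beats.
#' @export
detectBeats <- function(s, fs = 100, thresholdFrac = 0.5,
                        refractoryS = 0.25) {
  a <- abs(s - median(s))
  if (max(a) <= 0) return(integer(0))
  thr <- thresholdFrac * max(a)
  n <- length(a)
  isPeak <- c(FALSE, a[2:(n - 1)] >= a[1:(n - 2)] &
                a[2:(n - 1)] > a[3:n], FALSE) & a > thr
  cand <- which(isPeak)
  if (length(cand) == 0) return(integer(0))
  ref <- round(refractoryS * fs)
  keep <- cand[1]
  for (k in cand[-1]) {
    if (k - keep[length(keep)] >= ref) keep <- c(keep, k)
    else if (a[k] > a[keep[length(keep)]]) keep[length(keep)] <- k
  }
  keep
}

# Fuzzy entropy with embedding dimension m and tolerance r (defaults r =
# 0.2 * SD): templates are locally demeaned, similarity is a Gaussian
# membership exp(-(d/r)^2) of the Chebyshev distance, and the entropy is
# ln(phi_m) - ln(phi_{m+1}). Scale-invariant because r tracks the SD.
fuzzyEntropy <- function(s, m = 2L, rFrac = 0.2) {
  r <- rFrac * sd(s)
  if (!is.finite(r) || r <= 0) return(0)
  phi <- function(mm) {
    n <- length(s) - mm
    emb <- sapply(seq_len(mm), function(j) s[(j - 1) + seq_len(n)])
    emb <- emb - rowMeans(emb)
    dmax <- matrix(0, n, n)
    for (j in seq_len(mm)) {
      dj <- abs(outer(emb[, j], emb[, j], "-"))
      dmax <- pmax(dmax, dj)
    }
    sim <- exp(-(dmax / r)^2)
    (sum(sim) - n) / (n * (n - 1))
  }
  p1 <- phi(m)
  p2 <- phi(m + 1L)
  if (p1 <= 0 || p2 <= 0) return(0)
  log(p1) - log(p2)
}

#' Hand-crafted ECG feature vector
#'
#' Nine deterministic features of a processed (100-Hz) segment:
#' \enumerate{
#'   \item QRS rate (bpm) from detected beats;
#'   \item QRS narrowness: median width (ms) at half the per-beat peak;
#'   \item slope steepness: mean absolute first difference (amplitude/s);
#'   \item–6. spectral energy fractions in 0.5–4, 4–12 and 12–30 Hz
#'     (relative to total 0.5–30 Hz power);
#'   \item fuzzy entropy (m = 2, r = 0.2 SD);
#'   \item RR-interval coefficient of variation;
#'   \item normalized RMSSD of RR intervals.
#' }
#' Flat (zero-variance) signals return defined fallbacks (rate 0,
#' entropy 0) rather than failing.
#'
#' @param s numeric signal (>= 2 s of samples), or a matrix /
#'   [EcgSegmentSet-class] (one feature row per segment).
#' @param fs sampling frequency in Hz.
#' @return numeric vector of length 9 (or a matrix, segments x 9).
#' @export
extractFeatures <- function(s, fs = 100) {
  if (methods::is(s, "EcgSegmentSet")) {
    fs <- samplingRate(s)
    s <- ecgSignals(s)
  }
  if (is.matrix(s)) {
    out <- t(apply(s, 2, extractFeatures, fs = fs))
    colnames(out) <- c("rate_bpm", "qrs_width_ms", "slope", "band_lo",
                       "band_mid", "band_hi", "fuzzy_en", "rr_cv",
                       "rr_rmssd")
    return(out)
  }
  if (length(s) < 2 * fs) stop("signal must be at least 2 s long")
  beats <- detectBeats(s, fs)
  dur <- length(s) / fs

  rate <- if (length(beats) >= 2) {
    60 * (length(beats) - 1) / ((beats[length(beats)] - beats[1]) / fs)
  } else 60 * length(beats) / dur

  width <- if (length(beats) >= 1) {
    a <- abs(s - median(s))
    w <- vapply(beats, function(b) {
      half <- a[b] / 2
      lo <- b; while (lo > 1 && a[lo - 1] >= half) lo <- lo - 1
      hi <- b; while (hi < length(a) && a[hi + 1] >= half) hi <- hi + 1
      (hi - lo + 1) / fs * 1000
    }, numeric(1))
    median(w)
  } else 0

  slope <- mean(abs(diff(s))) * fs

  pw <- Mod(fft(s - mean(s)))^2
  freq <- (seq_along(pw) - 1) * fs / length(pw)
  half <- freq <= fs / 2
  pw <- pw[half]; freq <- freq[half]
  total <- sum(pw[freq >= 0.5 & freq <= 30])
  bandFrac <- function(lo, hi) {
    if (total <= 0) return(0)
    sum(pw[freq >= lo & freq < hi]) / total
  }

  rr <- diff(beats) / fs
  rrCv <- if (length(rr) >= 2 && mean(rr) > 0) sd(rr) / mean(rr) else 0
  rmssd <- if (length(rr) >= 3 && mean(rr) > 0)
    sqrt(mean(diff(rr)^2)) / mean(rr) else 0

  c(rate_bpm = rate, qrs_width_ms = width, slope = slope,
    band_lo = bandFrac(0.5, 4), band_mid = bandFrac(4, 12),
    band_hi = bandFrac(12, 30), fuzzy_en = fuzzyEntropy(s),
    rr_cv = rrCv, rr_rmssd = rmssd)
}

#' Gaussian (RBF) kernel
#'
#' `K(v, vi) = exp(-gammaS * ||v - vi||^2)`.
#'
#' @param v,vi numeric vectors of equal length.
#' @param gammaS positive kernel width parameter.
#' @return kernel value in (0, 1].
#' @export
gaussianKernel <- function(v, vi, gammaS) {
  if (length(v) != length(vi)) stop("dimension mismatch")
  if (gammaS <= 0) stop("gammaS must be positive")
  exp(-gammaS * sum((v - vi)^2))
}
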