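#' Band-pass filter ECG segments
#'
#' Zero-phase Butterworth band-pass over the typical AED bandwidth. A
#' 4th-order filter (a 2nd-order `signal::butter` design applied
#' forward-backward with `signal::filtfilt`) is used so QRS morphology is
#' not distorted by phase.
#'
#' @param x numeric vector, samples-x-segments matrix, or
#'   [EcgSegmentSet-class].
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   `0 < lowHz < highHz < fs/2`.
#' @param fs sampling frequency in Hz (taken from the object for an
#'   `EcgSegmentSet`).
#' @return same shape as the input, filtered.
#' @export
bandpassFilter <- function(x, lowHz = 0.5, highHz = 30, fs = 250) {
  if (methods::is(x, "EcgSegmentSet")) {
    fs <- samplingRate(x)
    out <- x
    SummarizedExperiment::assay(out, "ecg") <-
      bandpassFilter(ecgSignals(x), lowHz, highHz, fs)
    return(out)
  }
  if (!(lowHz > 0 && lowHz < highHz && highHz < fs / 2))
    stop("band edges must satisfy 0 < lowHz < highHz < fs/2")
  bf <- signal::butter(2, c(lowHz, highHz) / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    return(apply(x, 2, function(col) signal::filtfilt(bf, col)))
  }
  if (length(x) == 0) stop("empty input")
  signal::filtfilt(bf, x)
}

# Polyphase rational resampler (upsample by p, FIR anti-alias low-pass,
# downsample by q). Edge transients are reduced by replicating the end
# samples before filtering. DC gain is normalized exactly.
resampleRational <- function(x, p, q) {
  n <- length(x)
  if (n == 0) stop("empty input")
  ord <- 10L * max(p, q) * 2L
  h <- as.numeric(signal::fir1(ord, 1 / max(p, q)))
  h <- p * h / sum(h)
  delay <- ord %/% 2L
  pad <- ceiling(delay / p) + 5L
  xe <- c(rep(x[1], pad), x, rep(x[n], pad))
  up <- numeric(length(xe) * p)
  up[seq(1, length(up), by = p)] <- xe
  yf <- stats::filter(up, h, method = "convolution", sides = 1)
  yf[is.na(yf)] <- 0
  m <- ceiling(n * p / q)
  idx <- pad * p + (seq_len(m) - 1L) * q + 1L + delay
  as.numeric(yf[idx])
}

#' Resample filtered ECG to 100 Hz
#'
#' Rational polyphase resampling from 250 Hz to 100 Hz (upsample by 2,
#' anti-alias FIR low-pass, downsample by 5). A 5-s segment (1250 samples)
#' maps to exactly 500 samples.
#'
#' @param x numeric vector, matrix (samples x segments), or
#'   [EcgSegmentSet-class] at 250 Hz.
#' @param fs input sampling frequency; must be 250.
#' @return same container type at 100 Hz with `round(n * 100 / 250)` samples.
#' @export
resampleTo100Hz <- function(x, fs = 250) {
  if (methods::is(x, "EcgSegmentSet")) {
    if (samplingRate(x) != 250) stop("input must be sampled at 250 Hz")
    sig <- resampleTo100Hz(ecgSignals(x), fs = 250)
    return(EcgSegmentSet(sig, patientIds(x),
                         as.character(segmentLabels(x)), fs = 100))
  }
  if (fs != 250) stop("input must be sampled at 250 Hz")
  if (is.matrix(x)) {
    if (nrow(x) == 0) stop("empty input")
    return(apply(x, 2, resampleRational, p = 2L, q = 5L))
  }
  resampleRational(x, 2L, 5L)
}

#' Truncate a processed signal to its first seconds
#'
#' Keeps the first `floor(seconds * fs)` samples, the protocol used when
#' evaluating models trained on 5-s inputs with shorter segment durations.
#'
#' @param x numeric vector, matrix (samples x segments), or
#'   [EcgSegmentSet-class].
#' @param seconds duration to keep.
#' @param fs sampling frequency (default 100 Hz, the network input rate).
#' @return truncated object of the same type.
#' @export
truncateSignal <- function(x, seconds, fs = 100) {
  if (methods::is(x, "EcgSegmentSet")) {
    fs <- samplingRate(x)
    k <- floor(seconds * fs)
    if (k > nrow(x)) stop("seconds exceeds the signal duration")
    return(x[seq_len(k), ])
  }
  n <- if (is.matrix(x)) nrow(x) else length(x)
  k <- floor(seconds * fs)
  if (k > n) stop("seconds exceeds the signal duration")
  if (is.matrix(x)) x[seq_len(k), , drop = FALSE] else x[seq_len(k)]
}

#' Full preprocessing pipeline
#'
#' Band-pass (0.5-30 Hz by default) then resample to 100 Hz: the mapping
#' from a raw 250-Hz segment to the network input `s[n]` (N = 500 samples
#' for a 5-s segment).
#'
#' @param x an [EcgSegmentSet-class] at 250 Hz.
#' @param lowHz,highHz band edges in Hz.
#' @return an [EcgSegmentSet-class] at 100 Hz.
#' @examples
#' d <- generateDataset(2, 2, seed = 1)
#' p <- preprocessSegments(d)
#' nrow(p)  # 500
#' @export
preprocessSegments <- function(x, lowHz = 0.5, highHz = 30) {
  resampleTo100Hz(bandpassFilter(x, lowHz, highHz))
}
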