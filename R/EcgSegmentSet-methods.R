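#' Construct an EcgSegmentSet
#'
#' @param signals numeric matrix, one segment per column (rows are samples),
#'   amplitudes in mV for raw segments.
#' @param patientId character vector, one entry per segment.
#' @param label PR/PEA label per segment (character or factor).
#' @param fs sampling frequency in Hz.
#' @return an [EcgSegmentSet-class].
#' @examples
#' x <- EcgSegmentSet(matrix(rnorm(2500), 1250, 2),
#'                    patientId = c("p1", "p1"), label = c("PR", "PR"))
#' nSegments(x)
#' @export
EcgSegmentSet <- function(signals, patientId, label, fs = 250) {
  signals <- as.matrix(signals)
  if (ncol(signals) != length(patientId) || ncol(signals) != length(label))
    stop("patientId and label must have one entry per segment (column)")
  cd <- S4Vectors::DataFrame(
    patient_id = as.character(patientId),
    label = asRhythmFactor(label)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ecg = unname(signals)),
    colData = cd,
    metadata = list(fs = fs)
  )
  methods::new("EcgSegmentSet", se)
}

#' @rdname pulsegate-generics
#' @export
setMethod("ecgSignals", "EcgSegmentSet", function(x)
  SummarizedExperiment::assay(x, "ecg"))

#' @rdname pulsegate-generics
#' @export
setMethod("patientIds", "EcgSegmentSet", function(x)
  as.character(SummarizedExperiment::colData(x)$patient_id))

#' @rdname pulsegate-generics
#' @export
setMethod("segmentLabels", "EcgSegmentSet", function(x)
  asRhythmFactor(SummarizedExperiment::colData(x)$label))

#' @rdname pulsegate-generics
#' @export
setMethod("samplingRate", "EcgSegmentSet", function(x)
  S4Vectors::metadata(x)$fs)

#' @rdname pulsegate-generics
#' @export
setMethod("nSegments", "EcgSegmentSet", function(x) ncol(x))

setMethod("show", "EcgSegmentSet", function(object) {
  pid <- patientIds(object)
  lab <- segmentLabels(object)
  cat("EcgSegmentSet:", ncol(object), "segments x", nrow(object),
      "samples @", samplingRate(object), "Hz\n")
  cat("  patients:", length(unique(pid)), "\n")
  cat("  labels:  PR", sum(lab == "PR"), "/ PEA", sum(lab == "PEA"), "\n")
})

#' Split a segment set patient-wise
#'
#' Partitions the patients (never the segments of one patient) into two
#' disjoint sets. Splitting is stratified by patient label so both parts see
#' both classes whenever possible.
#'
#' @param x an [EcgSegmentSet-class].
#' @param fraction fraction of patients assigned to the first part.
#' @param seed integer seed controlling the patient shuffle.
#' @return list with elements `train` and `test` (both `EcgSegmentSet`).
#' @export
splitByPatient <- function(x, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  pid <- patientIds(x)
  lab <- segmentLabels(x)
  pats <- unique(pid)
  patLab <- lab[match(pats, pid)]
  trainPats <- withSeed(seed, {
    unlist(lapply(split(pats, patLab), function(p) {
      p <- sample(p)
      head(p, max(1L, round(fraction * length(p))))
    }), use.names = FALSE)
  })
  inTrain <- pid %in% trainPats
  list(train = x[, inTrain], test = x[, !inTrain])
}

#' Read / write segment tables
#'
#' Plain-text serialization of an [EcgSegmentSet-class]: one row per
#' segment with columns `patient_id`, `label`, `fs`, then the sample values
#' `s1`, `s2`, ...
#'
#' @param x an [EcgSegmentSet-class].
#' @param path file path.
#' @return `readSegmentCsv` returns an [EcgSegmentSet-class];
#'   `writeSegmentCsv` invisibly returns `path`.
#' @export
writeSegmentCsv <- function(x, path) {
  sig <- t(ecgSignals(x))
  colnames(sig) <- paste0("s", seq_len(ncol(sig)))
  dt <- data.table::data.table(
    patient_id = patientIds(x),
    label = as.character(segmentLabels(x)),
    fs = samplingRate(x)
  )
  data.table::fwrite(cbind(dt, data.table::as.data.table(sig)), path)
  invisible(path)
}

#' @rdname writeSegmentCsv
#' @export
readSegmentCsv <- function(path) {
  dt <- data.table::fread(path)
  sampleCols <- grep("^s[0-9]+$", names(dt), value = TRUE)
  sampleCols <- sampleCols[order(as.integer(sub("^s", "", sampleCols)))]
  EcgSegmentSet(
    t(as.matrix(dt[, sampleCols, with = FALSE])),
    patientId = dt$patient_id,
    label = dt$label,
    fs = dt$fs[1]
  )
}
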