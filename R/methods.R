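#' @describeIn TrialTensor number of trials
#' @param x,object a `TrialTensor`
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @export
setMethod("nTrials", "TrialTensor", function(x) dim(x@data)[1])

#' @describeIn TrialTensor number of channels
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setMethod("nChannels", "TrialTensor", function(x) dim(x@data)[2])

#' @describeIn TrialTensor samples per trial
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setMethod("nSamples", "TrialTensor", function(x) dim(x@data)[3])

#' @describeIn TrialTensor sampling rate in Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setMethod("samplingRate", "TrialTensor", function(x) x@fs)

#' @describeIn TrialTensor the underlying trials x channels x samples array
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))
#' @export
setMethod("trialData", "TrialTensor", function(x) x@data)

#' Per-trial class labels
#' @param x a `TrialTensor` or `PairedDataset`
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @export
setMethod("trialLabels", "TrialTensor", function(x) x@labels)
#' @export
setMethod("trialLabels", "PairedDataset", function(x) x@labels)

#' Extract a single trial as a channels x samples matrix
#' @param x a `TrialTensor`
#' @param i trial index
#' @export
getTrial <- function(x, i) {
  stopifnot(is(x, "TrialTensor"), i >= 1, i <= nTrials(x))
  m <- x@data[i, , , drop = FALSE]
  dim(m) <- dim(x@data)[2:3]
  m
}

#' Subset a TrialTensor by trial index
#' @param x a `TrialTensor`
#' @param idx trial indices to keep
#' @export
subsetTrials <- function(x, idx) {
  TrialTensor(x@data[idx, , , drop = FALSE], x@fs,
              if (length(x@labels)) x@labels[idx] else character(0),
              x@channelNames)
}

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@data)
  cat("TrialTensor:", d[1], "trials x", d[2], "channels x", d[3], "samples @",
      object@fs, "Hz\n")
  if (length(object@labels))
    cat("  classes:", paste(sprintf("%s (%d)", names(table(object@labels)),
                                    table(object@labels)), collapse = ", "), "\n")
})

setMethod("show", "FilterBankSpec", function(object) {
  be <- object@bandEdges
  cat("FilterBankSpec: ", nrow(be), " band(s), order-", object@filterOrder,
      " ", object@design, if (object@zeroPhase) " (zero-phase)" else "", "\n", sep = "")
  cat("  ", paste(sprintf("[%.3g, %.3g]", be[, 1], be[, 2]), collapse = " "), "\n")
})

setMethod("show", "SpatialFilterModel", function(object) {
  cat("SpatialFilterModel:", ncol(object@W), "spatial filters; positive class '",
      object@classOrder[1], "'\n", sep = "")
  cat("  eigvalsPos:", paste(sprintf("%.3f", object@eigvalsPos), collapse = " "), "\n")
})

setMethod("show", "FBCSPModel", function(object) {
  cat("FBCSPModel:", length(object@perBand), "bands x", object@nChannels,
      "channels, Nf =", object@nPairs, "\n")
  cat("  classes: +", object@classOrder[1], " / -", object@classOrder[2], "\n")
  cat("  feature width at Nf:", length(object@perBand) * 2 * object@nPairs, "\n")
})

setMethod("show", "EnvelopeSignal", function(object) {
  cat("EnvelopeSignal (", object@side, "): ", length(object@velocity),
      " frames @ ", round(object@frameRate, 2), " Hz, ",
      sum(object@flagged), " flagged\n", sep = "")
})

setMethod("show", "EvidenceModel", function(object) {
  cat("EvidenceModel [", object@modality, ", ", object@backend, "]: ",
      length(object@weights), " features; +", object@classOrder[1], "\n", sep = "")
})

setMethod("show", "ClassConditionalDensity", function(object) {
  cat("ClassConditionalDensity '", object@classTag, "': n = ",
      length(object@supportPoints), ", h = ", signif(object@bandwidth, 4), "\n", sep = "")
})

setMethod("show", "FusionModel", function(object) {
  cat("FusionModel: alpha =", object@alpha, "(EEG weight); classes +",
      object@classOrder[1], "/ -", object@classOrder[2], "\n")
})

setMethod("show", "PairedDataset", function(object) {
  cat("PairedDataset:", length(object@labels), "paired trials\n")
  cat("  EEG : "); show(object@eeg)
  cat("  fTCD: "); show(object@ftcdRaw)
})

setMethod("show", "CVReport", function(object) {
  cat("CVReport (", object@mode, " mode, ", object@nFolds, " folds, seed ",
      object@seed, ")\n", sep = "")
  cat("  problem:", paste(object@problem, collapse = " vs "), "\n")
  cat(sprintf("  EEG-only : %6.2f%% +/- %.2f\n", object@meanAccuracy["eeg"],
              object@stdAccuracy["eeg"]))
  cat(sprintf("  fTCD-only: %6.2f%% +/- %.2f\n", object@meanAccuracy["ftcd"],
              object@stdAccuracy["ftcd"]))
  cat(sprintf("  Fused    : %6.2f%% +/- %.2f  (alpha = %.2f, Nf = %d)\n",
              object@meanAccuracy["fused"], object@stdAccuracy["fused"],
              object@bestAlpha, as.integer(object@bestNPairs)))
})
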