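#' TrialTensor: a labeled set of multichannel trials for one modality
#'
#' Container for a `trials x channels x samples` real array together with its
#' sampling rate, optional per-trial class labels and channel names. This is
#' the common currency of both the EEG (filter bank + CSP) and the fTCD
#' (raw Doppler) processing paths.
#'
#' @slot data three-dimensional numeric array, `trials x channels x samples`.
#' @slot fs sampling rate in Hz.
#' @slot labels character vector of per-trial class tags (may be empty when
#'   the tensor is unlabeled, e.g. at transform time).
#' @slot channelNames character vector, one name per channel.
#'
#' @export
setClass("TrialTensor",
  representation(data = "array", fs = "numeric",
                 labels = "character", channelNames = "character"),
  prototype(labels = character(0), channelNames = character(0)))

setValidity("TrialTensor", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("'data' must be a 3-D array (trials x channels x samples)")
  if (dim(d)[2] < 2L) return("at least 2 channels required")
  if (anyNA(d) || any(!is.finite(d))) return("'data' contains NaN/Inf")
  if (length(object@fs) != 1L || object@fs <= 0) return("'fs' must be a single positive number")
  if (length(object@labels) && length(object@labels) != dim(d)[1])
    return("'labels' length must equal trial count")
  if (length(object@channelNames) && length(object@channelNames) != dim(d)[2])
    return("'channelNames' length must equal channel count")
  TRUE
})

#' Construct a TrialTensor
#'
#' @param data `trials x channels x samples` numeric array.
#' @param fs sampling rate (Hz).
#' @param labels optional per-trial class tags.
#' @param channelNames optional channel names.
#' @return A [TrialTensor-class] object.
#' @examples
#' tt <- TrialTensor(array(rnorm(2 * 4 * 64), c(2, 4, 64)), fs = 32)
#' nTrials(tt)
#' @export
TrialTensor <- function(data, fs, labels = character(0), channelNames = character(0)) {
  new("TrialTensor", data = data, fs = as.numeric(fs),
      labels = as.character(labels), channelNames = as.character(channelNames))
}

#' FilterBankSpec: non-overlapping band-pass bank definition
#'
#' @slot bandEdges `n_bands x 2` matrix of (low, high) edges in Hz.
#' @slot filterOrder Butterworth order of each band-pass.
#' @slot design filter family tag (only `"butterworth"`).
#' @slot zeroPhase logical; bands are applied with zero phase.
#' @export
setClass("FilterBankSpec",
  representation(bandEdges = "matrix", filterOrder = "numeric",
                 design = "character", zeroPhase = "logical"),
  prototype(filterOrder = 4, design = "butterworth", zeroPhase = TRUE))

setValidity("FilterBankSpec", function(object) {
  be <- object@bandEdges
  if (ncol(be) != 2L || nrow(be) < 1L) return("'bandEdges' must be an n x 2 matrix")
  if (any(be <= 0)) return("band edges must be positive")
  if (any(be[, 2] <= be[, 1])) return("each band needs high > low")
  if (nrow(be) > 1L) {
    if (any(diff(be[, 1]) <= 0)) return("bands must be strictly increasing")
    if (any(be[-nrow(be), 2] > be[-1L, 1] + 1e-9)) return("bands must not overlap")
  }
  if (!identical(object@design, "butterworth")) return("only 'butterworth' design supported")
  TRUE
})

#' SpatialFilterModel: one-band CSP solution
#'
#' Columns of `W` are the spatial filters w_j; `eigvalsPos[j] = w_j' S+ w_j`
#' is the fraction of (whitened) variance the j-th filter assigns to the
#' positive class, so eigvalsPos + eigvalsNeg = 1 filter-wise.
#'
#' @slot W `channels x channels` spatial filter matrix (columns = filters),
#'   ordered by decreasing positive-class eigenvalue.
#' @slot eigvalsPos per-filter positive-class eigenvalues, descending in [0,1].
#' @slot classOrder length-2 character: (positive tag, negative tag).
#' @export
setClass("SpatialFilterModel",
  representation(W = "matrix", eigvalsPos = "numeric", classOrder = "character"))

setValidity("SpatialFilterModel", function(object) {
  if (ncol(object@W) != length(object@eigvalsPos))
    return("one eigenvalue per filter column required")
  ev <- object@eigvalsPos
  if (any(ev < -1e-8 | ev > 1 + 1e-8)) return("eigvalsPos must lie in [0,1]")
  if (is.unsorted(rev(ev), strictly = FALSE)) return("eigvalsPos must be sorted descending")
  if (length(object@classOrder) != 2L) return("'classOrder' must name (positive, negative) class")
  TRUE
})

#' FBCSPModel: filter-bank CSP model (one CSP solution per band)
#'
#' @slot bank the [FilterBankSpec-class] used at fit time.
#' @slot perBand list of [SpatialFilterModel-class], one per band.
#' @slot nPairs default number of eigenvector pairs retained per end.
#' @slot nChannels channel count seen at fit time.
#' @slot classOrder (positive tag, negative tag).
#' @export
setClass("FBCSPModel",
  representation(bank = "FilterBankSpec", perBand = "list", nPairs = "numeric",
                 nChannels = "numeric", classOrder = "character"))

setValidity("FBCSPModel", function(object) {
  if (length(object@perBand) != nrow(object@bank@bandEdges))
    return("one SpatialFilterModel per band required")
  if (!all(vapply(object@perBand, is, logical(1), "SpatialFilterModel")))
    return("'perBand' must hold SpatialFilterModel objects")
  np <- object@nPairs
  if (np < 1 || 2 * np > object@nChannels) return("need 1 <= nPairs <= channels/2")
  TRUE
})

#' EnvelopeSignal: maximal blood-flow-velocity time series
#'
#' @slot velocity velocity per STFT frame (cm/s).
#' @slot frameRate frames per second.
#' @slot side transducer side, `"left"` or `"right"`.
#' @slot flagged logical per frame; TRUE where total frame power fell below
#'   the global noise floor and the trace was set to 0.
#' @export
setClass("EnvelopeSignal",
  representation(velocity = "numeric", frameRate = "numeric",
                 side = "character", flagged = "logical"))

setValidity("EnvelopeSignal", function(object) {
  if (any(!is.finite(object@velocity))) return("velocity must be finite")
  if (length(object@flagged) != length(object@velocity))
    return("'flagged' must align with 'velocity'")
  if (!object@side %in% c("left", "right")) return("side must be 'left' or 'right'")
  TRUE
})

#' EvidenceModel: per-modality linear projector to a scalar score
#'
#' score(x) = weights . (x - center)/scale + bias. Fitted on standardized
#' training features; positive scores favor the positive class.
#'
#' @slot weights per-feature weights (on the standardized scale).
#' @slot bias intercept.
#' @slot center,scale standardizer fitted on training data.
#' @slot modality `"EEG"` or `"fTCD"`.
#' @slot backend `"svm"` (L2-regularized squared-hinge) or `"lda"`.
#' @slot classOrder (positive tag, negative tag).
#' @export
setClass("EvidenceModel",
  representation(weights = "numeric", bias = "numeric", center = "numeric",
                 scale = "numeric", modality = "character",
                 backend = "character", classOrder = "character"))

setValidity("EvidenceModel", function(object) {
  if (any(!is.finite(object@weights)) || !is.finite(object@bias))
    return("weights/bias must be finite")
  if (length(object@center) != length(object@weights) ||
      length(object@scale) != length(object@weights))
    return("standardizer must align with weights")
  if (!object@modality %in% c("EEG", "fTCD")) return("modality must be 'EEG' or 'fTCD'")
  TRUE
})

#' ClassConditionalDensity: Gaussian-kernel score density for one class
#'
#' @slot supportPoints training scores of one class.
#' @slot bandwidth Scott's-rule bandwidth, > 0.
#' @slot classTag class label.
#' @export
setClass("ClassConditionalDensity",
  representation(supportPoints = "numeric", bandwidth = "numeric", classTag = "character"))

setValidity("ClassConditionalDensity", function(object) {
  if (length(object@supportPoints) < 2L) return("need >= 2 support points")
  if (!is.finite(object@bandwidth) || object@bandwidth <= 0) return("bandwidth must be > 0")
  TRUE
})

#' FusionModel: class-conditional score densities and modality weight
#'
#' Holds the two per-class KDEs per modality, the EEG weighting exponent
#' alpha (fTCD gets 1 - alpha) and the class prior.
#'
#' @slot eegDensities,ftcdDensities named lists of two
#'   [ClassConditionalDensity-class] objects (positive class first).
#' @slot alpha EEG weight in [0, 1].
#' @slot prior per-class prior probabilities, summing to 1.
#' @slot classOrder (positive tag, negative tag).
#' @export
setClass("FusionModel",
  representation(eegDensities = "list", ftcdDensities = "list",
                 alpha = "numeric", prior = "numeric", classOrder = "character"))

setValidity("FusionModel", function(object) {
  if (object@alpha < 0 || object@alpha > 1) return("alpha must lie in [0,1]")
  if (abs(sum(object@prior) - 1) > 1e-9) return("priors must sum to 1")
  for (dl in list(object@eegDensities, object@ftcdDensities)) {
    if (length(dl) != 2L) return("two class densities required per modality")
    if (!all(vapply(dl, is, logical(1), "ClassConditionalDensity")))
      return("densities must be ClassConditionalDensity objects")
  }
  TRUE
})

#' PairedDataset: aligned EEG and raw-Doppler trial sets
#'
#' @slot eeg EEG [TrialTensor-class].
#' @slot ftcdRaw two-channel raw Doppler [TrialTensor-class].
#' @slot labels shared per-trial class tags (exactly two classes for a
#'   binary problem).
#' @slot truth list recording the generating parameters (synthetic data) or
#'   acquisition metadata.
#' @export
setClass("PairedDataset",
  representation(eeg = "TrialTensor", ftcdRaw = "TrialTensor",
                 labels = "character", truth = "list"))

setValidity("PairedDataset", function(object) {
  ne <- dim(object@eeg@data)[1]; nf <- dim(object@ftcdRaw@data)[1]
  if (ne != nf) return("EEG and fTCD trial counts differ")
  if (length(object@labels) != ne) return("'labels' must align with trials")
  if (dim(object@ftcdRaw@data)[2] != 2L) return("fTCD raw tensor must have 2 channels")
  TRUE
})

#' CVReport: cross-validated accuracy report
#'
#' Accuracies are percentages. `eegOnly`/`ftcdOnly` are the single-modality
#' density-comparison accuracies (the alpha = 1 / alpha = 0 limits of the
#' fused rule, so the fusion-limit identities hold exactly); the per-fold
#' table also carries direct SVM-sign accuracies for comparison.
#'
#' @slot perFold data.frame with one row per fold.
#' @slot meanAccuracy,stdAccuracy named numeric: eeg, ftcd, fused.
#' @slot bestAlpha,bestNPairs selected hyper-parameters.
#' @slot alphaCurve data.frame (alpha, accuracy) at the best nPairs.
#' @slot nFolds,seed integers; @slot mode "nested" or "posthoc".
#' @slot problem class pair analyzed.
#' @slot fits list of per-fold fitted models (only when requested).
#' @export
setClass("CVReport",
  representation(perFold = "data.frame", meanAccuracy = "numeric",
                 stdAccuracy = "numeric", bestAlpha = "numeric",
                 bestNPairs = "numeric", alphaCurve = "data.frame",
                 nFolds = "numeric", seed = "numeric", mode = "character",
                 problem = "character", fits = "list"),
  prototype(fits = list()))

setValidity("CVReport", function(object) {
  acc <- c(object@meanAccuracy, object@perFold$fused)
  if (any(acc < -1e-9 | acc > 100 + 1e-9)) return("accuracies must lie in [0,100]%")
  if (nrow(object@perFold) != object@nFolds) return("fold rows must match nFolds")
  if (!object@mode %in% c("nested", "posthoc")) return("mode must be 'nested' or 'posthoc'")
  TRUE
})
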