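# Cross-validated evaluation of the multimodal pipeline.
#
# Within each fold, everything that learns from data — fTCD rank-sum
# feature screening, both evidence projectors, the per-band CSP filters and
# the class-conditional KDEs — is fitted on the training trials only.
# Hyper-parameter selection (the eigenvector-pair count Nf and the modality
# weight alpha) is either nested inside the training folds (default,
# leakage-free) or performed post hoc over the pooled cross-validated
# decisions ("posthoc" mode, replicating the optimistic maximum-accuracy
# reporting style).

#' Stratified fold assignment
#'
#' @param labels per-trial class tags.
#' @param nFolds requested fold count; reduced with a warning when the
#'   smallest class has fewer trials.
#' @param seed shuffle seed.
#' @return Integer fold id per trial.
#' @export
stratifiedFolds <- function(labels, nFolds = 10, seed = 0) {
  n <- length(labels)
  if (n < 4) stop("need at least 4 trials for cross-validation", call. = FALSE)
  minClass <- min(table(labels))
  if (minClass < nFolds) {
    nFolds <- max(2L, minClass)
    warning("fold count reduced to ", nFolds,
            " (smallest class has ", minClass, " trials)", call. = FALSE)
  }
  folds <- integer(n)
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}

#' Envelope feature matrix of a raw Doppler trial tensor
#'
#' Runs [envelopeFromRaw()] and [extractEnvelopeFeatures()] on every trial
#' of a two-channel tensor. Trial-wise and label-free, so it can be
#' computed once before cross-validation without leakage.
#'
#' @param ftcd two-channel [TrialTensor-class].
#' @param params,stft,relThreshold,smoothFrames see [envelopeFromRaw()].
#' @param catalogue feature catalogue version.
#' @return `trials x features` matrix with feature names.
#' @export
computeEnvelopeFeatures <- function(ftcd, params = dopplerParams(),
                                    stft = stftParams(), relThreshold = 0.1,
                                    smoothFrames = 5, catalogue = "v1") {
  nt <- nTrials(ftcd)
  rows <- lapply(seq_len(nt), function(i) {
    env <- envelopeFromRaw(getTrial(ftcd, i), samplingRate(ftcd), params,
                           stft, relThreshold, smoothFrames)
    extractEnvelopeFeatures(env, catalogue)
  })
  do.call(rbind, rows)
}

# Per-fold score computation shared by both modes. Returns, for the given
# train/test split, the test-trial class-conditional log densities per Nf
# plus raw scores and the fitted models.
foldEvidence <- function(scatter, ftcdFeat, labels, trainIdx, testIdx,
                         bank, nPairsGrid, classOrder, nc, nSamp,
                         selectionAlpha, regularization, backend) {
  sel <- withCallingHandlers(
    ranksumSelect(ftcdFeat[trainIdx, , drop = FALSE], labels[trainIdx],
                  selectionAlpha),
    warning = function(w) invokeRestart("muffleWarning"))
  ff <- ftcdFeat[, sel$selected, drop = FALSE]
  fProj <- fitEvidenceProjector(ff[trainIdx, , drop = FALSE], labels[trainIdx],
                                regularization, "fTCD", backend, classOrder)
  fTrain <- projectEvidence(fProj, ff[trainIdx, , drop = FALSE])
  fTest <- projectEvidence(fProj, ff[testIdx, , drop = FALSE])
  fbw <- poolBandwidth(fTrain)
  fDensPos <- fitClassDensity(fTrain[labels[trainIdx] == classOrder[1]],
                              classOrder[1], fbw)
  fDensNeg <- fitClassDensity(fTrain[labels[trainIdx] == classOrder[2]],
                              classOrder[2], fbw)

  fbcsp <- fbcspFitFromScatter(scatter, labels, bank, max(nPairsGrid),
                               classOrder, nc, trainIdx = trainIdx)
  perNf <- lapply(nPairsGrid, function(np) {
    xTr <- fbcspTransformFromScatter(scatter, fbcsp, np, nSamp, trainIdx)
    xTe <- fbcspTransformFromScatter(scatter, fbcsp, np, nSamp, testIdx)
    eProj <- fitEvidenceProjector(xTr, labels[trainIdx], regularization,
                                  "EEG", backend, classOrder)
    eTrain <- projectEvidence(eProj, xTr)
    eTest <- projectEvidence(eProj, xTe)
    ebw <- poolBandwidth(eTrain)
    ePos <- fitClassDensity(eTrain[labels[trainIdx] == classOrder[1]],
                            classOrder[1], ebw)
    eNeg <- fitClassDensity(eTrain[labels[trainIdx] == classOrder[2]],
                            classOrder[2], ebw)
    list(lePos = logKde(ePos, eTest), leNeg = logKde(eNeg, eTest),
         svmAcc = mean(ifelse(eTest >= 0, classOrder[1], classOrder[2]) ==
                       labels[testIdx]),
         proj = eProj, densPos = ePos, densNeg = eNeg)
  })
  list(perNf = perNf,
       lfPos = logKde(fDensPos, fTest), lfNeg = logKde(fDensNeg, fTest),
       ftcdSvmAcc = mean(ifelse(fTest >= 0, classOrder[1], classOrder[2]) ==
                         labels[testIdx]),
       ftcdSel = sel, ftcdProj = fProj, fbcsp = fbcsp,
       fDensPos = fDensPos, fDensNeg = fDensNeg)
}

#' Cross-validated multimodal evaluation
#'
#' Runs stratified k-fold cross-validation of the full pipeline on a paired
#' dataset: per fold, fTCD envelope features are screened by rank-sum test
#' and projected to scores, EEG trials are FBCSP-transformed and projected
#' to scores, class-conditional KDEs are fitted on the training scores, and
#' test trials are decided by the alpha-weighted fused likelihood. The
#' eigenvector-pair count Nf and alpha are selected by nested inner
#' cross-validation (`mode = "nested"`) or post hoc over the pooled
#' cross-validated decisions (`mode = "posthoc"`). EEG-only and fTCD-only
#' accuracies are the alpha = 1 and alpha = 0 limits of the same decision
#' rule; direct SVM-sign accuracies are reported alongside in the per-fold
#' table.
#'
#' @param dataset a [PairedDataset-class] with exactly two classes.
#' @param nFolds fold count (default 10; reduced with a warning when a
#'   class is smaller).
#' @param nPairsGrid Nf values swept (default 1..8, clipped to channels/2).
#' @param alphaStep alpha grid step (default 0.01).
#' @param mode `"nested"` (leakage-free, default) or `"posthoc"`.
#' @param selectionAlpha rank-sum screening level (default 0.05).
#' @param regularization,backend evidence projector settings.
#' @param bank EEG [FilterBankSpec-class] (default 2-60 Hz, 9 bands).
#' @param doppler,stft,relThreshold,smoothFrames envelope settings.
#' @param seed fold-shuffle seed (default 0).
#' @param folds optional explicit fold assignment (overrides `nFolds`).
#' @param innerFolds inner fold count for nested selection (default 3).
#' @param keepModels store per-fold fitted models in the report.
#' @return A [CVReport-class].
#' @export
runCrossValidation <- function(dataset, nFolds = 10, nPairsGrid = 1:8,
                               alphaStep = 0.01, mode = c("nested", "posthoc"),
                               selectionAlpha = 0.05, regularization = 1.0,
                               backend = "svm",
                               bank = buildFilterBank(2, 60, 9, 6.5),
                               doppler = dopplerParams(),
                               stft = stftParams(), relThreshold = 0.1,
                               smoothFrames = 5, seed = 0, folds = NULL,
                               innerFolds = 3, keepModels = FALSE) {
  mode <- match.arg(mode)
  labels <- trialLabels(dataset)
  classOrder <- sort(stopIfNot2Classes(labels))
  nc <- nChannels(dataset@eeg)
  nSamp <- nSamples(dataset@eeg)
  nPairsGrid <- nPairsGrid[2 * nPairsGrid <= nc]
  if (!length(nPairsGrid)) stop("no feasible Nf in grid", call. = FALSE)
  if (is.null(folds)) folds <- stratifiedFolds(labels, nFolds, seed)
  nFolds <- max(folds)
  alphas <- seq(0, 1, by = alphaStep)

  scatter <- bandScatterMatrices(dataset@eeg, bank)
  ftcdFeat <- computeEnvelopeFeatures(dataset@ftcdRaw, doppler, stft,
                                      relThreshold, smoothFrames)

  foldRes <- lapply(seq_len(nFolds), function(f) {
    trainIdx <- which(folds != f); testIdx <- which(folds == f)
    ev <- foldEvidence(scatter, ftcdFeat, labels, trainIdx, testIdx, bank,
                       nPairsGrid, classOrder, nc, nSamp, selectionAlpha,
                       regularization, backend)
    if (mode == "nested") {
      inner <- innerSelect(scatter, ftcdFeat, labels, trainIdx, bank,
                           nPairsGrid, classOrder, nc, nSamp, selectionAlpha,
                           regularization, backend, alphas, innerFolds, seed + f)
      ev$nfStar <- inner$nf; ev$alphaStar <- inner$alpha
      ev$nfStarEEG <- inner$nfEEG
    }
    ev$testIdx <- testIdx
    ev
  })

  truthPerFold <- lapply(foldRes, function(ev) labels[ev$testIdx])
  accAt <- function(ev, nfPos, alpha) {
    pn <- ev$perNf[[nfPos]]
    lr <- fusedLogRatio(pn$lePos, pn$leNeg, ev$lfPos, ev$lfNeg, alpha)
    ifelse(lr >= 0, classOrder[1], classOrder[2])
  }

  if (mode == "posthoc") {
    # pooled accuracy per (Nf, alpha) over all cross-validated decisions
    truthAll <- unlist(truthPerFold)
    accGrid <- sapply(seq_along(nPairsGrid), function(j) {
      vapply(alphas, function(a) {
        mean(unlist(lapply(foldRes, accAt, nfPos = j, alpha = a)) == truthAll)
      }, numeric(1))
    })                                        # alphas x Nf
    bestJ <- which.max(apply(accGrid, 2, max))
    bestA <- which.max(accGrid[, bestJ])      # first max = smallest alpha
    nfStar <- nPairsGrid[bestJ]; alphaStar <- alphas[bestA]
    eegJ <- which.max(accGrid[length(alphas), ])   # alpha = 1 row
    nfEEG <- nPairsGrid[eegJ]
    perFoldNf <- rep(bestJ, nFolds); perFoldAlpha <- rep(alphaStar, nFolds)
    perFoldNfEEG <- rep(eegJ, nFolds)
    alphaCurve <- data.frame(alpha = alphas, accuracy = accGrid[, bestJ])
  } else {
    perFoldNf <- vapply(foldRes, function(ev) match(ev$nfStar, nPairsGrid), integer(1))
    perFoldAlpha <- vapply(foldRes, function(ev) ev$alphaStar, numeric(1))
    perFoldNfEEG <- vapply(foldRes, function(ev) match(ev$nfStarEEG, nPairsGrid), integer(1))
    nfStar <- round(median(nPairsGrid[perFoldNf]))
    alphaStar <- median(perFoldAlpha)
    truthAll <- unlist(truthPerFold)
    alphaCurve <- data.frame(alpha = alphas, accuracy = vapply(alphas, function(a) {
      mean(unlist(lapply(seq_len(nFolds), function(f)
        accAt(foldRes[[f]], perFoldNf[f], a))) == truthAll)
    }, numeric(1)))
  }

  perFold <- do.call(rbind, lapply(seq_len(nFolds), function(f) {
    ev <- foldRes[[f]]; truth <- truthPerFold[[f]]
    data.frame(
      fold = f,
      eeg = 100 * mean(accAt(ev, perFoldNfEEG[f], 1) == truth),
      ftcd = 100 * mean(accAt(ev, perFoldNf[f], 0) == truth),
      fused = 100 * mean(accAt(ev, perFoldNf[f], perFoldAlpha[f]) == truth),
      eegSvm = 100 * ev$perNf[[perFoldNfEEG[f]]]$svmAcc,
      ftcdSvm = 100 * ev$ftcdSvmAcc,
      nPairs = nPairsGrid[perFoldNf[f]],
      alpha = perFoldAlpha[f],
      ftcdFallback = ev$ftcdSel$fallback)
  }))

  mAcc <- c(eeg = mean(perFold$eeg), ftcd = mean(perFold$ftcd),
            fused = mean(perFold$fused))
  sAcc <- c(eeg = sd(perFold$eeg), ftcd = sd(perFold$ftcd),
            fused = sd(perFold$fused))
  fits <- if (keepModels) lapply(foldRes, function(ev)
    list(fbcsp = ev$fbcsp, ftcdSel = ev$ftcdSel, ftcdProj = ev$ftcdProj,
         eegProj = lapply(ev$perNf, `[[`, "proj"),
         densities = list(f = list(ev$fDensPos, ev$fDensNeg),
                          e = lapply(ev$perNf, function(p)
                            list(p$densPos, p$densNeg))))) else list()
  new("CVReport", perFold = perFold, meanAccuracy = mAcc, stdAccuracy = sAcc,
      bestAlpha = alphaStar, bestNPairs = nfStar, alphaCurve = alphaCurve,
      nFolds = nFolds, seed = seed, mode = mode, problem = classOrder,
      fits = fits)
}

# Inner hyper-parameter selection on the training trials only: pooled
# inner-CV accuracy per (Nf, alpha); ties resolved toward the smallest
# alpha, then the smallest Nf.
innerSelect <- function(scatter, ftcdFeat, labels, trainIdx, bank, nPairsGrid,
                        classOrder, nc, nSamp, selectionAlpha, regularization,
                        backend, alphas, innerFolds, seed) {
  innerLab <- labels[trainIdx]
  folds <- suppressWarnings(stratifiedFolds(innerLab, innerFolds, seed))
  nf <- max(folds)
  res <- lapply(seq_len(nf), function(f) {
    tr <- trainIdx[folds != f]; va <- trainIdx[folds == f]
    ev <- foldEvidence(scatter, ftcdFeat, labels, tr, va, bank, nPairsGrid,
                       classOrder, nc, nSamp, selectionAlpha, regularization,
                       backend)
    ev$truth <- labels[va]
    ev
  })
  truthAll <- unlist(lapply(res, `[[`, "truth"))
  accGrid <- sapply(seq_along(nPairsGrid), function(j) {
    vapply(alphas, function(a) {
      pred <- unlist(lapply(res, function(ev) {
        pn <- ev$perNf[[j]]
        lr <- fusedLogRatio(pn$lePos, pn$leNeg, ev$lfPos, ev$lfNeg, a)
        ifelse(lr >= 0, classOrder[1], classOrder[2])
      }))
      mean(pred == truthAll)
    }, numeric(1))
  })
  bestJ <- which.max(apply(accGrid, 2, max))
  bestA <- which.max(accGrid[, bestJ])
  list(nf = nPairsGrid[bestJ], alpha = alphas[bestA],
       nfEEG = nPairsGrid[which.max(accGrid[length(alphas), ])])
}
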