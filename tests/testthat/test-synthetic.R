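test_that("generators are bit-identical under a repeated seed", {
  cfg <- eegSimConfig(nTrialsPerClass = 2, trialLen = 1, seed = 20)
  expect_identical(trialData(generateEEGTrials(cfg)),
                   trialData(generateEEGTrials(cfg)))
  fcfg <- ftcdSimConfig(nTrialsPerClass = 1, trialLen = 1, seed = 20)
  expect_identical(trialData(generateFTCDTrials(fcfg)),
                   trialData(generateFTCDTrials(fcfg)))
  # the generators leave the caller's RNG stream untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generateEEGTrials(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("EEG generator emits the configured shape and class structure", {
  cfg <- eegSimConfig(nTrialsPerClass = 3, nChannels = 8, fs = 128,
                      trialLen = 2, seed = 21)
  tt <- generateEEGTrials(cfg)
  expect_equal(nTrials(tt), 9)      # three classes
  expect_equal(nChannels(tt), 8)
  expect_equal(nSamples(tt), 256)
  expect_setequal(unique(trialLabels(tt)), c("mr", "wg", "baseline"))
  # MRWG classes carry their SSVEP line: band power at 7 Hz dominates for
  # 'mr' relative to 'baseline' trials
  bp <- function(i, lo, hi) {
    x <- bcifuse:::fftBandpass(t(getTrial(tt, i)), 128, lo, hi)
    mean(x^2)
  }
  mrIdx <- which(trialLabels(tt) == "mr")
  blIdx <- which(trialLabels(tt) == "baseline")
  expect_gt(mean(sapply(mrIdx, bp, 6, 8)), mean(sapply(blIdx, bp, 6, 8)))
  # configuration errors
  expect_error(eegSimConfig(nChannels = 1), "2 channels")
  expect_error(eegSimConfig(fs = 30, paradigm = "MI"), "stimulated band")
  expect_error(eegSimConfig(snrDb = Inf), "finite")
  badMix <- matrix(0, 16, 4)
  expect_error(eegSimConfig(mixingMatrix = badMix), "singular")
})

test_that("fTCD generator respects Nyquist and records recoverable truth", {
  expect_error(ftcdSimConfig(baseVelocity = 400), "Nyquist")
  expect_error(ftcdSimConfig(heartRate = 4), "heartRate")
  expect_error(ftcdSimConfig(baseVelocity = -1), "positive")
  cfg <- ftcdSimConfig(nTrialsPerClass = 1, trialLen = 2, seed = 22)
  tt <- generateFTCDTrials(cfg)
  expect_equal(dim(trialData(tt))[2], 2)
  truth <- attr(tt, "truth")
  v <- trueVelocity(truth, 1, "left", seq(0, 1, by = 0.001))
  expect_true(all(v > 0))
  expect_equal(max(v),
               unname(cfg$baseVelocity * (1 + cfg$pulsatility) +
                      cfg$classVelocityOffsets[truth$classes[1], 1]),
               tolerance = 0.01)
})

test_that("paired dataset aligns labels and restricts to the problem", {
  ds <- sepDataset()
  expect_s4_class(ds, "PairedDataset")
  expect_setequal(unique(trialLabels(ds)), c("mr", "baseline"))
  expect_equal(nTrials(ds@eeg), nTrials(ds@ftcdRaw))
  expect_identical(trialLabels(ds@eeg), trialLabels(ds@ftcdRaw))
  expect_error(generatePairedDataset(
    eegSimConfig(nTrialsPerClass = 2), ftcdSimConfig(nTrialsPerClass = 3),
    c("mr", "baseline")), "mismatched")
  expect_error(generatePairedDataset(
    eegSimConfig(nTrialsPerClass = 2, trialLen = 1),
    ftcdSimConfig(nTrialsPerClass = 2, trialLen = 1),
    c("mr", "nope")), "absent")
})

test_that("uninformative gains give chance-level FBCSP accuracy", {
  # no class information by construction: CV accuracy within the binomial
  # 95% interval of 0.5
  cfg <- eegSimConfig(nTrialsPerClass = 20, snrDb = 20, seed = 23,
    classBandGains = rbind(mr = c(1, 1, 1, 1), baseline = c(1, 1, 1, 1)))
  tt <- generateEEGTrials(cfg)
  bank <- buildFilterBank(2, 60, 9, 6.5)
  folds <- stratifiedFolds(trialLabels(tt), 5, seed = 23)
  preds <- character(nTrials(tt))
  scatter <- bcifuse:::bandScatterMatrices(tt, bank)
  for (f in 1:5) {
    tr <- which(folds != f); te <- which(folds == f)
    m <- bcifuse:::fbcspFitFromScatter(scatter, trialLabels(tt), bank, 2,
                                       c("baseline", "mr"), 16, trainIdx = tr)
    xtr <- bcifuse:::fbcspTransformFromScatter(scatter, m, 2, nSamples(tt), tr)
    xte <- bcifuse:::fbcspTransformFromScatter(scatter, m, 2, nSamples(tt), te)
    proj <- fitEvidenceProjector(xtr, trialLabels(tt)[tr],
                                 classOrder = c("baseline", "mr"))
    preds[te] <- ifelse(projectEvidence(proj, xte) >= 0, "baseline", "mr")
  }
  acc <- mean(preds == trialLabels(tt))
  n <- nTrials(tt)
  halfWidth <- 1.96 * sqrt(0.25 / n)
  expect_gte(acc, 0.5 - halfWidth)
  expect_lte(acc, 0.5 + halfWidth)
})

test_that("informative gains give high pipeline accuracy (4:1, 20 dB)", {
  ds <- sepDataset()
  rep <- runCrossValidation(ds, nFolds = 5, nPairsGrid = 2, mode = "posthoc")
  expect_gt(rep@meanAccuracy[["fused"]] / 100, 0.9)
  expect_gt(rep@meanAccuracy[["eeg"]] / 100, 0.9)
})

test_that("lateralized velocity offsets surface in rank-sum screening", {
  # +/- 8 cm/s between classes: the mean-velocity feature is selected with
  # p < 0.001 (oracle: the true mean velocities differ by construction)
  ds <- sepDataset()
  feats <- fixture("sepFeats", computeEnvelopeFeatures(ds@ftcdRaw))
  sel <- ranksumSelect(feats, trialLabels(ds), alpha = 0.05)
  # the mr class carries the +8 cm/s offset on the right probe only
  meanIdx <- which(colnames(feats) == "right_mean")
  expect_lt(sel$pvalues[meanIdx], 0.001)
  expect_true(meanIdx %in% sel$selected)
})

test_that("null envelope features keep the nominal selection rate", {
  # zero offsets: replicate-level check of the p < 0.05 selection rate
  # (features within a replicate are correlated, so the interval uses the
  # replicate-to-replicate standard error)
  rates <- vapply(1:6, function(r) {
    cfg <- ftcdSimConfig(nTrialsPerClass = 15, trialLen = 2, seed = 300 + r,
      classVelocityOffsets = rbind(mr = c(0, 0), baseline = c(0, 0)))
    tt <- generateFTCDTrials(cfg)
    feats <- computeEnvelopeFeatures(tt)
    suppressWarnings(
      mean(ranksumSelect(feats, trialLabels(tt))$pvalues < 0.05))
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.05), max(3 * se, 0.05))
})

test_that("fused accuracy is not worse than single modalities minus one SE", {
  # both modalities informative and independent (reduced replicate count)
  reps <- lapply(1:3, function(r) {
    ds <- generatePairedDataset(
      eegSimConfig(nTrialsPerClass = 14, snrDb = 0, seed = 400 + r),
      ftcdSimConfig(nTrialsPerClass = 14, trialLen = 2, seed = 400 + r),
      c("mr", "baseline"))
    runCrossValidation(ds, nFolds = 4, nPairsGrid = 2, mode = "posthoc")
  })
  fused <- vapply(reps, function(r) r@meanAccuracy[["fused"]], numeric(1))
  eeg <- vapply(reps, function(r) r@meanAccuracy[["eeg"]], numeric(1))
  ftcd <- vapply(reps, function(r) r@meanAccuracy[["ftcd"]], numeric(1))
  seM <- function(x) sd(x) / sqrt(length(x))
  expect_gte(mean(fused), mean(eeg) - max(seM(eeg), 1e-9))
  expect_gte(mean(fused), mean(ftcd) - max(seM(ftcd), 1e-9))
})
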