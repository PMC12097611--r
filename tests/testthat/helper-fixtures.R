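# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# random symmetric positive-definite matrix
randomSPD <- function(n) {
  a <- matrix(rnorm(n * (n + 2)), n + 2, n)
  crossprod(a) / (n + 2)
}

# independent CSP oracle: symmetric inverse-square-root whitening of the
# sum, then symmetric eigendecomposition of the whitened positive-class
# covariance (a different factorization than the implementation's Cholesky
# route)
cspOracleEigvals <- function(sp, sn) {
  s <- sp + sn
  es <- eigen(s, symmetric = TRUE)
  p <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  sort(eigen(p %*% sp %*% p, symmetric = TRUE)$values, decreasing = TRUE)
}

# small separable MRWG paired dataset (shared across test files)
sepDataset <- function() fixture("sepDataset", {
  generatePairedDataset(
    eegSimConfig(nTrialsPerClass = 20, snrDb = 20, seed = 3),
    ftcdSimConfig(nTrialsPerClass = 20, trialLen = 3, seed = 3),
    c("mr", "baseline"))
})

# paired Gaussian-feature world for evidence/fusion tests: n trials per
# class per split, class shift d on the first 3 of p features per modality
pairedFeatureWorld <- function(n, nv, pE, pF, dE, dF) {
  mk <- function(m, p, d) {
    y <- rep(c("a", "b"), each = m)
    x <- matrix(rnorm(2 * m * p), 2 * m)
    if (d > 0) x[y == "a", 1:3] <- x[y == "a", 1:3] + d
    list(x = x, y = y)
  }
  tE <- mk(n, pE, dE); tF <- mk(n, pF, dF)
  vE <- mk(nv, pE, dE); vF <- mk(nv, pF, dF)
  list(xeTrain = tE$x, xfTrain = tF$x, yTrain = tE$y,
       xeVal = vE$x, xfVal = vF$x, yVal = vE$y)
}

# one replicate of the informativeness-ratio sweep: the same noise
# realization is shared across all ratio levels (common random numbers), so
# the level ordering of recovered alpha is not scrambled by independent
# draws; only the class shifts differ between levels
alphaSweepOnce <- function(ratios, n = 80, nv = 150, p = 20, dBase = 0.8) {
  mkBase <- function(m) list(y = rep(c("a", "b"), each = m),
                             xe = matrix(rnorm(2 * m * p), 2 * m),
                             xf = matrix(rnorm(2 * m * p), 2 * m))
  tr <- mkBase(n); va <- mkBase(nv)
  shift <- function(base, d, y) {
    x <- base; x[y == "a", 1:3] <- x[y == "a", 1:3] + d; x
  }
  vapply(ratios, function(r) {
    dE <- dBase * sqrt(r); dF <- dBase / sqrt(r)
    w <- list(xeTrain = shift(tr$xe, dE, tr$y),
              xfTrain = shift(tr$xf, dF, tr$y), yTrain = tr$y,
              xeVal = shift(va$xe, dE, va$y),
              xfVal = shift(va$xf, dF, va$y), yVal = va$y)
    alphaSearchOnWorld(w)$bestAlpha
  }, numeric(1))
}

# fit projectors on the world and return the alpha grid search result
alphaSearchOnWorld <- function(w) {
  pe <- fitEvidenceProjector(w$xeTrain, w$yTrain)
  pf <- fitEvidenceProjector(w$xfTrain, w$yTrain, modality = "fTCD")
  alphaGridSearch(projectEvidence(pe, w$xeTrain),
                  projectEvidence(pf, w$xfTrain), w$yTrain,
                  projectEvidence(pe, w$xeVal),
                  projectEvidence(pf, w$xfVal), w$yVal)
}
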