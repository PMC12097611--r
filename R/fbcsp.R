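# Filter-bank common spatial patterns.
#
# Per band, CSP simultaneously diagonalizes the two class-mean covariance
# matrices: find W with W' S(+) W = L(+), W' S(-) W = L(-), L(+) + L(-) = I,
# equivalent to the generalized eigenproblem S(+) w = lambda S(-) w. The
# implementation whitens with the Cholesky factor of S(+) + S(-) and takes a
# symmetric eigendecomposition of the whitened positive-class covariance;
# eigenvalues are the positive-class variance fractions lambda(+), and
# W' (S(+) + S(-)) W = I holds by construction, including for degenerate
# (repeated-eigenvalue) pencils.

#' Normalized covariance of one trial
#'
#' `C = E E' / trace(E E')` for a `channels x samples` trial matrix `E`.
#' The normalization makes `C` scale-invariant with trace exactly 1.
#'
#' @param trial `channels x samples` numeric matrix.
#' @return Symmetric PSD matrix with unit trace.
#' @examples
#' trialCovariance(rbind(c(1, 1), c(1, -1)))
#' @export
trialCovariance <- function(trial) {
  trial <- as.matrix(trial)
  s <- tcrossprod(trial)
  tr <- sum(diag(s))
  if (tr <= 0) stop("all-zero trial: trace(EE') = 0", call. = FALSE)
  c <- s / tr
  (c + t(c)) / 2
}

#' Class-mean covariance
#'
#' Arithmetic mean of the per-trial normalized covariances of all trials
#' carrying `classTag`.
#'
#' @param trials a [TrialTensor-class] with labels.
#' @param labels per-trial class tags (defaults to the tensor's labels).
#' @param classTag class whose trials are averaged.
#' @return Symmetric PSD matrix with unit trace.
#' @export
classMeanCovariance <- function(trials, labels = trialLabels(trials), classTag) {
  idx <- which(labels == classTag)
  if (!length(idx)) stop("class '", classTag, "' absent from labels", call. = FALSE)
  acc <- 0
  for (i in idx) acc <- acc + trialCovariance(getTrial(trials, i))
  acc / length(idx)
}

regularizeCov <- function(s, gamma = 1e-6) {
  n <- nrow(s)
  (1 - gamma) * s + gamma * (sum(diag(s)) / n) * diag(n)
}

#' Fit CSP spatial filters from two class covariances
#'
#' Solves the simultaneous diagonalization of `sigmaPos` and `sigmaNeg`
#' under the constraint `W' (sigmaPos + sigmaNeg) W = I`. Columns of `W` are
#' ordered by decreasing positive-class eigenvalue `lambda(+)`; each
#' `lambda(+) + lambda(-) = 1`. Column signs are fixed so the
#' largest-magnitude entry of each filter is positive; equal eigenvalues
#' keep their original (stable) order.
#'
#' @param sigmaPos,sigmaNeg symmetric PSD class covariance matrices.
#' @param classOrder length-2 character, (positive tag, negative tag).
#' @param gamma shrinkage weight of the identity regularizer applied to each
#'   covariance before the eigensolve when their sum is numerically rank
#'   deficient (default 1e-6; well-conditioned problems are solved
#'   unregularized).
#' @return A [SpatialFilterModel-class].
#' @examples
#' m <- fitCSP(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)))
#' m@eigvalsPos  # 0.8, 0.2
#' @export
fitCSP <- function(sigmaPos, sigmaNeg, classOrder = c("pos", "neg"), gamma = 1e-6) {
  sigmaPos <- as.matrix(sigmaPos); sigmaNeg <- as.matrix(sigmaNeg)
  if (!isTRUE(all.equal(sigmaPos, t(sigmaPos), tolerance = 1e-8)) ||
      !isTRUE(all.equal(sigmaNeg, t(sigmaNeg), tolerance = 1e-8)))
    stop("class covariances must be symmetric", call. = FALSE)
  if (!all(dim(sigmaPos) == dim(sigmaNeg)))
    stop("covariance dimensions differ", call. = FALSE)
  sp <- (sigmaPos + t(sigmaPos)) / 2
  sn <- (sigmaNeg + t(sigmaNeg)) / 2
  s <- sp + sn
  # regularize lazily: shrinkage is only applied when the sum covariance is
  # numerically rank deficient, so well-conditioned problems keep the
  # whitening identity at machine precision
  ch <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(ch) || kappa(s, exact = FALSE) > 1e10) {
    sp <- regularizeCov(sp, gamma)
    sn <- regularizeCov(sn, gamma)
    s <- sp + sn
    ch <- tryCatch(chol(s), error = function(e) NULL)
    if (is.null(ch))
      stop("sum of class covariances is rank deficient after regularization",
           call. = FALSE)
  }
  # whiten: B = L^-T' Sp L^-1-style symmetric reduction via the Cholesky factor
  li <- backsolve(ch, diag(nrow(s)))          # inv(U) with s = U'U
  b <- crossprod(li, sp %*% li)               # inv(U)' Sp inv(U), symmetric
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lam <- pmin(pmax(e$values, 0), 1)           # clip fp noise into [0,1]
  w <- li %*% e$vectors                       # w' (Sp+Sn) w = I exactly
  # deterministic sign: largest-magnitude entry of each filter positive
  for (j in seq_len(ncol(w))) {
    k <- which.max(abs(w[, j]))
    if (w[k, j] < 0) w[, j] <- -w[, j]
  }
  new("SpatialFilterModel", W = w, eigvalsPos = lam,
      classOrder = as.character(classOrder))
}

#' Log-variance CSP features of one trial
#'
#' Projects the trial onto the `nPairs` filters with the largest and the
#' `nPairs` filters with the smallest positive-class eigenvalues and returns
#' the log of the power (mean square) of each projected series, top filters
#' first. Band-passed signals are zero-mean, so power equals variance.
#'
#' @param trial `channels x samples` matrix.
#' @param model a [SpatialFilterModel-class].
#' @param nPairs eigenvector pairs retained per end (`2*nPairs <= channels`).
#' @return Numeric vector of length `2*nPairs`.
#' @export
cspLogVariance <- function(trial, model, nPairs) {
  w <- selectCSPFilters(model, nPairs)
  v <- rowMeans((t(w) %*% trial)^2)
  if (any(v <= 0) || any(!is.finite(v)))
    stop("non-positive projected variance (constant signal?)", call. = FALSE)
  log(v)
}

selectCSPFilters <- function(model, nPairs) {
  n <- ncol(model@W)
  if (2 * nPairs > n)
    stop("need 2*nPairs <= channels (", n, ")", call. = FALSE)
  model@W[, c(seq_len(nPairs), seq.int(n - nPairs + 1, n)), drop = FALSE]
}

#' Fit a filter-bank CSP model
#'
#' Band-passes the trials through every band of `bank` and fits one CSP
#' solution per band on the class-mean covariances of the training labels.
#'
#' @param trials labeled [TrialTensor-class] with exactly two classes.
#' @param bank a [FilterBankSpec-class].
#' @param nPairs default eigenvector pairs per end retained at transform.
#' @param labels per-trial class tags (defaults to the tensor's labels).
#' @param classOrder optional (positive, negative) tag pair; default is the
#'   sorted unique labels.
#' @param gamma covariance regularizer, see [fitCSP()].
#' @return An [FBCSPModel-class].
#' @export
fbcspFit <- function(trials, bank, nPairs = 2, labels = trialLabels(trials),
                     classOrder = NULL, gamma = 1e-6) {
  cls <- stopIfNot2Classes(labels)
  if (is.null(classOrder)) classOrder <- sort(cls)
  covs <- bandScatterMatrices(trials, bank)
  fbcspFitFromScatter(covs, labels, bank, nPairs, classOrder,
                      nChannels(trials), gamma)
}

# Per-band per-trial scatter matrices S_i = E E' (unnormalized), cached once
# so that cross-validation folds and the Nf sweep avoid re-filtering.
# Returns list(bands = list of ch x ch x trials arrays, traces = matrix).
bandScatterMatrices <- function(trials, bank) {
  bands <- applyFilterBank(trials, bank)
  nt <- nTrials(trials); nc <- nChannels(trials)
  lapply(bands, function(tt) {
    arr <- array(0, c(nc, nc, nt))
    for (i in seq_len(nt)) arr[, , i] <- tcrossprod(getTrial(tt, i))
    arr
  })
}

fbcspFitFromScatter <- function(scatter, labels, bank, nPairs, classOrder,
                                nc, gamma = 1e-6, trainIdx = NULL) {
  if (is.null(trainIdx)) trainIdx <- seq_along(labels)
  ip <- trainIdx[labels[trainIdx] == classOrder[1]]
  im <- trainIdx[labels[trainIdx] == classOrder[2]]
  if (!length(ip) || !length(im))
    stop("both classes must be present in the training trials", call. = FALSE)
  perBand <- lapply(scatter, function(arr) {
    sp <- meanNormalizedCov(arr, ip)
    sn <- meanNormalizedCov(arr, im)
    fitCSP(sp, sn, classOrder, gamma)
  })
  new("FBCSPModel", bank = bank, perBand = perBand, nPairs = nPairs,
      nChannels = nc, classOrder = as.character(classOrder))
}

meanNormalizedCov <- function(scatterArr, idx) {
  acc <- 0
  for (i in idx) {
    s <- scatterArr[, , i]
    tr <- sum(diag(s))
    if (tr <= 0) stop("all-zero trial in covariance averaging", call. = FALSE)
    acc <- acc + s / tr
  }
  (acc + t(acc)) / (2 * length(idx))
}

#' Extract FBCSP features for a set of trials
#'
#' Per trial, concatenates the per-band `2*nPairs` log-variance features in
#' band-major order (all features of band 1 first).
#'
#' @param trials a [TrialTensor-class] with the channel count seen at fit.
#' @param model an [FBCSPModel-class].
#' @param nPairs pairs per end (default: the model's).
#' @return `trials x (bands * 2*nPairs)` feature matrix.
#' @export
fbcspTransform <- function(trials, model, nPairs = model@nPairs) {
  if (nChannels(trials) != model@nChannels)
    stop("channel count (", nChannels(trials), ") differs from fit time (",
         model@nChannels, ")", call. = FALSE)
  scatter <- bandScatterMatrices(trials, model@bank)
  fbcspTransformFromScatter(scatter, model, nPairs, nSamples(trials))
}

fbcspTransformFromScatter <- function(scatter, model, nPairs, nSamp,
                                      idx = NULL) {
  nb <- length(model@perBand)
  nt <- if (is.null(idx)) dim(scatter[[1]])[3] else length(idx)
  if (is.null(idx)) idx <- seq_len(nt)
  out <- matrix(NA_real_, nt, nb * 2 * nPairs)
  for (b in seq_len(nb)) {
    w <- selectCSPFilters(model@perBand[[b]], nPairs)
    cols <- (b - 1) * 2 * nPairs + seq_len(2 * nPairs)
    for (k in seq_along(idx)) {
      v <- diag(t(w) %*% scatter[[b]][, , idx[k]] %*% w) / nSamp
      if (any(v <= 0) || any(!is.finite(v)))
        stop("non-positive projected variance at trial ", idx[k], call. = FALSE)
      out[k, cols] <- log(v)
    }
  }
  colnames(out) <- paste0("band", rep(seq_len(nb), each = 2 * nPairs),
                          "_f", rep(seq_len(2 * nPairs), nb))
  out
}
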