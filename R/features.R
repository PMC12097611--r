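# Time-series feature catalogue for the fTCD envelope (catalogue "v1").
#
# Three families, mirroring the exploratory statistical / temporal /
# spectral feature sets used for functional Doppler: the catalogue is
# deterministic (fixed length, fixed names) so feature matrices are
# column-aligned across trials. Degenerate (constant) envelopes yield
# defined zeros, never NaN.

histBreaks <- seq(0, 160, length.out = 9)   # fixed cm/s bins, catalogue v1

statisticalFeatures <- function(x) {
  n <- length(x)
  xc <- pmin(pmax(x, histBreaks[1]), histBreaks[length(histBreaks)] - 1e-9)
  h <- hist(xc, breaks = histBreaks, plot = FALSE)$counts / n
  p <- as.numeric(quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7))
  c(mean = mean(x), variance = mean((x - mean(x))^2),
    skewness = momentSkewness(x), kurtosis = momentKurtosis(x),
    mad = mad(x), iqr = IQR(x),
    setNames(h, paste0("hist_", seq_len(8))),
    setNames(p, paste0("ecdf_p", c(5, 25, 50, 75, 95))))
}

autocorrAtLags <- function(x, lags = 1:5) {
  n <- length(x); xm <- x - mean(x); denom <- sum(xm^2)
  vapply(lags, function(k) {
    if (denom == 0 || k >= n) return(0)
    sum(xm[1:(n - k)] * xm[(k + 1):n]) / denom
  }, numeric(1))
}

sampleEntropy <- function(x, m = 2L, rFrac = 0.2) {
  n <- length(x); s <- sqrt(mean((x - mean(x))^2))
  if (s == 0 || n < m + 2) return(0)
  r <- rFrac * s
  d <- abs(outer(x, x, "-")) <= r            # pointwise Chebyshev matches
  acc <- d[1:(n - 1), 1:(n - 1)] & d[2:n, 2:n]   # length-2 templates
  for (l in seq_len(max(0L, m - 2L)) + 1L) {     # extend to length m
    nn <- nrow(acc) - 1L
    acc <- acc[1:nn, 1:nn] & d[(l + 1):n, (l + 1):n]
  }
  b <- (sum(acc) - nrow(acc)) / 2            # template pairs i < j, length m
  nn <- nrow(acc) - 1L
  acc <- acc[1:nn, 1:nn] & d[(m + 1):n, (m + 1):n]
  a <- (sum(acc) - nrow(acc)) / 2            # length m + 1
  if (b == 0 || a == 0) return(0)
  -log(a / b)
}

temporalFeatures <- function(x, frameRate) {
  n <- length(x)
  xm <- x - mean(x)
  zc <- if (n < 2) 0 else sum(diff(sign(xm)[sign(xm) != 0]) != 0) / (n - 1)
  dx <- diff(x)
  inner <- if (n >= 3) seq(2, n - 1) else integer(0)
  isPeak <- inner[x[inner] > x[inner - 1] & x[inner] > x[inner + 1]]
  isTrough <- inner[x[inner] < x[inner - 1] & x[inner] < x[inner + 1]]
  p2p <- if (length(isPeak) && length(isTrough))
    mean(x[isPeak]) - mean(x[isTrough]) else 0
  c(setNames(autocorrAtLags(x), paste0("acf_lag", 1:5)),
    zcr = zc,
    peak_count = length(isPeak),
    mean_p2p = p2p,
    mean_slope = if (length(dx)) mean(dx) * frameRate else 0,
    line_length = sum(abs(dx)),
    sample_entropy = sampleEntropy(x))
}

haarDWT <- function(x, levels = 4L) {
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    if (length(a) < 2) { details[[l]] <- numeric(0); next }
    if (length(a) %% 2 == 1) a <- a[-length(a)]
    odd <- a[seq(1, length(a), 2)]; even <- a[seq(2, length(a), 2)]
    details[[l]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(details = details, approx = a)
}

spectralFeatures <- function(x, frameRate) {
  n <- length(x)
  xm <- x - mean(x)
  nb <- n %/% 2L + 1L
  p <- Mod(fft(xm)[seq_len(nb)])^2 / n
  f <- (seq_len(nb) - 1) * frameRate / n
  p[1] <- 0                               # mean removed; drop DC
  tot <- sum(p)
  centroid <- if (tot > 0) sum(f * p) / tot else 0
  spread <- if (tot > 0) sqrt(sum((f - centroid)^2 * p) / tot) else 0
  rolloff <- if (tot > 0) f[which(cumsum(p) >= 0.85 * tot)[1]] else 0
  cardiac <- sum(p[f >= 0.7 & f <= 2])
  w <- haarDWT(xm, 4L)
  dEn <- vapply(w$details, function(d) sum(d^2), numeric(1))
  dAll <- unlist(w$details)
  c(total_power = tot, spectral_centroid = centroid, spectral_spread = spread,
    rolloff85 = rolloff, cardiac_power = cardiac,
    setNames(dEn, paste0("dwt_d", 1:4, "_energy")),
    dwt_a4_energy = sum(w$approx^2),
    dwt_detail_mean_abs = if (length(dAll)) mean(abs(dAll)) else 0,
    dwt_detail_sd = if (length(dAll) > 1) sd(dAll) else 0)
}

#' Extract the envelope feature catalogue
#'
#' Deterministic vector of statistical, temporal and spectral features of a
#' maximal-velocity envelope (catalogue `"v1"`, 42 features per side). When
#' given a `left`/`right` pair (as returned by [envelopeFromRaw()] on a
#' two-channel trial), the per-side vectors are concatenated side-major
#' (all left features first) with `left_`/`right_` name prefixes.
#'
#' @param env an [EnvelopeSignal-class] or a list of two (left, right).
#' @param catalogue catalogue version tag; only `"v1"`.
#' @return Named numeric feature vector.
#' @export
extractEnvelopeFeatures <- function(env, catalogue = "v1") {
  if (!identical(catalogue, "v1"))
    stop("unknown feature catalogue '", catalogue, "'", call. = FALSE)
  if (is.list(env)) {
    stopifnot(length(env) == 2L)
    lf <- extractEnvelopeFeatures(env[[1]], catalogue)
    rf <- extractEnvelopeFeatures(env[[2]], catalogue)
    return(c(setNames(lf, paste0("left_", names(lf))),
             setNames(rf, paste0("right_", names(rf)))))
  }
  stopifnot(is(env, "EnvelopeSignal"))
  x <- env@velocity
  if (length(x) < 32) stop("envelope shorter than 32 frames", call. = FALSE)
  c(statisticalFeatures(x), temporalFeatures(x, env@frameRate),
    spectralFeatures(x, env@frameRate))
}

#' Wilcoxon rank-sum feature screening
#'
#' Two-sided rank-sum p-value per feature column (exact when the combined
#' sample size is at most 20 and ties allow it, otherwise the normal
#' approximation with tie correction); features with `p < alpha` are
#' selected. If none pass, the single lowest-p feature is kept and the
#' result is flagged, so a downstream evidence stream always exists.
#'
#' @param features `trials x features` numeric matrix.
#' @param labels per-trial class tags, exactly two classes with >= 2 trials
#'   each.
#' @param alpha significance level (default 0.05).
#' @return List: `selected` (column indices), `pvalues`, `fallback`
#'   (TRUE when the lowest-p fallback was used).
#' @export
ranksumSelect <- function(features, labels, alpha = 0.05) {
  features <- as.matrix(features)
  cls <- stopIfNot2Classes(labels)
  g1 <- features[labels == cls[1], , drop = FALSE]
  g2 <- features[labels == cls[2], , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2)
    stop("each class needs >= 2 trials", call. = FALSE)
  exact <- (nrow(g1) + nrow(g2)) <= 20
  pv <- vapply(seq_len(ncol(features)), function(j) {
    x <- g1[, j]; y <- g2[, j]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                 exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  sel <- which(pv < alpha)
  fallback <- FALSE
  if (!length(sel)) {
    sel <- which.min(pv)
    fallback <- TRUE
    warning("no feature passed p < ", alpha,
            "; keeping the single lowest-p feature", call. = FALSE)
  }
  list(selected = sel, pvalues = pv, fallback = fallback)
}
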