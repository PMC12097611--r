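# Zero-phase Butterworth band-pass, realized in the frequency domain.
#
# A forward-backward (filtfilt-style) pass of an order-n Butterworth
# band-pass has overall amplitude gain |H(f)|^2 and zero phase. With trials
# of fixed finite length we apply that gain directly to the trial spectrum,
# which avoids IIR edge transients entirely. |H(f)|^2 = 1/(1 + x^(2n)) with
# x = (f^2 - f_lo*f_hi) / (f * (f_hi - f_lo)).

butterBandGain <- function(f, lo, hi, order = 4) {
  f0sq <- lo * hi
  bw <- hi - lo
  g <- numeric(length(f))
  nz <- f > 0
  x <- (f[nz]^2 - f0sq) / (f[nz] * bw)
  g[nz] <- 1 / (1 + x^(2 * order))
  g
}

# x: samples-long numeric vector or a samples x k matrix (columns filtered
# independently). Returns the same shape.
fftBandpass <- function(x, fs, lo, hi, order = 4) {
  if (hi >= fs / 2) stop("band edge at/above Nyquist (", fs / 2, " Hz)", call. = FALSE)
  xm <- as.matrix(x)
  n <- nrow(xm)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided magnitude frequency
  g <- butterBandGain(f, lo, hi, order)
  y <- Re(stats::mvfft(stats::mvfft(xm) * g, inverse = TRUE)) / n
  if (is.matrix(x)) y else drop(y)
}

#' Build a non-overlapping band-pass filter bank
#'
#' Band k spans `[fLo + k*bandwidth, fLo + (k+1)*bandwidth]`; an upper edge
#' exceeding `fHi` is clipped to `fHi`, so the default EEG bank covering
#' 2-60 Hz in 9 bands of 6.5 Hz ends with the clipped band [54, 60].
#'
#' @param fLo,fHi frequency range to cover (Hz).
#' @param nBands number of bands (>= 1).
#' @param bandwidth nominal bandwidth of each band (Hz).
#' @param filterOrder Butterworth order (default 4, applied zero-phase).
#' @return A [FilterBankSpec-class].
#' @examples
#' buildFilterBank(2, 60, 9, 6.5)
#' @export
buildFilterBank <- function(fLo, fHi, nBands, bandwidth, filterOrder = 4) {
  if (fLo <= 0) stop("'fLo' must be positive", call. = FALSE)
  if (nBands < 1) stop("'nBands' must be >= 1", call. = FALSE)
  if (bandwidth <= 0) stop("'bandwidth' must be positive", call. = FALSE)
  k <- seq_len(nBands) - 1
  lo <- fLo + k * bandwidth
  hi <- pmin(fLo + (k + 1) * bandwidth, fHi)
  if (any(hi - lo < 1))
    stop("clipped band narrower than 1 Hz; reduce nBands or bandwidth", call. = FALSE)
  new("FilterBankSpec", bandEdges = cbind(lo = lo, hi = hi),
      filterOrder = filterOrder, design = "butterworth", zeroPhase = TRUE)
}

#' Apply a filter bank to a trial tensor
#'
#' Splits the trials into one band-pass-filtered copy per band of the bank.
#' Filtering is zero phase (no group delay), so trial alignment is preserved.
#'
#' @param trials a [TrialTensor-class].
#' @param spec a [FilterBankSpec-class]; all edges must lie below Nyquist.
#' @return A list of [TrialTensor-class], one per band, same shape as input.
#' @export
applyFilterBank <- function(trials, spec) {
  stopifnot(is(trials, "TrialTensor"), is(spec, "FilterBankSpec"))
  fs <- trials@fs
  if (any(spec@bandEdges >= fs / 2))
    stop("filter-bank edge at/above Nyquist (", fs / 2, " Hz)", call. = FALSE)
  d <- trials@data
  dd <- dim(d)
  # samples x (trials*channels) matrix, filter all series in one FFT batch
  flat <- matrix(aperm(d, c(3, 1, 2)), nrow = dd[3])
  lapply(seq_len(nrow(spec@bandEdges)), function(b) {
    y <- fftBandpass(flat, fs, spec@bandEdges[b, 1], spec@bandEdges[b, 2],
                     spec@filterOrder)
    arr <- aperm(array(y, c(dd[3], dd[1], dd[2])), c(2, 3, 1))
    TrialTensor(arr, fs, trials@labels, trials@channelNames)
  })
}
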