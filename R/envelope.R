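# Raw Doppler -> maximal-velocity envelope.
#
# The raw fTCD signal is a superposition of echoes from scatterers moving at
# different velocities; each contributes a Doppler-shifted tone at
# f_d = 2 f_t v cos(theta) / c. The envelope (maximal blood flow velocity)
# is traced as the highest significant frequency of the short-time spectrum,
# converted through the Doppler equation.

#' Spectrogram container
#'
#' @slot power `frames x bins` one-sided magnitude-squared STFT.
#' @slot freqs bin center frequencies (Hz), 0 .. fs/2.
#' @slot times frame center times (s).
#' @slot windowLen,hop STFT parameters in samples.
#' @export
setClass("Spectrogram",
  representation(power = "matrix", freqs = "numeric", times = "numeric",
                 windowLen = "numeric", hop = "numeric"))

setValidity("Spectrogram", function(object) {
  if (any(object@power < 0)) return("power must be non-negative")
  if (ncol(object@power) != length(object@freqs)) return("freqs must align with bins")
  if (nrow(object@power) != length(object@times)) return("times must align with frames")
  if (is.unsorted(object@freqs, strictly = TRUE)) return("freqs must be strictly increasing")
  TRUE
})

setMethod("show", "Spectrogram", function(object) {
  cat("Spectrogram:", nrow(object@power), "frames x", ncol(object@power),
      "bins; df =", signif(diff(object@freqs[1:2]), 4), "Hz\n")
})

#' STFT parameter bundle
#'
#' Defaults: 32 ms Hann window with 75% overlap. Short windows are needed
#' because the systolic upstroke sweeps the maximal Doppler frequency fast
#' enough that long windows smear the spectral edge (see the vignette).
#'
#' @param windowSec window length in seconds.
#' @param overlap fractional window overlap in [0, 1).
#' @export
stftParams <- function(windowSec = 0.032, overlap = 0.75) {
  stopifnot(windowSec > 0, overlap >= 0, overlap < 1)
  list(windowSec = windowSec, overlap = overlap, window = "hann")
}

#' One-sided STFT spectrogram
#'
#' Hann-windowed magnitude-squared short-time Fourier transform. Frame count
#' is `floor((len - window)/hop) + 1`.
#'
#' @param raw numeric sample vector.
#' @param fs sampling rate (Hz).
#' @param params an [stftParams()] list.
#' @return A [Spectrogram-class].
#' @export
stftSpectrogram <- function(raw, fs, params = stftParams()) {
  wl <- max(2L, round(params$windowSec * fs))
  hop <- max(1L, round(wl * (1 - params$overlap)))
  n <- length(raw)
  if (wl > n) stop("STFT window (", wl, " samples) longer than signal (", n, ")",
                   call. = FALSE)
  nFrames <- (n - wl) %/% hop + 1L
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(wl) / wl)   # periodic Hann
  starts <- (seq_len(nFrames) - 1L) * hop
  frames <- vapply(starts, function(s) raw[(s + 1):(s + wl)] * win, numeric(wl))
  spec <- stats::mvfft(frames)                         # wl x nFrames
  nb <- wl %/% 2L + 1L
  power <- t(Mod(spec[seq_len(nb), , drop = FALSE])^2)  # frames x bins
  new("Spectrogram", power = power,
      freqs = (seq_len(nb) - 1) * fs / wl,
      times = (starts + wl / 2) / fs,
      windowLen = wl, hop = hop)
}

#' Maximal significant frequency per frame
#'
#' Per frame, the highest frequency bin whose power reaches
#' `relThreshold` times that frame's peak power. Frames whose total power
#' falls below the global noise floor — `floorFactor` times the median
#' total power of the lowest-energy decile of frames — return 0 and are
#' flagged. (`floorFactor < 1` keeps the decile median, an estimate of the
#' quiet-frame power level, from flagging ordinary fluctuation in
#' all-signal recordings, where exactly one half of the lowest decile sits
#' below its own median by construction.)
#'
#' @param spec a [Spectrogram-class].
#' @param relThreshold fraction of the per-frame peak power, in (0, 1).
#' @param floorFactor multiplier on the decile-median noise floor
#'   (default 0.5).
#' @return List with `freq` (Hz per frame) and `flagged` (logical).
#' @export
maxFrequencyTrace <- function(spec, relThreshold = 0.1, floorFactor = 0.5) {
  stopifnot(is(spec, "Spectrogram"))
  if (relThreshold <= 0 || relThreshold >= 1)
    stop("'relThreshold' must lie in (0, 1)", call. = FALSE)
  p <- spec@power
  if (!nrow(p) || !ncol(p)) stop("empty spectrogram", call. = FALSE)
  tot <- rowSums(p)
  nLow <- max(1L, floor(nrow(p) / 10))
  floorPow <- floorFactor * median(sort(tot)[seq_len(nLow)])
  flagged <- tot < floorPow
  peak <- apply(p, 1, max)
  freq <- vapply(seq_len(nrow(p)), function(i) {
    if (flagged[i] || peak[i] <= 0) return(0)
    idx <- which(p[i, ] >= relThreshold * peak[i])
    k <- idx[length(idx)]
    # a strong edge tone pushes its Hann mainlobe tail past the threshold;
    # snap down (at most the ~2-bin half-width) to the tone's line center
    # when the bin below is mainlobe-tail-like (>= 2.5x stronger, vs ~4x
    # for a pure Hann tail), so ordinary tone-stack texture is untouched
    for (step in 1:2)
      if (k > 1 && p[i, k - 1] > 2.5 * p[i, k]) k <- k - 1 else break
    spec@freqs[k]
  }, numeric(1))
  list(freq = freq, flagged = flagged)
}

#' Doppler acquisition parameters
#'
#' @param ft transmitted ultrasound frequency (Hz), default 2 MHz.
#' @param c speed of sound in tissue (m/s), default 1540.
#' @param theta insonation angle (radians), default 0.
#' @export
dopplerParams <- function(ft = 2e6, c = 1540, theta = 0) {
  stopifnot(ft > 0, c > 0)
  if (abs(cos(theta)) < 1e-12)
    stop("insonation angle of pi/2 leaves velocity unobservable", call. = FALSE)
  list(ft = ft, c = c, theta = theta)
}

#' Convert a Doppler shift to blood flow velocity
#'
#' Inverts the Doppler relation `f_d = 2 f_t v cos(theta) / c`, returning
#' the velocity in cm/s. Linear in `fd` with the sign preserved.
#'
#' @param fd Doppler shift (Hz), scalar or vector.
#' @param params a [dopplerParams()] list.
#' @examples
#' dopplerToVelocity(1000, dopplerParams(ft = 2e6, c = 1540))  # 38.5 cm/s
#' @export
dopplerToVelocity <- function(fd, params = dopplerParams()) {
  100 * fd * params$c / (2 * params$ft * cos(params$theta))
}

velocityToDoppler <- function(v, params = dopplerParams()) {
  2 * params$ft * (v / 100) * cos(params$theta) / params$c
}

#' Maximal-velocity envelope of a raw Doppler trial
#'
#' Composition of [stftSpectrogram()], [maxFrequencyTrace()] and
#' [dopplerToVelocity()], followed by a running-median smoother that
#' suppresses single-frame dropouts.
#'
#' @param raw one side's sample vector, or a `2 x samples` (or `samples x 2`)
#'   matrix holding both transducer channels; channels are processed
#'   independently.
#' @param fs sampling rate (Hz).
#' @param params [dopplerParams()].
#' @param stft [stftParams()].
#' @param relThreshold per-frame relative power threshold.
#' @param smoothFrames running-median window (odd; 1 disables).
#' @param side side tag used when `raw` is a vector.
#' @return An [EnvelopeSignal-class], or a list `left`/`right` of them when
#'   both channels are supplied.
#' @export
envelopeFromRaw <- function(raw, fs, params = dopplerParams(),
                            stft = stftParams(), relThreshold = 0.1,
                            smoothFrames = 5, side = "left") {
  if (is.matrix(raw)) {
    if (nrow(raw) != 2L && ncol(raw) == 2L) raw <- t(raw)
    if (nrow(raw) != 2L) stop("expected two transducer channels", call. = FALSE)
    return(list(
      left  = envelopeFromRaw(raw[1, ], fs, params, stft, relThreshold,
                              smoothFrames, "left"),
      right = envelopeFromRaw(raw[2, ], fs, params, stft, relThreshold,
                              smoothFrames, "right")))
  }
  spec <- stftSpectrogram(raw, fs, stft)
  tr <- maxFrequencyTrace(spec, relThreshold)
  v <- dopplerToVelocity(tr$freq, params)
  if (smoothFrames > 1 && length(v) >= smoothFrames)
    v <- as.numeric(stats::runmed(v, k = smoothFrames, endrule = "median"))
  frameRate <- fs / spec@hop
  new("EnvelopeSignal", velocity = v, frameRate = frameRate,
      side = side, flagged = tr$flagged)
}
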