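# Synthetic paired EEG / raw-Doppler generator.
#
# The generator states a controllable ground-truth world: EEG trials are
# linear mixtures of band-limited sources whose power is modulated per
# class (SSVEP components at 7 and 17 Hz for the flickering MR/WG
# paradigm; lateralized mu/beta power for motor imagery), and raw Doppler
# trials are sums of randomly phased scatterer tones below the
# instantaneous maximal shift implied by a pulsatile velocity waveform
# with class-dependent bilateral offsets. Additive white Gaussian noise in
# both modalities keeps chance-level behavior provable.

#' EEG simulation configuration
#'
#' Four latent sources (two class-informative, two common background) are
#' mixed into the channels; `classBandGains` multiplies per-class,
#' per-source band-limited power.
#'
#' @param nTrialsPerClass trials per class.
#' @param nChannels channel count (>= 2), default 16.
#' @param fs sampling rate (Hz), default 256.
#' @param trialLen trial length (s), default 10.
#' @param paradigm `"MI"` (mu/beta lateralization, classes left/right/
#'   baseline) or `"MRWG"` (7 Hz vs 17 Hz SSVEP, classes mr/wg/baseline).
#' @param mixingMatrix optional `channels x 4` full-column-rank mixing
#'   matrix; default a seeded random orthonormal basis.
#' @param classBandGains optional `classes x 4` power-multiplier matrix
#'   with class-tag rownames; defaults encode a 4:1 informative contrast.
#' @param snrDb sensor signal-to-noise ratio in dB, default 10.
#' @param seed RNG seed.
#' @return A config list for [generateEEGTrials()].
#' @export
eegSimConfig <- function(nTrialsPerClass = 50, nChannels = 16, fs = 256,
                         trialLen = 10, paradigm = c("MRWG", "MI"),
                         mixingMatrix = NULL, classBandGains = NULL,
                         snrDb = 10, seed = 1) {
  paradigm <- match.arg(paradigm)
  if (nChannels < 2) stop("need >= 2 channels", call. = FALSE)
  if (!is.finite(snrDb)) stop("'snrDb' must be finite", call. = FALSE)
  fmax <- if (paradigm == "MRWG") 17 else 30
  if (fs <= 2 * fmax)
    stop("fs too low for the stimulated band (need > ", 2 * fmax, " Hz)",
         call. = FALSE)
  if (is.null(classBandGains)) {
    # SSVEP components are stimulus-driven: strong at the attended flicker
    # frequency, weak (residual attention leakage) otherwise
    classBandGains <- if (paradigm == "MRWG")
      rbind(mr = c(4, 0.05, 1, 1), wg = c(0.05, 4, 1, 1),
            baseline = c(0.05, 0.05, 1, 1))
    else
      rbind(left = c(1, 0.25, 1, 1), right = c(0.25, 1, 1, 1),
            baseline = c(1, 1, 1, 1))
  }
  if (is.null(rownames(classBandGains)))
    stop("'classBandGains' needs class-tag rownames", call. = FALSE)
  if (is.null(mixingMatrix)) {
    mixingMatrix <- withSeed(seed + 1000003, {
      qr.Q(qr(matrix(rnorm(nChannels * ncol(classBandGains)),
                     nChannels)))
    })
  }
  if (qr(mixingMatrix)$rank < ncol(mixingMatrix))
    stop("singular mixing matrix", call. = FALSE)
  structure(list(nTrialsPerClass = nTrialsPerClass, nChannels = nChannels,
                 fs = fs, trialLen = trialLen, paradigm = paradigm,
                 mixingMatrix = mixingMatrix, classBandGains = classBandGains,
                 snrDb = snrDb, seed = seed), class = "eegSimConfig")
}

unitPower <- function(x) x / sqrt(mean(x^2))

#' Generate synthetic EEG trials
#'
#' Deterministic given the config seed (bit-identical on repeated calls).
#' Trials are ordered class-block-wise, labels attached.
#'
#' @param cfg an [eegSimConfig()].
#' @return A labeled [TrialTensor-class].
#' @export
generateEEGTrials <- function(cfg) {
  stopifnot(inherits(cfg, "eegSimConfig"))
  classes <- rownames(cfg$classBandGains)
  ns <- round(cfg$fs * cfg$trialLen)
  nt <- cfg$nTrialsPerClass * length(classes)
  t <- (seq_len(ns) - 1) / cfg$fs
  nSrc <- ncol(cfg$classBandGains)
  withSeed(cfg$seed, {
    data <- array(0, c(nt, cfg$nChannels, ns))
    k <- 0L
    for (cl in classes) {
      gains <- cfg$classBandGains[cl, ]
      for (i in seq_len(cfg$nTrialsPerClass)) {
        k <- k + 1L
        src <- matrix(0, nSrc, ns)
        if (cfg$paradigm == "MRWG") {
          src[1, ] <- unitPower(sin(2 * pi * 7 * t + runif(1, 0, 2 * pi)))
          src[2, ] <- unitPower(sin(2 * pi * 17 * t + runif(1, 0, 2 * pi)))
        } else {
          src[1, ] <- unitPower(fftBandpass(rnorm(ns), cfg$fs, 8, 13) +
                                fftBandpass(rnorm(ns), cfg$fs, 14, 30))
          src[2, ] <- unitPower(fftBandpass(rnorm(ns), cfg$fs, 8, 13) +
                                fftBandpass(rnorm(ns), cfg$fs, 14, 30))
        }
        for (j in seq.int(3, nSrc))
          src[j, ] <- unitPower(fftBandpass(rnorm(ns), cfg$fs, 2,
                                            min(45, cfg$fs / 2 - 1)))
        src <- src * sqrt(gains)
        sig <- cfg$mixingMatrix %*% src
        noiseSd <- sqrt(mean(sig^2) / 10^(cfg$snrDb / 10))
        data[k, , ] <- sig + noiseSd * matrix(rnorm(length(sig)), nrow(sig))
      }
    }
    TrialTensor(data, cfg$fs,
                labels = rep(classes, each = cfg$nTrialsPerClass),
                channelNames = paste0("ch", seq_len(cfg$nChannels)))
  })
}

#' fTCD simulation configuration
#'
#' @param nTrialsPerClass trials per class.
#' @param fs sampling rate after decimation (Hz), default 8820.
#' @param trialLen trial length (s), default 10.
#' @param heartRate cardiac frequency (Hz), in (0.5, 3); default 1.2.
#' @param baseVelocity mean blood flow velocity (cm/s), default 60.
#' @param classVelocityOffsets `classes x 2` (left, right) cm/s offset
#'   matrix with class-tag rownames; defaults lateralize +/- 8 cm/s.
#' @param carrierFt transmitted ultrasound frequency (Hz), default 2 MHz.
#' @param soundSpeed speed of sound in tissue (m/s), default 1540.
#' @param noiseFloorDb white-noise floor relative to signal power (dB);
#'   `-Inf` disables noise. Default -20.
#' @param pulsatility fractional systolic velocity excursion, default 0.4.
#' @param nScatterers tones per channel, default 40.
#' @param paradigm class-tag set when `classVelocityOffsets` is defaulted.
#' @param seed RNG seed.
#' @return A config list for [generateFTCDTrials()].
#' @export
ftcdSimConfig <- function(nTrialsPerClass = 50, fs = 8820, trialLen = 10,
                          heartRate = 1.2, baseVelocity = 60,
                          classVelocityOffsets = NULL, carrierFt = 2e6,
                          soundSpeed = 1540, noiseFloorDb = -20,
                          pulsatility = 0.4, nScatterers = 40,
                          paradigm = c("MRWG", "MI"), seed = 1) {
  paradigm <- match.arg(paradigm)
  if (baseVelocity <= 0) stop("'baseVelocity' must be positive", call. = FALSE)
  if (heartRate <= 0.5 || heartRate >= 3)
    stop("'heartRate' must lie in (0.5, 3) Hz", call. = FALSE)
  if (is.null(classVelocityOffsets)) {
    classVelocityOffsets <- if (paradigm == "MRWG")
      rbind(mr = c(0, 8), wg = c(8, 0), baseline = c(0, 0))
    else
      rbind(left = c(0, 8), right = c(8, 0), baseline = c(0, 0))
  }
  if (is.null(rownames(classVelocityOffsets)))
    stop("'classVelocityOffsets' needs class-tag rownames", call. = FALSE)
  vmax <- baseVelocity * (1 + pulsatility) + max(classVelocityOffsets, 0)
  fdMax <- 2 * carrierFt * (vmax / 100) / soundSpeed
  if (fdMax >= fs / 2)
    stop("maximal implied Doppler shift (", round(fdMax), " Hz) reaches ",
         "Nyquist; raise fs or lower velocities", call. = FALSE)
  structure(list(nTrialsPerClass = nTrialsPerClass, fs = fs,
                 trialLen = trialLen, heartRate = heartRate,
                 baseVelocity = baseVelocity,
                 classVelocityOffsets = classVelocityOffsets,
                 carrierFt = carrierFt, soundSpeed = soundSpeed,
                 noiseFloorDb = noiseFloorDb, pulsatility = pulsatility,
                 nScatterers = nScatterers, seed = seed),
            class = "ftcdSimConfig")
}

# Raised-cosine systolic upstroke (first 15% of the beat) followed by an
# exponential diastolic decay; pulsatility-normalized to peak 1.
cardiacWaveform <- function(t, heartRate, phase0 = 0) {
  ph <- (t * heartRate + phase0) %% 1
  up <- ph < 0.15
  w <- numeric(length(t))
  w[up] <- 0.5 * (1 - cos(pi * ph[up] / 0.15))
  w[!up] <- exp(-(ph[!up] - 0.15) / 0.25)
  w
}

#' True velocity waveform of a synthetic Doppler trial
#'
#' Evaluates the generating `v(t)` recorded in a dataset's `truth` for one
#' trial and side, at arbitrary times.
#'
#' @param truth the `truth` element of a generated fTCD tensor (attribute
#'   `"truth"`) or [PairedDataset-class].
#' @param trial trial index.
#' @param side `"left"` or `"right"`.
#' @param t times (s).
#' @return Velocity in cm/s.
#' @export
trueVelocity <- function(truth, trial, side = c("left", "right"), t) {
  side <- match.arg(side)
  cfg <- truth$cfg
  off <- cfg$classVelocityOffsets[truth$classes[trial],
                                  if (side == "left") 1 else 2]
  cfg$baseVelocity *
    (1 + cfg$pulsatility * cardiacWaveform(t, cfg$heartRate,
                                           truth$phase0[trial])) + off
}

#' Generate synthetic raw Doppler trials
#'
#' Each trial is a two-channel (left, right transducer) sum of randomly
#' phased tones at fractions of the instantaneous maximal Doppler shift
#' `f_d(t) = 2 f_t v(t) / c` (one tone rides exactly at the maximal shift),
#' plus a white noise floor. The generating parameters and per-trial
#' cardiac phases are recorded in the `"truth"` attribute of the returned
#' tensor.
#'
#' @param cfg an [ftcdSimConfig()].
#' @return A labeled two-channel [TrialTensor-class] with a `"truth"`
#'   attribute (list: `cfg`, `classes`, `phase0`).
#' @export
generateFTCDTrials <- function(cfg) {
  stopifnot(inherits(cfg, "ftcdSimConfig"))
  classes <- rownames(cfg$classVelocityOffsets)
  ns <- round(cfg$fs * cfg$trialLen)
  nt <- cfg$nTrialsPerClass * length(classes)
  t <- (seq_len(ns) - 1) / cfg$fs
  params <- dopplerParams(ft = cfg$carrierFt, c = cfg$soundSpeed)
  withSeed(cfg$seed, {
    data <- array(0, c(nt, 2, ns))
    phase0 <- runif(nt)
    labs <- rep(classes, each = cfg$nTrialsPerClass)
    for (k in seq_len(nt)) {
      card <- cardiacWaveform(t, cfg$heartRate, phase0[k])
      for (side in 1:2) {
        v <- cfg$baseVelocity * (1 + cfg$pulsatility * card) +
          cfg$classVelocityOffsets[labs[k], side]
        basePhase <- 2 * pi * cumsum(velocityToDoppler(v, params)) / cfg$fs
        u <- c(1, runif(cfg$nScatterers - 1, 0.1, 1))
        a <- c(1, runif(cfg$nScatterers - 1, 0.3, 0.8))
        ph0 <- runif(cfg$nScatterers, 0, 2 * pi)
        sig <- cos(outer(basePhase, u) +
                   matrix(ph0, ns, cfg$nScatterers, byrow = TRUE)) %*% a
        if (is.finite(cfg$noiseFloorDb)) {
          noiseSd <- sqrt(mean(sig^2) * 10^(cfg$noiseFloorDb / 10))
          sig <- sig + noiseSd * rnorm(ns)
        }
        data[k, side, ] <- sig
      }
    }
    tt <- TrialTensor(data, cfg$fs, labels = labs,
                      channelNames = c("left", "right"))
    attr(tt, "truth") <- list(cfg = cfg, classes = labs, phase0 = phase0)
    tt
  })
}

#' Generate an aligned EEG + fTCD paired dataset for a binary problem
#'
#' Generates both modalities, restricts to the two requested classes and
#' pairs trials one-to-one (trial i of a class in one modality is paired
#' with trial i of the same class in the other, emulating simultaneous
#' acquisition).
#'
#' @param eegCfg an [eegSimConfig()].
#' @param ftcdCfg an [ftcdSimConfig()]; must share `nTrialsPerClass`.
#' @param problem length-2 character, the two class tags of the binary
#'   problem (e.g. `c("mr", "baseline")`).
#' @return A [PairedDataset-class]; the `truth` slot records both configs
#'   and the fTCD cardiac phases.
#' @export
generatePairedDataset <- function(eegCfg, ftcdCfg,
                                  problem = c("mr", "baseline")) {
  if (eegCfg$nTrialsPerClass != ftcdCfg$nTrialsPerClass)
    stop("mismatched trial counts between modality configs", call. = FALSE)
  if (length(problem) != 2L || problem[1] == problem[2])
    stop("'problem' must name two distinct classes", call. = FALSE)
  eeg <- generateEEGTrials(eegCfg)
  ftcd <- generateFTCDTrials(ftcdCfg)
  if (!all(problem %in% trialLabels(eeg)) || !all(problem %in% trialLabels(ftcd)))
    stop("problem classes absent from generated labels", call. = FALSE)
  if (!identical(trialLabels(eeg), trialLabels(ftcd)))
    stop("EEG and fTCD configs generate misaligned class labels", call. = FALSE)
  keep <- which(trialLabels(eeg) %in% problem)
  truth <- attr(ftcd, "truth")
  truth$classes <- truth$classes[keep]
  truth$phase0 <- truth$phase0[keep]
  new("PairedDataset",
      eeg = subsetTrials(eeg, keep),
      ftcdRaw = subsetTrials(ftcd, keep),
      labels = trialLabels(eeg)[keep],
      truth = list(eegCfg = eegCfg, ftcdCfg = ftcdCfg, ftcd = truth,
                   problem = problem))
}
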