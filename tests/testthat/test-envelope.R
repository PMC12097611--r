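test_that("spectrogram localizes a pure tone and conserves energy", {
  fs <- 8820; n <- fs
  x <- sin(2 * pi * 1000 * (0:(n - 1)) / fs)
  sp <- stftSpectrogram(x, fs, stftParams(0.032, 0.75))
  wl <- sp@windowLen; hop <- sp@hop
  expect_equal(nrow(sp@power), (n - wl) %/% hop + 1)
  df <- sp@freqs[2] - sp@freqs[1]
  peaks <- sp@freqs[apply(sp@power, 1, which.max)]
  expect_true(all(abs(peaks - 1000) <= df))
  # Parseval: spectrogram energy of one frame ~ windowed-frame energy
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(wl) / wl)
  fr <- x[1:wl] * win
  # one-sided power doubles interior bins; reconstruct two-sided total
  p1 <- sp@power[1, ]
  twoSided <- sum(p1) + sum(p1[-c(1, length(p1))])
  expect_equal(twoSided / wl, sum(fr^2), tolerance = 0.01)
  # zero signal -> all-zero power
  expect_true(all(stftSpectrogram(numeric(n), fs)@power == 0))
  expect_error(stftSpectrogram(numeric(100), fs, stftParams(0.032)), "longer")
})

test_that("maximal-frequency trace follows tones and chirps", {
  fs <- 8820; n <- 2 * fs
  t <- (0:(n - 1)) / fs
  sp <- stftSpectrogram(sin(2 * pi * 1200 * t), fs)
  df <- sp@freqs[2] - sp@freqs[1]
  tr <- maxFrequencyTrace(sp, 0.1)
  expect_true(all(abs(tr$freq - 1200) <= df))
  # linear chirp 500 -> 1500 Hz: trace nondecreasing within one bin
  f0 <- 500; f1 <- 1500
  chirp <- sin(2 * pi * (f0 * t + (f1 - f0) / 2 * t^2 / max(t)))
  trc <- maxFrequencyTrace(stftSpectrogram(chirp, fs), 0.1)
  expect_true(all(diff(trc$freq) >= -df - 1e-9))
  expect_error(maxFrequencyTrace(sp, 1.5), "relThreshold")
})

test_that("Doppler conversion inverts the shift equation", {
  p <- dopplerParams(ft = 2e6, c = 1540, theta = 0)
  expect_equal(dopplerToVelocity(0, p), 0)
  expect_equal(dopplerToVelocity(1000, p), 38.5)
  expect_equal(dopplerToVelocity(2000, p), 2 * dopplerToVelocity(1000, p))
  # velocityToDoppler is its inverse
  expect_equal(bcifuse:::velocityToDoppler(dopplerToVelocity(777, p), p), 777)
  expect_error(dopplerParams(theta = pi / 2), "unobservable")
  # cos(theta) scales linearly
  p60 <- dopplerParams(theta = pi / 3)
  expect_equal(dopplerToVelocity(1000, p60), 38.5 / cos(pi / 3))
})

test_that("a constant tone yields a constant envelope; channels split", {
  fs <- 8820; n <- 2 * fs
  p <- dopplerParams()
  fd <- bcifuse:::velocityToDoppler(50, p)
  x <- sin(2 * pi * fd * (0:(n - 1)) / fs)
  env <- envelopeFromRaw(x, fs, p, side = "right")
  expect_s4_class(env, "EnvelopeSignal")
  expect_identical(env@side, "right")
  df <- fs / round(0.032 * fs)
  expect_true(all(abs(env@velocity - 50) <= dopplerToVelocity(df, p)))
  both <- envelopeFromRaw(rbind(x, x), fs, p)
  expect_named(both, c("left", "right"))
  expect_equal(both$left@velocity, both$right@velocity)
})

test_that("noiseless single tone inverts to velocity within one bin", {
  # deterministic inversion of the Doppler relation through the full path
  cfg <- ftcdSimConfig(nTrialsPerClass = 1, trialLen = 2, noiseFloorDb = -Inf,
                       pulsatility = 0, nScatterers = 1, seed = 8,
                       classVelocityOffsets = rbind(x = c(0, 0)))
  tt <- generateFTCDTrials(cfg)
  p <- dopplerParams(ft = cfg$carrierFt, c = cfg$soundSpeed)
  env <- envelopeFromRaw(getTrial(tt, 1)[1, ], samplingRate(tt), p)
  df <- samplingRate(tt) / round(0.032 * samplingRate(tt))
  expect_true(all(abs(env@velocity - cfg$baseVelocity) <=
                  dopplerToVelocity(df, p)))
})

test_that("feature catalogue is deterministic with defined degenerate values", {
  env <- new("EnvelopeSignal", velocity = rep(55, 64), frameRate = 20,
             side = "left", flagged = rep(FALSE, 64))
  f <- extractEnvelopeFeatures(env)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["zcr"]), 0)
  expect_equal(unname(f["line_length"]), 0)
  expect_equal(unname(f["sample_entropy"]), 0)
  expect_false(any(is.na(f)))
  # sinusoid envelope at 1 Hz, frame rate 20: centroid within 0.1 Hz
  t <- (0:159) / 20
  envS <- new("EnvelopeSignal", velocity = 50 + 10 * sin(2 * pi * t),
              frameRate = 20, side = "left", flagged = rep(FALSE, 160))
  fS <- extractEnvelopeFeatures(envS)
  expect_lt(abs(fS[["spectral_centroid"]] - 1), 0.1)
  expect_gt(fS[["cardiac_power"]], 0.9 * fS[["total_power"]])
  # same length and names across trials / sides
  both <- list(left = env, right = envS)
  fb <- extractEnvelopeFeatures(both)
  expect_length(fb, 2 * length(f))
  expect_identical(names(fb),
                   c(paste0("left_", names(f)), paste0("right_", names(f))))
  expect_error(extractEnvelopeFeatures(env, catalogue = "v2"), "catalogue")
  short <- new("EnvelopeSignal", velocity = rep(1, 10), frameRate = 20,
               side = "left", flagged = rep(FALSE, 10))
  expect_error(extractEnvelopeFeatures(short), "32 frames")
})

test_that("autocorrelation and entropy features match brute-force oracles", {
  set.seed(6)
  x <- rnorm(120)
  acf5 <- bcifuse:::autocorrAtLags(x, 1:5)
  oracle <- drop(acf(x, lag.max = 5, plot = FALSE, demean = TRUE)$acf)[-1]
  # acf() divides by n, ours by sum of squares: both are the standard
  # r_k = c_k / c_0 ratio
  expect_equal(acf5, oracle, tolerance = 1e-10)
  sampEnBrute <- function(x, m = 2, r = 0.2 * sqrt(mean((x - mean(x))^2))) {
    n <- length(x)
    cnt <- function(mm) {
      tm <- sapply(0:(mm - 1), function(t) x[(1:(n - mm + 1)) + t])
      s <- 0
      for (i in 1:(nrow(tm) - 1)) for (j in (i + 1):nrow(tm))
        if (max(abs(tm[i, ] - tm[j, ])) <= r) s <- s + 1
      s
    }
    b <- cnt(m); a <- cnt(m + 1)
    if (a == 0 || b == 0) 0 else -log(a / b)
  }
  expect_equal(bcifuse:::sampleEntropy(x), sampEnBrute(x))
  # Haar DWT conserves energy across levels
  w <- bcifuse:::haarDWT(x[1:112], 4)
  expect_equal(sum(unlist(w$details)^2) + sum(w$approx^2), sum(x[1:112]^2))
})

test_that("rank-sum screening gives exact p-values and a fallback", {
  # perfectly separated 10 vs 10: exact two-sided p = 2 / choose(20, 10)
  feats <- cbind(sep = c(1:10, 101:110), const = rep(3, 20))
  labs <- rep(c("a", "b"), each = 10)
  res <- ranksumSelect(feats, labs, alpha = 0.05)
  expect_equal(res$pvalues[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$pvalues[2], 1)
  expect_identical(res$selected, 1L)
  expect_false(res$fallback)
  # nothing significant -> single lowest-p feature kept, flagged
  set.seed(7)
  nullF <- matrix(rnorm(40 * 3), 40)
  nullF[, 2] <- nullF[, 2] + rep(c(0.45, 0), each = 20)  # mild, subthreshold
  r2 <- NULL
  expect_warning(r2 <- ranksumSelect(nullF, rep(c("a", "b"), each = 20),
                                     alpha = 1e-6), "lowest-p")
  expect_length(r2$selected, 1)
  expect_true(r2$fallback)
  expect_error(ranksumSelect(feats, rep("a", 20)), "2 classes")
  expect_error(ranksumSelect(feats[1:11, ], c(rep("a", 10), "b")), ">= 2")
})
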