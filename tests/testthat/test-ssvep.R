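test_that("windowed Fourier reads on-bin sinusoid amplitude directly", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  A <- 2.5
  dat <- rbind(Oz = A * sin(2 * pi * 4 * t))
  rec <- matrixRecording(dat, fs)
  sp <- trialSpectrum(rec, 1, windowStart_s = 0, windowLen_s = 10,
                      channels = "Oz")
  amp <- Mod(sp@amp[, 1])
  expect_equal(binResolution(sp), 0.1)
  expect_equal(amp[binIndexFor(sp, 4)], A, tolerance = 1e-9)
  expect_lt(max(amp[-binIndexFor(sp, 4)]), 1e-9)
  # constant signal: zero everywhere except DC
  spc <- trialSpectrum(matrixRecording(rbind(Oz = rep(3, 10 * fs)), fs), 1,
                       windowStart_s = 0, windowLen_s = 10, channels = "Oz")
  expect_lt(max(Mod(spc@amp[-1, 1])), 1e-9)
  expect_equal(Mod(spc@amp[1, 1]), 3, tolerance = 1e-9)
})

test_that("off-bin leakage matches the closed-form geometric-sum oracle", {
  fs <- 1000; N <- 10 * fs
  f <- 4.05
  t <- (0:(N - 1)) / fs
  rec <- matrixRecording(rbind(Oz = sin(2 * pi * f * t)), fs)
  sp <- trialSpectrum(rec, 1, windowStart_s = 0, windowLen_s = 10,
                      channels = "Oz")
  # oracle: DFT of sin(2*pi*f*t) as two geometric series, scaled 2/N
  geom <- function(r) if (abs(r - 1) < 1e-15) N + 0i else (1 - r^N) / (1 - r)
  oracleBin <- function(k) {
    rp <- exp(2i * pi * (f / fs - k / N))
    rm <- exp(2i * pi * (-f / fs - k / N))
    Mod((geom(rp) - geom(rm)) / (2i) * (2 / N))
  }
  for (fk in c(3.9, 4.0, 4.1, 4.2)) {
    k <- round(fk * 10)
    expect_equal(Mod(sp@amp[binIndexFor(sp, fk), 1]), oracleBin(k),
                 tolerance = 1e-9)
  }
  # leakage splits across the bracketing bins
  expect_gt(Mod(sp@amp[binIndexFor(sp, 4.0), 1]), 0.4)
  expect_gt(Mod(sp@amp[binIndexFor(sp, 4.1), 1]), 0.4)
})

test_that("window validation rejects windows longer than the trial", {
  rec <- noiselessRecording(48, 0, trial_s = 12)
  expect_error(trialSpectrum(rec, 1, windowStart_s = 3, windowLen_s = 10),
               "exceeds")
  expect_error(trialSpectrum(rec, 5), "no such trial")
})

test_that("coherent averaging retains phase-locked signal and cancels phase", {
  fs <- 1000; t <- (0:(2 * fs - 1)) / fs
  mk <- function(phi) {
    rec <- matrixRecording(rbind(Oz = sin(2 * pi * 4 * t + phi)), fs)
    trialSpectrum(rec, 1, windowStart_s = 0, windowLen_s = 2, channels = "Oz")
  }
  s0 <- mk(0)
  avSame <- coherentAverage(list(s0, mk(0)))
  expect_equal(avSame@amp[, 1], s0@amp[, 1], tolerance = 1e-12)
  expect_equal(avSame@nAveraged, 2)
  # equal amplitude, opposite phase: exact cancellation
  avOpp <- coherentAverage(list(mk(0), mk(pi)))
  expect_lt(Mod(avOpp@amp[binIndexFor(avOpp, 4), 1]), 1e-12)
})

test_that("coherent averaging shrinks noise as 1/sqrt(n) (Monte Carlo)", {
  # 200 seeded draws; fixed-phase signal with white noise, n = 8 reps
  sch <- buildEegBlockSchedule(
    data.frame(index = 0L, contrast_L = 96, contrast_R = 0),
    trial_s = 2.5, iti_s = 0.5, seed = 1)
  p <- modelParams()
  oneSpec <- function(seed) {
    rec <- generateSsvepRecording(sch, p,
      noise = list(alpha = 0, sigma_1f = 0, sigma_white = 1),
      channels = "Oz", seed = seed)
    trialSpectrum(rec, 1, windowStart_s = 1, windowLen_s = 1, channels = "Oz")
  }
  nSeeds <- 200; nrep <- 8
  sig1 <- noise1 <- sigN <- noiseN <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    sps <- lapply(s * 100 + seq_len(nrep), oneSpec)
    av <- coherentAverage(sps)
    kSig <- binIndexFor(av, 4); kNoise <- binIndexFor(av, 9)
    sig1[s] <- Mod(sps[[1]]@amp[kSig, 1])
    noise1[s] <- Mod(sps[[1]]@amp[kNoise, 1])
    sigN[s] <- Mod(av@amp[kSig, 1])
    noiseN[s] <- Mod(av@amp[kNoise, 1])
  }
  # signal bin is preserved under averaging
  expect_equal(mean(sigN) / mean(sig1), 1, tolerance = 0.05)
  # noise bin shrinks by sqrt(8); assert within the Monte-Carlo CI
  ratio <- mean(noise1) / mean(noiseN)
  se <- ratio * sqrt((sd(noise1) / mean(noise1))^2 +
                     (sd(noiseN) / mean(noiseN))^2) / sqrt(nSeeds)
  expect_lt(abs(ratio - sqrt(nrep)), 4 * se + 0.05 * sqrt(nrep))
})

test_that("adjacent-bin SNR has its arithmetic identities", {
  freq <- seq(0, 20, by = 0.1)
  flat <- new("Spectrum", freq = freq,
              amp = matrix(complex(modulus = 0.7, argument = 0),
                           length(freq), 1),
              channels = "avg", windowStart_s = 0, windowLen_s = 10,
              nAveraged = 1)
  expect_equal(snrAt(flat, 4), 1)
  spiked <- flat
  spiked@amp[41, 1] <- complex(modulus = 3.5, argument = 0)  # 4 Hz bin
  expect_equal(snrAt(spiked, 4), 5)
})

test_that("SNR is invariant to global amplitude scaling", {
  p <- modelParams()
  sch <- oneTrialSchedule(48, 0)
  rec <- generateSsvepRecording(sch, p,
    noise = list(alpha = 1, sigma_1f = 0.3, sigma_white = 0.3),
    channels = c("Oz", "POz"), seed = 3)
  sp1 <- coherentAverage(trialSpectrum(rec, 1))
  scaled <- rec
  SummarizedExperiment::assay(scaled) <- assay(rec) * 7
  sp2 <- coherentAverage(trialSpectrum(scaled, 1))
  expect_equal(snrAt(sp2), snrAt(sp1), tolerance = 1e-9)
})

test_that("recorded SNR sits inside the Monte-Carlo CI of the ratio oracle", {
  # oracle: with white noise of SD sigma, a length-N rectangular window
  # puts iid complex Gaussian coefficients in each bin; the expected
  # adjacent-bin amplitude is sigma*sqrt(pi/N) and the signal bin adds A.
  p <- modelParams(responseGain = 4)
  sch <- oneTrialSchedule(96, 0)
  A <- modelResponse(96, 0, p)
  sigma <- 1; N <- 10000
  draws <- vapply(1:60, function(s) {
    rec <- generateSsvepRecording(sch, p,
      noise = list(alpha = 0, sigma_1f = 0, sigma_white = sigma),
      channels = "Oz", seed = s)
    snrAt(coherentAverage(trialSpectrum(rec, 1)))
  }, 0)
  oracleNoise <- sigma * sqrt(pi / N)
  expected <- A / oracleNoise
  expect_equal(mean(draws), expected, tolerance = 0.15)
})

test_that("sliding SNR traces rise, plateau and fall over a trial", {
  p <- modelParams(responseGain = 4)
  conds <- data.frame(index = 0:1, contrast_L = c(0, 96), contrast_R = 0)
  sch <- miniEegSchedule(conds, seed = 2)
  rec <- generateSsvepRecording(sch, p,
    noise = list(alpha = 1, sigma_1f = 0.2, sigma_white = 0.2),
    channels = c("Oz", "POz", "O1", "O2"), seed = 6)
  ev <- scheduleEvents(sch)
  stim <- which(ev$contrast_L[ev$kind == "trial"] == 96)
  tc <- slidingSnr(rec, stim, step_s = 0.05)
  during <- tc$snr[tc$time_s > 1.5 & tc$time_s < 10.5]
  before <- tc$snr[tc$time_s < -1]
  expect_gt(length(before), 0)
  expect_gt(median(during), 5 * median(before))
  # plateau only reached once the window fully overlaps stimulation
  early <- tc$snr[tc$time_s >= -0.4 & tc$time_s <= -0.3]
  expect_lt(median(early), median(during))
})

test_that("sliding SNR floors silent noiseless windows instead of dividing", {
  rec <- noiselessRecording(96, 0, channels = c("Oz", "POz"))
  tc <- slidingSnr(rec, 1, step_s = 0.25)
  # windows fully inside the silent intertrial interval
  silent <- tc[tc$time_s > 13 & tc$time_s < 14, ]
  expect_gt(nrow(silent), 0)
  expect_true(all(silent$floored))
  expect_true(all(is.finite(tc$snr)))
})

test_that("phase lags convert to latency at the flicker frequency", {
  expect_equal(phaseLagFromDeg(112, 4)$lag_ms, 77.8, tolerance = 0.05)
  expect_equal(phaseLagFromDeg(0, 4)$lag_ms, 0)
  expect_equal(phaseLagFromDeg(28, 4)$lag_ms, 19.4, tolerance = 0.05)
  # wrap convention: (-180, 180]
  expect_equal(phaseLagFromDeg(190, 4)$lag_deg, -170, tolerance = 1e-6)
  expect_equal(phaseLagFromDeg(-180, 4)$lag_deg, 180, tolerance = 1e-6)
})

test_that("interocular lag in generated data is recovered as ~78 ms", {
  p <- modelParams()
  conds <- data.frame(index = 0:1, contrast_L = c(24, 0), contrast_R = c(0, 24))
  sch <- miniEegSchedule(conds, seed = 2)
  rec <- generateSsvepRecording(sch, p,
    noise = list(alpha = 1, sigma_1f = 0.1, sigma_white = 0.1),
    interocularLagDeg = 112, weakerEye = "left",
    channels = c("Oz", "POz", "O1", "O2"), seed = 9)
  ev <- scheduleEvents(sch); tr <- ev[ev$kind == "trial", ]
  iWeak <- which(tr$contrast_L == 24)
  iFellow <- which(tr$contrast_R == 24)
  lag <- phaseLag(coherentAverage(trialSpectrum(rec, iFellow)),
                  coherentAverage(trialSpectrum(rec, iWeak)), 4)
  expect_equal(lag$lag_deg, 112, tolerance = 2)
  expect_equal(lag$lag_ms, 77.8, tolerance = 1.5)
})

test_that("phase-randomised averaging kills the signal bin; locked keeps it", {
  fs <- 1000; t <- (0:(2 * fs - 1)) / fs
  mk <- function(phi) {
    rec <- matrixRecording(rbind(Oz = sin(2 * pi * 4 * t + phi)), fs)
    trialSpectrum(rec, 1, windowStart_s = 0, windowLen_s = 2, channels = "Oz")
  }
  set.seed(13)
  locked <- coherentAverage(lapply(1:16, function(i) mk(0)))
  scrambled <- coherentAverage(lapply(1:16, function(i) mk(runif(1, 0, 2 * pi))))
  k <- binIndexFor(locked, 4)
  expect_equal(Mod(locked@amp[k, 1]), 1, tolerance = 1e-9)
  expect_lt(Mod(scrambled@amp[k, 1]), 0.5)
})

test_that("the harmonic is analysed with the same machinery", {
  p <- modelParams(responseGain = 4)
  rec <- generateSsvepRecording(oneTrialSchedule(96, 0), p,
    noise = list(alpha = 1, sigma_1f = 0.2, sigma_white = 0.2),
    harmonicRatio = 0.5, channels = c("Oz", "POz", "O1", "O2"), seed = 21)
  av <- coherentAverage(trialSpectrum(rec, 1))
  snr4 <- snrAt(av, f0 = 4)
  snr8 <- snrAt(av, f0 = 8)
  expect_gt(snr8, 3)       # clear harmonic response
  expect_gt(snr4, snr8)    # fundamental dominates at ratio 0.5
})

test_that("bootstrap median CI is seeded, bracketing and degenerate-safe", {
  ci <- bootstrapMedianCi(rep(5, 20), nBoot = 500, seed = 1)
  expect_equal(unname(ci), c(5, 5, 5))
  set.seed(3)
  x <- rnorm(44, 5, 1)
  ci2 <- bootstrapMedianCi(x, nBoot = 1000, seed = 2)
  expect_lte(ci2["lower"], ci2["median"])
  expect_lte(ci2["median"], ci2["upper"])
  expect_identical(bootstrapMedianCi(x, nBoot = 200, seed = 7),
                   bootstrapMedianCi(x, nBoot = 200, seed = 7))
})

test_that("bootstrap CI of the median has near-nominal coverage", {
  # coverage experiment at n = 44 per sample (true median 5)
  hits <- 0; nexp <- 150
  set.seed(99)
  for (i in seq_len(nexp)) {
    x <- rnorm(44, 5, 1)
    ci <- bootstrapMedianCi(x, nBoot = 400, seed = i)
    if (ci["lower"] <= 5 && 5 <= ci["upper"]) hits <- hits + 1
  }
  expect_gt(hits / nexp, 0.85)
  expect_lte(hits / nexp, 1)
})
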