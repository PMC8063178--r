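# Shared fixtures for the test suite. Everything is generated in code;
# sizes are kept small so the full suite runs quickly on one core.

crfLevelsDefault <- c(0, 6, 24, 48, 96)

# A short EEG schedule containing only the conditions named, in order.
miniEegSchedule <- function(conds, trial_s = 12, iti_s = 3, seed = 1) {
  buildEegBlockSchedule(conds, trial_s = trial_s, iti_s = iti_s, seed = seed)
}

# Single-condition EEG schedule (one trial + ITI).
oneTrialSchedule <- function(cl, cr, trial_s = 12, iti_s = 3) {
  miniEegSchedule(data.frame(index = 0L, contrast_L = cl, contrast_R = cr),
                  trial_s = trial_s, iti_s = iti_s)
}

# Noise-free single-trial recording with known amplitude A at f0.
noiselessRecording <- function(cl = 96, cr = 0, params = modelParams(),
                               channels = c("Oz", "POz", "O1", "O2"),
                               harmonicRatio = 0.5, lagDeg = 0,
                               weakerEye = "left", trial_s = 12) {
  generateSsvepRecording(
    oneTrialSchedule(cl, cr, trial_s = trial_s), params,
    noise = list(alpha = 1, sigma_1f = 0, sigma_white = 0),
    harmonicRatio = harmonicRatio, interocularLagDeg = lagDeg,
    weakerEye = weakerEye, channels = channels, seed = 1)
}

# Wrap a bare channels x samples matrix as a Recording whose single trial
# spans the whole matrix, for spectra of hand-constructed signals. A one-
# sample zero pad covers the nominal 1 ms intertrial interval.
matrixRecording <- function(dat, sampleRate = 1000) {
  trial_s <- ncol(dat) / sampleRate
  sched <- oneTrialSchedule(96, 0, trial_s = trial_s, iti_s = 0.001)
  dat <- cbind(dat, 0)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(eeg = dat),
    rowData = S4Vectors::DataFrame(channel = rownames(dat)),
    metadata = list(sample_rate = sampleRate, schedule = sched))
  new("Recording", se)
}

# Frequency-bin index helper for reading Spectrum objects in tests.
binIndexFor <- function(sp, f) which.min(abs(sp@freq - f))

# Phase lag between two synthetic unit spectra differing by `deg` at f0.
phaseLagFromDeg <- function(deg, f0) {
  freq <- seq(0, 10, by = 1)
  mk <- function(phi) new("Spectrum", freq = freq,
    amp = matrix(complex(modulus = 1, argument = phi), length(freq), 1),
    channels = "avg", windowStart_s = 0, windowLen_s = 1, nAveraged = 1)
  phaseLag(mk(deg * pi / 180), mk(0), f0)
}

# Cohort of per-participant CRF matrices sampled around a generating
# parameter set with iid cell noise (model-level shortcut used where the
# full acquisition pipeline is not the thing under test).
modelCohort <- function(params, nSubj, sigma, seed,
                        levels = crfLevelsDefault) {
  truth <- crfValues(predictCrfMatrix(params, levels))
  set.seed(seed)
  lapply(seq_len(nSubj), function(s) {
    v <- truth + matrix(rnorm(length(truth), sd = sigma), nrow(truth))
    new("CRFMatrix", values = unname(v), levels = levels,
        targetEye = "left", modality = "model",
        dispersion = matrix(numeric(0), 0, 0))
  })
}

# One participant's session of the full fMRI pipeline: nRuns block-design
# runs generated from `params`, combined by GLM design concatenation,
# returned as the mean-beta left x right matrix.
participantBetaMatrix <- function(params, seed, nRuns = 4, nVoxels = 8,
                                  noise = list(ar1_rho = 0.3, sigma = 0.3,
                                               drift = 0.05),
                                  levels = crfLevelsDefault) {
  cm <- buildConditionMatrix(levels)
  runs <- lapply(seq_len(nRuns), function(r) {
    sch <- buildFmriCrfSchedule(cm, seed = seed * 100 + r)
    generateBoldRun(sch, params, noise = noise, nVoxels = nVoxels,
                    seed = seed * 100 + r)
  })
  betaMatrix(glmBetas(runs), levels)
}
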