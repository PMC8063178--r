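#' Approximate 10--20 scalp layout
#'
#' 2D positions (unit head radius, nose up) for a common subset of the
#' 10--20 electrode set, used to weight the steady-state signal
#' topography. Positions are schematic, adequate for distance-based
#' falloff from Oz.
#'
#' @return data.frame with columns \code{channel}, \code{x}, \code{y}.
#' @export
electrodeLayout <- function() {
  data.frame(
    channel = c("Oz", "POz", "O1", "O2", "Pz", "P3", "P4", "P7", "P8",
                "Cz", "C3", "C4", "T7", "T8", "Fz", "F3", "F4", "Fp1", "Fp2"),
    x = c(0, 0, -0.31, 0.31, 0, -0.4, 0.4, -0.81, 0.81,
          0, -0.5, 0.5, -1, 1, 0, -0.4, 0.4, -0.31, 0.31),
    y = c(-1, -0.72, -0.95, -0.95, -0.45, -0.55, -0.55, -0.59, -0.59,
          0, 0, 0, 0, 0, 0.45, 0.55, 0.55, 0.95, 0.95),
    stringsAsFactors = FALSE
  )
}

#' Occipitally-weighted signal topography
#'
#' Per-channel weight for the steady-state signal: exponential falloff in
#' inter-electrode distance from Oz, \eqn{w = e^{-d/\lambda}}, with
#' \code{lambda} in head-radius units. Oz gets weight 1; frontal sites
#' are near 0 so they carry essentially noise only.
#'
#' @param channels channel labels present in [electrodeLayout()].
#' @param lambda falloff length constant (head-radius units).
#' @return named numeric vector of weights in (0, 1].
#' @export
topographyWeights <- function(channels, lambda = 0.35) {
  lay <- electrodeLayout()
  idx <- match(channels, lay$channel)
  if (anyNA(idx))
    stop("unknown channel(s): ", paste(channels[is.na(idx)], collapse = ", "))
  oz <- lay[lay$channel == "Oz", ]
  d <- sqrt((lay$x[idx] - oz$x)^2 + (lay$y[idx] - oz$y)^2)
  stats::setNames(exp(-d / lambda), channels)
}

defaultEegChannels <- function() {
  c("Oz", "POz", "O1", "O2", "Pz", "P3", "P4", "Cz", "C3", "C4",
    "Fz", "F3", "F4", "Fp1", "Fp2", "T7", "T8")
}

#' Generate a synthetic SSVEP recording
#'
#' Simulates a multichannel EEG-like recording for a dichoptic schedule.
#' During each trial, channels carry a steady-state response at the 4 Hz
#' flicker frequency plus a second harmonic at 8 Hz, with amplitude given
#' by the two-stage model evaluated at the trial's left/right contrasts,
#' weighted by an occipital topography, and tapered at trial edges by a
#' brief raised-cosine ramp. Trials driven monocularly by the designated
#' weaker eye are delayed by \code{interocularLagDeg} of phase at the
#' fundamental (and twice that at the harmonic, as for a pure latency
#' shift). Every channel receives independent 1/f plus white noise.
#'
#' The generator is linear: dichoptic trials take their single amplitude
#' from the model (which is where the nonlinearity lives); the analyses
#' only require calibrated amplitudes and phases.
#'
#' @param schedule an EEG [DichopticSchedule-class].
#' @param params a [ModelParams-class]; per-trial amplitude =
#'   \code{modelResponse(contrast_L, contrast_R, params)}.
#' @param noise list with \code{alpha} (1/f exponent), \code{sigma_1f}
#'   and \code{sigma_white} (time-domain SDs); non-negative.
#' @param harmonicRatio amplitude of the 8 Hz harmonic relative to the
#'   4 Hz fundamental.
#' @param interocularLagDeg phase delay (degrees at f0) applied to
#'   weaker-eye monocular trials.
#' @param weakerEye which eye is the weaker (lagged) one.
#' @param f0 flicker frequency, Hz.
#' @param channels channel labels (subset of [electrodeLayout()]).
#' @param sampleRate sampling rate, Hz.
#' @param seed integer seed; identical seeds give identical recordings.
#' @return a [Recording-class]; \code{metadata(x)$truth} holds the
#'   per-trial amplitudes and phases actually used.
#' @export
generateSsvepRecording <- function(schedule, params,
                                   noise = list(alpha = 1, sigma_1f = 1,
                                                sigma_white = 1),
                                   harmonicRatio = 0.5,
                                   interocularLagDeg = 0,
                                   weakerEye = c("left", "right"),
                                   f0 = 4,
                                   channels = defaultEegChannels(),
                                   sampleRate = 1000, seed = 1) {
  weakerEye <- match.arg(weakerEye)
  if (any(unlist(noise[c("sigma_1f", "sigma_white")]) < 0))
    stop("noise sigmas must be non-negative")
  ev <- scheduleEvents(schedule)
  dur <- scheduleDuration(schedule)
  n <- round(dur * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  w <- topographyWeights(channels)

  trials <- ev[ev$kind == "trial", , drop = FALSE]
  amp <- if (nrow(trials)) modelResponse(trials$contrast_L, trials$contrast_R, params)
         else numeric(0)
  cw <- if (weakerEye == "left") trials$contrast_L else trials$contrast_R
  cf <- if (weakerEye == "left") trials$contrast_R else trials$contrast_L
  lagged <- nrow(trials) > 0 & cw > 0 & cf == 0
  phase <- ifelse(lagged, -interocularLagDeg * pi / 180, 0)

  sig <- numeric(n)
  ramp_s <- 0.1
  for (i in seq_len(nrow(trials))) {
    i0 <- floor(trials$onset_s[i] * sampleRate) + 1
    i1 <- min(n, floor((trials$onset_s[i] + trials$duration_s[i]) * sampleRate))
    idx <- i0:i1
    tt <- t[idx] - trials$onset_s[i]
    env <- pmin(1, pmin(tt, trials$duration_s[i] - tt) / ramp_s)
    env <- pmax(env, 0)
    sig[idx] <- sig[idx] + env * amp[i] *
      (sin(2 * pi * f0 * tt + phase[i]) +
       harmonicRatio * sin(2 * pi * 2 * f0 * tt + 2 * phase[i]))
  }

  withSeed(seed, {
    dat <- matrix(0, nrow = length(channels), ncol = n,
                  dimnames = list(channels, NULL))
    for (ch in seq_along(channels)) {
      dat[ch, ] <- w[ch] * sig +
        oneOverFNoise(n, noise$alpha, noise$sigma_1f) +
        rnorm(n, sd = noise$sigma_white)
    }
    dat
  }) -> dat

  truth <- list(
    trial_amplitude = amp,
    trial_phase_rad = phase,
    harmonic_ratio = harmonicRatio,
    interocular_lag_deg = interocularLagDeg,
    weaker_eye = weakerEye,
    f0 = f0
  )
  se <- SummarizedExperiment(
    assays = list(eeg = dat),
    rowData = DataFrame(channel = channels, weight = unname(w)),
    metadata = list(sample_rate = sampleRate, schedule = schedule,
                    truth = truth, seed = seed)
  )
  new("Recording", se)
}
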