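#' Windowed Fourier spectrum of one trial
#'
#' Takes the Fourier transform of the recording at each requested channel
#' for a window starting \code{windowStart_s} after trial onset (skipping
#' onset transients) and lasting \code{windowLen_s}. No taper is applied:
#' the design puts the flicker frequency exactly on a bin for both the
#' 10 s (0.1 Hz resolution) and 1 s (1 Hz) windows, so leakage control is
#' unnecessary and the adjacent-bin SNR definition is preserved exactly.
#' Amplitudes are scaled by 2/N (DC by 1/N) so a unit sinusoid at a bin
#' frequency reads amplitude 1.
#'
#' @param recording a [Recording-class].
#' @param trial 1-based index among the schedule's trial events.
#' @param windowStart_s window start relative to trial onset, seconds.
#' @param windowLen_s window length, seconds.
#' @param channels channel labels; default the recording's channels.
#' @return a [Spectrum-class] (bins x channels, complex).
#' @export
trialSpectrum <- function(recording, trial, windowStart_s = 1,
                          windowLen_s = 10, channels = NULL) {
  sched <- schedule(recording)
  ev <- scheduleEvents(sched)
  trials <- ev[ev$kind == "trial", , drop = FALSE]
  if (trial < 1 || trial > nrow(trials)) stop("no such trial: ", trial)
  tr <- trials[trial, ]
  if (windowStart_s + windowLen_s > tr$duration_s + 1e-9)
    stop(sprintf("window [%g, %g] s exceeds the %g s trial",
                 windowStart_s, windowStart_s + windowLen_s, tr$duration_s))
  fs <- sampleRate(recording)
  if (is.null(channels)) channels <- rownames(recording)
  i0 <- round((tr$onset_s + windowStart_s) * fs) + 1
  N <- round(windowLen_s * fs)
  seg <- assay(recording)[channels, i0:(i0 + N - 1), drop = FALSE]
  co <- stats::mvfft(t(seg))         # N x channels
  nb <- floor(N / 2) + 1
  amp <- co[seq_len(nb), , drop = FALSE] * (2 / N)
  amp[1, ] <- amp[1, ] / 2           # DC is not doubled
  dimnames(amp) <- NULL
  new("Spectrum", freq = (seq_len(nb) - 1) / windowLen_s, amp = amp,
      channels = channels, windowStart_s = tr$onset_s + windowStart_s,
      windowLen_s = windowLen_s, nAveraged = 1)
}

#' Coherent (complex) averaging of spectra
#'
#' Averages complex Fourier coefficients across spectra and across their
#' channels, retaining phase, so phase-locked signal survives while
#' non-phase-locked noise cancels as \eqn{1/\sqrt{n}}. Magnitudes are
#' taken downstream (e.g. by [snrAt()]). Averaging across channels and
#' across repetitions commutes, so the order is immaterial.
#'
#' @param spectra a list of [Spectrum-class] objects on the same bin grid.
#' @return a single-channel [Spectrum-class]; \code{nAveraged} records the
#'   total number of channel-spectra averaged.
#' @export
coherentAverage <- function(spectra) {
  if (inherits(spectra, "Spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("no spectra to average")
  f <- spectra[[1]]@freq
  for (s in spectra)
    if (length(s@freq) != length(f) || max(abs(s@freq - f)) > 1e-9)
      stop("spectra must share the same frequency bins")
  tot <- 0 + 0i
  n <- 0
  for (s in spectra) {
    tot <- tot + rowSums(s@amp) * s@nAveraged
    n <- n + ncol(s@amp) * s@nAveraged
  }
  new("Spectrum", freq = f, amp = matrix(tot / n, ncol = 1),
      channels = "avg", windowStart_s = spectra[[1]]@windowStart_s,
      windowLen_s = spectra[[1]]@windowLen_s, nAveraged = n)
}

specAmplitude <- function(spectrum) {
  a <- spectrum@amp
  if (ncol(a) > 1) a <- matrix(rowMeans(a), ncol = 1)  # coherent channel mean
  a[, 1]
}

binIndex <- function(spectrum, f) {
  i <- which(abs(spectrum@freq - f) < binResolution(spectrum) / 2 - 1e-12)
  if (length(i) != 1) stop(sprintf("frequency %g Hz is not on the bin grid", f))
  i
}

#' Adjacent-bin signal-to-noise ratio
#'
#' Divides the absolute amplitude in the signal bin at \code{f0} by the
#' mean absolute amplitude of the adjacent bins at \code{f0 +/- k step}
#' for k = 1..halfWidth/step (ten bins for the defaults at 0.1 Hz
#' resolution), excluding the signal bin itself.
#'
#' @param spectrum a [Spectrum-class] (multichannel input is coherently
#'   averaged across channels first).
#' @param f0 signal frequency, Hz.
#' @param halfWidth half-width of the noise band, Hz.
#' @param step bin step within the noise band, Hz; defaults to the
#'   spectrum's bin resolution.
#' @return non-negative SNR. When the noise denominator is exactly 0 the
#'   result is \code{Inf} carrying attribute \code{flagged = TRUE}.
#' @export
snrAt <- function(spectrum, f0 = 4, halfWidth = 0.5, step = NULL) {
  if (is.null(step)) step <- binResolution(spectrum)
  amp <- Mod(specAmplitude(spectrum))
  k <- seq_len(round(halfWidth / step))
  sideF <- c(f0 - rev(k) * step, f0 + k * step)
  idx <- vapply(sideF, function(f) binIndex(spectrum, f), integer(1))
  sig <- amp[binIndex(spectrum, f0)]
  noise <- mean(amp[idx])
  # a denominator at floating-point-residual level means a noiseless
  # recording: the ratio is unbounded and flagged rather than reported
  if (noise <= .Machine$double.eps^0.75 * max(sig, 1)) {
    out <- Inf
    attr(out, "flagged") <- TRUE
    return(out)
  }
  sig / noise
}

#' Sliding-window SNR timecourse
#'
#' Repeats the Fourier transform in a sliding short window (default 1 s,
#' stepped every 10 ms) across one trial and its surround, and scales the
#' signal-bin amplitude by the mean of the two bins \code{+/- 1} bin step
#' away (\code{+/- 1 Hz} for the 1 s window) to give an SNR per window
#' centre. Windows whose noise estimate falls below a small floor
#' (silent noiseless stretches) are floored and flagged rather than
#' divided to infinity.
#'
#' @param recording a [Recording-class].
#' @param trial 1-based trial index.
#' @param f0 signal frequency, Hz.
#' @param window_s window length, seconds (bin resolution = 1/window_s).
#' @param step_s window step, seconds.
#' @param pre_s,post_s context before onset / after offset, seconds.
#' @param channels channels to average coherently; default the four
#'   occipital sites present in the recording.
#' @param floor_eps denominator floor.
#' @return data.frame with columns \code{time_s} (window centre relative
#'   to trial onset), \code{snr}, \code{floored}.
#' @export
slidingSnr <- function(recording, trial, f0 = 4, window_s = 1, step_s = 0.010,
                       pre_s = 2, post_s = 3, channels = NULL,
                       floor_eps = 1e-12) {
  sched <- schedule(recording)
  ev <- scheduleEvents(sched)
  trials <- ev[ev$kind == "trial", , drop = FALSE]
  tr <- trials[trial, ]
  fs <- sampleRate(recording)
  if (is.null(channels))
    channels <- intersect(c("Oz", "POz", "O1", "O2"), rownames(recording))
  if (!length(channels)) channels <- rownames(recording)
  a <- assay(recording)[channels, , drop = FALSE]
  N <- round(window_s * fs)
  nTot <- ncol(a)
  centres <- seq(tr$onset_s - pre_s, tr$onset_s + tr$duration_s + post_s,
                 by = step_s)
  starts <- round((centres - window_s / 2) * fs) + 1
  keep <- starts >= 1 & starts + N - 1 <= nTot
  centres <- centres[keep]; starts <- starts[keep]
  kSig <- round(f0 * window_s) + 1
  kLo <- kSig - 1; kHi <- kSig + 1
  snr <- numeric(length(starts)); floored <- logical(length(starts))
  basis <- exp(-2i * pi * (round(f0 * window_s) + c(-1, 0, 1)) %o%
                 (seq_len(N) - 1) / N)
  for (i in seq_along(starts)) {
    seg <- a[, starts[i]:(starts[i] + N - 1), drop = FALSE]
    x <- colMeans(seg)                       # coherent channel mean
    co <- basis %*% x * (2 / N)
    sig <- Mod(co[2]); noise <- mean(Mod(co[c(1, 3)]))
    if (noise < floor_eps) { noise <- floor_eps; floored[i] <- TRUE }
    snr[i] <- sig / noise
  }
  data.frame(time_s = centres - tr$onset_s, snr = snr, floored = floored)
}

#' Phase lag between two spectra at a frequency
#'
#' Angular difference \code{Arg(A) - Arg(B)} at \code{f0}, wrapped to
#' (-180, 180] degrees, and the equivalent latency
#' \eqn{lag_{ms} = lag_{deg}/360 \times 1000/f_0}. A positive lag means
#' B is delayed relative to A. At 4 Hz, 112 degrees corresponds to
#' 77.8 ms and 28 degrees to 19.4 ms.
#'
#' @param specA,specB [Spectrum-class] objects (channels averaged
#'   coherently).
#' @param f0 frequency, Hz.
#' @return list with \code{lag_deg} and \code{lag_ms}.
#' @export
phaseLag <- function(specA, specB, f0 = 4) {
  aA <- specAmplitude(specA)[binIndex(specA, f0)]
  aB <- specAmplitude(specB)[binIndex(specB, f0)]
  d <- (Arg(aA) - Arg(aB)) * 180 / pi
  d <- ((d + 180) %% 360) - 180
  if (d == -180) d <- 180
  list(lag_deg = d, lag_ms = d / 360 * 1000 / f0)
}

#' Bootstrap percentile CI of the median
#'
#' @param values numeric sample (e.g. one value per participant).
#' @param nBoot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return named numeric vector \code{c(lower, median, upper)}.
#' @export
bootstrapMedianCi <- function(values, nBoot = 2000, level = 0.95, seed = 1) {
  stopifnot(length(values) >= 1)
  meds <- withSeed(seed, {
    vapply(seq_len(nBoot),
           function(i) median(sample(values, replace = TRUE)), 0)
  })
  a <- (1 - level) / 2
  ci <- quantile(meds, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = ci[1], median = median(values), upper = ci[2])
}

#' Per-condition SSVEP SNR matrix from one or more blocks
#'
#' Runs the full steady-state pipeline: a windowed Fourier transform per
#' trial, coherent averaging across repetitions of the same condition and
#' across the occipital electrode set, then adjacent-bin SNR, assembled
#' as a left-eye-contrast x right-eye-contrast matrix.
#'
#' @param recordings a [Recording-class] or list of them (repetitions).
#' @param levels contrast levels indexing the matrix.
#' @param f0 analysis frequency, Hz (use 8 for the second harmonic).
#' @param channels electrodes averaged; default \code{Oz, POz, O1, O2}.
#' @param windowStart_s,windowLen_s Fourier window (see [trialSpectrum()]).
#' @return numeric matrix, rows = left-eye contrast, cols = right-eye.
#' @export
conditionSnrMatrix <- function(recordings, levels = c(0, 6, 24, 48, 96),
                               f0 = 4, channels = c("Oz", "POz", "O1", "O2"),
                               windowStart_s = 1, windowLen_s = 10) {
  if (inherits(recordings, "Recording")) recordings <- list(recordings)
  n <- length(levels)
  bank <- vector("list", n * n)
  dim(bank) <- c(n, n)
  for (rec in recordings) {
    ev <- scheduleEvents(schedule(rec))
    trials <- ev[ev$kind == "trial", , drop = FALSE]
    for (k in seq_len(nrow(trials))) {
      i <- match(trials$contrast_L[k], levels)
      j <- match(trials$contrast_R[k], levels)
      if (is.na(i) || is.na(j)) stop("trial contrast not in the level set")
      sp <- trialSpectrum(rec, k, windowStart_s, windowLen_s,
                          channels = intersect(channels, rownames(rec)))
      bank[[i, j]] <- c(bank[[i, j]], list(sp))
    }
  }
  out <- matrix(NA_real_, n, n, dimnames = list(left = levels, right = levels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (is.null(bank[[i, j]])) next
    out[i, j] <- snrAt(coherentAverage(bank[[i, j]]), f0 = f0)
  }
  out
}
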