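#' @import methods
#' @importFrom stats fft rnorm runif sd aov optim dgamma quantile
#'   median lm.fit pt
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Parameters of the two-stage binocular gain-control model
#'
#' Holds all constants of the two-stage contrast gain-control model of
#' binocular combination, together with the per-eye attenuation factors
#' (tonic suppression) and directional interocular suppression weights
#' (dynamic suppression).
#'
#' The model takes Michelson contrasts \eqn{C_L, C_R} in percent (0--100)
#' for the two eyes. Stage 1 applies, per eye, a gain-controlled
#' transducer with excitatory exponent \code{m}, saturation constant
#' \code{S} and a suppressive drive from the other eye weighted by the
#' directional weight \eqn{\omega}. The two monocular outputs are summed
#' binocularly and passed through a second gain-control stage with
#' exponents \code{p} (numerator) and \code{q} (denominator) and
#' saturation constant \code{Z}. \code{responseGain} maps the
#' dimensionless model output to measurement units (GLM beta or SSVEP
#' SNR), and is typically a free parameter at fitting time.
#'
#' @slot m excitatory exponent of stage 1 (dimensionless, > 0).
#' @slot p numerator exponent of stage 2 (> 0).
#' @slot q denominator exponent of stage 2 (> 0).
#' @slot S stage-1 saturation constant, in percent-contrast units (> 0).
#' @slot Z stage-2 saturation constant, in response units (> 0).
#' @slot omegaLtoR weight of the left-eye signal suppressing the right
#'   channel (>= 0).
#' @slot omegaRtoL weight of the right-eye signal suppressing the left
#'   channel (>= 0).
#' @slot attenL attenuation factor applied to left-eye input, in (0, 1].
#' @slot attenR attenuation factor applied to right-eye input, in (0, 1].
#' @slot responseGain output scale factor (> 0).
#'
#' @seealso [modelParams()] for the user-facing constructor,
#'   [modelResponse()], [applyVariant()], [predictCrfMatrix()].
#' @export
setClass("ModelParams",
  representation(
    m = "numeric", p = "numeric", q = "numeric",
    S = "numeric", Z = "numeric",
    omegaLtoR = "numeric", omegaRtoL = "numeric",
    attenL = "numeric", attenR = "numeric",
    responseGain = "numeric"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character(0)
  pos <- c(m = object@m, p = object@p, q = object@q, S = object@S,
           Z = object@Z, responseGain = object@responseGain)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "m, p, q, S, Z and responseGain must be finite and strictly positive")
  for (nm in c("attenL", "attenR")) {
    a <- slot(object, nm)
    if (!is.finite(a) || a <= 0 || a > 1)
      msg <- c(msg, sprintf("%s must lie in (0, 1]", nm))
  }
  for (nm in c("omegaLtoR", "omegaRtoL")) {
    w <- slot(object, nm)
    if (!is.finite(w) || w < 0)
      msg <- c(msg, sprintf("%s must be finite and >= 0", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Dichoptic stimulation schedule
#'
#' An ordered sequence of trials and blanks with onsets, durations and the
#' Michelson contrasts shown to the left and right eyes, plus the modality
#' the schedule was built for and the RNG seed used to order trials.
#'
#' @slot events data.frame with columns \code{index}, \code{onset_s},
#'   \code{duration_s}, \code{contrast_L}, \code{contrast_R}, \code{kind}
#'   (\code{"trial"} or \code{"blank"}); events are contiguous,
#'   non-overlapping, half-open intervals \code{[onset, onset + duration)}.
#' @slot modality one of \code{"eeg"}, \code{"fmri"}, \code{"localiser"}.
#' @slot TR_s repetition time in seconds (\code{NA} for EEG schedules).
#' @slot levels the contrast level set the schedule draws from.
#' @slot seed integer seed used for trial ordering (\code{NA} if none).
#' @export
setClass("DichopticSchedule",
  representation(
    events = "data.frame",
    modality = "character",
    TR_s = "numeric",
    levels = "numeric",
    seed = "numeric"
  )
)

setValidity("DichopticSchedule", function(object) {
  ev <- object@events
  need <- c("index", "onset_s", "duration_s", "contrast_L", "contrast_R", "kind")
  if (!all(need %in% names(ev)))
    return(sprintf("events must have columns: %s", paste(need, collapse = ", ")))
  if (!object@modality %in% c("eeg", "fmri", "localiser"))
    return("modality must be 'eeg', 'fmri' or 'localiser'")
  if (nrow(ev) > 0) {
    if (any(ev$duration_s <= 0)) return("event durations must be positive")
    o <- order(ev$onset_s)
    ends <- ev$onset_s[o] + ev$duration_s[o]
    if (any(abs(ev$onset_s[o][-1] - ends[-length(ends)]) > 1e-9))
      return("events must tile time contiguously without overlap")
    if (abs(ev$onset_s[o][1]) > 1e-9)
      return("coverage must start at 0 s")
  }
  if (object@modality %in% c("fmri", "localiser") && nrow(ev) > 0) {
    tot <- scheduleDuration(object)
    if (!is.na(object@TR_s) && abs(tot %% object@TR_s) > 1e-9 &&
        abs(tot %% object@TR_s - object@TR_s) > 1e-9)
      return("total duration must be divisible by TR for fMRI schedules")
  }
  TRUE
})

#' Complex Fourier spectrum with known bin resolution
#'
#' Complex amplitude per frequency bin for one or more channels, as
#' returned by [trialSpectrum()]. Amplitudes are scaled so that a unit
#' sinusoid exactly at a bin frequency has magnitude 1 in that bin.
#' Supports coherent (complex) averaging via [coherentAverage()].
#'
#' @slot freq frequency per bin, Hz; uniform spacing = 1 / window length.
#' @slot amp complex matrix, bins x channels.
#' @slot channels channel labels (columns of \code{amp}).
#' @slot windowStart_s window start relative to recording, seconds.
#' @slot windowLen_s window length, seconds (bin resolution = 1 / this).
#' @slot nAveraged number of spectra coherently averaged into this one.
#' @export
setClass("Spectrum",
  representation(
    freq = "numeric",
    amp = "matrix",
    channels = "character",
    windowStart_s = "numeric",
    windowLen_s = "numeric",
    nAveraged = "numeric"
  )
)

setValidity("Spectrum", function(object) {
  if (!is.complex(object@amp)) return("amp must be a complex matrix")
  if (length(object@freq) != nrow(object@amp))
    return("freq length must equal nrow(amp)")
  if (length(object@channels) != ncol(object@amp))
    return("channels length must equal ncol(amp)")
  if (length(object@freq) > 1) {
    d <- diff(object@freq)
    if (max(abs(d - d[1])) > 1e-9) return("bin spacing must be uniform")
  }
  TRUE
})

#' Contrast-response matrix over (target, mask) contrast combinations
#'
#' An n x n grid of response estimates (GLM beta or SSVEP SNR) indexed by
#' the contrast shown to the target eye (rows) and the mask eye (columns).
#'
#' @slot values numeric matrix, target levels x mask levels.
#' @slot levels contrast levels labelling rows and columns (percent).
#' @slot targetEye which eye the rows index: \code{"left"}, \code{"right"},
#'   \code{"fellow"}, \code{"amblyopic"} or \code{"either"} (after
#'   control folding).
#' @slot modality \code{"fmri"}, \code{"eeg"} or \code{"model"}.
#' @slot dispersion optional matrix of per-cell dispersion across
#'   participants (same shape as \code{values}; may be 0 x 0).
#' @export
setClass("CRFMatrix",
  representation(
    values = "matrix",
    levels = "numeric",
    targetEye = "character",
    modality = "character",
    dispersion = "matrix"
  )
)

setValidity("CRFMatrix", function(object) {
  n <- length(object@levels)
  if (!all(dim(object@values) == c(n, n)))
    return("values must be an n x n matrix matching length(levels)")
  if (anyDuplicated(object@levels)) return("levels must be unique")
  if (nrow(object@dispersion) > 0 && !all(dim(object@dispersion) == c(n, n)))
    return("dispersion, when present, must match dim(values)")
  TRUE
})

#' Block-design GLM result
#'
#' Per-voxel regression weights for each condition plus nuisance terms
#' (per-run intercept and linear drift) and residual variance, as returned
#' by [glmBetas()].
#'
#' @slot betas numeric matrix, voxels x conditions.
#' @slot conditions condition labels ("L<contrast>_R<contrast>").
#' @slot nuisance numeric matrix, voxels x nuisance terms.
#' @slot sigma2 per-voxel residual variance.
#' @slot dof residual degrees of freedom.
#' @export
setClass("GLMResult",
  representation(
    betas = "matrix",
    conditions = "character",
    nuisance = "matrix",
    sigma2 = "numeric",
    dof = "numeric"
  )
)

setValidity("GLMResult", function(object) {
  if (ncol(object@betas) != length(object@conditions))
    return("ncol(betas) must equal length(conditions)")
  if (length(object@sigma2) != nrow(object@betas))
    return("sigma2 must have one entry per voxel")
  TRUE
})

#' EEG-like multichannel recording
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay is a
#' channels x samples matrix sampled uniformly at \code{sampleRate(x)} Hz.
#' Channel metadata (10--20 labels, scalp positions, topography weight)
#' live in \code{rowData}; the generating [DichopticSchedule-class] and,
#' for synthetic data, the ground-truth block live in \code{metadata}.
#'
#' @export
setClass("Recording", contains = "SummarizedExperiment")

setValidity("Recording", function(object) {
  md <- metadata(object)
  if (is.null(md$sample_rate) || md$sample_rate <= 0)
    return("metadata$sample_rate must be a positive sampling rate in Hz")
  if (!is.null(md$schedule)) {
    dur <- scheduleDuration(md$schedule)
    if (ncol(object) < round(dur * md$sample_rate))
      return("sample count must cover the schedule duration")
  }
  TRUE
})

#' BOLD-like voxel x TR series
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay is a
#' voxels x TR matrix. \code{metadata} holds \code{TR_s}, the generating
#' schedule and (for synthetic data) the truth block; per-voxel generating
#' truth (pRF parameters, gain) lives in \code{rowData} when present.
#'
#' @export
setClass("VoxelSeries", contains = "SummarizedExperiment")

setValidity("VoxelSeries", function(object) {
  md <- metadata(object)
  if (is.null(md$TR_s) || md$TR_s <= 0)
    return("metadata$TR_s must be a positive repetition time in seconds")
  if (!is.null(md$schedule)) {
    want <- round(scheduleDuration(md$schedule) / md$TR_s)
    if (ncol(object) != want)
      return(sprintf("TR count (%d) must match schedule (%d TRs)", ncol(object), want))
  }
  TRUE
})
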