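#' Generate a synthetic block-design BOLD run
#'
#' Each voxel's series is the schedule's trial boxcars, scaled per trial
#' by the two-stage model response at that trial's contrasts, convolved
#' with the haemodynamic response function, plus a linear drift and AR(1)
#' noise. Voxel gains scatter around 1 so voxels are not identical.
#'
#' @param schedule an fMRI [DichopticSchedule-class].
#' @param params a [ModelParams-class]; per-trial amplitude =
#'   \code{modelResponse(contrast_L, contrast_R, params)}.
#' @param hrf HRF kernel sampled at TR, e.g. from [hrfDoubleGamma()].
#' @param noise list with \code{ar1_rho} (|rho| < 1), \code{sigma}
#'   (marginal SD of the AR(1) component) and \code{drift} (slope, units
#'   per TR, of the linear drift; a per-voxel random sign/scale jitter is
#'   applied).
#' @param nVoxels number of voxels to simulate.
#' @param seed integer seed.
#' @return a [VoxelSeries-class]; \code{metadata(x)$truth} retains the
#'   per-condition generating amplitudes, \code{rowData} the voxel gains.
#' @export
generateBoldRun <- function(schedule, params, hrf = hrfDoubleGamma(schedule@TR_s),
                            noise = list(ar1_rho = 0.3, sigma = 0.5, drift = 0.01),
                            nVoxels = 20, seed = 1) {
  if (abs(noise$ar1_rho) >= 1) stop("AR(1) coefficient must satisfy |rho| < 1")
  TR <- schedule@TR_s
  nTR <- scheduleTRs(schedule)
  ev <- scheduleEvents(schedule)
  trials <- ev[ev$kind == "trial", , drop = FALSE]
  amp <- if (nrow(trials)) modelResponse(trials$contrast_L, trials$contrast_R, params)
         else numeric(0)

  # amplitude-weighted boxcar at TR resolution, convolved with the HRF
  neural <- numeric(nTR)
  for (i in seq_len(nrow(trials))) {
    on <- floor(trials$onset_s[i] / TR) + 1
    off <- min(nTR, ceiling((trials$onset_s[i] + trials$duration_s[i]) / TR))
    neural[on:off] <- neural[on:off] + amp[i]
  }
  clean <- convolveHrf(neural, hrf)

  dat <- withSeed(seed, {
    gains <- 1 + 0.1 * rnorm(nVoxels)
    m <- matrix(0, nVoxels, nTR)
    for (v in seq_len(nVoxels)) {
      drift <- noise$drift * (1 + 0.5 * rnorm(1)) * (seq_len(nTR) - nTR / 2)
      m[v, ] <- gains[v] * clean + drift + ar1Noise(nTR, noise$ar1_rho, noise$sigma)
    }
    attr(m, "gains") <- gains
    m
  })
  gains <- attr(dat, "gains"); attr(dat, "gains") <- NULL
  rownames(dat) <- paste0("v", seq_len(nVoxels))

  truth <- list(
    trial_amplitude = amp,
    condition_amplitude = unique(data.frame(contrast_L = trials$contrast_L,
                                            contrast_R = trials$contrast_R,
                                            amplitude = amp)),
    clean_timecourse = clean
  )
  se <- SummarizedExperiment(
    assays = list(bold = dat),
    rowData = DataFrame(voxel = rownames(dat), gain = gains),
    metadata = list(TR_s = TR, schedule = schedule, truth = truth, seed = seed)
  )
  new("VoxelSeries", se)
}

# causal discrete convolution truncated to the input length
convolveHrf <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (k in seq_along(kernel)) {
    idx <- seq_len(n - k + 1)
    out[idx + k - 1] <- out[idx + k - 1] + kernel[k] * x[idx]
  }
  out
}

#' Drifting-bar aperture sequence for pRF mapping
#'
#' Binary aperture masks, one per TR, for a bar of width \code{barWidth}
#' degrees sweeping across a square field of radius \code{fieldRadius}
#' degrees in four cardinal directions (left-to-right, top-to-bottom,
#' right-to-left, bottom-to-top), \code{stepsPerPass} TRs per pass.
#'
#' @param stepsPerPass TR steps for one sweep across the field.
#' @param fieldRadius half-width of the stimulated field, degrees.
#' @param barWidth bar width, degrees.
#' @param gridRes spatial resolution of the mask grid, degrees.
#' @return list with \code{masks} (TR x pixel binary matrix), \code{x},
#'   \code{y} (pixel-centre coordinates, degrees).
#' @export
barApertureSequence <- function(stepsPerPass = 16, fieldRadius = 6,
                                barWidth = 0.5, gridRes = 0.5) {
  g <- seq(-fieldRadius, fieldRadius, by = gridRes)
  xy <- expand.grid(x = g, y = g, KEEP.OUT.ATTRS = FALSE)
  centres <- seq(-fieldRadius, fieldRadius, length.out = stepsPerPass)
  rows <- list()
  for (dir in c("LR", "TB", "RL", "BT")) {
    cc <- if (dir %in% c("RL", "BT")) rev(centres) else centres
    for (c0 in cc) {
      m <- if (dir %in% c("LR", "RL")) abs(xy$x - c0) <= barWidth / 2
           else abs(xy$y - c0) <= barWidth / 2
      rows[[length(rows) + 1]] <- as.numeric(m)
    }
  }
  masks <- do.call(rbind, rows)
  if (all(colSums(masks) == 0)) stop("degenerate aperture: nothing stimulated")
  list(masks = masks, x = xy$x, y = xy$y)
}

#' Generate synthetic pRF voxel timecourses
#'
#' Each voxel's neural drive at a TR is the integral of its 2D Gaussian
#' receptive field over that TR's bar aperture; the drive is convolved
#' with the HRF and white noise is added.
#'
#' @param aperture list from [barApertureSequence()].
#' @param truths data.frame with columns \code{x0}, \code{y0} (degrees,
#'   within the stimulated field), \code{sigma} (> 0, degrees),
#'   \code{gain}.
#' @param hrf HRF kernel sampled at TR.
#' @param noiseSigma white-noise SD.
#' @param TR_s repetition time (recorded in metadata).
#' @param seed integer seed.
#' @return a [VoxelSeries-class] with the generating truth in
#'   \code{rowData}.
#' @export
generatePrfVoxels <- function(aperture, truths, hrf = hrfDoubleGamma(3),
                              noiseSigma = 0, TR_s = 3, seed = 1) {
  stopifnot(all(c("x0", "y0", "sigma", "gain") %in% names(truths)))
  if (any(truths$sigma <= 0)) stop("pRF sigma must be positive")
  nTR <- nrow(aperture$masks)
  dat <- withSeed(seed, {
    m <- matrix(0, nrow(truths), nTR)
    for (v in seq_len(nrow(truths))) {
      g <- exp(-((aperture$x - truths$x0[v])^2 + (aperture$y - truths$y0[v])^2) /
                 (2 * truths$sigma[v]^2))
      drive <- as.numeric(aperture$masks %*% g)
      m[v, ] <- truths$gain[v] * convolveHrf(drive, hrf) +
        rnorm(nTR, sd = noiseSigma)
    }
    m
  })
  rownames(dat) <- paste0("v", seq_len(nrow(truths)))
  se <- SummarizedExperiment(
    assays = list(bold = dat),
    rowData = DataFrame(truths),
    metadata = list(TR_s = TR_s, truth = truths, seed = seed)
  )
  new("VoxelSeries", se)
}

#' Write / read a multichannel matrix with a truth sidecar
#'
#' Recordings and voxel series are exchanged as tab-separated matrices
#' (rows = channels/voxels) with a YAML sidecar (\code{<path>.yaml})
#' holding the sampling metadata and, for synthetic data, the generating
#' truth.
#'
#' @param x a [Recording-class] or [VoxelSeries-class].
#' @param path path for the matrix file.
#' @return \code{writeSeriesMatrix} returns \code{path} invisibly;
#'   \code{readSeriesMatrix} returns a list with elements \code{data}
#'   (matrix) and \code{meta} (list).
#' @export
writeSeriesMatrix <- function(x, path) {
  a <- assay(x)
  utils::write.table(a, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  md <- metadata(x)
  md$schedule <- NULL  # schedules have their own file format
  yaml::write_yaml(md, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeSeriesMatrix
#' @export
readSeriesMatrix <- function(path) {
  a <- utils::read.table(path, sep = "\t", row.names = 1, header = FALSE)
  list(data = as.matrix(a), meta = yaml::read_yaml(paste0(path, ".yaml")))
}
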