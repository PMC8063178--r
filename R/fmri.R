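#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities sampled at the TR: a positive
#' response peaking near 5 s and an undershoot peaking near 15 s scaled
#' by \code{1/ratio}, normalised to unit sum so convolution preserves the
#' mean block amplitude.
#'
#' @param TR_s sampling interval, seconds.
#' @param peak_s time-to-peak of the positive lobe, seconds.
#' @param undershoot_s time-to-peak of the undershoot, seconds.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param duration_s kernel support, seconds.
#' @return numeric kernel sampled every \code{TR_s}, summing to 1.
#' @export
hrfDoubleGamma <- function(TR_s = 3, peak_s = 5, undershoot_s = 15,
                           ratio = 6, duration_s = 30) {
  t <- seq(0, duration_s, by = TR_s)
  h <- dgamma(t, shape = peak_s + 1, rate = 1) -
    dgamma(t, shape = undershoot_s + 1, rate = 1) / ratio
  h / sum(h)
}

conditionLabel <- function(cl, cr) sprintf("L%g_R%g", cl, cr)

# Condition + nuisance design matrix for one run (rows = kept TRs)
buildDesign <- function(sched, hrf, discardLeadinTRs, conditions) {
  nTR <- scheduleTRs(sched)
  TR <- sched@TR_s
  ev <- scheduleEvents(sched)
  trials <- ev[ev$kind == "trial", , drop = FALSE]
  lab <- conditionLabel(trials$contrast_L, trials$contrast_R)
  X <- matrix(0, nTR, length(conditions),
              dimnames = list(NULL, conditions))
  for (i in seq_len(nrow(trials))) {
    j <- match(lab[i], conditions)
    if (is.na(j)) stop("trial condition not in the condition set: ", lab[i])
    on <- floor(trials$onset_s[i] / TR) + 1
    off <- min(nTR, ceiling((trials$onset_s[i] + trials$duration_s[i]) / TR))
    X[on:off, j] <- X[on:off, j] + 1
  }
  X <- apply(X, 2, convolveHrf, kernel = hrf)
  keep <- seq_len(nTR) > discardLeadinTRs
  list(X = X[keep, , drop = FALSE], keep = keep,
       nuisance = cbind(intercept = 1,
                        drift = seq_len(sum(keep)) - (sum(keep) + 1) / 2))
}

#' Block-design GLM estimation
#'
#' Fits, by ordinary least squares, one regressor per dichoptic condition
#' (trial boxcar convolved with the HRF) plus per-run nuisance terms
#' (intercept and linear drift). The first \code{discardLeadinTRs} TRs of
#' every run are discarded (magnetic saturation), and repeated runs are
#' combined by design concatenation: condition columns are shared across
#' runs, nuisance columns are per-run.
#'
#' @param voxelSeries a [VoxelSeries-class] or list of them (runs); all
#'   runs must share the voxel set.
#' @param hrf HRF kernel sampled at TR, e.g. [hrfDoubleGamma()].
#' @param discardLeadinTRs TRs dropped at the start of each run.
#' @return a [GLMResult-class].
#' @export
glmBetas <- function(voxelSeries, hrf = NULL, discardLeadinTRs = 4) {
  runs <- if (inherits(voxelSeries, "VoxelSeries")) list(voxelSeries)
          else voxelSeries
  sched1 <- schedule(runs[[1]])
  if (is.null(hrf)) hrf <- hrfDoubleGamma(sched1@TR_s)
  ev <- scheduleEvents(sched1)
  tr <- ev[ev$kind == "trial", , drop = FALSE]
  conditions <- unique(conditionLabel(tr$contrast_L, tr$contrast_R))

  Xs <- list(); Ys <- list(); Ns <- list()
  for (r in seq_along(runs)) {
    d <- buildDesign(schedule(runs[[r]]), hrf, discardLeadinTRs, conditions)
    Xs[[r]] <- d$X
    Ys[[r]] <- t(assay(runs[[r]])[, d$keep, drop = FALSE])
    Ns[[r]] <- d$nuisance
  }
  X <- do.call(rbind, Xs)
  Y <- do.call(rbind, Ys)
  # block-diagonal nuisance
  nN <- vapply(Ns, ncol, 0L)
  Nmat <- matrix(0, nrow(X), sum(nN))
  r0 <- 0; c0 <- 0
  for (r in seq_along(Ns)) {
    Nmat[r0 + seq_len(nrow(Ns[[r]])), c0 + seq_len(nN[r])] <- Ns[[r]]
    r0 <- r0 + nrow(Ns[[r]]); c0 <- c0 + nN[r]
  }
  colnames(Nmat) <- paste0(rep(c("intercept", "drift"), length(Ns)),
                           "_run", rep(seq_along(Ns), each = 2))
  D <- cbind(X, Nmat)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[setdiff(seq_len(ncol(D)), qrD$pivot[seq_len(qrD$rank)])]
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- lm.fit(D, Y)
  B <- t(fit$coefficients)
  dof <- nrow(D) - ncol(D)
  res <- Y - D %*% fit$coefficients
  new("GLMResult",
      betas = B[, seq_len(ncol(X)), drop = FALSE],
      conditions = conditions,
      nuisance = B[, -seq_len(ncol(X)), drop = FALSE],
      sigma2 = colSums(res^2) / dof,
      dof = dof)
}

#' Mean GLM betas arranged as a left x right contrast matrix
#'
#' Averages each condition's beta across voxels (optionally a subset,
#' e.g. a localiser-restricted ROI) and arranges the result on the
#' factorial contrast grid.
#'
#' @param glm a [GLMResult-class].
#' @param levels contrast levels of the factorial design.
#' @param voxels optional voxel indices to average over.
#' @return numeric matrix, rows = left-eye contrast, cols = right-eye.
#' @export
betaMatrix <- function(glm, levels = c(0, 6, 24, 48, 96), voxels = NULL) {
  b <- betas(glm)
  if (!is.null(voxels)) b <- b[voxels, , drop = FALSE]
  mb <- colMeans(b)
  out <- matrix(NA_real_, length(levels), length(levels),
                dimnames = list(left = levels, right = levels))
  for (i in seq_along(levels)) for (j in seq_along(levels)) {
    lab <- conditionLabel(levels[i], levels[j])
    if (lab %in% names(mb)) out[i, j] <- mb[lab]
  }
  out
}

#' Travelling-wave coherence and phase
#'
#' For each voxel, the Fourier amplitude at the stimulus repetition
#' frequency (\code{nCycles} cycles per run) divided by the
#' root-sum-square of amplitudes over the analysis band -- all bins from
#' \code{driftCutoffBins} up to the Nyquist bin. The phase of the
#' response at that frequency is returned in \code{[0, 2*pi)}. Coherence
#' is invariant to amplitude scaling of the series and to the phase of
#' its stimulus-frequency component.
#'
#' @param voxelSeries a [VoxelSeries-class].
#' @param nCycles stimulus repetitions per run (signal bin index in
#'   cycles/run).
#' @param driftCutoffBins lowest bin (cycles/run) included in the band;
#'   bins below this are treated as drift and excluded.
#' @return data.frame with columns \code{voxel}, \code{coherence},
#'   \code{phase}.
#' @export
coherencePhase <- function(voxelSeries, nCycles, driftCutoffBins = 2) {
  a <- assay(voxelSeries)
  nTR <- ncol(a)
  if (nCycles < driftCutoffBins || nCycles > floor(nTR / 2))
    stop("nCycles must lie inside the analysis band")
  co <- stats::mvfft(t(a))                 # nTR x voxels
  band <- (driftCutoffBins + 1):(floor(nTR / 2) + 1)
  ampBand <- Mod(co[band, , drop = FALSE])
  sig <- co[nCycles + 1, ]
  coh <- Mod(sig) / sqrt(colSums(ampBand^2))
  ph <- Arg(sig) %% (2 * pi)
  data.frame(voxel = rownames(a), coherence = as.numeric(coh),
             phase = as.numeric(ph), stringsAsFactors = FALSE)
}

#' Fit population receptive fields
#'
#' Estimates, per voxel, the centre and size of the 2D Gaussian receptive
#' field that best predicts the BOLD timecourse given the bar aperture
#' sequence: the predicted neural drive is the aperture-masked integral
#' of the Gaussian, convolved with the HRF; gain and offset are solved
#' analytically per candidate. A coarse grid search (positions on a
#' \code{gridStep}-degree lattice over the field, log-spaced sigmas) is
#' followed by Nelder-Mead refinement of the best candidate; grid ties
#' are broken towards the smallest sigma.
#'
#' @param voxelSeries a [VoxelSeries-class].
#' @param aperture list from [barApertureSequence()].
#' @param hrf HRF kernel sampled at TR.
#' @param gridStep coarse lattice spacing for x0/y0, degrees.
#' @param fieldRadius search field half-width, degrees.
#' @param sigmas candidate sigmas, degrees (log-spaced by default).
#' @return data.frame with columns \code{voxel}, \code{x0}, \code{y0},
#'   \code{sigma}, \code{ve} (variance explained in [0, 1]).
#' @export
fitPrf <- function(voxelSeries, aperture, hrf = hrfDoubleGamma(3),
                   gridStep = 0.25, fieldRadius = 6,
                   sigmas = exp(seq(log(0.25), log(4), length.out = 8))) {
  if (all(colSums(aperture$masks) == 0))
    stop("degenerate aperture: nothing is ever stimulated")
  a <- assay(voxelSeries)
  nTR <- ncol(a)
  if (nrow(aperture$masks) != nTR)
    stop("aperture sequence length must match the TR count")
  H <- hrfConvMatrix(nTR, hrf)

  cand <- expand.grid(
    x0 = seq(-fieldRadius, fieldRadius, by = gridStep),
    y0 = seq(-fieldRadius, fieldRadius, by = gridStep),
    sigma = sigmas, KEEP.OUT.ATTRS = FALSE)
  # order so that ties resolve to the smallest sigma
  cand <- cand[order(cand$sigma), ]
  G <- exp(-(outer(aperture$x, cand$x0, "-")^2 +
             outer(aperture$y, cand$y0, "-")^2) /
            (2 * matrix(cand$sigma^2, length(aperture$x), nrow(cand),
                        byrow = TRUE)))
  P <- H %*% (aperture$masks %*% G)     # nTR x candidates, predicted BOLD
  Pc <- sweep(P, 2, colMeans(P))
  Pn2 <- colSums(Pc^2)

  out <- data.frame(voxel = rownames(a), x0 = NA_real_, y0 = NA_real_,
                    sigma = NA_real_, ve = NA_real_,
                    stringsAsFactors = FALSE)
  predFun <- function(par, y) {
    g <- exp(-((aperture$x - par[1])^2 + (aperture$y - par[2])^2) /
               (2 * par[3]^2))
    p <- as.numeric(H %*% (aperture$masks %*% g))
    pc <- p - mean(p)
    ss <- sum(pc^2)
    yc <- y - mean(y)
    if (ss < 1e-12) return(sum(yc^2))
    sum(yc^2) - sum(pc * yc)^2 / ss     # RSS with gain+offset solved out
  }
  for (v in seq_len(nrow(a))) {
    y <- a[v, ]
    yc <- y - mean(y)
    tss <- sum(yc^2)
    if (tss == 0) { out[v, c("x0", "y0", "sigma", "ve")] <- c(0, 0, sigmas[1], 0); next }
    num <- as.numeric(crossprod(Pc, yc))^2
    r2 <- ifelse(Pn2 > 1e-12, num / (Pn2 * tss), 0)
    best <- which.max(r2)               # first max = smallest sigma on ties
    p0 <- as.numeric(cand[best, c("x0", "y0", "sigma")])
    opt <- optim(p0, predFun, y = y, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-10))
    par <- opt$par
    # keep the refinement only if it stayed in-range and improved
    inRange <- abs(par[1]) <= fieldRadius + 1 && abs(par[2]) <= fieldRadius + 1 &&
      par[3] > 0.01 && par[3] <= 3 * max(sigmas)
    if (!inRange || opt$value > predFun(p0, y)) par <- p0
    rss <- predFun(par, y)
    out[v, c("x0", "y0", "sigma")] <- par
    out$ve[v] <- max(0, 1 - rss / tss)
  }
  out
}

# Lower-triangular Toeplitz convolution matrix for an HRF kernel
hrfConvMatrix <- function(n, kernel) {
  H <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    idx <- seq_len(n - k + 1)
    H[cbind(idx + k - 1, idx)] <- kernel[k]
  }
  H
}

#' Restrict an ROI by coherence and variance explained
#'
#' Retains voxels whose localiser coherence strictly exceeds
#' \code{coherenceMin} (a coherence of exactly 0.3 is excluded) and, when
#' a \code{ve} column is present, whose pRF variance explained is at
#' least \code{veMin}. Selection is idempotent and order-independent.
#'
#' @param metrics data.frame with a \code{coherence} column and
#'   optionally a \code{ve} column (as from [coherencePhase()] /
#'   [fitPrf()], merged by voxel).
#' @param coherenceMin coherence threshold (strict inequality).
#' @param veMin variance-explained threshold (inclusive).
#' @return integer indices of retained rows; a warning is raised when the
#'   input or the result is empty.
#' @export
selectRoi <- function(metrics, coherenceMin = 0.3, veMin = 0.10) {
  if (nrow(metrics) == 0) {
    warning("empty metrics table: ROI is empty")
    return(integer(0))
  }
  keep <- metrics$coherence > coherenceMin
  if ("ve" %in% names(metrics)) keep <- keep & metrics$ve >= veMin
  idx <- which(keep)
  if (!length(idx)) warning("no voxels survive the ROI thresholds")
  message(sprintf("ROI restriction: %d of %d voxels retained", length(idx),
                  nrow(metrics)))
  idx
}

#' Trial-triggered percent-signal-change timecourse
#'
#' Averages the ROI-mean series over all trials matching a condition
#' filter, expressed as percent signal change per TR relative to trial
#' onset. The baseline is the mean of the \code{preTRs} TRs immediately
#' before onset; when that baseline is not positive (e.g. drift-free
#' zero-mean synthetic data), the series mean is used as the divisor
#' instead so the measure stays defined.
#'
#' @param voxelSeries a [VoxelSeries-class].
#' @param contrast_L,contrast_R condition filter; \code{NULL} matches any.
#' @param voxels optional voxel subset (e.g. from [selectRoi()]).
#' @param preTRs baseline TRs before onset (also plotted).
#' @param postTRs TRs after trial offset to include.
#' @return data.frame with \code{tr} (TR index relative to onset),
#'   \code{time_s}, \code{pct_change} (mean across matching trials) and
#'   \code{n_trials}.
#' @export
trialTriggeredTimecourse <- function(voxelSeries, contrast_L = NULL,
                                     contrast_R = NULL, voxels = NULL,
                                     preTRs = 4, postTRs = 4) {
  sched <- schedule(voxelSeries)
  TR <- sched@TR_s
  a <- assay(voxelSeries)
  if (!is.null(voxels)) a <- a[voxels, , drop = FALSE]
  series <- colMeans(a)
  ev <- scheduleEvents(sched)
  tr <- ev[ev$kind == "trial", , drop = FALSE]
  if (!is.null(contrast_L)) tr <- tr[tr$contrast_L == contrast_L, , drop = FALSE]
  if (!is.null(contrast_R)) tr <- tr[tr$contrast_R == contrast_R, , drop = FALSE]
  if (nrow(tr) == 0) stop("no trials match the condition filter")
  lens <- unique(round(tr$duration_s / TR))
  span <- (-preTRs):(max(lens) + postTRs - 1)
  acc <- matrix(NA_real_, nrow(tr), length(span))
  for (i in seq_len(nrow(tr))) {
    onTR <- round(tr$onset_s[i] / TR)
    idx <- onTR + span + 1
    ok <- idx >= 1 & idx <= length(series)
    x <- rep(NA_real_, length(span))
    x[ok] <- series[idx[ok]]
    base <- mean(series[onTR + ((-preTRs):(-1)) + 1], na.rm = TRUE)
    div <- if (is.finite(base) && base > 0) base else mean(series)
    if (!is.finite(div) || div == 0) div <- 1
    acc[i, ] <- 100 * (x - base) / div
  }
  data.frame(tr = span, time_s = span * TR,
             pct_change = colMeans(acc, na.rm = TRUE),
             n_trials = colSums(!is.na(acc)))
}
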