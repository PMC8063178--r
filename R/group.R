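#' Assemble a contrast-response matrix with eye-role handling
#'
#' Takes the raw left-eye x right-eye response grid (betas or SNRs) and
#' produces a [CRFMatrix-class] in one of two modes. \code{"control-fold"}
#' averages each cell with its mirror -- complementary conditions for the
#' left and right eyes -- as appropriate when neither eye is special.
#' \code{"patient-roles"} relabels the axes by the participant's
#' amblyopic eye without averaging: the same numbers are re-ordered so
#' that rows index the chosen target role. Re-ordering is a pure
#' permutation (a transpose), hence involutive.
#'
#' @param m numeric matrix, rows = left-eye contrast, cols = right-eye
#'   contrast (as from [betaMatrix()] or [conditionSnrMatrix()]).
#' @param levels contrast levels labelling the grid.
#' @param mode \code{"control-fold"} or \code{"patient-roles"}.
#' @param amblyopicEye for patient mode, which eye is amblyopic.
#' @param targetRole for patient mode, the role the rows should index.
#' @param modality recorded in the result.
#' @return a [CRFMatrix-class].
#' @export
assembleCrf <- function(m, levels = as.numeric(rownames(m)),
                        mode = c("control-fold", "patient-roles"),
                        amblyopicEye = c("left", "right"),
                        targetRole = c("fellow", "amblyopic"),
                        modality = "fmri") {
  mode <- match.arg(mode)
  amblyopicEye <- match.arg(amblyopicEye)
  targetRole <- match.arg(targetRole)
  if (any(is.na(m))) stop("missing cells are not allowed in the CRF grid")
  if (mode == "control-fold") {
    v <- (m + t(m)) / 2
    eye <- "either"
  } else {
    # rows must index the target role's eye
    targetIsLeft <- (amblyopicEye == "left") == (targetRole == "amblyopic")
    v <- if (targetIsLeft) m else t(m)
    eye <- targetRole
  }
  dimnames(v) <- NULL
  new("CRFMatrix", values = v, levels = as.numeric(levels), targetEye = eye,
      modality = modality, dispersion = matrix(numeric(0), 0, 0))
}

#' Swap the target/mask roles of a CRF matrix
#'
#' Transposes the grid and swaps the role label; applying it twice
#' restores the original object.
#'
#' @param crf a [CRFMatrix-class].
#' @return the role-swapped [CRFMatrix-class].
#' @export
swapRoles <- function(crf) {
  other <- c(fellow = "amblyopic", amblyopic = "fellow",
             left = "right", right = "left", either = "either")
  crf@values <- t(crf@values)
  crf@targetEye <- unname(other[crf@targetEye])
  crf
}

#' Dichoptic suppression contrast across participants
#'
#' For each participant, the dip difference
#' \eqn{\Delta = R(\mathrm{target}=0, \mathrm{mask}=max) -
#' R(\mathrm{target}=low, \mathrm{mask}=max)} -- positive when adding a
#' weak target to a strong mask *reduces* the response -- followed by a
#' paired t-test of \eqn{\Delta} against zero with Cohen's
#' \eqn{d = \bar\Delta / s_\Delta}.
#'
#' @param crfs list of [CRFMatrix-class], one per participant, on a
#'   common level grid and role ordering.
#' @param lowLevel the weak target contrast (percent).
#' @param maxLevel the strong mask contrast (percent); default the
#'   highest level.
#' @return list with \code{delta} (per participant), \code{mean_delta},
#'   \code{t}, \code{df}, \code{p}, \code{d}, \code{degenerate} (TRUE
#'   when all deltas are identical and nonzero, so t is undefined).
#' @export
suppressionContrast <- function(crfs, lowLevel = 6, maxLevel = NULL) {
  stopifnot(length(crfs) >= 1)
  lev <- crfLevels(crfs[[1]])
  if (is.null(maxLevel)) maxLevel <- max(lev)
  iZero <- match(0, lev); iLow <- match(lowLevel, lev); jMax <- match(maxLevel, lev)
  if (anyNA(c(iZero, iLow, jMax))) stop("levels not found in the CRF grid")
  delta <- vapply(crfs, function(crf) {
    v <- crf@values
    v[iZero, jMax] - v[iLow, jMax]
  }, 0)
  mD <- mean(delta); sD <- sd(delta)
  n <- length(delta)
  if (n < 2 || is.na(sD)) sD <- NA_real_
  degenerate <- FALSE
  if (!is.na(sD) && sD == 0) {
    if (mD == 0) {
      tval <- 0; pval <- 1; dval <- 0
    } else {
      degenerate <- TRUE
      tval <- NA_real_; pval <- NA_real_; dval <- NA_real_
      warning("zero-variance nonzero suppression differences: t undefined")
    }
  } else if (is.na(sD)) {
    tval <- NA_real_; pval <- NA_real_; dval <- NA_real_
  } else {
    tval <- mD / (sD / sqrt(n))
    pval <- 2 * pt(-abs(tval), df = n - 1)
    dval <- mD / sD
  }
  list(delta = delta, mean_delta = mD, t = tval, df = n - 1, p = pval,
       d = dval, degenerate = degenerate)
}

#' Repeated-measures ANOVA over a cohort of CRF matrices
#'
#' Two-way repeated-measures ANOVA with target level and mask level as
#' within-participant factors, reporting F, degrees of freedom, p and
#' the omega-squared effect size
#' \deqn{\omega^2 = (SS_{eff} - df_{eff} MS_{err}) / (SS_{total} + MS_{err})}
#' per main effect and the interaction (each effect's own error stratum
#' supplies its \eqn{MS_{err}}). No sphericity correction is applied;
#' uncorrected degrees of freedom are reported.
#'
#' @param crfs list of [CRFMatrix-class], one per participant.
#' @param effectNames length-2 labels for the two factors in the output
#'   table (target first).
#' @return data.frame with columns \code{effect}, \code{F},
#'   \code{df1}, \code{df2}, \code{p}, \code{omega_sq}.
#' @export
crfAnova <- function(crfs, effectNames = c("target contrast", "mask contrast")) {
  stopifnot(length(crfs) >= 2)
  lev <- crfLevels(crfs[[1]])
  n <- length(lev)
  long <- do.call(rbind, lapply(seq_along(crfs), function(s) {
    v <- crfs[[s]]@values
    data.frame(subject = factor(s),
               target = factor(rep(lev, times = n), levels = lev),
               mask = factor(rep(lev, each = n), levels = lev),
               y = as.numeric(v))
  }))
  fit <- aov(y ~ target * mask + Error(subject / (target * mask)), data = long)
  sm <- summary(fit)
  ssTotal <- sum((long$y - mean(long$y))^2)
  grab <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    ie <- match("Residuals", trimws(rownames(tab)))
    c(F = tab$`F value`[i], df1 = tab$Df[i], df2 = tab$Df[ie],
      p = tab$`Pr(>F)`[i],
      omega = (tab$`Sum Sq`[i] - tab$Df[i] * tab$`Mean Sq`[ie]) /
        (ssTotal + tab$`Mean Sq`[ie]))
  }
  rows <- rbind(
    grab("Error: subject:target", "target"),
    grab("Error: subject:mask", "mask"),
    grab("Error: subject:target:mask", "target:mask"))
  data.frame(effect = c(effectNames, "interaction"),
             F = rows[, "F"], df1 = rows[, "df1"], df2 = rows[, "df2"],
             p = rows[, "p"], omega_sq = rows[, "omega"],
             row.names = NULL)
}

#' Fit model variants to a contrast-response matrix
#'
#' Bounded nonlinear least squares of the two-stage model against the 25
#' CRF cells, for each requested variant. Free parameters: baseline
#' \{responseGain, Z\}; tonic adds the affected eye's attenuation;
#' dynamic adds a multiplier (>= 1) on the suppression weight from the
#' affected eye onto the other. Gain and Z are fitted on a log scale.
#' Optimisation uses L-BFGS-B from a seeded multi-start grid; variants
#' are ranked by AIC computed with the cell count as n (AICc is also
#' reported).
#'
#' @param crf a [CRFMatrix-class] on the raw left x right grid
#'   (\code{targetEye} "left" or "right") or a plain matrix with level
#'   rownames (rows = left-eye contrast).
#' @param variants subset of \code{c("baseline", "tonic", "dynamic")}.
#' @param affectedEye eye carrying the deficit for tonic/dynamic.
#' @param base fixed model constants (a [ModelParams-class]); only the
#'   free parameters above are fitted.
#' @param nStarts multi-start count.
#' @param seed integer seed for the start grid.
#' @return list with one element per variant -- each a list with
#'   \code{params} (fitted [ModelParams-class]), \code{magnitude} (the
#'   fitted attenuation or multiplier, NA for baseline), \code{rss},
#'   \code{aic}, \code{aicc}, \code{converged} -- plus an attribute
#'   \code{"ranking"} with variants ordered by AIC.
#' @export
fitModelToCrf <- function(crf, variants = c("baseline", "tonic", "dynamic"),
                          affectedEye = c("left", "right"),
                          base = modelParams(), nStarts = 8, seed = 1) {
  affectedEye <- match.arg(affectedEye)
  if (inherits(crf, "CRFMatrix")) {
    if (!crf@targetEye %in% c("left", "right", "either"))
      stop("fit the raw left/right grid, not a role-reordered view")
    m <- crf@values
    lev <- crf@levels
    rowsAreLeft <- crf@targetEye != "right"
  } else {
    m <- crf; lev <- as.numeric(rownames(crf)); rowsAreLeft <- TRUE
  }
  if (!rowsAreLeft) m <- t(m)      # rows = left eye from here on
  y <- as.numeric(m)
  cl <- rep(lev, times = length(lev))
  cr <- rep(lev, each = length(lev))
  nCells <- length(y)

  # slot assignment instead of applyVariant(): this runs inside optim and
  # the box bounds already guarantee validity
  predict <- function(theta, variant) {
    p <- base
    p@responseGain <- exp(theta[1])
    p@Z <- exp(theta[2])
    if (variant == "tonic") {
      if (affectedEye == "left") p@attenL <- theta[3] else p@attenR <- theta[3]
    } else if (variant == "dynamic") {
      if (affectedEye == "left") p@omegaLtoR <- base@omegaLtoR * theta[3]
      else p@omegaRtoL <- base@omegaRtoL * theta[3]
    }
    modelResponse(cl, cr, p)
  }
  loss <- function(theta, variant) {
    r <- try(sum((y - predict(theta, variant))^2), silent = TRUE)
    if (inherits(r, "try-error") || !is.finite(r)) return(1e12)
    r
  }

  scaleGuess <- log(max(mean(y[y > 0]), 1e-6))
  fits <- list()
  for (variant in variants) {
    k <- if (variant == "baseline") 2L else 3L
    lower <- c(scaleGuess - 12, log(1e-4), if (k == 3) {
      if (variant == "tonic") 0.05 else 1 })
    upper <- c(scaleGuess + 12, log(1e6), if (k == 3) {
      if (variant == "tonic") 1 else 50 })
    starts <- withSeed(seed, {
      s <- matrix(runif(nStarts * k), nStarts, k)
      sweep(sweep(s, 2, upper - lower, "*"), 2, lower, "+")
    })
    starts[1, 1:2] <- c(scaleGuess, log(base@Z))
    if (k == 3) starts[1, 3] <- if (variant == "tonic") 1 else 1
    best <- NULL
    conv <- FALSE
    for (si in seq_len(nStarts)) {
      o <- try(optim(starts[si, ], loss, variant = variant,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500)), silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value) best <- o
      if (o$convergence == 0) conv <- TRUE
    }
    if (is.null(best)) stop("optimisation failed for variant ", variant)
    rss <- best$value
    # AIC with gaussian errors; +1 parameter for the error variance
    kAic <- k + 1
    aic <- nCells * log(max(rss, 1e-300) / nCells) + 2 * kAic
    aicc <- aic + 2 * kAic * (kAic + 1) / max(nCells - kAic - 1, 1)
    pFit <- base
    pFit@responseGain <- exp(best$par[1]); pFit@Z <- exp(best$par[2])
    mag <- NA_real_
    if (k == 3) {
      mag <- best$par[3]
      pFit <- applyVariant(pFit, variant, mag, affectedEye)
    }
    fits[[variant]] <- list(params = pFit, magnitude = mag, rss = rss,
                            aic = aic, aicc = aicc, converged = conv)
  }
  aics <- vapply(fits, `[[`, 0, "aic")
  attr(fits, "ranking") <- names(sort(aics))
  fits
}
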