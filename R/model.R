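#' Construct a two-stage model parameter set
#'
#' The defaults implement the standard two-stage binocular contrast
#' gain-control parameterisation: excitatory exponent m = 1.28 with
#' stage-1 semisaturation S = 0.985 (percent contrast), stage-2 exponents
#' p = 7.99 and q = 6.59 with Z = 0.076, unit interocular suppression
#' weights, no attenuation, unit output gain. With these values the
#' monocular contrast-response function is monotonic and a high-contrast
#' mask produces the characteristic dip when a low-contrast target is
#' added to the other eye.
#'
#' @param m,p,q,S,Z model constants (see [ModelParams-class]).
#' @param omegaLtoR,omegaRtoL directional interocular suppression weights.
#' @param attenL,attenR per-eye input attenuation, in (0, 1].
#' @param responseGain output scale mapping model response to measurement
#'   units (beta or SNR).
#' @return a validated [ModelParams-class] object.
#' @examples
#' p <- modelParams()
#' modelResponse(96, 0, p)
#' @export
modelParams <- function(m = 1.28, p = 7.99, q = 6.59, S = 0.985, Z = 0.076,
                        omegaLtoR = 1, omegaRtoL = 1,
                        attenL = 1, attenR = 1, responseGain = 1) {
  new("ModelParams", m = m, p = p, q = q, S = S, Z = Z,
      omegaLtoR = omegaLtoR, omegaRtoL = omegaRtoL,
      attenL = attenL, attenR = attenR, responseGain = responseGain)
}

checkContrast <- function(C, what = "contrast") {
  if (any(!is.finite(C)) || any(C < 0) || any(C > 100))
    stop(what, " must be a Michelson contrast in [0, 100] percent, got: ",
         paste(format(C), collapse = ", "))
  invisible(C)
}

#' Stage-1 monocular drive under interocular suppression
#'
#' Computes the stage-1 output for one eye:
#' \deqn{S_1 = \frac{(a\,C_{self})^m}{S + a\,C_{self} + \omega\, a'\,C_{other}}}
#' where \eqn{a} and \eqn{a'} are the attenuation factors of the eye
#' itself and of the other eye, and \eqn{\omega} is the weight of
#' suppression from the other eye onto this one. Attenuation is applied
#' to an eye's contrast before both its excitatory and its suppressive
#' use, so an attenuated eye both responds less and suppresses less.
#'
#' @param C_self contrast in the eye being computed, percent (0--100).
#' @param C_other contrast in the other eye, percent.
#' @param params a [ModelParams-class] object.
#' @param eye which eye \code{C_self} belongs to: \code{"left"} or
#'   \code{"right"}.
#' @return non-negative scalar stage-1 drive; 0 when \code{C_self} is 0.
#' @export
eyeDrive <- function(C_self, C_other, params, eye = c("left", "right")) {
  eye <- match.arg(eye)
  checkContrast(C_self, "C_self")
  checkContrast(C_other, "C_other")
  validObject(params)
  .eyeDrive(C_self, C_other, params, eye)
}

.eyeDrive <- function(C_self, C_other, params, eye) {
  if (eye == "left") {
    a <- params@attenL; aOther <- params@attenR; w <- params@omegaRtoL
  } else {
    a <- params@attenR; aOther <- params@attenL; w <- params@omegaLtoR
  }
  cs <- a * C_self
  co <- aOther * C_other
  cs^params@m / (params@S + cs + w * co)
}

#' Binocular response of the two-stage model
#'
#' Sums the two stage-1 drives binocularly, \eqn{B = S_{1,L} + S_{1,R}},
#' and applies the second gain-control stage:
#' \deqn{R = g \frac{B^p}{Z + B^q}.}
#' The response is deterministic, continuous in both contrasts, zero for
#' zero input, and monotonically increasing along the monocular axis for
#' the default parameterisation.
#'
#' @param C_L,C_R left- and right-eye Michelson contrasts, percent
#'   (0--100). Vectorised over contrast pairs.
#' @param params a [ModelParams-class] object.
#' @return non-negative response in \code{responseGain} units.
#' @examples
#' p <- modelParams()
#' # dichoptic dip: adding a weak target to a strong mask lowers the response
#' modelResponse(6, 96, p) < modelResponse(0, 96, p)
#' @export
modelResponse <- function(C_L, C_R, params) {
  checkContrast(C_L, "C_L")
  checkContrast(C_R, "C_R")
  B <- .eyeDrive(C_L, C_R, params, "left") + .eyeDrive(C_R, C_L, params, "right")
  out <- params@responseGain * B^params@p / (params@Z + B^params@q)
  if (any(!is.finite(out)))
    stop("non-finite model response; check Z > 0 and exponents")
  out
}

#' Derive a tonic- or dynamic-suppression variant of a parameter set
#'
#' \code{"tonic"} models a fixed attenuation of the affected eye's input
#' prior to any other processing: its signal is weakened both as an
#' excitatory drive and as a source of suppression, regardless of what
#' the other eye sees. \code{"dynamic"} scales the suppressive weight
#' FROM the affected eye ONTO the other eye, so monocular predictions
#' are untouched but dichoptic suppression of the other eye deepens with
#' mask contrast. (The empirical direction in impaired binocular vision
#' is the weaker eye suppressing the dominant eye more strongly.)
#' \code{"baseline"} returns the parameters unchanged.
#'
#' @param params a [ModelParams-class] object.
#' @param variant \code{"baseline"}, \code{"tonic"} or \code{"dynamic"}.
#' @param magnitude for tonic, the attenuation factor in (0, 1]; for
#'   dynamic, the multiplier (>= 1) applied to the directional
#'   suppression weight. Ignored for baseline.
#' @param affectedEye the eye carrying the deficit.
#' @return a new [ModelParams-class] object.
#' @examples
#' weakLeft <- applyVariant(modelParams(), "tonic", 0.6, "left")
#' @export
applyVariant <- function(params, variant = c("baseline", "tonic", "dynamic"),
                         magnitude = 1, affectedEye = c("left", "right")) {
  variant <- match.arg(variant)
  affectedEye <- match.arg(affectedEye)
  validObject(params)
  if (variant == "baseline") return(params)
  if (!is.finite(magnitude)) stop("magnitude must be finite")
  if (variant == "tonic") {
    if (magnitude <= 0 || magnitude > 1)
      stop("tonic magnitude is an attenuation factor and must lie in (0, 1]")
    if (affectedEye == "left") params@attenL <- magnitude
    else params@attenR <- magnitude
  } else {
    if (magnitude < 1)
      stop("dynamic magnitude is a suppression multiplier and must be >= 1")
    if (affectedEye == "left") params@omegaLtoR <- params@omegaLtoR * magnitude
    else params@omegaRtoL <- params@omegaRtoL * magnitude
  }
  validObject(params)
  params
}

#' Predict a full dichoptic contrast-response matrix
#'
#' Evaluates the model over the factorial crossing of target and mask
#' contrasts: entry (i, j) is the response with target level i in
#' \code{targetEye} and mask level j in the other eye. The first column
#' (mask = 0) is the monocular contrast-response function.
#'
#' @param params a [ModelParams-class] object.
#' @param levels contrast levels in percent, sorted ascending, first 0.
#' @param targetEye which eye receives the target contrasts.
#' @return a [CRFMatrix-class] with \code{modality = "model"}.
#' @examples
#' predictCrfMatrix(modelParams(), c(0, 6, 24, 48, 96))
#' @export
predictCrfMatrix <- function(params, levels = c(0, 6, 24, 48, 96),
                             targetEye = c("left", "right")) {
  targetEye <- match.arg(targetEye)
  if (anyDuplicated(levels)) stop("contrast levels must be unique")
  if (is.unsorted(levels)) stop("levels must be sorted ascending")
  if (levels[1] != 0) stop("the first level must be 0 (monocular baseline)")
  checkContrast(levels, "levels")
  n <- length(levels)
  tl <- rep(levels, times = n)   # target varies down rows
  ml <- rep(levels, each = n)    # mask varies across columns
  v <- if (targetEye == "left") modelResponse(tl, ml, params)
       else modelResponse(ml, tl, params)
  new("CRFMatrix", values = matrix(v, n, n), levels = as.numeric(levels),
      targetEye = targetEye, modality = "model",
      dispersion = matrix(numeric(0), 0, 0))
}
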