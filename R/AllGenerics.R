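#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes. Accessors are the
#' supported way to read object contents; slots are internal.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scheduleEvents", function(x) standardGeneric("scheduleEvents"))

#' @rdname accessors
#' @export
setGeneric("scheduleDuration", function(x) standardGeneric("scheduleDuration"))

#' @rdname accessors
#' @export
setGeneric("scheduleTRs", function(x) standardGeneric("scheduleTRs"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' @rdname accessors
#' @export
setGeneric("truthBlock", function(x) standardGeneric("truthBlock"))

#' @rdname accessors
#' @export
setGeneric("binResolution", function(x) standardGeneric("binResolution"))

#' @rdname accessors
#' @export
setGeneric("crfValues", function(x) standardGeneric("crfValues"))

#' @rdname accessors
#' @export
setGeneric("crfLevels", function(x) standardGeneric("crfLevels"))

#' @rdname accessors
#' @export
setGeneric("targetEye", function(x) standardGeneric("targetEye"))

#' @rdname accessors
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' @export
#' @rdname accessors
setMethod("scheduleEvents", "DichopticSchedule", function(x) x@events)

#' @export
#' @rdname accessors
setMethod("scheduleDuration", "DichopticSchedule", function(x) {
  ev <- x@events
  if (nrow(ev) == 0) return(0)
  max(ev$onset_s + ev$duration_s)
})

#' @export
#' @rdname accessors
setMethod("scheduleTRs", "DichopticSchedule", function(x) {
  if (is.na(x@TR_s)) stop("schedule has no TR (modality '", x@modality, "')")
  as.integer(round(scheduleDuration(x) / x@TR_s))
})

#' @export
#' @rdname accessors
setMethod("sampleRate", "Recording", function(x) metadata(x)$sample_rate)

#' @export
#' @rdname accessors
setMethod("schedule", "Recording", function(x) metadata(x)$schedule)

#' @export
#' @rdname accessors
setMethod("schedule", "VoxelSeries", function(x) metadata(x)$schedule)

#' @export
#' @rdname accessors
setMethod("truthBlock", "Recording", function(x) metadata(x)$truth)

#' @export
#' @rdname accessors
setMethod("truthBlock", "VoxelSeries", function(x) metadata(x)$truth)

#' @export
#' @rdname accessors
setMethod("binResolution", "Spectrum", function(x) 1 / x@windowLen_s)

#' @export
#' @rdname accessors
setMethod("crfValues", "CRFMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(target = x@levels, mask = x@levels)
  v
})

#' @export
#' @rdname accessors
setMethod("crfLevels", "CRFMatrix", function(x) x@levels)

#' @export
#' @rdname accessors
setMethod("targetEye", "CRFMatrix", function(x) x@targetEye)

#' @export
#' @rdname accessors
setMethod("betas", "GLMResult", function(x) {
  b <- x@betas
  colnames(b) <- x@conditions
  b
})

setMethod("show", "ModelParams", function(object) {
  cat("Two-stage binocular gain-control parameters\n")
  cat(sprintf("  stage 1: m = %.3g, S = %.3g; omega L->R = %.3g, R->L = %.3g\n",
              object@m, object@S, object@omegaLtoR, object@omegaRtoL))
  cat(sprintf("  stage 2: p = %.3g, q = %.3g, Z = %.3g\n",
              object@p, object@q, object@Z))
  cat(sprintf("  attenuation: left = %.3g, right = %.3g; response gain = %.3g\n",
              object@attenL, object@attenR, object@responseGain))
})

setMethod("show", "DichopticSchedule", function(object) {
  ev <- object@events
  cat(sprintf("DichopticSchedule (%s): %d events, %g s total",
              object@modality, nrow(ev), scheduleDuration(object)))
  if (!is.na(object@TR_s))
    cat(sprintf(" (%d TRs at TR = %g s)", scheduleTRs(object), object@TR_s))
  cat("\n")
  cat(sprintf("  %d trials, levels {%s}, ordering seed %s\n",
              sum(ev$kind == "trial"), paste(object@levels, collapse = ", "),
              format(object@seed)))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d bins at %.3g Hz resolution, %d channel(s), n averaged = %g\n",
              length(object@freq), binResolution(object),
              ncol(object@amp), object@nAveraged))
})

setMethod("show", "CRFMatrix", function(object) {
  cat(sprintf("CRFMatrix (%s): target eye = %s\n", object@modality, object@targetEye))
  print(round(crfValues(object), 4))
})

setMethod("show", "GLMResult", function(object) {
  cat(sprintf("GLMResult: %d voxels x %d conditions (+%d nuisance), residual df = %g\n",
              nrow(object@betas), ncol(object@betas),
              ncol(object@nuisance), object@dof))
})
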