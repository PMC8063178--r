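#' Serialise model parameters to / from a flat YAML config
#'
#' @param params a [ModelParams-class].
#' @param path file path (".yaml" by convention).
#' @return \code{writeModelParams} returns \code{path} invisibly;
#'   \code{readModelParams} returns a validated [ModelParams-class].
#' @export
writeModelParams <- function(params, path) {
  validObject(params)
  yaml::write_yaml(list(
    m = params@m, p = params@p, q = params@q, S = params@S, Z = params@Z,
    omegaLtoR = params@omegaLtoR, omegaRtoL = params@omegaRtoL,
    attenL = params@attenL, attenR = params@attenR,
    responseGain = params@responseGain), path)
  invisible(path)
}

#' @rdname writeModelParams
#' @export
readModelParams <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(modelParams, v)
}

#' Write / read a CRF matrix as delimited text
#'
#' Tab-separated grid with a header row of mask levels and a header
#' column of target levels; commented lines record the target-eye role
#' and modality.
#'
#' @param crf a [CRFMatrix-class].
#' @param path file path.
#' @return \code{writeCrfMatrix} returns \code{path} invisibly;
#'   \code{readCrfMatrix} returns the reconstructed [CRFMatrix-class].
#' @export
writeCrfMatrix <- function(crf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# target_eye: %s", crf@targetEye),
               sprintf("# modality: %s", crf@modality)), con)
  v <- crf@values
  dimnames(v) <- list(crf@levels, crf@levels)
  utils::write.table(format(v, digits = 15), con, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname writeCrfMatrix
#' @export
readCrfMatrix <- function(path) {
  hdr <- readLines(path, n = 2)
  val <- function(i) sub("^# [a-z_]+: ?", "", hdr[i])
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   comment.char = "#", row.names = 1,
                                   check.names = FALSE))
  new("CRFMatrix", values = unname(m), levels = as.numeric(rownames(m)),
      targetEye = val(1), modality = val(2),
      dispersion = matrix(numeric(0), 0, 0))
}
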