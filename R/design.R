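#' Factorial dichoptic condition set
#'
#' Builds the full factorial crossing of contrast levels over the two
#' eyes. With the default five levels this gives the 25 dichoptic
#' conditions of the contrast-response experiment.
#'
#' @param levels distinct Michelson contrast levels in percent, must
#'   include 0. Default \code{c(0, 6, 24, 48, 96)}; the 48 level is the
#'   configurable mid level.
#' @return data.frame with columns \code{index} (0-based ordinal),
#'   \code{contrast_L}, \code{contrast_R}; one row per unique (L, R) pair.
#' @examples
#' nrow(buildConditionMatrix())  # 25
#' @export
buildConditionMatrix <- function(levels = c(0, 6, 24, 48, 96)) {
  if (anyDuplicated(levels)) stop("contrast levels must be distinct")
  if (!0 %in% levels) stop("levels must include 0 (blank/monocular baseline)")
  checkContrast(levels, "levels")
  g <- expand.grid(contrast_L = levels, contrast_R = levels,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(index = seq_len(nrow(g)) - 1L,
             contrast_L = g$contrast_L, contrast_R = g$contrast_R)
}

makeSchedule <- function(events, modality, TR_s, levels, seed) {
  if (nrow(events)) {
    events$index <- seq_len(nrow(events)) - 1L
    rownames(events) <- NULL
  }
  new("DichopticSchedule", events = events, modality = modality,
      TR_s = TR_s, levels = as.numeric(sort(unique(levels))),
      seed = as.numeric(seed))
}

emptyEvents <- function() {
  data.frame(index = integer(0), onset_s = numeric(0), duration_s = numeric(0),
             contrast_L = numeric(0), contrast_R = numeric(0),
             kind = character(0))
}

blankRow <- function(onset, dur) {
  data.frame(index = 0L, onset_s = onset, duration_s = dur,
             contrast_L = 0, contrast_R = 0, kind = "blank")
}

#' fMRI contrast-response scan schedule
#'
#' One run of the block-design contrast-response sequence: a lead-in
#' blank (discarded at analysis time to allow for magnetic saturation),
#' then each condition once in seeded random order, each 12 s trial
#' followed by a 12 s blank. With the 25-condition factorial set and
#' defaults this lasts 612 s = 204 TRs at TR = 3 s.
#'
#' @param conditions condition data.frame from [buildConditionMatrix()].
#' @param trial_s,blank_s,leadin_s timing in seconds.
#' @param TR_s repetition time; the total duration must divide by it.
#' @param seed integer seed fixing the trial order.
#' @return a [DichopticSchedule-class] with \code{modality = "fmri"}.
#' @export
buildFmriCrfSchedule <- function(conditions, trial_s = 12, blank_s = 12,
                                 leadin_s = 12, TR_s = 3, seed = 1) {
  total <- leadin_s + nrow(conditions) * (trial_s + blank_s)
  if (abs(total %% TR_s) > 1e-9)
    stop(sprintf("total duration %g s is not divisible by TR = %g s", total, TR_s))
  ord <- withSeed(seed, sample.int(nrow(conditions)))
  nc <- length(ord)
  tOn <- leadin_s + (seq_len(nc) - 1) * (trial_s + blank_s)
  ev <- rbind(
    blankRow(0, leadin_s),
    data.frame(index = 0L, onset_s = tOn, duration_s = trial_s,
               contrast_L = conditions$contrast_L[ord],
               contrast_R = conditions$contrast_R[ord], kind = "trial"),
    blankRow(tOn + trial_s, blank_s))
  ev <- ev[order(ev$onset_s), ]
  makeSchedule(ev, "fmri", TR_s,
               unique(c(conditions$contrast_L, conditions$contrast_R)), seed)
}

#' EEG contrast-response block schedule
#'
#' One EEG block: each condition once in seeded random order, 12 s trials
#' separated by a 3 s intertrial interval (modelled as a blank after each
#' trial). The 25-condition set takes 375 s per block; a session of 8
#' repetitions is 8 independently permuted blocks.
#'
#' @param conditions condition data.frame from [buildConditionMatrix()].
#' @param trial_s,iti_s trial duration and intertrial interval, seconds.
#' @param seed integer seed fixing the trial order.
#' @return a [DichopticSchedule-class] with \code{modality = "eeg"}.
#' @export
buildEegBlockSchedule <- function(conditions, trial_s = 12, iti_s = 3, seed = 1) {
  if (nrow(conditions) == 0)
    return(makeSchedule(emptyEvents(), "eeg", NA_real_, numeric(0), seed))
  ord <- withSeed(seed, sample.int(nrow(conditions)))
  nc <- length(ord)
  tOn <- (seq_len(nc) - 1) * (trial_s + iti_s)
  ev <- rbind(
    data.frame(index = 0L, onset_s = tOn, duration_s = trial_s,
               contrast_L = conditions$contrast_L[ord],
               contrast_R = conditions$contrast_R[ord], kind = "trial"),
    blankRow(tOn + trial_s, iti_s))
  ev <- ev[order(ev$onset_s), ]
  makeSchedule(ev, "eeg", NA_real_,
               unique(c(conditions$contrast_L, conditions$contrast_R)), seed)
}

#' Phase-encoded localiser schedule
#'
#' A lead-in blank followed by repetitions of the localiser position
#' sequence (the stimulus steps through \code{n_positions} locations,
#' dwelling \code{step_s} at each). Defaults reproduce the 156 s / 52 TR
#' localiser scan. Position events are tagged as trials with full
#' contrast in both eyes (the localiser is binocular); the position index
#' cycles in \code{onset} order.
#'
#' @param n_positions number of stimulus locations per cycle.
#' @param step_s dwell time per position, seconds.
#' @param reps number of cycles.
#' @param leadin_s initial blank, seconds.
#' @param TR_s repetition time, seconds.
#' @return a [DichopticSchedule-class] with \code{modality = "localiser"}.
#' @export
buildLocaliserSchedule <- function(n_positions = 4, step_s = 6, reps = 6,
                                   leadin_s = 12, TR_s = 3) {
  total <- leadin_s + reps * n_positions * step_s
  if (abs(total %% TR_s) > 1e-9)
    stop(sprintf("total duration %g s is not divisible by TR = %g s", total, TR_s))
  ev <- blankRow(0, leadin_s)
  t0 <- leadin_s
  for (r in seq_len(reps)) for (p in seq_len(n_positions)) {
    ev <- rbind(ev, data.frame(index = 0L, onset_s = t0, duration_s = step_s,
                               contrast_L = 100, contrast_R = 100,
                               kind = "trial"))
    t0 <- t0 + step_s
  }
  makeSchedule(ev, "localiser", TR_s, c(0, 100), NA)
}

#' On/off flicker waveform
#'
#' Instantaneous contrast of a stimulus flickering sinusoidally between 0
#' and its nominal contrast: \eqn{c(t) = c_0 (1 - \cos 2\pi f t)/2}
#' (raised cosine starting from 0, so onset is smooth). Mean over one
#' period is \code{nominal/2}; any static nonlinearity of the response
#' introduces harmonic content at 2f (8 Hz for the 4 Hz flicker).
#'
#' @param t time in seconds (vectorised).
#' @param f flicker frequency, Hz.
#' @param nominal nominal Michelson contrast, percent.
#' @return instantaneous contrast in \code{[0, nominal]}.
#' @export
flickerWaveform <- function(t, f = 4, nominal = 100) {
  checkContrast(nominal, "nominal contrast")
  nominal * (1 - cos(2 * pi * f * t)) / 2
}

#' Write / read a schedule as delimited text
#'
#' The file is tab-separated with a commented header block recording the
#' modality, TR, level set and ordering seed, so schedules round-trip
#' losslessly.
#'
#' @param x a [DichopticSchedule-class].
#' @param path file path.
#' @return \code{writeSchedule} returns \code{path} invisibly;
#'   \code{readSchedule} returns the reconstructed schedule.
#' @export
writeSchedule <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# modality: %s", x@modality),
    sprintf("# TR_s: %s", format(x@TR_s, digits = 15)),
    sprintf("# levels: %s", paste(format(x@levels, digits = 15), collapse = ",")),
    sprintf("# seed: %s", format(x@seed, digits = 15))
  ), con)
  utils::write.table(x@events, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  hdr <- readLines(path, n = 4)
  val <- function(i) sub("^# [a-zA-Z_]+: ?", "", hdr[i])
  ev <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(ev) == 0) ev <- emptyEvents()
  lv <- suppressWarnings(as.numeric(strsplit(val(3), ",")[[1]]))
  new("DichopticSchedule", events = ev, modality = val(1),
      TR_s = suppressWarnings(as.numeric(val(2))),
      levels = lv[is.finite(lv)],
      seed = suppressWarnings(as.numeric(val(4))))
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
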