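#' Write a session container
#'
#' One directory per session, in plain-text formats for random inspection:
#' `activity.csv` (cells x frames rate matrix), `cell_xy.csv`,
#' `licks_hi.csv`, `licks_lo.csv`, `stim.csv` (onset, freq),
#' `trials.csv` (columnar trial table) and `meta.json` (frame_rate,
#' session_index, bin_index, phase).
#'
#' @param session a [SessionRecording-class].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fw <- function(df, f) data.table::fwrite(df, file.path(path, f))
  fw(data.table::as.data.table(activityMatrix(session)), "activity.csv")
  xy <- cellXY(session)
  fw(data.frame(x = xy[, 1], y = xy[, 2]), "cell_xy.csv")
  fw(data.frame(time = licksHi(session)), "licks_hi.csv")
  fw(data.frame(time = licksLo(session)), "licks_lo.csv")
  fw(data.frame(onset = stimOnsets(session), freq = stimFreqs(session)),
     "stim.csv")
  fw(trialTable(session), "trials.csv")
  meta <- list(frame_rate = frameRate(session),
               session_index = sessionIndex(session),
               bin_index = binIndex(session),
               phase = sessionPhase(session))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  invisible(path)
}

#' Read a session container
#'
#' Inverse of [writeSession()]. Missing files raise a format error naming
#' the field; non-monotone lick times fail validation.
#'
#' @param path session directory.
#' @return a validated [SessionRecording-class].
#' @export
readSession <- function(path) {
  need <- c(activity = "activity.csv", cell_xy = "cell_xy.csv",
            licks_hi = "licks_hi.csv", licks_lo = "licks_lo.csv",
            stim = "stim.csv", trials = "trials.csv", meta = "meta.json")
  for (field in names(need)) {
    if (!file.exists(file.path(path, need[[field]])))
      stop(sprintf("format error: %s missing", field))
  }
  fr <- function(f) data.table::fread(file.path(path, f),
                                      data.table = FALSE)
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  act <- as.matrix(fr("activity.csv"))
  dimnames(act) <- NULL
  xy <- as.matrix(fr("cell_xy.csv"))
  dimnames(xy) <- NULL
  stim <- fr("stim.csv")
  trials <- fr("trials.csv")
  trials$freq <- as.numeric(trials$freq)
  trials$first_lick_post <- as.numeric(trials$first_lick_post)
  trials$reward_time <- as.numeric(trials$reward_time)
  SessionRecording(
    activity = act, frameRate = meta$frame_rate, cellXY = xy,
    licksHi = fr("licks_hi.csv")$time, licksLo = fr("licks_lo.csv")$time,
    stimOnsets = stim$onset, stimFreqs = stim$freq, trials = trials,
    sessionIndex = meta$session_index, binIndex = meta$bin_index)
}

#' Write an experiment (sessions + ground truth)
#'
#' Writes each session container under `dir/session_<k>/` and the pooled
#' ground-truth cell table as `ground_truth.csv`.
#'
#' @param experiment output of [generateExperiment()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeExperiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(experiment$sessions)) {
    writeSession(experiment$sessions[[k]],
                 file.path(dir, sprintf("session_%03d", k)))
  }
  gt <- do.call(rbind, lapply(experiment$ground_truth, `[[`, "cells"))
  data.table::fwrite(gt, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read an experiment directory
#'
#' @param dir directory written by [writeExperiment()].
#' @return list with `sessions` (sorted by directory name).
#' @export
readExperiment <- function(dir) {
  paths <- sort(list.dirs(dir, recursive = FALSE))
  paths <- paths[grepl("session_", basename(paths))]
  list(sessions = lapply(paths, readSession))
}
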