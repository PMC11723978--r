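#' @import methods
NULL

OUTCOME_LEVELS <- c("HIT", "EL", "LL", "MISS", "FA", "CR")
CLASS_LEVELS <- c("ENHANCED", "SUPPRESSED", "NONE")

#' SessionRecording: one imaging session
#'
#' Container for a single session of a delayed tone-detection task: the
#' deconvolved event-rate matrix (cells x frames, events/s, non-negative),
#' cell field-of-view coordinates, the lick train at native (500 Hz) and
#' frame-grid (30 Hz) resolution, tone onsets and frequencies, the trial
#' table, and the session's position in the experience sequence (bin 1-6,
#' training bins 1-3 / testing bins 4-6).
#'
#' The trial table holds one row per trial with columns `onset` (s), `kind`
#' ("TONE"/"CATCH"), `freq` (kHz, NA for catch), `outcome`
#' (HIT/EL/LL/MISS/FA/CR), `first_lick_post` (s, NA if none),
#' `quiet_period` (s, the preceding silence, 5-10 s) and `reward_time`
#' (s, NA if unrewarded).
#'
#' @slot activity numeric matrix, cells x frames, deconvolved event rate in
#'   events/s.
#' @slot frameRate sampling rate of the activity matrix in Hz.
#' @slot cellXY numeric matrix, cells x 2, field-of-view coordinates (um).
#' @slot licksHi sorted lick-onset times (s) at native resolution.
#' @slot licksLo sorted lick-onset times (s) on the frame grid.
#' @slot stimOnsets sorted tone-onset times (s); catch trials have no entry.
#' @slot stimFreqs tone frequency (kHz) per stimulus onset.
#' @slot trials data.frame trial table (see Details).
#' @slot sessionIndex ordinal position of the session.
#' @slot binIndex experience bin, 1-6.
#' @slot phase "training" (bins 1-3) or "testing" (bins 4-6).
#'
#' @aliases SessionRecording-class
#' @exportClass SessionRecording
setClass("SessionRecording",
  representation(
    activity = "matrix",
    frameRate = "numeric",
    cellXY = "matrix",
    licksHi = "numeric",
    licksLo = "numeric",
    stimOnsets = "numeric",
    stimFreqs = "numeric",
    trials = "data.frame",
    sessionIndex = "integer",
    binIndex = "integer",
    phase = "character"
  )
)

.validSessionRecording <- function(object) {
  msgs <- character(0)
  a <- object@activity
  if (length(a) && any(a < 0)) {
    msgs <- c(msgs, "activity must be non-negative everywhere")
  }
  if (nrow(object@cellXY) != nrow(a)) {
    msgs <- c(msgs, "cellXY must have one row per cell")
  }
  if (is.unsorted(object@licksHi, strictly = TRUE)) {
    msgs <- c(msgs, "licksHi must be strictly increasing")
  }
  if (is.unsorted(object@licksLo, strictly = TRUE)) {
    msgs <- c(msgs, "licksLo must be strictly increasing")
  }
  if (is.unsorted(object@stimOnsets)) {
    msgs <- c(msgs, "stimOnsets must be sorted")
  }
  if (length(object@stimFreqs) != length(object@stimOnsets)) {
    msgs <- c(msgs, "stimFreqs must match stimOnsets in length")
  }
  if (!(object@binIndex %in% 1:6)) {
    msgs <- c(msgs, "binIndex must be in 1..6")
  }
  expected_phase <- if (object@binIndex <= 3L) "training" else "testing"
  if (!identical(object@phase, expected_phase)) {
    msgs <- c(msgs, sprintf(
      "phase must be '%s' for bin %d", expected_phase, object@binIndex))
  }
  tr <- object@trials
  need <- c("onset", "kind", "freq", "outcome", "first_lick_post",
            "quiet_period")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    msgs <- c(msgs, paste("trials missing column(s):",
                          paste(miss, collapse = ", ")))
  } else {
    tone <- tr$kind == "TONE"
    if (any(tone) && !all(tr$onset[tone] %in% object@stimOnsets)) {
      msgs <- c(msgs, "every tone-trial onset must appear in stimOnsets")
    }
    qp <- tr$quiet_period
    if (any(qp < 5 - 1e-9 | qp > 10 + 1e-9)) {
      msgs <- c(msgs, "quiet_period must lie in [5, 10] s")
    }
    if (!all(tr$outcome %in% OUTCOME_LEVELS)) {
      msgs <- c(msgs, "unknown outcome label in trials")
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("SessionRecording", .validSessionRecording)

#' Construct a SessionRecording
#'
#' @param activity cells x frames matrix of event rates (events/s).
#' @param frameRate sampling rate (Hz), default 30.
#' @param cellXY cells x 2 coordinate matrix (um).
#' @param licksHi,licksLo sorted lick times (s) at native / frame resolution.
#'   `licksLo` defaults to [downsampleLicks()] of `licksHi`.
#' @param stimOnsets,stimFreqs tone onset times (s) and frequencies (kHz).
#' @param trials trial table data.frame (see [SessionRecording-class]).
#' @param sessionIndex ordinal session number.
#' @param binIndex experience bin 1-6; bins 1-3 are the training phase.
#' @return A validated `SessionRecording`.
#' @export
SessionRecording <- function(activity, frameRate = 30, cellXY,
                             licksHi = numeric(0), licksLo = NULL,
                             stimOnsets = numeric(0),
                             stimFreqs = numeric(0),
                             trials, sessionIndex = 1L, binIndex = 1L) {
  if (is.null(licksLo)) licksLo <- downsampleLicks(licksHi, frameRate)
  new("SessionRecording",
      activity = as.matrix(activity), frameRate = frameRate,
      cellXY = as.matrix(cellXY), licksHi = as.numeric(licksHi),
      licksLo = as.numeric(licksLo), stimOnsets = as.numeric(stimOnsets),
      stimFreqs = as.numeric(stimFreqs), trials = trials,
      sessionIndex = as.integer(sessionIndex),
      binIndex = as.integer(binIndex),
      phase = if (binIndex <= 3) "training" else "testing")
}

setMethod("show", "SessionRecording", function(object) {
  cat(sprintf(
    "SessionRecording: %d cells x %d frames @ %g Hz (%.1f s)\n",
    nrow(object@activity), ncol(object@activity), object@frameRate,
    ncol(object@activity) / object@frameRate))
  cat(sprintf("  session %d, bin %d (%s phase)\n",
              object@sessionIndex, object@binIndex, object@phase))
  tab <- table(factor(object@trials$outcome, OUTCOME_LEVELS))
  cat(sprintf("  %d trials (%s)\n", nrow(object@trials),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
  cat(sprintf("  %d licks (native), %d stimuli\n",
              length(object@licksHi), length(object@stimOnsets)))
})

#' @rdname SessionRecording-accessors
#' @name SessionRecording-accessors
#' @title Accessors for SessionRecording
#' @param object a `SessionRecording`.
#' @return The corresponding component.
NULL

#' @rdname SessionRecording-accessors
#' @export
setGeneric("activityMatrix", function(object) standardGeneric("activityMatrix"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("activityMatrix", "SessionRecording", function(object) object@activity)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("frameRate", "SessionRecording", function(object) object@frameRate)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("cellXY", function(object) standardGeneric("cellXY"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("cellXY", "SessionRecording", function(object) object@cellXY)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("licksHi", function(object) standardGeneric("licksHi"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("licksHi", "SessionRecording", function(object) object@licksHi)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("licksLo", function(object) standardGeneric("licksLo"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("licksLo", "SessionRecording", function(object) object@licksLo)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("stimOnsets", function(object) standardGeneric("stimOnsets"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("stimOnsets", "SessionRecording", function(object) object@stimOnsets)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("stimFreqs", function(object) standardGeneric("stimFreqs"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("stimFreqs", "SessionRecording", function(object) object@stimFreqs)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("trialTable", function(object) standardGeneric("trialTable"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("trialTable", "SessionRecording", function(object) object@trials)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("binIndex", function(object) standardGeneric("binIndex"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("binIndex", "SessionRecording", function(object) object@binIndex)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("sessionPhase", function(object) standardGeneric("sessionPhase"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("sessionPhase", "SessionRecording", function(object) object@phase)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("sessionIndex", function(object) standardGeneric("sessionIndex"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("sessionIndex", "SessionRecording", function(object) object@sessionIndex)

#' @rdname SessionRecording-accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("nCells", "SessionRecording", function(object) nrow(object@activity))

#' @rdname SessionRecording-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname SessionRecording-accessors
#' @export
setMethod("nFrames", "SessionRecording", function(object) ncol(object@activity))

#' CellClassSet: per-cell functional labels
#'
#' Result of the peri-lick Wilcoxon classification. The `table` slot holds
#' one row per cell: `cell`, `label` (ENHANCED/SUPPRESSED/NONE), `p_value`,
#' `sign` (sign of the median during-baseline difference), `included`
#' (passed the event-rate floor), `reason` (exclusion reason or ""). The
#' sound-responsive flags live in `sound_responsive` / `sound_p` columns
#' when [classifySoundResponsive()] results are attached.
#'
#' @slot table data.frame, one row per cell.
#' @slot basis anchor context used: "POST_SOUND" or "PRE_SOUND".
#' @slot alpha significance level used.
#' @slot nAnchors number of anchors used.
#' @slot lowAnchors TRUE if too few anchors were available (all labels NONE).
#' @aliases CellClassSet-class
#' @exportClass CellClassSet
setClass("CellClassSet",
  representation(table = "data.frame", basis = "character",
                 alpha = "numeric", nAnchors = "integer",
                 lowAnchors = "logical"))

setValidity("CellClassSet", function(object) {
  tb <- object@table
  msgs <- character(0)
  if (!all(c("cell", "label", "p_value", "sign", "included") %in% names(tb)))
    msgs <- c(msgs, "table must have cell/label/p_value/sign/included")
  if (nrow(tb)) {
    if (!all(tb$label %in% CLASS_LEVELS))
      msgs <- c(msgs, "labels must be ENHANCED/SUPPRESSED/NONE")
    bad <- tb$label == "ENHANCED" & !(tb$sign > 0)
    if (any(bad, na.rm = TRUE))
      msgs <- c(msgs, "ENHANCED requires a positive during-baseline sign")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CellClassSet", function(object) {
  tab <- table(factor(object@table$label, CLASS_LEVELS))
  cat(sprintf("CellClassSet (%s basis, alpha=%g, %d anchors%s)\n",
              object@basis, object@alpha, object@nAnchors,
              if (object@lowAnchors) ", LOW ANCHOR COUNT" else ""))
  cat(sprintf("  %s\n", paste(sprintf("%s:%d", names(tab), tab),
                              collapse = " ")))
})

#' @rdname CellClassSet-class
#' @param object a `CellClassSet`.
#' @export
setGeneric("classTable", function(object) standardGeneric("classTable"))
#' @rdname CellClassSet-class
#' @export
setMethod("classTable", "CellClassSet", function(object) object@table)

#' @rdname CellClassSet-class
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname CellClassSet-class
#' @export
setMethod("classLabels", "CellClassSet", function(object) {
  structure(object@table$label, names = object@table$cell)
})

#' LatentDynamics: low-dimensional peri-lick population trajectories
#'
#' Trials of matched conditions are cut to a fixed peri-lick frame grid,
#' concatenated in condition-ordered blocks, and projected on the leading
#' principal components of the concatenated matrix.
#'
#' @slot scores time x m latent matrix (rows = trials x grid frames).
#' @slot rotation cells x m PCA basis.
#' @slot center per-cell means removed before projection.
#' @slot condition condition label per row.
#' @slot trial trial id per row.
#' @slot tau peri-lick time (s) per row; negative = pre-lick.
#' @slot binIndex experience bin of the source session.
#' @aliases LatentDynamics-class
#' @exportClass LatentDynamics
setClass("LatentDynamics",
  representation(scores = "matrix", rotation = "matrix", center = "numeric",
                 condition = "character", trial = "integer", tau = "numeric",
                 binIndex = "integer"))

setValidity("LatentDynamics", function(object) {
  n <- nrow(object@scores)
  if (length(object@condition) != n || length(object@trial) != n ||
      length(object@tau) != n)
    return("row metadata must match the score matrix")
  TRUE
})

setMethod("show", "LatentDynamics", function(object) {
  cat(sprintf(
    "LatentDynamics: bin %d, %d rows x %d dims, %d trials (%s)\n",
    object@binIndex, nrow(object@scores), ncol(object@scores),
    length(unique(object@trial)),
    paste(sprintf("%s:%d", names(table(object@condition)),
                  table(object@condition) /
                    length(unique(object@tau))), collapse = " ")))
})

#' @rdname LatentDynamics-class
#' @param object a `LatentDynamics`.
#' @export
setGeneric("latentScores", function(object) standardGeneric("latentScores"))
#' @rdname LatentDynamics-class
#' @export
setMethod("latentScores", "LatentDynamics", function(object) object@scores)

#' AlignmentResult: CCA alignment of two latent spaces
#'
#' @slot binPair the two experience bins aligned (reference first).
#' @slot cc canonical correlations (descending).
#' @slot xcoef,ycoef canonical transformations for each side.
#' @slot xcenter,ycenter centers removed by the CCA.
#' @slot alignedA,alignedB latent rows projected into the shared canonical
#'   space.
#' @slot upperBound,lowerBound top-3 resampled within-day bound and
#'   unaligned-space bound (may be length 0 before [ccaBounds()]).
#' @slot latA,latB the aligned `LatentDynamics` objects.
#' @aliases AlignmentResult-class
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(binPair = "integer", cc = "numeric",
                 xcoef = "matrix", ycoef = "matrix",
                 xcenter = "numeric", ycenter = "numeric",
                 alignedA = "matrix", alignedB = "matrix",
                 upperBound = "numeric", lowerBound = "numeric",
                 latA = "LatentDynamics", latB = "LatentDynamics"))

setValidity("AlignmentResult", function(object) {
  cc <- object@cc
  if (length(cc) && (any(cc < -1e-8) || any(cc > 1 + 1e-8)))
    return("canonical correlations must lie in [0, 1]")
  if (length(cc) > 1 && is.unsorted(rev(cc), strictly = FALSE) &&
      any(diff(cc) > 1e-8))
    return("canonical correlations must be non-increasing")
  TRUE
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: bins %d <-> %d\n",
              object@binPair[1], object@binPair[2]))
  cat("  top canonical correlations:",
      paste(sprintf("%.3f", utils::head(object@cc, 3)), collapse = ", "), "\n")
  if (length(object@upperBound))
    cat("  upper bound:",
        paste(sprintf("%.3f", object@upperBound), collapse = ", "), "\n")
  if (length(object@lowerBound))
    cat("  lower bound:",
        paste(sprintf("%.3f", object@lowerBound), collapse = ", "), "\n")
})

#' @rdname AlignmentResult-class
#' @param object an `AlignmentResult`.
#' @export
setGeneric("canonicalCors", function(object) standardGeneric("canonicalCors"))
#' @rdname AlignmentResult-class
#' @export
setMethod("canonicalCors", "AlignmentResult", function(object) object@cc)
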