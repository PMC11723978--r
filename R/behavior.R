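#' Task rule: response windows and rewards
#'
#' The delayed tone-detection task divides the 4.5 s after tone onset into
#' three contiguous 1.5 s windows: the delay (licking here is an early lick,
#' EL, and aborts the trial), the high-water window (a correctly timed lick,
#' HIT, earns 12 uL one second after the lick), and the low-water window
#' (a late lick, LL, is met by the 4 uL droplet dispensed unconditionally at
#' onset + 3 s). No lick in the full response window on a tone trial is a
#' MISS; on a catch trial any lick is a false alarm (FA), none a correct
#' rejection (CR). In the training phase the reward arrives at onset + 3 s
#' regardless of lick timing; outcome labels are still assigned for
#' bookkeeping.
#'
#' @param delay delay-window length (s), default 1.5.
#' @param high_water high-water window, default \[1.5, 3.0).
#' @param low_water low-water window, default \[3.0, 4.5).
#' @return A list of class `TaskRule`.
#' @export
taskRule <- function(delay = 1.5, high_water = c(1.5, 3.0),
                     low_water = c(3.0, 4.5)) {
  structure(list(
    delay = c(0, delay), high_water = high_water, low_water = low_water,
    response_end = low_water[2],
    hit_reward_ul = 12, ll_reward_ul = 4,
    hit_reward_delay = 1.0, ll_reward_at = high_water[2]
  ), class = "TaskRule")
}

#' Classify trial outcomes from lick times
#'
#' For each tone trial the first lick after onset determines the outcome by
#' the window it falls in: delay -> EL, high-water -> HIT, low-water -> LL,
#' none within the response window -> MISS. Catch trials with any lick in the
#' response window are FA, otherwise CR. Labels are assigned identically in
#' the training phase even though reward there is unconditional.
#'
#' @param trials data.frame with at least `onset` and `kind`
#'   ("TONE"/"CATCH") columns.
#' @param licks sorted lick times (s).
#' @param rule a [taskRule()].
#' @param phase "training" or "testing"; affects `reward_time` only.
#' @return `trials` with `outcome`, `first_lick_post` and `reward_time`
#'   columns filled in.
#' @export
classifyOutcomes <- function(trials, licks, rule = taskRule(),
                             phase = "testing") {
  if (is.unsorted(licks)) stop("licks must be sorted")
  ons <- trials$onset
  if (length(ons) > 1 && any(diff(ons) < rule$response_end))
    stop("overlapping trials: onsets closer than the response window")
  n <- nrow(trials)
  outcome <- character(n)
  first_lick <- rep(NA_real_, n)
  reward <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    on <- ons[i]
    rel <- licks[licks >= on] - on
    t1 <- if (length(rel)) rel[1] else NA_real_
    if (!is.na(t1) && t1 < rule$response_end) first_lick[i] <- on + t1
    if (trials$kind[i] == "CATCH") {
      outcome[i] <- if (!is.na(t1) && t1 < rule$response_end) "FA" else "CR"
    } else if (is.na(t1) || t1 >= rule$response_end) {
      outcome[i] <- "MISS"
    } else if (t1 < rule$delay[2]) {
      outcome[i] <- "EL"
    } else if (t1 < rule$high_water[2]) {
      outcome[i] <- "HIT"
    } else {
      outcome[i] <- "LL"
    }
    if (trials$kind[i] == "TONE") {
      if (phase == "training") {
        reward[i] <- on + rule$ll_reward_at
      } else if (outcome[i] == "HIT") {
        reward[i] <- first_lick[i] + rule$hit_reward_delay
      } else if (outcome[i] == "LL") {
        reward[i] <- on + rule$ll_reward_at
      }
    }
  }
  trials$outcome <- outcome
  trials$first_lick_post <- first_lick
  trials$reward_time <- reward
  trials
}

#' Signal-detection sensitivity d'
#'
#' `d' = z(H) - z(F)` with the hit rate `H` from tone trials and the
#' false-alarm rate `F` from catch trials. Extreme rates are clipped to
#' `[1/(2n), 1 - 1/(2n)]` (with the corresponding trial count `n`) so 0 and
#' 1 stay finite.
#'
#' @param H hit rate in \[0, 1\].
#' @param F false-alarm rate in \[0, 1\].
#' @param n_signal,n_catch trial counts behind each rate.
#' @return d' (unitless).
#' @examples
#' dprime(0.69, 0.31, 100, 100)  # ~0.992
#' @export
dprime <- function(H, F, n_signal, n_catch) {
  if (n_signal <= 0 || n_catch <= 0) stop("trial counts must be positive")
  if (H < 0 || H > 1 || F < 0 || F > 1) stop("rates must lie in [0, 1]")
  clip <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(H, n_signal)) - stats::qnorm(clip(F, n_catch))
}

#' Behavioral counts from a trial table
#'
#' The hit rate is the fraction of tone trials with a correctly timed lick
#' (outcome HIT); the false-alarm rate is the fraction of catch trials with
#' any lick in the response window.
#'
#' @param trials classified trial table.
#' @return list with H, F, n_signal, n_catch and the outcome counts.
#' @export
behavioralCounts <- function(trials) {
  tone <- trials[trials$kind == "TONE", , drop = FALSE]
  catch <- trials[trials$kind == "CATCH", , drop = FALSE]
  n_signal <- nrow(tone)
  n_catch <- nrow(catch)
  H <- if (n_signal) mean(tone$outcome == "HIT") else NA_real_
  F <- if (n_catch) mean(catch$outcome == "FA") else NA_real_
  list(H = H, F = F, n_signal = n_signal, n_catch = n_catch,
       counts = table(factor(trials$outcome, OUTCOME_LEVELS)))
}

#' Pre- and post-sound lick probabilities
#'
#' Fraction of trials with at least one lick in the 4.7 s after tone onset,
#' and in the matched 4.7 s before it. The pre window draws 3.7 s from the
#' preceding quiet period; when that quiet period is shorter the available
#' span is used and reported.
#'
#' @param trials classified trial table (needs `onset`, `quiet_period`).
#' @param licks sorted lick times (s).
#' @param windows an [analysisWindows()] (for the 4.7 s span).
#' @return list with `pre`, `post` (probabilities) and a per-trial
#'   data.frame (`pre_lick`, `post_lick`, `pre_span`).
#' @export
lickProbabilities <- function(trials, licks, windows = analysisWindows()) {
  span <- windows$pre_sound_period
  n <- nrow(trials)
  pre <- logical(n); post <- logical(n); pre_span <- numeric(n)
  for (i in seq_len(n)) {
    on <- trials$onset[i]
    post[i] <- any(licks >= on & licks < on + span)
    avail <- min(span, (span - 3.7) + trials$quiet_period[i])
    pre_span[i] <- avail
    pre[i] <- any(licks >= on - avail & licks < on)
  }
  list(pre = if (n) mean(pre) else NA_real_,
       post = if (n) mean(post) else NA_real_,
       per_trial = data.frame(pre_lick = pre, post_lick = post,
                              pre_span = pre_span))
}

#' Segment a lick train into bursts and singletons
#'
#' A lick burst is a maximal run of two or more consecutive licks whose
#' inter-lick pauses are all at most `pause_threshold` (a pause *greater*
#' than 500 ms separates bursts, so a gap of exactly 0.5 s stays within a
#' burst). Runs of length one are reported as singletons, not bursts.
#'
#' @param licks sorted lick times (s).
#' @param pause_threshold maximal intra-burst pause (s), default 0.5.
#' @return list with `bursts` (data.frame: start, end, n_licks, duration)
#'   and `singletons` (times).
#' @export
segmentBursts <- function(licks, pause_threshold = 0.5) {
  if (length(licks) == 0)
    return(list(bursts = data.frame(start = numeric(0), end = numeric(0),
                                    n_licks = integer(0),
                                    duration = numeric(0)),
                singletons = numeric(0)))
  if (is.unsorted(licks)) stop("licks must be sorted")
  brk <- c(0, which(diff(licks) > pause_threshold), length(licks))
  starts <- integer(0); ends <- integer(0)
  singles <- numeric(0)
  for (j in seq_len(length(brk) - 1)) {
    i0 <- brk[j] + 1L; i1 <- brk[j + 1]
    if (i1 - i0 >= 1L) {
      starts <- c(starts, i0); ends <- c(ends, i1)
    } else {
      singles <- c(singles, licks[i0])
    }
  }
  list(bursts = data.frame(start = licks[starts], end = licks[ends],
                           n_licks = ends - starts + 1L,
                           duration = licks[ends] - licks[starts]),
       singletons = singles)
}

#' Categorize a lick burst by duration
#'
#' Duration categories follow half-open, low-inclusive intervals. At native
#' 500 Hz resolution ("HI"): short \[0.002, 0.15), intermediate
#' \[0.15, 0.5), long \[0.5, 1); at the down-sampled 30 Hz grid ("LO"):
#' short \[0.033, 0.2), intermediate \[0.2, 0.5), long \[0.5, 1.33).
#' Durations at or beyond the upper cap (too few trials at that length) or
#' below the lower bound are EXCLUDED.
#'
#' @param duration burst duration(s) in seconds.
#' @param resolution "HI" (500 Hz) or "LO" (30 Hz).
#' @return character vector: SHORT, INTERMEDIATE, LONG or EXCLUDED.
#' @export
categorizeBurst <- function(duration, resolution = c("HI", "LO")) {
  resolution <- match.arg(resolution)
  b <- if (resolution == "HI") c(0.002, 0.15, 0.5, 1)
       else c(0.033, 0.2, 0.5, 1.33)
  out <- rep("EXCLUDED", length(duration))
  out[duration >= b[1] & duration < b[2]] <- "SHORT"
  out[duration >= b[2] & duration < b[3]] <- "INTERMEDIATE"
  out[duration >= b[3] & duration < b[4]] <- "LONG"
  out
}

#' Burst table for a session
#'
#' Segments the lick train at both resolutions, categorizes bursts, and tags
#' each burst PRE_SOUND or POST_SOUND by its start relative to the governing
#' tone onset.
#'
#' @param session a [SessionRecording-class].
#' @param pause_threshold intra-burst pause cap (s).
#' @return data.frame: one row per burst with resolution, context, category.
#' @export
sessionBursts <- function(session, pause_threshold = 0.5) {
  res <- list(HI = licksHi(session), LO = licksLo(session))
  out <- list()
  for (r in names(res)) {
    seg <- segmentBursts(res[[r]], pause_threshold)$bursts
    if (!nrow(seg)) next
    seg$resolution <- r
    seg$category <- categorizeBurst(seg$duration, r)
    seg$context <- lickContext(seg$start, stimOnsets(session))
    seg$bin_index <- binIndex(session)
    out[[r]] <- seg
  }
  if (!length(out))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_licks = integer(0), duration = numeric(0),
                      resolution = character(0), category = character(0),
                      context = character(0), bin_index = integer(0)))
  do.call(rbind, out)
}

# PRE_SOUND / POST_SOUND tag for event times: POST if the last tone onset at
# or before the event lies within the 4.7 s post-sound period.
lickContext <- function(times, stim_onsets, post_span = 4.7) {
  if (length(stim_onsets) == 0) return(rep("PRE_SOUND", length(times)))
  idx <- findInterval(times, stim_onsets)
  ctx <- rep("PRE_SOUND", length(times))
  has <- idx > 0
  ctx[has & (times - stim_onsets[pmax(idx, 1)]) < post_span] <- "POST_SOUND"
  ctx
}

#' Per-session behavioral summary
#'
#' @param session a [SessionRecording-class].
#' @param windows an [analysisWindows()].
#' @return one-row data.frame: session, bin, phase, outcome counts, H, F,
#'   d', pre/post lick probabilities.
#' @export
behaviorSummary <- function(session, windows = analysisWindows()) {
  tr <- trialTable(session)
  bc <- behavioralCounts(tr)
  dp <- if (bc$n_signal > 0 && bc$n_catch > 0)
    dprime(bc$H, bc$F, bc$n_signal, bc$n_catch) else NA_real_
  lp <- lickProbabilities(tr, licksHi(session), windows)
  cn <- as.list(as.integer(bc$counts))
  names(cn) <- paste0("n_", tolower(names(bc$counts)))
  cbind(data.frame(session = sessionIndex(session), bin = binIndex(session),
                   phase = sessionPhase(session), H = bc$H, F = bc$F,
                   dprime = dp, p_lick_pre = lp$pre, p_lick_post = lp$post),
        as.data.frame(cn))
}
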