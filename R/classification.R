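#' Select isolated lick anchors
#'
#' Keeps licks preceded by at least 330 ms free of any other lick or
#' stimulus onset (strictly: no event in the open interval `(t - 0.330, t)`,
#' so a lick exactly 330 ms after the previous event is kept), isolating
#' activity attributable to the individual lick. Each anchor is tagged
#' PRE_SOUND or POST_SOUND by its position relative to the governing trial's
#' tone onset.
#'
#' @param licks sorted lick times (s).
#' @param stim_onsets sorted tone-onset times (s).
#' @param clearance required event-free lapse before a lick (s), 0.330.
#' @param context optional filter: "PRE_SOUND", "POST_SOUND" or NULL (all).
#' @return data.frame: `time`, `context`.
#' @export
selectIsolatedLicks <- function(licks, stim_onsets, clearance = 0.330,
                                context = NULL) {
  keep <- logical(length(licks))
  for (j in seq_along(licks)) {
    t <- licks[j]
    prev_lick <- any(licks > t - clearance & licks < t)
    prev_stim <- any(stim_onsets > t - clearance & stim_onsets < t)
    keep[j] <- !prev_lick && !prev_stim
  }
  out <- data.frame(time = licks[keep],
                    context = lickContext(licks[keep], stim_onsets))
  if (!is.null(context)) out <- out[out$context == context, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cells passing the event-rate floor
#'
#' Cells whose mean deconvolved event rate across the whole session is below
#' `min_rate` (1 event/s) are removed from analysis.
#'
#' @param session a [SessionRecording-class].
#' @param min_rate events/s floor.
#' @return logical vector, one entry per cell.
#' @export
includedCells <- function(session, min_rate = 1.0) {
  rowMeans(activityMatrix(session)) >= min_rate
}

# Per-anchor window means: rows anchors, cols cells. Anchors whose window
# leaves the recording are dropped and counted.
.anchorWindowMeans <- function(session, anchor_times, interval) {
  act <- activityMatrix(session)
  fr <- frameRate(session)
  nf <- ncol(act)
  rows <- vector("list", length(anchor_times))
  used <- logical(length(anchor_times))
  for (j in seq_along(anchor_times)) {
    a <- timeToFrame(anchor_times[j], fr)
    idx <- windowToFrames(interval, fr, a, nf)
    if (is.null(idx)) next
    used[j] <- TRUE
    rows[[j]] <- frameMean(act, idx)
  }
  m <- do.call(rbind, rows[used])
  if (is.null(m)) m <- matrix(numeric(0), 0, nrow(act))
  list(matrix = m, used = which(used),
       n_used = sum(used), n_dropped = sum(!used))
}

# Two-sided paired Wilcoxon signed-rank p via the normal approximation
# (exact p-values are unavailable with the ties typical of deconvolved
# rates). Returns NA when every pair is tied.
.pairedWilcoxP <- function(x, y) {
  p <- tryCatch(
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                        exact = FALSE,
                                        correct = FALSE)$p.value),
    error = function(e) NA_real_)
  p
}

#' Classify lick-modulated cells
#'
#' For each included cell, pairs the mean rate in the during window
#' (\[-165, +165) ms around each isolated-lick anchor) with the mean rate in
#' the 330 ms baseline window immediately before, and applies a two-sided
#' Wilcoxon signed-rank test across anchors. Cells significant at `alpha`
#' are labelled ENHANCED or SUPPRESSED by the sign of the median paired
#' difference; all others (and excluded cells) are NONE. With
#' `basis = "PRE_SOUND"` the same procedure runs on pre-sound anchors.
#'
#' @param session a [SessionRecording-class].
#' @param anchors data.frame from [selectIsolatedLicks()]; filtered to
#'   `basis` internally.
#' @param windows an [analysisWindows()].
#' @param alpha two-sided significance level (0.05).
#' @param basis "POST_SOUND" (default) or "PRE_SOUND".
#' @param min_rate event-rate inclusion floor (events/s).
#' @param min_anchors minimum usable anchors; below it every label is NONE
#'   and the result is flagged.
#' @param p_adjust optional [stats::p.adjust()] method across cells
#'   ("none").
#' @return a [CellClassSet-class].
#' @export
classifyLickModulation <- function(session, anchors,
                                   windows = analysisWindows(),
                                   alpha = 0.05, basis = "POST_SOUND",
                                   min_rate = 1.0, min_anchors = 10L,
                                   p_adjust = "none") {
  at <- anchors$time[anchors$context == basis]
  n_cells <- nCells(session)
  inc <- includedCells(session, min_rate)
  dur <- .anchorWindowMeans(session, at, windows$during)
  base <- .anchorWindowMeans(session, at, windows$baseline)
  common <- intersect(dur$used, base$used)
  D <- dur$matrix[match(common, dur$used), , drop = FALSE]
  B <- base$matrix[match(common, base$used), , drop = FALSE]
  n_anchors <- length(common)
  tb <- data.frame(cell = seq_len(n_cells), label = "NONE",
                   p_value = NA_real_, sign = NA_real_, included = inc,
                   reason = ifelse(inc, "", "rate_floor"))
  low <- n_anchors < min_anchors
  if (!low) {
    for (c in which(inc)) {
      d <- D[, c]; b0 <- B[, c]
      p <- .pairedWilcoxP(d, b0)
      tb$p_value[c] <- p
      tb$sign[c] <- sign(stats::median(d - b0))
    }
    if (p_adjust != "none")
      tb$p_value[inc] <- stats::p.adjust(tb$p_value[inc], p_adjust)
    sig <- inc & !is.na(tb$p_value) & tb$p_value < alpha & tb$sign != 0
    tb$label[sig & tb$sign > 0] <- "ENHANCED"
    tb$label[sig & tb$sign < 0] <- "SUPPRESSED"
  } else {
    tb$reason[inc] <- "too_few_anchors"
    warning(sprintf("only %d usable anchors (< %d): all labels NONE",
                    n_anchors, min_anchors))
  }
  new("CellClassSet", table = tb, basis = basis, alpha = alpha,
      nAnchors = as.integer(n_anchors), lowAnchors = low)
}

#' Classify sound-responsive cells
#'
#' Paired Wilcoxon signed-rank test, per cell, of the mean rate in the
#' 500 ms before versus the 500 ms after tone onset, across tone trials
#' (catch trials have no onset and contribute nothing).
#'
#' @param session a [SessionRecording-class].
#' @param windows an [analysisWindows()].
#' @param alpha significance level.
#' @param min_rate event-rate inclusion floor.
#' @param min_trials minimum tone trials required.
#' @return data.frame: `cell`, `sound_responsive`, `sound_p`, `included`.
#' @export
classifySoundResponsive <- function(session, windows = analysisWindows(),
                                    alpha = 0.05, min_rate = 1.0,
                                    min_trials = 5L) {
  onsets <- stimOnsets(session)
  inc <- includedCells(session, min_rate)
  n_cells <- nCells(session)
  out <- data.frame(cell = seq_len(n_cells), sound_responsive = FALSE,
                    sound_p = NA_real_, included = inc)
  pre <- .anchorWindowMeans(session, onsets, c(-windows$sound_pre, 0))
  post <- .anchorWindowMeans(session, onsets, c(0, windows$sound_post))
  common <- intersect(pre$used, post$used)
  if (length(common) < min_trials) {
    warning("too few tone trials for sound-responsiveness")
    return(out)
  }
  P0 <- pre$matrix[match(common, pre$used), , drop = FALSE]
  P1 <- post$matrix[match(common, post$used), , drop = FALSE]
  for (c in which(inc)) {
    p <- .pairedWilcoxP(P1[, c], P0[, c])
    out$sound_p[c] <- p
    out$sound_responsive[c] <- !is.na(p) && p < alpha
  }
  out
}

#' Peri-lick activity summary per cell
#'
#' For each included cell: the mean peri-lick trace over a
#' \[-0.495, +0.495) s grid across anchors, its z-scored version (mean and
#' sd taken over the peri-event frames of all anchors), the absolute peak of
#' the z trace within +/-165 ms, and raw-rate summaries: `pre_mean`
#' (165 ms before the lick), `post_mean` (165 ms after), `delta = post -
#' pre` and the symmetric proportional change
#' `(post - pre) / (post + pre + 1e-9)`. Zero-variance cells are omitted
#' from the z summaries (`abs_peak = NA`) but keep their raw summaries.
#' Analogous pre/post sound summaries (0.5 s windows across tone trials)
#' are appended.
#'
#' @param session a [SessionRecording-class].
#' @param anchors data.frame from [selectIsolatedLicks()].
#' @param windows an [analysisWindows()].
#' @param basis anchor context to summarize ("POST_SOUND").
#' @param min_rate event-rate floor.
#' @return list: `cells` (per-cell data.frame), `trace` (cells x grid mean
#'   z traces), `tau` (grid times), `n_anchors_used`, `n_anchors_dropped`.
#' @export
periLickSummary <- function(session, anchors, windows = analysisWindows(),
                            basis = "POST_SOUND", min_rate = 1.0) {
  at <- anchors$time[anchors$context == basis]
  act <- activityMatrix(session)
  fr <- frameRate(session)
  nf <- ncol(act)
  half <- round(0.495 * fr)                 # 15 frames
  grid <- seq(-half, half - 1)
  used <- 0L; dropped <- 0L
  segs <- list()
  for (t in at) {
    a <- timeToFrame(t, fr)
    if (a - half < 1 || a + half - 1 > nf) { dropped <- dropped + 1L; next }
    used <- used + 1L
    segs[[used]] <- act[, (a - half):(a + half - 1), drop = FALSE]
  }
  n_cells <- nrow(act)
  inc <- includedCells(session, min_rate)
  tau <- grid / fr
  dur_idx <- which(grid >= -round(0.165 * fr) & grid < round(0.165 * fr))
  pre_idx <- which(grid >= -round(0.165 * fr) & grid < 0)
  post_idx <- which(grid >= 0 & grid < round(0.165 * fr))
  cells <- data.frame(cell = seq_len(n_cells), abs_peak = NA_real_,
                      pre_mean = NA_real_, post_mean = NA_real_,
                      delta = NA_real_, prop_change = NA_real_,
                      sound_pre = NA_real_, sound_post = NA_real_,
                      sound_delta = NA_real_, included = inc)
  ztrace <- matrix(NA_real_, n_cells, length(grid))
  if (used > 0) {
    arr <- array(unlist(segs), dim = c(n_cells, length(grid), used))
    mtrace <- apply(arr, c(1, 2), mean)
    for (c in which(inc)) {
      v <- as.numeric(arr[c, , ])
      mu <- mean(v); sdv <- stats::sd(v)
      if (!is.na(sdv) && sdv > 0) {
        ztrace[c, ] <- (mtrace[c, ] - mu) / sdv
        cells$abs_peak[c] <- max(abs(ztrace[c, dur_idx]))
      }
      cells$pre_mean[c] <- mean(mtrace[c, pre_idx])
      cells$post_mean[c] <- mean(mtrace[c, post_idx])
      cells$delta[c] <- cells$post_mean[c] - cells$pre_mean[c]
      cells$prop_change[c] <- cells$delta[c] /
        (cells$post_mean[c] + cells$pre_mean[c] + 1e-9)
    }
  }
  onsets <- stimOnsets(session)
  spre <- .anchorWindowMeans(session, onsets, c(-windows$sound_pre, 0))
  spost <- .anchorWindowMeans(session, onsets, c(0, windows$sound_post))
  common <- intersect(spre$used, spost$used)
  if (length(common)) {
    p0 <- colMeans(spre$matrix[match(common, spre$used), , drop = FALSE])
    p1 <- colMeans(spost$matrix[match(common, spost$used), , drop = FALSE])
    cells$sound_pre[inc] <- p0[inc]
    cells$sound_post[inc] <- p1[inc]
    cells$sound_delta[inc] <- (p1 - p0)[inc]
  }
  list(cells = cells, trace = ztrace, tau = tau,
       n_anchors_used = used, n_anchors_dropped = dropped)
}

#' Pairwise spatial distances by functional group
#'
#' All within-group pairwise Euclidean distances of cell coordinates for the
#' ENHANCED, SUPPRESSED and NONE groups, plus cross pairings of
#' sound-responsive cells with each group. Groups of size < 2 yield empty
#' distributions.
#'
#' @param cell_xy cells x 2 coordinate matrix.
#' @param labels per-cell class labels.
#' @param sound_responsive optional logical per-cell flag for the cross
#'   pairings.
#' @return list: `within` (named list of distance vectors), `cross` (named
#'   list), `summary` (data.frame of group, n_pairs, mean distance).
#' @export
pairwiseSpatialDistance <- function(cell_xy, labels,
                                    sound_responsive = NULL) {
  within <- list()
  for (g in CLASS_LEVELS) {
    idx <- which(labels == g)
    within[[g]] <- if (length(idx) >= 2)
      as.numeric(stats::dist(cell_xy[idx, , drop = FALSE])) else numeric(0)
  }
  cross <- list()
  if (!is.null(sound_responsive)) {
    sidx <- which(sound_responsive)
    for (g in CLASS_LEVELS) {
      gidx <- setdiff(which(labels == g), sidx)
      if (length(sidx) && length(gidx)) {
        d <- outer(sidx, gidx, function(i, j) {
          sqrt((cell_xy[i, 1] - cell_xy[j, 1])^2 +
               (cell_xy[i, 2] - cell_xy[j, 2])^2)
        })
        cross[[paste0("SOUNDx", g)]] <- as.numeric(d)
      } else cross[[paste0("SOUNDx", g)]] <- numeric(0)
    }
  }
  all <- c(within, cross)
  summary <- data.frame(
    group = names(all),
    n_pairs = vapply(all, length, integer(1)),
    mean_distance = vapply(all, function(x)
      if (length(x)) mean(x) else NA_real_, numeric(1)))
  rownames(summary) <- NULL
  list(within = within, cross = cross, summary = summary)
}
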