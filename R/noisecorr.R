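WINDOW_NAMES <- c(DURING = "during", BEFORE = "baseline", FARTHER = "farther")

#' Trial x cell window-activity matrix
#'
#' For a set of isolated-lick anchors, the mean rate of each cell in the
#' requested 330 ms window (DURING: starting 165 ms before the lick;
#' BEFORE: 495 ms before; FARTHER: 825 ms before). Anchors whose window
#' leaves the recording are dropped; trials with zero activity across the
#' whole population in the window are discarded. Both counts are reported.
#'
#' @param session a [SessionRecording-class].
#' @param anchor_times anchor times (s), e.g. from [selectIsolatedLicks()].
#' @param window "DURING", "BEFORE" or "FARTHER".
#' @param windows an [analysisWindows()].
#' @param cells optional cell index subset (default all).
#' @return list: `matrix` (trials x cells), `anchor_index` (surviving
#'   anchors), `n_used`, `n_dropped`, `n_discarded_zero`.
#' @export
windowActivityMatrix <- function(session, anchor_times,
                                 window = c("DURING", "BEFORE", "FARTHER"),
                                 windows = analysisWindows(),
                                 cells = NULL) {
  window <- match.arg(window)
  interval <- windows[[WINDOW_NAMES[[window]]]]
  wm <- .anchorWindowMeans(session, anchor_times, interval)
  m <- wm$matrix
  nonzero <- rowSums(m) > 0  # discard rule is population-wide
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  list(matrix = m[nonzero, , drop = FALSE],
       anchor_index = wm$used[nonzero],
       n_used = sum(nonzero), n_dropped = wm$n_dropped,
       n_discarded_zero = sum(!nonzero))
}

#' Pairwise noise correlations
#'
#' Pearson correlation of every cell pair's trial-to-trial window means,
#' after per-cell normalization (z-scoring the trial vector; the raw-rate
#' variant is available). Zero-variance cells are dropped from pairing.
#'
#' @param mat trials x cells matrix (e.g. from [windowActivityMatrix()]).
#' @param normalization "zscore" (default) or "raw".
#' @param min_trials minimum trials required (3).
#' @return list: `r` (symmetric correlation matrix over retained cells),
#'   `cells` (retained column indices), `n_trials`; or `NULL`-ish flagged
#'   list when fewer than `min_trials` trials or no cell has variance.
#' @export
noiseCorr <- function(mat, normalization = c("zscore", "raw"),
                      min_trials = 3L) {
  normalization <- match.arg(normalization)
  if (nrow(mat) < min_trials)
    return(list(r = NULL, cells = integer(0), n_trials = nrow(mat),
                insufficient = TRUE))
  v <- apply(mat, 2, stats::var)
  keep <- which(!is.na(v) & v > 0)
  if (length(keep) < 2)
    return(list(r = NULL, cells = keep, n_trials = nrow(mat),
                insufficient = TRUE))
  m <- mat[, keep, drop = FALSE]
  if (normalization == "zscore") m <- scale(m)
  r <- stats::cor(m)
  list(r = r, cells = keep, n_trials = nrow(mat), insufficient = FALSE)
}

#' Mean pairwise correlation by group pairing
#'
#' Averages the off-diagonal correlations within and across functional
#' groups (ENHANCED x ENHANCED, SUPPRESSED x SUPPRESSED, NONE x NONE, and
#' the cross pairings), given per-cell labels aligned with the correlation
#' matrix columns.
#'
#' @param nc result of [noiseCorr()].
#' @param labels per-cell labels for the *original* matrix columns.
#' @return data.frame: pairing, mean_r, n_pairs.
#' @export
groupMeanCorr <- function(nc, labels) {
  if (is.null(nc$r))
    return(data.frame(pairing = character(0), mean_r = numeric(0),
                      n_pairs = integer(0)))
  lab <- labels[nc$cells]
  r <- nc$r
  pairings <- list(
    ENHxENH = c("ENHANCED", "ENHANCED"),
    SUPxSUP = c("SUPPRESSED", "SUPPRESSED"),
    NONExNONE = c("NONE", "NONE"),
    ENHxSUP = c("ENHANCED", "SUPPRESSED"),
    ENHxNONE = c("ENHANCED", "NONE"),
    SUPxNONE = c("SUPPRESSED", "NONE"),
    ALL = NULL)
  rows <- lapply(names(pairings), function(p) {
    pr <- pairings[[p]]
    if (is.null(pr)) {
      vals <- r[upper.tri(r)]
    } else if (pr[1] == pr[2]) {
      idx <- which(lab == pr[1])
      vals <- if (length(idx) >= 2)
        r[idx, idx][upper.tri(r[idx, idx])] else numeric(0)
    } else {
      i1 <- which(lab == pr[1]); i2 <- which(lab == pr[2])
      vals <- if (length(i1) && length(i2))
        as.numeric(r[i1, i2, drop = FALSE]) else numeric(0)
    }
    data.frame(pairing = p,
               mean_r = if (length(vals)) mean(vals) else NA_real_,
               n_pairs = length(vals))
  })
  do.call(rbind, rows)
}

#' Session noise-correlation table
#'
#' Computes the full windowed noise-correlation design for one session:
#' for each window (DURING/BEFORE/FARTHER) and each outcome subset
#' (ALL plus HIT/EL/LL), the mean pairwise correlation per group pairing.
#' Anchors are the isolated first post-sound licks; the outcome subsets keep
#' anchors whose governing trial has that outcome.
#'
#' @param session a [SessionRecording-class].
#' @param anchors data.frame from [selectIsolatedLicks()].
#' @param windows an [analysisWindows()].
#' @param labels per-cell class labels (e.g. from
#'   [classifyLickModulation()]).
#' @param normalization passed to [noiseCorr()].
#' @param min_trials minimum trials per correlation.
#' @return data.frame keyed by (session, bin, window, outcome, pairing)
#'   with mean_r, n_pairs, n_trials_used, n_trials_discarded.
#' @export
sessionNoiseCorr <- function(session, anchors,
                             windows = analysisWindows(), labels,
                             normalization = "zscore", min_trials = 3L) {
  at <- anchors$time[anchors$context == "POST_SOUND"]
  tr <- trialTable(session)
  gov <- findInterval(at, tr$onset)
  out_of <- gov >= 1
  outcome_of <- rep(NA_character_, length(at))
  outcome_of[out_of] <- tr$outcome[gov[out_of]]
  rows <- list()
  for (w in c("DURING", "BEFORE", "FARTHER")) {
    for (oc in c("ALL", "HIT", "EL", "LL")) {
      sel <- if (oc == "ALL") rep(TRUE, length(at)) else outcome_of == oc
      sel[is.na(sel)] <- FALSE
      wam <- windowActivityMatrix(session, at[sel], w, windows)
      nc <- noiseCorr(wam$matrix, normalization, min_trials)
      g <- groupMeanCorr(nc, labels)
      if (!nrow(g))
        g <- data.frame(pairing = "ALL", mean_r = NA_real_, n_pairs = 0L)
      g$session <- sessionIndex(session)
      g$bin <- binIndex(session)
      g$window <- w
      g$outcome <- oc
      g$n_trials_used <- wam$n_used
      g$n_trials_discarded <- wam$n_dropped + wam$n_discarded_zero
      rows[[length(rows) + 1]] <- g
    }
  }
  do.call(rbind, rows)
}

#' Window and outcome contrasts on noise-correlation tables
#'
#' Utility statistics over a pooled noise-correlation table: mean
#' differences for the window contrasts (DURING - BEFORE, BEFORE - FARTHER)
#' per pairing, and a two-way ANOVA (window x outcome) with Bonferroni
#' post hocs on the ALL pairing. These are descriptive test utilities;
#' contrasts with missing cells are skipped.
#'
#' @param tbl row-bound output of [sessionNoiseCorr()] across sessions.
#' @param pairing which pairing to test in the ANOVA ("ENHxENH").
#' @return list: `window_contrasts` (data.frame), `anova` (summary or
#'   NULL), `posthoc` (pairwise.t.test result or NULL).
#' @export
corrContrasts <- function(tbl, pairing = "ENHxENH") {
  sub <- tbl[!is.na(tbl$mean_r), , drop = FALSE]
  wc <- list()
  for (p in unique(sub$pairing)) {
    s <- sub[sub$pairing == p & sub$outcome == "ALL", ]
    m <- tapply(s$mean_r, s$window, mean)
    if (all(c("DURING", "BEFORE") %in% names(m)))
      wc[[length(wc) + 1]] <- data.frame(
        pairing = p, contrast = "DURING-BEFORE",
        diff = unname(m["DURING"] - m["BEFORE"]))
    if (all(c("BEFORE", "FARTHER") %in% names(m)))
      wc[[length(wc) + 1]] <- data.frame(
        pairing = p, contrast = "BEFORE-FARTHER",
        diff = unname(m["BEFORE"] - m["FARTHER"]))
  }
  s <- sub[sub$pairing == pairing & sub$outcome != "ALL", ]
  an <- NULL; ph <- NULL
  if (nrow(s) >= 6 && length(unique(s$window)) > 1 &&
      length(unique(s$outcome)) > 1) {
    an <- summary(stats::aov(mean_r ~ window * outcome, data = s))
    ph <- tryCatch(
      stats::pairwise.t.test(s$mean_r, s$window,
                             p.adjust.method = "bonferroni"),
      error = function(e) NULL)
  }
  list(window_contrasts = if (length(wc)) do.call(rbind, wc) else
         data.frame(), anova = an, posthoc = ph)
}
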