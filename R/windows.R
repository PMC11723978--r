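#' Peri-event analysis windows
#'
#' The canonical window set used throughout the pipeline, all in seconds
#' relative to the anchoring event (lick onset or tone onset):
#' * `during`: \[-0.165, +0.165) around the lick onset;
#' * `baseline` ("before"): \[-0.495, -0.165), the same-length window
#'   immediately preceding;
#' * `farther`: \[-0.825, -0.495);
#' * `sound_pre` / `sound_post`: 0.5 s before / after the tone onset;
#' * `pre_sound_period`: 4.7 s, the span used for pre/post lick-probability
#'   comparisons (3.7 s of it drawn from the preceding quiet period).
#'
#' At 30 Hz each 330 ms window is exactly 10 frames (165 ms rounds to 5
#' frames), so during/baseline/farther are contiguous, disjoint and
#' equal-length.
#'
#' @param frame_rate sampling rate in Hz (default 30).
#' @return A list of class `AnalysisWindows`.
#' @export
analysisWindows <- function(frame_rate = 30) {
  structure(list(
    peri_lick_half = 0.165,
    during = c(-0.165, 0.165),
    baseline = c(-0.495, -0.165),
    farther = c(-0.825, -0.495),
    sound_pre = 0.5,
    sound_post = 0.5,
    pre_sound_period = 4.7,
    frame_rate = frame_rate
  ), class = "AnalysisWindows")
}

#' Down-sample lick times to the imaging frame grid
#'
#' Lick onsets recorded at native resolution (500 Hz) are mapped onto the
#' imaging frame grid: each time becomes `floor(t * frame_rate) / frame_rate`
#' and licks landing in the same frame collapse to a single event.
#'
#' @param licks_hi sorted lick onset times (s).
#' @param frame_rate imaging rate (Hz).
#' @return Sorted unique times on the frame grid.
#' @examples
#' downsampleLicks(c(0.010, 0.020, 0.040), 30)  # -> 0, 1/30
#' @export
downsampleLicks <- function(licks_hi, frame_rate = 30) {
  if (length(licks_hi) == 0) return(numeric(0))
  if (any(licks_hi < 0)) stop("lick times must be non-negative")
  if (is.unsorted(licks_hi)) stop("lick times must be sorted")
  sort(unique(floor(licks_hi * frame_rate) / frame_rate))
}

#' Convert a time interval around an anchor frame to a frame range
#'
#' Intervals are half-open `[start, end)` and endpoints are converted with
#' nearest-frame rounding, so the 165 ms half-window is exactly 5 frames at
#' 30 Hz and the lick-onset frame belongs to the post-lick half. Frames are
#' 1-based. Events whose window would leave the recording are dropped, not
#' errors: the function returns `NULL` for those and callers count them.
#'
#' @param interval numeric length-2, window in seconds relative to the anchor.
#' @param frame_rate Hz.
#' @param anchor 1-based anchor frame.
#' @param n_frames total frames in the recording (bounds check); `Inf` skips
#'   the check.
#' @return Integer vector of frame indices, or `NULL` if out of bounds.
#' @examples
#' windowToFrames(c(-0.165, 0.165), 30, 100, 1000)  # frames 95..104
#' @export
windowToFrames <- function(interval, frame_rate, anchor, n_frames = Inf) {
  lo <- anchor + round(interval[1] * frame_rate)
  hi <- anchor + round(interval[2] * frame_rate)  # exclusive
  if (lo < 1 || hi - 1 > n_frames) return(NULL)
  seq.int(lo, hi - 1L)
}

#' Anchor frame for an event time
#'
#' The frame containing time `t` (1-based): `floor(t * frame_rate) + 1`.
#' Inverse of the frame-grid time `(frame - 1) / frame_rate` on grid points.
#'
#' @param t event time(s) in seconds.
#' @param frame_rate Hz.
#' @return Integer frame index/indices.
#' @export
timeToFrame <- function(t, frame_rate = 30) {
  as.integer(floor(t * frame_rate + 1e-9)) + 1L
}

#' @rdname timeToFrame
#' @param frame 1-based frame index.
#' @export
frameToTime <- function(frame, frame_rate = 30) {
  (frame - 1) / frame_rate
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the full analysis: the window set, the
#' significance level for classification tests, the event-rate inclusion
#' floor (cells averaging under 1 event/s across the session are excluded),
#' lick-burst thresholds, CCA latent dimensionality and repetition counts,
#' decoding repetitions, and the PCA variance fraction for the decoder.
#'
#' @param windows an [analysisWindows()] list.
#' @param alpha two-sided significance level for cell classification (0.05).
#' @param min_rate events/s cell-inclusion floor (1.0).
#' @param min_anchors minimum isolated-lick anchors per context (10).
#' @param pause_threshold burst-segmentation pause threshold (0.5 s).
#' @param cca_m latent dimensionality for alignment (10).
#' @param cca_reps within-day bound repetitions (500).
#' @param decode_reps per-group decoding repetitions (100).
#' @param decode_folds cross-validation folds (10).
#' @param variance_frac PCA cumulative variance fraction for decoding (0.80).
#' @param p_adjust multiple-testing correction across cells ("none";
#'   any method of [stats::p.adjust()]).
#' @param seed root RNG seed; every stage derives a named substream from it.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(windows = analysisWindows(), alpha = 0.05,
                           min_rate = 1.0, min_anchors = 10L,
                           pause_threshold = 0.5,
                           cca_m = 10L, cca_reps = 500L,
                           decode_reps = 100L, decode_folds = 10L,
                           variance_frac = 0.80, p_adjust = "none",
                           seed = 1L) {
  stopifnot(is.numeric(alpha))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (min_anchors < 1 || cca_reps < 1 || decode_reps < 1 || decode_folds < 1)
    stop("all counts must be >= 1")
  if (!(variance_frac > 0 && variance_frac <= 1))
    stop("variance_frac must lie in (0, 1]")
  structure(list(
    windows = windows, alpha = alpha, min_rate = min_rate,
    min_anchors = as.integer(min_anchors),
    pause_threshold = pause_threshold,
    cca_m = as.integer(cca_m), cca_reps = as.integer(cca_reps),
    decode_reps = as.integer(decode_reps),
    decode_folds = as.integer(decode_folds),
    variance_frac = variance_frac, p_adjust = p_adjust,
    seed = as.integer(seed)
  ), class = "PipelineConfig")
}
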