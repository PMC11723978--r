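#' Synthetic-session generator configuration
#'
#' Defines the generative model that emulates the delayed tone-detection
#' task and deconvolved calcium population activity: a six-bin experience
#' sequence (bins 1-3 training, 4-6 testing), tone/catch trial schedules
#' with exponential 5-10 s quiet periods, lick bursts whose length shrinks
#' with experience, and neural populations containing sound-responsive
#' cells plus enhanced/suppressed/non-modulated lick-locked cells whose
#' modulation is gated by the post-sound context, grows along an experience
#' curve, resets at the bin 3 -> 4 rule change, and carries planted pairwise
#' noise correlations via a per-group shared factor.
#'
#' Firing model per cell and frame:
#' `rate = baseline * (1 + e_b * A * g(t - t_lick) * gate(t)) + sound term
#' + shared factor + noise`, rectified at zero. `g` is a linear ramp rising
#' from 165 ms before the lick, peaking 100 ms after it and returning to
#' baseline by +330 ms. `gate` is 1 in the 4.7 s post-sound period and
#' `gate_leak` elsewhere. On HIT trials enhanced cells receive an extra
#' post-lick gain `choice_amp * e_b`, the planted HIT-vs-LL condition
#' contrast.
#'
#' @param n_cells cells per session (100).
#' @param f_enh,f_sup,f_sound planted fractions of enhanced, suppressed and
#'   sound-responsive cells (0.25, 0.15, 0.20).
#' @param baseline_rate baseline event rate, events/s (5).
#' @param amp_enh,amp_sup kernel amplitudes for enhanced (+) and suppressed
#'   (-) cells (1.2, 0.6); each cell gets a x0.8-1.2 jitter.
#' @param experience_curve per-bin modulation multiplier `e_b`, b = 1..6;
#'   grows within each phase and dips back toward the bin-1 level at the
#'   bin 3 -> 4 rule change.
#' @param gate_leak pre-sound leak of the lick modulation, in \[0, 1) (0.2).
#' @param choice_amp extra post-lick gain on enhanced cells in HIT trials
#'   (2), scaled per bin by `choice_curve`.
#' @param choice_curve per-bin multiplier of the choice gain; grows more
#'   steeply than `experience_curve`, emulating decision-related
#'   separation that compounds with task experience.
#' @param shared_factor_sd sd of the per-lick shared Gaussian factor (in
#'   units of baseline rate) planted within the enhanced and suppressed
#'   groups during the +/-165 ms peri-lick window (0.25); scaled per bin by
#'   `experience_curve`, emulating synchronized activity that heightens
#'   with task experience.
#' @param sound_amp evoked-response amplitude, events/s (1.5).
#' @param trials_per_session trials per session (100).
#' @param catch_frac fraction of catch trials (0.2).
#' @param sessions_per_bin sessions per bin (11, i.e. 66 sessions; tests use
#'   fewer).
#' @param outcome_prop 6 x 4 matrix of per-bin tone-trial outcome
#'   propensities (columns HIT, EL, LL, MISS).
#' @param fa_prob per-bin catch-trial lick probability.
#' @param pre_burst_prob per-bin probability of a spontaneous lick burst in
#'   each quiet period (declines with experience).
#' @param burst_len_mean per-bin mean number of licks after the first in a
#'   burst (shrinks with experience).
#' @param ili_mean mean intra-burst inter-lick interval, s (1/7: ~7 Hz
#'   licking).
#' @param noise "poisson" (counts per frame, spike-like) or "gaussian"
#'   (rectified Gaussian on rates; continuous, used for planted-correlation
#'   constructions).
#' @param noise_sd per-frame rate sd for the Gaussian law (events/s).
#' @param fov_um field-of-view side length for cell coordinates (500 um).
#' @param seed root seed; sessions draw named substreams from it.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(n_cells = 100L, f_enh = 0.25, f_sup = 0.15,
                      f_sound = 0.20, baseline_rate = 5,
                      amp_enh = 1.2, amp_sup = 0.6,
                      experience_curve = c(0.30, 0.65, 1.00,
                                           0.35, 0.70, 1.05),
                      gate_leak = 0.2, choice_amp = 2,
                      choice_curve = c(0.10, 0.20, 0.30,
                                       0.35, 0.70, 1.10),
                      shared_factor_sd = 0.25, sound_amp = 1.5,
                      trials_per_session = 100L, catch_frac = 0.2,
                      sessions_per_bin = 11L,
                      outcome_prop = rbind(
                        c(0.25, 0.30, 0.20, 0.25),
                        c(0.35, 0.25, 0.20, 0.20),
                        c(0.45, 0.20, 0.20, 0.15),
                        c(0.40, 0.25, 0.20, 0.15),
                        c(0.50, 0.15, 0.25, 0.10),
                        c(0.55, 0.10, 0.25, 0.10)),
                      fa_prob = c(0.6, 0.5, 0.4, 0.35, 0.3, 0.25),
                      pre_burst_prob = c(0.9, 0.75, 0.6, 0.55, 0.45, 0.35),
                      burst_len_mean = c(4, 3.5, 3, 2.5, 2, 1.5),
                      ili_mean = 1 / 7,
                      noise = c("poisson", "gaussian"), noise_sd = 1,
                      fov_um = 500, seed = 1L) {
  noise <- match.arg(noise)
  if (f_enh + f_sup > 1) stop("f_enh + f_sup must be <= 1")
  if (any(experience_curve <= 0)) stop("experience_curve must be positive")
  if (gate_leak < 0 || gate_leak >= 1) stop("gate_leak must lie in [0, 1)")
  stopifnot(length(choice_curve) == 6, length(experience_curve) == 6)
  if (baseline_rate < 0 || sound_amp < 0) stop("rates must be >= 0")
  colnames(outcome_prop) <- c("HIT", "EL", "LL", "MISS")
  if (any(abs(rowSums(outcome_prop) - 1) > 1e-8))
    stop("outcome_prop rows must sum to 1")
  structure(list(
    n_cells = as.integer(n_cells), f_enh = f_enh, f_sup = f_sup,
    f_sound = f_sound, baseline_rate = baseline_rate,
    amp_enh = amp_enh, amp_sup = amp_sup,
    experience_curve = experience_curve, gate_leak = gate_leak,
    choice_amp = choice_amp, choice_curve = choice_curve,
    shared_factor_sd = shared_factor_sd,
    sound_amp = sound_amp,
    trials_per_session = as.integer(trials_per_session),
    catch_frac = catch_frac, sessions_per_bin = as.integer(sessions_per_bin),
    outcome_prop = outcome_prop, fa_prob = fa_prob,
    pre_burst_prob = pre_burst_prob, burst_len_mean = burst_len_mean,
    ili_mean = ili_mean, noise = noise, noise_sd = noise_sd,
    fov_um = fov_um, seed = as.integer(seed)
  ), class = "SimConfig")
}

# Lick kernel g(tau): ramp from -165 ms, peak +1 at +100 ms, back to zero at
# +330 ms; zero outside.
lickKernel <- function(tau) {
  g <- ifelse(tau < 0.1, (tau + 0.165) / 0.265, (0.33 - tau) / 0.23)
  g[tau < -0.165 | tau > 0.33] <- 0
  pmax(g, 0)
}

# A burst of licks starting at `start`: intra-burst intervals ~7 Hz
# (gamma-distributed, floored at 20 ms), n_extra licks after the first.
.burstLicks <- function(start, n_extra, ili_mean) {
  if (n_extra <= 0) return(start)
  gaps <- pmax(stats::rgamma(n_extra, shape = 8, rate = 8 / ili_mean), 0.02)
  c(start, start + cumsum(gaps))
}

#' Generate one session's behavior
#'
#' Builds the trial schedule (tone or catch, exponential 5-10 s quiet
#' periods), draws each tone trial's intended outcome from the bin's
#' propensities, places the first post-sound lick in the corresponding task
#' window, appends a lick burst with bin-dependent length, adds spontaneous
#' pre-sound bursts with bin-dependent probability, and finally labels
#' outcomes by running [classifyOutcomes()] on the generated licks, so the
#' generator and the classifier agree by construction.
#'
#' Uses the current RNG state; seed via [generateExperiment()] or
#' `set.seed()`.
#'
#' @param cfg a [simConfig()].
#' @param bin_index experience bin 1-6.
#' @return list: `trials` (classified trial table), `licks_hi` (500 Hz
#'   grid), `intended` (generative outcome per trial).
#' @export
generateBehavior <- function(cfg, bin_index) {
  b <- bin_index
  n <- cfg$trials_per_session
  phase <- if (b <= 3) "training" else "testing"
  quiet <- 5 + pmin(stats::rexp(n, rate = 1 / 1.5), 5)
  onsets <- numeric(n)
  prev_end <- 2
  for (i in seq_len(n)) {
    onsets[i] <- prev_end + quiet[i]
    prev_end <- onsets[i] + 6
  }
  kind <- ifelse(stats::runif(n) < cfg$catch_frac, "CATCH", "TONE")
  freq <- ifelse(kind == "TONE", sample(c(6, 16), n, replace = TRUE),
                 NA_real_)
  intended <- character(n)
  licks <- numeric(0)
  prop <- cfg$outcome_prop[b, ]
  for (i in seq_len(n)) {
    on <- onsets[i]
    if (kind[i] == "TONE") {
      o <- sample(names(prop), 1, prob = prop)
      intended[i] <- o
      t1 <- switch(o,
        EL = stats::runif(1, 0.25, 1.45),
        HIT = stats::runif(1, 1.55, 2.95),
        LL = stats::runif(1, 3.05, 4.45),
        MISS = NA_real_)
    } else {
      fa <- stats::runif(1) < cfg$fa_prob[b]
      intended[i] <- if (fa) "FA" else "CR"
      t1 <- if (fa) stats::runif(1, 0.25, 4.45) else NA_real_
    }
    if (!is.na(t1)) {
      n_extra <- stats::rgeom(1, prob = 1 / (1 + cfg$burst_len_mean[b]))
      licks <- c(licks, .burstLicks(on + t1, n_extra, cfg$ili_mean))
    }
    # spontaneous pre-sound burst inside the quiet period
    if (stats::runif(1) < cfg$pre_burst_prob[b]) {
      q0 <- on - quiet[i] + 0.3
      q1 <- on - 2.0
      if (q1 > q0) {
        st <- stats::runif(1, q0, q1)
        n_extra <- stats::rgeom(1, prob = 1 / (1 + cfg$burst_len_mean[b]))
        pre <- .burstLicks(st, n_extra, cfg$ili_mean)
        licks <- c(licks, pre[pre < on - 1.2])
      }
    }
  }
  licks_hi <- sort(unique(round(licks * 500) / 500))  # native 500 Hz grid
  trials <- data.frame(onset = onsets, kind = kind, freq = freq,
                       quiet_period = quiet)
  trials <- classifyOutcomes(trials, licks_hi, taskRule(), phase)
  list(trials = trials, licks_hi = licks_hi, intended = intended)
}

# Draw per-cell ground truth: class labels partition cells; the
# sound-responsive flag is independent of the lick-modulation class.
.drawClasses <- function(cfg) {
  n <- cfg$n_cells
  n_enh <- round(cfg$f_enh * n)
  n_sup <- round(cfg$f_sup * n)
  label <- rep("NONE", n)
  ord <- sample.int(n)
  label[ord[seq_len(n_enh)]] <- "ENHANCED"
  if (n_sup > 0) label[ord[n_enh + seq_len(n_sup)]] <- "SUPPRESSED"
  amp <- numeric(n)
  amp[label == "ENHANCED"] <- cfg$amp_enh *
    stats::runif(sum(label == "ENHANCED"), 0.8, 1.2)
  amp[label == "SUPPRESSED"] <- -cfg$amp_sup *
    stats::runif(sum(label == "SUPPRESSED"), 0.8, 1.2)
  sound <- stats::runif(n) < cfg$f_sound
  data.frame(cell = seq_len(n), label = label, amplitude = amp,
             sound_responsive = sound)
}

#' Generate one session's neural activity
#'
#' Applies the firing model described in [simConfig()] to a generated
#' behavior, on the 30 Hz frame grid. The per-group shared factor is drawn
#' once per lick and added, in units of baseline rate, over the exact 10
#' frames of the analysis "during" window, planting trial-to-trial noise
#' correlations within the enhanced and suppressed groups that are present
#' in the peri-lick window and absent in earlier windows.
#'
#' @param cfg a [simConfig()].
#' @param behavior output of [generateBehavior()].
#' @param bin_index experience bin 1-6.
#' @param classes optional ground-truth table (from a previous draw);
#'   defaults to a fresh draw.
#' @return list: `activity` (cells x frames, events/s), `classes`
#'   (ground-truth data.frame).
#' @export
generateNeural <- function(cfg, behavior, bin_index, classes = NULL) {
  if (is.null(classes)) classes <- .drawClasses(cfg)
  trials <- behavior$trials
  licks <- behavior$licks_hi
  e_b <- cfg$experience_curve[bin_index]
  fr <- 30
  n_frames <- as.integer(ceiling((max(trials$onset) + 6) * fr))
  tc <- (seq_len(n_frames) - 0.5) / fr
  tone_onsets <- trials$onset[trials$kind == "TONE"]

  # frame profiles: gated lick kernel, and the HIT-trial post-lick bonus
  P_gate <- numeric(n_frames)
  P_choice <- numeric(n_frames)
  ctx <- lickContext(licks, tone_onsets)
  gov <- findInterval(licks, trials$onset)
  for (j in seq_along(licks)) {
    t <- licks[j]
    i0 <- max(1L, as.integer(floor((t - 0.165) * fr)))
    i1 <- min(n_frames, as.integer(ceiling((t + 0.33) * fr)) + 1L)
    idx <- i0:i1
    g <- lickKernel(tc[idx] - t)
    gate <- if (ctx[j] == "POST_SOUND") 1 else cfg$gate_leak
    P_gate[idx] <- pmax(P_gate[idx], g * gate)
    if (ctx[j] == "POST_SOUND" && gov[j] >= 1 &&
        trials$outcome[gov[j]] == "HIT") {
      post <- tc[idx] - t >= 0
      P_choice[idx][post] <- pmax(P_choice[idx][post], g[post])
    }
  }

  A <- classes$amplitude
  R <- cfg$baseline_rate * (1 + e_b * outer(A, P_gate))
  enh <- classes$label == "ENHANCED"
  sup <- classes$label == "SUPPRESSED"
  if (any(enh) && cfg$choice_amp > 0) {
    # decision-related separation compounds with experience: its curve is
    # steeper than the overall lick-modulation curve, so the HIT-vs-LL
    # contrast strengthens relative to the shared dynamics
    R[enh, ] <- R[enh, ] + cfg$baseline_rate * cfg$choice_amp *
      cfg$choice_curve[bin_index] * outer(A[enh], P_choice)
  }
  if (any(classes$sound_responsive) && cfg$sound_amp > 0) {
    S <- numeric(n_frames)
    for (o in tone_onsets) {
      i0 <- as.integer(floor(o * fr)) + 1L
      i1 <- min(n_frames, i0 + 14L)  # 0.5 s
      idx <- i0:i1
      S[idx] <- S[idx] + exp(-(tc[idx] - o) / 0.15) * (tc[idx] >= o)
    }
    R[classes$sound_responsive, ] <-
      R[classes$sound_responsive, , drop = FALSE] +
      cfg$sound_amp * rep(S, each = sum(classes$sound_responsive))
  }
  sf_sd <- cfg$shared_factor_sd * e_b
  if (sf_sd > 0 && (any(enh) || any(sup))) {
    for (t in licks) {
      a <- timeToFrame(t, fr)
      idx <- windowToFrames(c(-0.165, 0.165), fr, a, n_frames)
      if (is.null(idx)) next
      if (any(enh)) R[enh, idx] <- R[enh, idx] +
          cfg$baseline_rate * stats::rnorm(1, 0, sf_sd)
      if (any(sup)) R[sup, idx] <- R[sup, idx] +
          cfg$baseline_rate * stats::rnorm(1, 0, sf_sd)
    }
  }
  R[R < 0] <- 0
  activity <- if (cfg$noise == "poisson") {
    matrix(stats::rpois(length(R), R / fr) * fr, nrow = nrow(R))
  } else {
    pmax(R + matrix(stats::rnorm(length(R), 0, cfg$noise_sd),
                    nrow = nrow(R)), 0)
  }
  list(activity = activity, classes = classes)
}

#' Generate one full session
#'
#' @param cfg a [simConfig()].
#' @param bin_index experience bin 1-6.
#' @param session_index ordinal session number.
#' @return list: `session` (a [SessionRecording-class]) and `ground_truth`
#'   (per-cell class table plus the per-trial generative outcome).
#' @export
generateSession <- function(cfg, bin_index, session_index = 1L) {
  beh <- generateBehavior(cfg, bin_index)
  neu <- generateNeural(cfg, beh, bin_index)
  xy <- matrix(stats::runif(2 * cfg$n_cells, 0, cfg$fov_um), ncol = 2)
  tone <- beh$trials$kind == "TONE"
  sr <- SessionRecording(
    activity = neu$activity, frameRate = 30, cellXY = xy,
    licksHi = beh$licks_hi,
    stimOnsets = beh$trials$onset[tone],
    stimFreqs = beh$trials$freq[tone],
    trials = beh$trials, sessionIndex = session_index,
    binIndex = bin_index)
  gt <- neu$classes
  gt$session <- session_index
  gt$bin <- bin_index
  list(session = sr,
       ground_truth = list(cells = gt, intended_outcome = beh$intended))
}

#' Generate a full synthetic experiment
#'
#' `sessions_per_bin` sessions per bin, bins 1-6 in order; cell identities
#' are resampled per session (the same field of view is re-imaged across
#' days, but not necessarily the same cells). Each session runs in a named
#' RNG substream of `cfg$seed`, so the experiment is reproducible and any
#' single session can be regenerated independently.
#'
#' @param cfg a [simConfig()].
#' @return list: `sessions` (list of [SessionRecording-class]),
#'   `ground_truth` (list, parallel to sessions).
#' @export
generateExperiment <- function(cfg) {
  sessions <- list()
  gts <- list()
  k <- 0L
  for (b in 1:6) {
    for (s in seq_len(cfg$sessions_per_bin)) {
      k <- k + 1L
      res <- withSubstream(cfg$seed, sprintf("session_%d_%d", b, s),
                           function() generateSession(cfg, b, k))
      sessions[[k]] <- res$session
      gts[[k]] <- res$ground_truth
    }
  }
  list(sessions = sessions, ground_truth = gts)
}

#' Planted window-mean noise correlation implied by a SimConfig
#'
#' For the Gaussian noise law the trial-to-trial correlation of two
#' same-group cells' during-window means is
#' `(baseline * sd_shared)^2 / ((baseline * sd_shared)^2 + sd_noise^2 / 10)`
#' (10 frames per window, independent per-frame noise, one shared factor per
#' lick). For the Poisson law the noise term is approximated by the
#' baseline-rate variance `3 * baseline` of a 10-frame window mean.
#'
#' @param cfg a [simConfig()].
#' @param bin_index bin whose experience multiplier scales the shared
#'   factor.
#' @return the implied pairwise correlation.
#' @export
plantedNoiseCorr <- function(cfg, bin_index = 1L) {
  num <- (cfg$baseline_rate * cfg$shared_factor_sd *
          cfg$experience_curve[bin_index])^2
  den <- if (cfg$noise == "gaussian") num + cfg$noise_sd^2 / 10
         else num + 3 * cfg$baseline_rate
  num / den
}
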