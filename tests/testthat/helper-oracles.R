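# Independent brute-force oracles and small generator configs shared by the
# test files. The oracles deliberately use naive enumeration, independent of
# the package's implementations.

# Outcome by direct interval membership for a single trial.
oracleOutcome <- function(onset, kind, licks) {
  rel <- licks[licks >= onset] - onset
  in_win <- rel[rel < 4.5]
  if (kind == "CATCH") return(if (length(in_win)) "FA" else "CR")
  if (!length(in_win)) return("MISS")
  t1 <- in_win[1]
  if (t1 >= 0 && t1 < 1.5) "EL"
  else if (t1 < 3.0) "HIT"
  else "LL"
}

# O(n^2) burst segmentation: a run i..j is connected iff *every*
# consecutive gap inside it is <= threshold, re-checked from scratch at
# each extension (quadratic, structurally independent of the
# implementation's single diff pass).
oracleBursts <- function(licks, thr = 0.5) {
  n <- length(licks)
  if (n == 0) return(list())
  conn <- function(i, j) all(diff(licks[i:j]) <= thr)
  grp <- integer(n); g <- 0L; i <- 1L
  while (i <= n) {
    g <- g + 1L
    j <- i
    while (j < n && conn(i, j + 1L)) j <- j + 1L
    grp[i:j] <- g
    i <- j + 1L
  }
  unname(split(licks, grp))
}

# Random lick schedule around a trial onset, mixing all outcome windows.
randomSchedule <- function() {
  n <- rpois(1, 4)
  sort(runif(n, -2, 7))
}

# Generator config with every modulation switched off (null model) on the
# continuous noise law; 50 cells, all-HIT schedule so every trial yields an
# isolated post-sound anchor.
nullSimConfig <- function(seed, n_cells = 50L, n_trials = 45L,
                          amp_enh = 0, n_anchors_hint = NULL) {
  simConfig(
    n_cells = n_cells, f_enh = 0.3, f_sup = 0.2, f_sound = 0,
    baseline_rate = 20, amp_enh = amp_enh, amp_sup = 0,
    experience_curve = rep(1, 6), choice_curve = rep(0, 6),
    gate_leak = 0, choice_amp = 0, shared_factor_sd = 0, sound_amp = 0,
    trials_per_session = n_trials, catch_frac = 0,
    outcome_prop = matrix(rep(c(1, 0, 0, 0), 6), 6, byrow = TRUE),
    fa_prob = rep(0, 6), pre_burst_prob = rep(0, 6),
    burst_len_mean = rep(0, 6),
    noise = "gaussian", noise_sd = 3, seed = seed)
}

# Shared-factor construction with an exactly planted window-mean
# correlation of `rho` among the enhanced group.
rhoSimConfig <- function(n_trials, rho = 0.3, seed = 1L) {
  baseline <- 20; sf <- 0.05
  noise_sd <- sqrt(10 * (baseline * sf)^2 * (1 - rho) / rho)
  simConfig(
    n_cells = 20L, f_enh = 0.8, f_sup = 0, f_sound = 0,
    baseline_rate = baseline, amp_enh = 0, amp_sup = 0,
    experience_curve = rep(1, 6), choice_curve = rep(0, 6),
    gate_leak = 0, choice_amp = 0, shared_factor_sd = sf, sound_amp = 0,
    trials_per_session = as.integer(n_trials), catch_frac = 0,
    outcome_prop = matrix(rep(c(1, 0, 0, 0), 6), 6, byrow = TRUE),
    fa_prob = rep(0, 6), pre_burst_prob = rep(0, 6),
    burst_len_mean = rep(0, 6),
    noise = "gaussian", noise_sd = noise_sd, seed = seed)
}

# Small fast session for plumbing tests.
tinySimConfig <- function(seed = 1L, n_cells = 30L,
                          trials_per_session = 30L, ...) {
  simConfig(n_cells = n_cells, trials_per_session = trials_per_session,
            sessions_per_bin = 1L, seed = seed, ...)
}

# Hand-built session: one trial table, constant-rate cells with optional
# per-cell peri-lick bumps, for deterministic window arithmetic tests.
manualSession <- function(activity, licks = numeric(0),
                          stim_onsets = numeric(0), bin_index = 4L) {
  n_tone <- length(stim_onsets)
  onsets <- if (n_tone) stim_onsets else 10
  trials <- data.frame(onset = onsets,
                       kind = if (n_tone) "TONE" else "CATCH",
                       freq = if (n_tone) 6 else NA_real_,
                       quiet_period = 6)
  trials <- classifyOutcomes(trials, licks, taskRule(),
                             if (bin_index <= 3) "training" else "testing")
  SessionRecording(activity = activity, frameRate = 30,
                   cellXY = matrix(runif(2 * nrow(activity), 0, 100),
                                   ncol = 2),
                   licksHi = licks,
                   stimOnsets = stim_onsets,
                   stimFreqs = rep(6, length(stim_onsets)),
                   trials = trials, sessionIndex = 1L,
                   binIndex = bin_index)
}

# Synthetic LatentDynamics with the given scores and trial structure.
manualLatents <- function(scores, n_trials, n_tau, bin = 4L,
                          conditions = c("HIT", "LL")) {
  half <- n_trials / 2
  new("LatentDynamics", scores = scores,
      rotation = diag(ncol(scores)), center = rep(0, ncol(scores)),
      condition = rep(conditions, each = half * n_tau),
      trial = rep(seq_len(n_trials), each = n_tau),
      tau = rep(seq(-0.5, by = 1 / 30, length.out = n_tau), n_trials),
      binIndex = as.integer(bin))
}
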