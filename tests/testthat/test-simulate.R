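test_that("an experiment has sessions_per_bin sessions per bin, in order", {
  cfg <- simConfig(n_cells = 10L, trials_per_session = 12L,
                   sessions_per_bin = 2L, seed = 3)
  exp <- generateExperiment(cfg)
  expect_length(exp$sessions, 12)
  expect_equal(vapply(exp$sessions, binIndex, integer(1)),
               rep(1:6, each = 2))
  expect_equal(vapply(exp$sessions, sessionPhase, character(1)),
               rep(c("training", "testing"), each = 6))
})

test_that("the same seed regenerates an identical experiment", {
  cfg <- simConfig(n_cells = 8L, trials_per_session = 10L,
                   sessions_per_bin = 1L, seed = 11)
  e1 <- generateExperiment(cfg)
  e2 <- generateExperiment(cfg)
  expect_equal(activityMatrix(e1$sessions[[4]]),
               activityMatrix(e2$sessions[[4]]))
  expect_equal(licksHi(e1$sessions[[2]]), licksHi(e2$sessions[[2]]))
  expect_equal(trialTable(e1$sessions[[6]]), trialTable(e2$sessions[[6]]))
  expect_equal(e1$ground_truth[[3]]$cells, e2$ground_truth[[3]]$cells)
})

test_that("degenerate outcome propensities force the outcome", {
  cfg <- simConfig(n_cells = 5L, trials_per_session = 30L,
                   catch_frac = 0,
                   outcome_prop = matrix(rep(c(1, 0, 0, 0), 6), 6,
                                         byrow = TRUE),
                   pre_burst_prob = rep(0, 6), seed = 5)
  set.seed(5)
  beh <- generateBehavior(cfg, 5)
  expect_true(all(beh$trials$outcome == "HIT"))
  # no licking at all: every tone trial is a MISS, every catch a CR
  cfg0 <- simConfig(n_cells = 5L, trials_per_session = 30L,
                    catch_frac = 0.3,
                    outcome_prop = matrix(rep(c(0, 0, 0, 1), 6), 6,
                                          byrow = TRUE),
                    fa_prob = rep(0, 6), pre_burst_prob = rep(0, 6),
                    seed = 5)
  set.seed(5)
  beh0 <- generateBehavior(cfg0, 2)
  expect_length(beh0$licks_hi, 0)
  expect_true(all(beh0$trials$outcome[beh0$trials$kind == "TONE"] ==
                    "MISS"))
  expect_true(all(beh0$trials$outcome[beh0$trials$kind == "CATCH"] ==
                    "CR"))
})

test_that("generated outcomes agree with the classifier on every trial", {
  cfg <- simConfig(n_cells = 5L, trials_per_session = 60L, seed = 9)
  set.seed(9)
  for (b in c(1, 4, 6)) {
    beh <- generateBehavior(cfg, b)
    reclassified <- classifyOutcomes(
      beh$trials[c("onset", "kind", "freq", "quiet_period")],
      beh$licks_hi, taskRule(), if (b <= 3) "training" else "testing")
    expect_equal(beh$trials$outcome, reclassified$outcome)
    expect_equal(beh$trials$outcome, beh$intended)
  }
})

test_that("empirical outcome frequencies match the propensities", {
  cfg <- simConfig(n_cells = 5L, trials_per_session = 200L,
                   catch_frac = 0, pre_burst_prob = rep(0, 6), seed = 13)
  set.seed(13)
  beh <- generateBehavior(cfg, 6)
  prop <- cfg$outcome_prop[6, ]
  n <- nrow(beh$trials)
  for (oc in names(prop)) {
    phat <- mean(beh$trials$outcome == oc)
    se <- sqrt(prop[[oc]] * (1 - prop[[oc]]) / n)
    expect_lt(abs(phat - prop[[oc]]), 3 * se + 1e-12)
  }
})

test_that("quiet periods follow the truncated-exponential law on [5, 10]", {
  cfg <- simConfig(n_cells = 5L, trials_per_session = 300L, seed = 2)
  set.seed(2)
  q <- generateBehavior(cfg, 1)$trials$quiet_period
  expect_true(all(q >= 5 & q <= 10))
  expect_lt(abs(mean(q) - (5 + 1.5)), 0.4)  # cap at 5 barely binds
})

test_that("a null generator plants nothing the classifier can find", {
  set.seed(31)
  r <- generateSession(nullSimConfig(31), 6, 1)
  s <- r$session
  anc <- selectIsolatedLicks(licksLo(s), stimOnsets(s))
  lab <- classLabels(classifyLickModulation(s, anc))
  # binomial 3-SE bound on 50 cells at alpha = 0.05
  expect_lt(mean(lab != "NONE"), 0.05 + 3 * sqrt(0.05 * 0.95 / 50))
  # and pairwise correlations sit at zero without the shared factor
  wam <- windowActivityMatrix(s, anc$time[anc$context == "POST_SOUND"],
                              "DURING")
  nc <- noiseCorr(wam$matrix)
  expect_lt(abs(mean(nc$r[upper.tri(nc$r)])), 0.02)
})

test_that("a strongly modulated cell is detected on most seeds", {
  # calibrated construction: gain e*A = 1 on the continuous noise law,
  # ~60 isolated post-sound anchors
  hits <- vapply(1:10, function(sd) {
    set.seed(sd)
    r <- generateSession(nullSimConfig(sd, n_trials = 60L, amp_enh = 1),
                         6, 1)
    s <- r$session
    gt <- r$ground_truth$cells
    anc <- selectIsolatedLicks(licksLo(s), stimOnsets(s))
    lab <- classLabels(classifyLickModulation(s, anc))
    mean(lab[gt$label == "ENHANCED"] == "ENHANCED")
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("planted class fractions and amplitudes are recorded", {
  cfg <- simConfig(n_cells = 100L, trials_per_session = 10L, seed = 17)
  set.seed(17)
  r <- generateSession(cfg, 3, 1)
  gt <- r$ground_truth$cells
  expect_equal(sum(gt$label == "ENHANCED"), 25)
  expect_equal(sum(gt$label == "SUPPRESSED"), 15)
  expect_true(all(gt$amplitude[gt$label == "ENHANCED"] > 0))
  expect_true(all(gt$amplitude[gt$label == "SUPPRESSED"] < 0))
  expect_true(all(gt$amplitude[gt$label == "NONE"] == 0))
  expect_true(all(activityMatrix(r$session) >= 0))
})

test_that("simConfig rejects inconsistent parameters", {
  expect_error(simConfig(f_enh = 0.7, f_sup = 0.5), "f_enh")
  expect_error(simConfig(gate_leak = 1), "gate_leak")
  expect_error(simConfig(experience_curve = c(1, 1, 0, 1, 1, 1)),
               "positive")
  expect_error(simConfig(outcome_prop = matrix(rep(c(0.5, 0, 0, 0), 6),
                                               6, byrow = TRUE)),
               "sum to 1")
})

test_that("lick probabilities shift from pre- to post-sound with experience", {
  cfg <- simConfig(n_cells = 5L, trials_per_session = 150L, seed = 37)
  lp <- lapply(c(1, 3), function(b) {
    set.seed(37)
    beh <- generateBehavior(cfg, b)
    lickProbabilities(beh$trials, beh$licks_hi)
  })
  expect_gt(lp[[2]]$post, lp[[1]]$post)  # post-sound licking rises 1 -> 3
  expect_lt(lp[[2]]$pre, lp[[1]]$pre)    # pre-sound licking falls
})
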