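test_that("isolated-lick selection enforces the 330 ms clearance", {
  got <- selectIsolatedLicks(c(2.0, 2.1, 3.0), 1.9)
  expect_equal(got$time, 3.0)
  expect_equal(selectIsolatedLicks(5.0, numeric(0))$time, 5.0)
  # a lapse of exactly 330 ms counts as clear ("at least 330 ms")
  expect_equal(selectIsolatedLicks(c(1.0, 1.33), numeric(0))$time,
               c(1.0, 1.33))
  expect_equal(selectIsolatedLicks(c(1.0, 1.32), numeric(0))$time, 1.0)
  # stimulus onsets block a lick just like other licks do
  expect_equal(nrow(selectIsolatedLicks(2.1, 2.0)), 0)
})

test_that("anchors are tagged by position relative to the tone onset", {
  got <- selectIsolatedLicks(c(5.0, 12.0, 16.0), 10.0)
  expect_equal(got$context, c("PRE_SOUND", "POST_SOUND", "PRE_SOUND"))
})

test_that("classification finds a hand-built enhanced and suppressed cell", {
  # three cells on a flat rate; cells 1/2 bump up/down around each lick
  nf <- 3000L
  licks <- seq(10, 80, by = 5)
  stims <- licks - 2  # each lick 2 s after a tone: post-sound context
  act <- matrix(4, 3, nf)
  for (t in licks) {
    a <- timeToFrame(t, 30)
    act[1, (a - 5):(a + 4)] <- 9
    act[2, (a - 5):(a + 4)] <- 0.5
  }
  s <- manualSession(act, licks = licks, stim_onsets = stims)
  anc <- selectIsolatedLicks(licks, stims)
  cls <- classifyLickModulation(s, anc)
  expect_equal(unname(classLabels(cls)),
               c("ENHANCED", "SUPPRESSED", "NONE"))
  tb <- classTable(cls)
  expect_true(tb$p_value[1] < 0.05 && tb$sign[1] > 0)
  expect_true(tb$p_value[2] < 0.05 && tb$sign[2] < 0)
  # constant cell: every paired difference is zero, p undefined, NONE
  expect_true(is.na(tb$p_value[3]) || tb$p_value[3] >= 0.05)
})

test_that("labels are invariant to positive rescaling of a cell's trace", {
  set.seed(21)
  r <- generateSession(tinySimConfig(21), 6, 1)
  s <- r$session
  anc <- selectIsolatedLicks(licksLo(s), stimOnsets(s))
  cls1 <- classTable(classifyLickModulation(s, anc))
  act <- activityMatrix(s)
  act[5, ] <- act[5, ] * 3
  s2 <- SessionRecording(act, frameRate(s), cellXY(s), licksHi(s),
                         licksLo(s), stimOnsets(s), stimFreqs(s),
                         trialTable(s), sessionIndex(s), binIndex(s))
  cls2 <- classTable(classifyLickModulation(s2, anc))
  expect_equal(cls1$label[5], cls2$label[5])
  expect_equal(cls1$p_value[5], cls2$p_value[5])
  expect_equal(cls1$sign[5], cls2$sign[5])
})

test_that("the event-rate floor excludes silent cells with a reason", {
  act <- matrix(4, 2, 2400)
  act[2, ] <- 0  # silent cell
  licks <- seq(10, 75, by = 5)
  stims <- licks - 2
  s <- manualSession(act, licks = licks, stim_onsets = stims)
  anc <- selectIsolatedLicks(licks, stims)
  tb <- classTable(classifyLickModulation(s, anc))
  expect_false(tb$included[2])
  expect_equal(tb$label[2], "NONE")
  expect_equal(tb$reason[2], "rate_floor")
})

test_that("too few anchors yields all-NONE with a warning", {
  act <- matrix(4, 2, 2000)
  s <- manualSession(act, licks = c(10, 20), stim_onsets = 5.0)
  anc <- selectIsolatedLicks(c(10, 20), 5.0)
  expect_warning(cls <- classifyLickModulation(s, anc), "anchors")
  expect_true(all(classTable(cls)$label == "NONE"))
  expect_true(cls@lowAnchors)
})

test_that("sound-responsive cells are recovered and nulls stay near alpha", {
  set.seed(23)
  cfg <- simConfig(n_cells = 40L, f_enh = 0, f_sup = 0, f_sound = 0.5,
                   amp_enh = 0, amp_sup = 0, shared_factor_sd = 0,
                   choice_amp = 0, sound_amp = 8,
                   trials_per_session = 50L, catch_frac = 0, seed = 23)
  r <- generateSession(cfg, 6, 1)
  gt <- r$ground_truth$cells
  snd <- classifySoundResponsive(r$session)
  expect_gt(mean(snd$sound_responsive[gt$sound_responsive]), 0.8)
  expect_lt(mean(snd$sound_responsive[!gt$sound_responsive]), 0.25)
})

test_that("peri-lick summary computes deltas and proportional change", {
  # cell 1: post-lick rate doubles (pre 3 -> post 6): prop_change = 1/3
  nf <- 3000L
  licks <- seq(10, 80, by = 5)
  stims <- licks - 2
  act <- matrix(3, 2, nf)
  for (t in licks) {
    a <- timeToFrame(t, 30)
    act[1, a:(a + 4)] <- 6
  }
  s <- manualSession(act, licks = licks, stim_onsets = stims)
  anc <- selectIsolatedLicks(licks, stims)
  ps <- periLickSummary(s, anc)
  expect_equal(ps$cells$pre_mean[1], 3)
  expect_equal(ps$cells$post_mean[1], 6)
  expect_equal(ps$cells$delta[1], 3)
  expect_equal(ps$cells$prop_change[1], 1 / 3, tolerance = 1e-6)
  expect_gt(ps$cells$abs_peak[1], 0)
  # cell 2 is constant: no change, z trace undefined
  expect_equal(ps$cells$delta[2], 0)
  expect_equal(ps$cells$prop_change[2], 0)
  expect_true(is.na(ps$cells$abs_peak[2]))
  expect_equal(ps$n_anchors_used + ps$n_anchors_dropped, nrow(anc))
})

test_that("spatial distances are Euclidean and small groups yield empties", {
  xy <- rbind(c(0, 0), c(3, 4), c(10, 10))
  labels <- c("ENHANCED", "ENHANCED", "SUPPRESSED")
  d <- pairwiseSpatialDistance(xy, labels)
  expect_equal(d$within$ENHANCED, 5)
  expect_length(d$within$SUPPRESSED, 0)  # one-cell group
  expect_length(d$within$NONE, 0)
  d2 <- pairwiseSpatialDistance(xy, labels,
                                sound_responsive = c(FALSE, FALSE, TRUE))
  expect_equal(sort(d2$cross$SOUNDxENHANCED),
               sort(c(sqrt(200), sqrt(85))))
})

test_that("uniformly scattered classes are spatially indistinguishable", {
  set.seed(29)
  ps <- replicate(12, {
    xy <- matrix(runif(200, 0, 500), ncol = 2)
    labels <- sample(rep(c("ENHANCED", "SUPPRESSED", "NONE"),
                         times = c(30, 30, 40)))
    d <- pairwiseSpatialDistance(xy, labels)
    suppressWarnings(ks.test(d$within$ENHANCED,
                             d$within$SUPPRESSED)$p.value)
  })
  expect_gt(median(ps), 0.05)
})
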