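test_that("trial outcomes follow the task windows", {
  trials <- data.frame(onset = 10, kind = "TONE", freq = 6,
                       quiet_period = 6)
  out <- function(licks)
    classifyOutcomes(trials, licks, taskRule(), "testing")$outcome
  expect_equal(out(11.2), "EL")
  expect_equal(out(12.0), "HIT")
  expect_equal(out(13.5), "LL")
  expect_equal(out(numeric(0)), "MISS")
  expect_equal(out(14.6), "MISS")  # outside the response window
  catch <- data.frame(onset = 10, kind = "CATCH", freq = NA_real_,
                      quiet_period = 6)
  expect_equal(classifyOutcomes(catch, 12.2, taskRule(),
                                "testing")$outcome, "FA")
  expect_equal(classifyOutcomes(catch, numeric(0), taskRule(),
                                "testing")$outcome, "CR")
})

test_that("outcome classifier matches brute-force interval enumeration", {
  set.seed(101)
  rule <- taskRule()
  for (i in 1:300) {
    onset <- runif(1, 5, 20)
    kind <- sample(c("TONE", "CATCH"), 1)
    licks <- onset + randomSchedule()
    trials <- data.frame(onset = onset, kind = kind,
                         freq = ifelse(kind == "TONE", 6, NA_real_),
                         quiet_period = 6)
    got <- classifyOutcomes(trials, licks, rule, "testing")$outcome
    expect_equal(got, oracleOutcome(onset, kind, licks))
  }
})

test_that("overlapping trials are rejected", {
  trials <- data.frame(onset = c(10, 12), kind = "TONE", freq = 6,
                       quiet_period = 6)
  expect_error(classifyOutcomes(trials, numeric(0)), "overlapping")
})

test_that("training-phase reward is unconditional at onset + 3 s", {
  trials <- data.frame(onset = 10, kind = "TONE", freq = 6,
                       quiet_period = 6)
  tr <- classifyOutcomes(trials, 11.0, taskRule(), "training")
  expect_equal(tr$outcome, "EL")      # label still assigned
  expect_equal(tr$reward_time, 13.0)  # reward regardless of timing
  te <- classifyOutcomes(trials, 12.0, taskRule(), "testing")
  expect_equal(te$reward_time, 13.0)  # HIT: lick + 1 s
})

test_that("d-prime matches the inverse-normal closed form", {
  expect_equal(dprime(0.5, 0.5, 100, 100), 0)
  expect_equal(dprime(0.69, 0.31, 100, 100),
               qnorm(0.69) - qnorm(0.31), tolerance = 1e-10)
  # extreme rates are clipped at 1/(2n)
  expect_equal(dprime(1, 0, 20, 20),
               qnorm(1 - 1 / 40) - qnorm(1 / 40), tolerance = 1e-10)
  expect_true(is.finite(dprime(1, 0, 20, 20)))
  expect_error(dprime(0.5, 0.5, 0, 10), "positive")
})

test_that("d-prime is antisymmetric and monotone", {
  set.seed(7)
  for (i in 1:20) {
    H <- runif(1); F <- runif(1)
    expect_equal(dprime(H, F, 50, 50), -dprime(F, H, 50, 50))
  }
  hs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(hs, function(h)
    dprime(h, 0.3, 50, 50), numeric(1))) > 0))
  expect_true(all(diff(vapply(hs, function(f)
    dprime(0.7, f, 50, 50), numeric(1))) < 0))
})

test_that("pre/post lick probabilities use the 4.7 s windows", {
  trials <- data.frame(onset = c(20, 40), kind = "TONE", freq = 6,
                       quiet_period = 6)
  none <- lickProbabilities(trials, numeric(0))
  expect_equal(c(none$pre, none$post), c(0, 0))
  post_only <- lickProbabilities(trials, c(22, 42))
  expect_equal(c(post_only$pre, post_only$post), c(0, 1))
  # lick 4.6 s before onset is inside the pre window (span 4.7)
  pre_edge <- lickProbabilities(trials, c(15.4, 44))
  expect_equal(pre_edge$pre, 0.5)
  expect_equal(pre_edge$per_trial$pre_span, c(4.7, 4.7))
})

test_that("burst segmentation finds maximal runs; singletons separate", {
  seg <- segmentBursts(c(0, 0.1, 0.2, 1.0))
  expect_equal(nrow(seg$bursts), 1)
  expect_equal(seg$bursts$start, 0)
  expect_equal(seg$bursts$end, 0.2)
  expect_equal(seg$bursts$n_licks, 3L)
  expect_equal(seg$bursts$duration, 0.2)
  expect_equal(seg$singletons, 1.0)
  single <- segmentBursts(5.0)
  expect_equal(nrow(single$bursts), 0)
  expect_equal(single$singletons, 5.0)
  # a pause of exactly 0.5 s stays within the burst (threshold is ">")
  seg05 <- segmentBursts(c(1.0, 1.5, 2.1))
  expect_equal(seg05$bursts$n_licks, 2L)
  expect_equal(seg05$singletons, 2.1)
})

test_that("burst segmentation equals the quadratic oracle and partitions licks", {
  set.seed(202)
  for (i in 1:300) {
    n <- rpois(1, 6)
    licks <- sort(runif(n, 0, 4))
    # plant occasional exact-threshold gaps
    if (n > 1 && runif(1) < 0.3) licks[2] <- licks[1] + 0.5
    licks <- sort(unique(licks))
    seg <- segmentBursts(licks)
    oracle <- oracleBursts(licks)
    got <- c(
      unlist(lapply(seq_len(nrow(seg$bursts)), function(j)
        licks[licks >= seg$bursts$start[j] & licks <= seg$bursts$end[j]])),
      seg$singletons)
    expect_equal(sort(got), licks)  # partition property
    oracle_bursts <- oracle[vapply(oracle, length, integer(1)) >= 2]
    expect_equal(nrow(seg$bursts), length(oracle_bursts))
    if (length(oracle_bursts)) {
      expect_equal(seg$bursts$start,
                   vapply(oracle_bursts, min, numeric(1)))
      expect_equal(seg$bursts$end,
                   vapply(oracle_bursts, max, numeric(1)))
    }
  }
})

test_that("burst categories follow the printed half-open bounds", {
  expect_equal(categorizeBurst(0.2, "HI"), "INTERMEDIATE")
  expect_equal(categorizeBurst(1.2, "HI"), "EXCLUDED")
  expect_equal(categorizeBurst(1.2, "LO"), "LONG")
  expect_equal(categorizeBurst(0.5, "HI"), "LONG")
  expect_equal(categorizeBurst(0.5, "LO"), "LONG")
  expect_equal(categorizeBurst(0.001, "HI"), "EXCLUDED")
  expect_equal(categorizeBurst(0.033, "LO"), "SHORT")
  expect_equal(categorizeBurst(c(0.1, 0.3, 0.7, 1.5), "HI"),
               c("SHORT", "INTERMEDIATE", "LONG", "EXCLUDED"))
})
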