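test_that("latents equalize condition counts and honor the seed", {
  set.seed(61)
  r <- generateSession(tinySimConfig(61, trials_per_session = 50L), 6, 1)
  lat <- buildLatents(r$session, seed = 5)
  expect_s4_class(lat, "LatentDynamics")
  n_hit <- length(unique(lat@trial[lat@condition == "HIT"]))
  n_ll <- length(unique(lat@trial[lat@condition == "LL"]))
  expect_equal(n_hit, n_ll)
  tr <- trialTable(r$session)
  expect_equal(n_hit, min(table(tr$outcome)[c("HIT", "LL")]))
  lat2 <- buildLatents(r$session, seed = 5)
  expect_equal(latentScores(lat), latentScores(lat2))
  expect_lte(ncol(latentScores(lat)), 10)
})

test_that("CCA recovers an orthogonal rotation with ccs near 1", {
  set.seed(67)
  n_trials <- 12; n_tau <- 20; m <- 5
  base <- matrix(rnorm(n_trials * n_tau * m), ncol = m)
  R <- qr.Q(qr(matrix(rnorm(m * m), m)))
  latA <- manualLatents(base, n_trials, n_tau, bin = 4)
  latB <- manualLatents(base %*% R, n_trials, n_tau, bin = 5)
  ar <- alignCCA(latA, latB)
  expect_true(all(canonicalCors(ar)[1:3] >= 0.99))
  # and ccs are invariant to any invertible re-mixing of one side
  M <- matrix(rnorm(m * m), m) + 3 * diag(m)
  latB2 <- manualLatents(base %*% M, n_trials, n_tau, bin = 5)
  ar2 <- alignCCA(latA, latB2)
  expect_equal(canonicalCors(ar2), canonicalCors(ar), tolerance = 1e-6)
})

test_that("independent latents give small ccs; permuted dimension drops", {
  set.seed(71)
  n_trials <- 40; n_tau <- 20; m <- 4
  A <- matrix(rnorm(n_trials * n_tau * m), ncol = m)
  B <- matrix(rnorm(n_trials * n_tau * m), ncol = m)
  ar <- alignCCA(manualLatents(A, n_trials, n_tau, 4),
                 manualLatents(B, n_trials, n_tau, 5))
  expect_lt(canonicalCors(ar)[1], 0.25)
  # same latents with one dimension scrambled in time: that structure is
  # destroyed but the other dimensions still align perfectly
  B2 <- A
  B2[, 2] <- A[sample.int(nrow(A)), 2]
  ar2 <- alignCCA(manualLatents(A, n_trials, n_tau, 4),
                  manualLatents(B2, n_trials, n_tau, 5))
  expect_true(all(canonicalCors(ar2)[1:3] > 0.99))
  expect_lt(canonicalCors(ar2)[m], 0.3)
})

test_that("bounds: noiseless repeats give upper ~1; rotations beat the lower bound", {
  set.seed(73)
  n_trials <- 16; n_tau <- 15; m <- 3
  proto <- matrix(rnorm(n_tau * m), n_tau, m)
  reps <- do.call(rbind, replicate(n_trials, proto, simplify = FALSE)) +
    matrix(rnorm(n_trials * n_tau * m, 0, 1e-3), ncol = m)
  latA <- manualLatents(reps, n_trials, n_tau, 4)
  bd <- ccaBounds(latA, latA, reps = 20, seed = 1)
  expect_true(all(bd$upper > 0.99))
  # rotated copy: aligned ccs high, unaligned diagonal correlations low
  R <- qr.Q(qr(matrix(rnorm(m * m), m)))
  noisy <- matrix(rnorm(n_trials * n_tau * m), ncol = m)
  latN <- manualLatents(noisy, n_trials, n_tau, 4)
  latR <- manualLatents(noisy %*% R, n_trials, n_tau, 5)
  ar <- alignCCA(latN, latR)
  bd2 <- ccaBounds(latN, latR, reps = 10, seed = 1)
  expect_gt(mean(canonicalCors(ar)[1:3]), mean(bd2$lower))
})

test_that("bound repetitions are reproducible under a seed", {
  set.seed(79)
  n_trials <- 12; n_tau <- 10; m <- 3
  A <- matrix(rnorm(n_trials * n_tau * m), ncol = m)
  latA <- manualLatents(A, n_trials, n_tau, 4)
  b1 <- ccaBounds(latA, latA, reps = 15, seed = 9)
  b2 <- ccaBounds(latA, latA, reps = 15, seed = 9)
  expect_equal(b1, b2)
})

test_that("distance profiles see a planted post-lick condition offset", {
  set.seed(83)
  n_trials <- 20; n_tau <- 30; m <- 4
  tau_vec <- seq(-0.5, by = 1 / 30, length.out = n_tau)
  mk <- function(offset) {
    X <- matrix(rnorm(n_trials * n_tau * m, 0, 0.5), ncol = m)
    lat <- manualLatents(X, n_trials, n_tau, 4)
    hit_post <- lat@condition == "HIT" & lat@tau >= 0
    lat@scores[hit_post, 1] <- lat@scores[hit_post, 1] + offset
    lat
  }
  latA <- mk(1); latB <- mk(3)
  ar <- alignCCA(latA, latB)
  dpost <- distanceProfile(ar, epoch = "POST_LICK", n_perm = 99, seed = 2)
  dpre <- distanceProfile(ar, epoch = "PRE_LICK", n_perm = 99, seed = 2)
  # offset is post-lick only, and three times larger on the B side
  expect_gt(mean(dpost$distA), mean(dpre$distA))
  expect_gt(mean(dpost$distB), mean(dpost$distA))
  expect_lt(dpost$perm_p, 0.05)
  # identical sides: distances match and the permutation p is large
  ar0 <- alignCCA(mk(1), mk(1))
  dp0 <- distanceProfile(ar0, n_perm = 99, seed = 3)
  expect_gt(dp0$perm_p, 0.05)
})

test_that("identical condition means give zero distance", {
  n_trials <- 8; n_tau <- 10; m <- 3
  proto <- matrix(rnorm(n_tau * m), n_tau, m)
  X <- do.call(rbind, replicate(n_trials, proto, simplify = FALSE))
  lat <- manualLatents(X, n_trials, n_tau, 4)
  ar <- alignCCA(lat, lat)
  dp <- distanceProfile(ar, n_perm = 19, seed = 1)
  expect_equal(max(dp$distA), 0, tolerance = 1e-8)
  expect_equal(max(dp$distB), 0, tolerance = 1e-8)
})

test_that("permutation p-values are roughly uniform under the null", {
  set.seed(89)
  ps <- replicate(40, {
    n_trials <- 12; n_tau <- 8; m <- 3
    mkn <- function() manualLatents(
      matrix(rnorm(n_trials * n_tau * m), ncol = m), n_trials, n_tau, 4)
    ar <- alignCCA(mkn(), mkn())
    distanceProfile(ar, n_perm = 60, seed = sample.int(1e6, 1))$perm_p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
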