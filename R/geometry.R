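#' Build latent peri-lick dynamics for a session
#'
#' Takes the first post-sound lick of every trial whose outcome is in
#' `conditions` (default HIT and LL), equalizes the per-condition trial
#' counts by seeded subsampling, cuts each trial to a fixed peri-lick frame
#' grid (default -0.5 s .. +1.0 s around the lick at 30 Hz, 45 frames),
#' concatenates the segments in condition-ordered blocks, and projects the
#' concatenated matrix on its top `m` principal components.
#'
#' @param session a [SessionRecording-class].
#' @param m latent dimensionality (10; reduced if rank-deficient).
#' @param conditions outcome labels to include, default `c("HIT", "LL")`.
#' @param grid peri-lick segment in seconds, default `c(-0.5, 1.0)`.
#' @param cells optional cell subset (e.g. one functional group).
#' @param min_trials minimum trials per condition (4); below it `NULL` is
#'   returned with a message.
#' @param basis "trial_average" (default): principal components of the
#'   condition-averaged peri-lick trajectories, the standard construction
#'   for latent population dynamics — with spike-like deconvolved rates the
#'   per-frame noise variance dwarfs the lick-locked signal, so PCs of the
#'   raw concatenated matrix would be noise directions.  "concatenated":
#'   PCs of the trial-concatenated matrix itself.
#' @param smooth_frames boxcar width (frames) applied to each trial segment
#'   before projection (5, ~165 ms; 1 disables).
#' @param seed subsampling seed.
#' @return a [LatentDynamics-class] or `NULL`.
#' @export
buildLatents <- function(session, m = 10L, conditions = c("HIT", "LL"),
                         grid = c(-0.5, 1.0), cells = NULL,
                         min_trials = 4L,
                         basis = c("trial_average", "concatenated"),
                         smooth_frames = 5L, seed = 1L) {
  basis <- match.arg(basis)
  tr <- trialTable(session)
  fr <- frameRate(session)
  act <- activityMatrix(session)
  if (!is.null(cells)) act <- act[cells, , drop = FALSE]
  nf <- ncol(act)
  sel <- which(tr$outcome %in% conditions & !is.na(tr$first_lick_post))
  by_cond <- split(sel, tr$outcome[sel])
  by_cond <- by_cond[conditions[conditions %in% names(by_cond)]]
  if (length(by_cond) < length(conditions)) {
    message("buildLatents: a condition has no trials; session skipped")
    return(NULL)
  }
  n_eq <- min(vapply(by_cond, length, integer(1)))
  if (n_eq < min_trials) {
    message(sprintf("buildLatents: only %d trials in the rarest condition",
                    n_eq))
    return(NULL)
  }
  keep <- withSubstream(seed, "latent_equalize", function()
    lapply(by_cond, function(ix) sort(sample(ix, n_eq))))
  lo <- round(grid[1] * fr); hi <- round(grid[2] * fr)
  tau <- (seq(lo, hi - 1)) / fr
  n_tau <- hi - lo
  smooth1 <- function(seg) {
    # within-segment running mean, edge-padded
    if (smooth_frames <= 1) return(seg)
    w <- smooth_frames
    apply(seg, 2, function(v) {
      cs <- cumsum(c(0, v))
      i <- seq_along(v)
      lo_i <- pmax(i - (w %/% 2), 1)
      hi_i <- pmin(i + ((w - 1) %/% 2), length(v))
      (cs[hi_i + 1] - cs[lo_i]) / (hi_i - lo_i + 1)
    })
  }
  segs <- list(); cond <- character(0); trial <- integer(0)
  for (cd in names(keep)) {
    for (i in keep[[cd]]) {
      a <- timeToFrame(tr$first_lick_post[i], fr)
      if (a + lo < 1 || a + hi - 1 > nf) next
      segs[[length(segs) + 1]] <- smooth1(t(act[, (a + lo):(a + hi - 1),
                                                drop = FALSE]))
      cond <- c(cond, rep(cd, n_tau))
      trial <- c(trial, rep(i, n_tau))
    }
  }
  if (!length(segs)) return(NULL)
  X <- do.call(rbind, segs)
  if (basis == "concatenated") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    m_use <- min(m, ncol(pc$rotation), sum(pc$sdev > 1e-10))
    scores <- pc$x[, seq_len(m_use), drop = FALSE]
    rot <- pc$rotation[, seq_len(m_use), drop = FALSE]
    ctr <- pc$center
  } else {
    # basis from condition-averaged trajectories, trials projected onto it
    key <- interaction(cond, rep(seq_len(n_tau), length(segs)))
    avg <- rowsum(X, key) / as.numeric(table(key))
    pc <- stats::prcomp(avg, center = TRUE, scale. = FALSE)
    m_use <- min(m, ncol(pc$rotation), sum(pc$sdev > 1e-10))
    rot <- pc$rotation[, seq_len(m_use), drop = FALSE]
    ctr <- pc$center
    scores <- sweep(X, 2, ctr) %*% rot
  }
  new("LatentDynamics",
      scores = scores, rotation = rot, center = ctr,
      condition = cond, trial = as.integer(trial),
      tau = rep(tau, length.out = nrow(X)),
      binIndex = binIndex(session))
}

# Subsample two LatentDynamics to matched, corresponding rows: the same
# number of trials per condition on both sides, rows ordered condition-block
# then trial then peri-lick time.
matchLatentRows <- function(latA, latB, seed = 1L) {
  pick <- function(lat, cd, n) {
    tr <- unique(lat@trial[lat@condition == cd])
    sort(sample(tr, n))
  }
  conds <- sort(unique(latA@condition))
  rowsA <- integer(0); rowsB <- integer(0)
  withSubstream(seed, "cca_row_match", function() {
    for (cd in conds) {
      nA <- length(unique(latA@trial[latA@condition == cd]))
      nB <- length(unique(latB@trial[latB@condition == cd]))
      n <- min(nA, nB)
      for (t in pick(latA, cd, n))
        rowsA <<- c(rowsA, which(latA@trial == t & latA@condition == cd))
      for (t in pick(latB, cd, n))
        rowsB <<- c(rowsB, which(latB@trial == t & latB@condition == cd))
    }
  })
  list(A = rowsA, B = rowsB)
}

#' Align two latent spaces with CCA
#'
#' Finds the linear transformations that make the two latent dynamics
#' maximally correlated dimension by dimension (canonical correlation
#' analysis via [stats::cancor()]), after matching rows across the two
#' sides (equal per-condition trial counts, corresponding order, identical
#' peri-lick grid). Both sides are projected into the shared canonical
#' space for downstream distance analyses.
#'
#' @param latA,latB [LatentDynamics-class] objects; `latA` is the reference
#'   (e.g. bin 4).
#' @param seed row-matching seed.
#' @return an [AlignmentResult-class] (bounds unfilled).
#' @export
alignCCA <- function(latA, latB, seed = 1L) {
  mr <- matchLatentRows(latA, latB, seed)
  A <- latA@scores[mr$A, , drop = FALSE]
  B <- latB@scores[mr$B, , drop = FALSE]
  k <- min(ncol(A), ncol(B))
  cc <- tryCatch(stats::cancor(A, B),
                 error = function(e) {
                   warning("rank deficiency in CCA; reducing dimensions")
                   stats::cancor(A[, 1:(k - 1), drop = FALSE],
                                 B[, 1:(k - 1), drop = FALSE])
                 })
  kk <- length(cc$cor)
  Ac <- sweep(A[, seq_len(nrow(cc$xcoef)), drop = FALSE], 2, cc$xcenter)
  Bc <- sweep(B[, seq_len(nrow(cc$ycoef)), drop = FALSE], 2, cc$ycenter)
  subA <- function(lat, rows) new("LatentDynamics",
    scores = lat@scores[rows, , drop = FALSE], rotation = lat@rotation,
    center = lat@center, condition = lat@condition[rows],
    trial = lat@trial[rows], tau = lat@tau[rows], binIndex = lat@binIndex)
  new("AlignmentResult",
      binPair = c(latA@binIndex, latB@binIndex),
      cc = cc$cor,
      xcoef = cc$xcoef[, seq_len(kk), drop = FALSE],
      ycoef = cc$ycoef[, seq_len(kk), drop = FALSE],
      xcenter = cc$xcenter, ycenter = cc$ycenter,
      alignedA = Ac %*% cc$xcoef[, seq_len(kk), drop = FALSE],
      alignedB = Bc %*% cc$ycoef[, seq_len(kk), drop = FALSE],
      upperBound = numeric(0), lowerBound = numeric(0),
      latA = subA(latA, mr$A), latB = subA(latB, mr$B))
}

#' Resampled bounds for canonical correlations
#'
#' Upper bound: the trials of the reference bin are split into two
#' non-overlapping halves matched by condition, CCA is run between the
#' halves, and the top-3 canonical correlations are averaged over `reps`
#' repetitions — the within-day ceiling set by trial-to-trial variability.
#' Lower bound: the top-3 absolute Pearson correlations between
#' corresponding *unaligned* latent dimensions of the two bins.
#'
#' @param latA reference-bin [LatentDynamics-class].
#' @param latB comparison-bin [LatentDynamics-class] (for the lower bound).
#' @param reps split repetitions (500).
#' @param seed RNG seed.
#' @return list: `upper` (length 3), `lower` (length 3).
#' @export
ccaBounds <- function(latA, latB, reps = 500L, seed = 1L) {
  conds <- sort(unique(latA@condition))
  trials_by_cond <- lapply(conds, function(cd)
    unique(latA@trial[latA@condition == cd]))
  if (any(vapply(trials_by_cond, length, integer(1)) < 4)) {
    warning("too few trials for CCA bounds")
    return(list(upper = rep(NA_real_, 3), lower = rep(NA_real_, 3)))
  }
  upper <- withSubstream(seed, "cca_upper", function() {
    acc <- matrix(NA_real_, reps, 3)
    for (r in seq_len(reps)) {
      rows1 <- integer(0); rows2 <- integer(0)
      for (ci in seq_along(conds)) {
        tr <- trials_by_cond[[ci]]
        half <- floor(length(tr) / 2)
        perm <- sample(tr)
        t1 <- perm[seq_len(half)]
        t2 <- perm[half + seq_len(half)]
        rows1 <- c(rows1, which(latA@trial %in% t1 &
                                  latA@condition == conds[ci]))
        rows2 <- c(rows2, which(latA@trial %in% t2 &
                                  latA@condition == conds[ci]))
      }
      cc <- stats::cancor(latA@scores[rows1, , drop = FALSE],
                          latA@scores[rows2, , drop = FALSE])
      acc[r, ] <- cc$cor[1:3]
    }
    colMeans(acc, na.rm = TRUE)
  })
  mr <- matchLatentRows(latA, latB, substreamSeed(seed, "cca_lower_rows"))
  A <- latA@scores[mr$A, , drop = FALSE]
  B <- latB@scores[mr$B, , drop = FALSE]
  k <- min(ncol(A), ncol(B))
  diag_r <- vapply(seq_len(k), function(i)
    abs(stats::cor(A[, i], B[, i])), numeric(1))
  lower <- sort(diag_r, decreasing = TRUE)[1:3]
  list(upper = upper, lower = lower)
}

#' Condition-distance profile in an aligned space
#'
#' Computes, for each side of an [alignCCA()] result, the condition-mean
#' trajectory per peri-lick timepoint and the per-timepoint Euclidean
#' distance between the two conditions, in the aligned space projected back
#' to each side's latent (rate-unit) coordinates and restricted to the
#' `k_dims` leading canonical dimensions. Back-projection keeps each bin's
#' physical activity scale (the unit-variance canonical variates would
#' cancel it), while the restriction to the leading canonical subspace
#' keeps only structure shared across the aligned bins. The distance
#' samples of the comparison side (later bin) are tested against the
#' reference side with a one-sided t-test and a label-permutation test
#' (condition labels shuffled within each bin).
#'
#' @param ar an [AlignmentResult-class].
#' @param conditions the condition pair (default the two labels present).
#' @param epoch "ALL", "PRE_LICK" (tau < 0) or "POST_LICK" (tau >= 0).
#' @param k_dims canonical dimensions retained (3, the leading
#'   correlations).
#' @param n_perm permutations (1000).
#' @param seed permutation seed.
#' @return list: `distA`, `distB` (per-timepoint distances), `tau`,
#'   `mean_diff` (mean(distB) - mean(distA)), `t_p` (one-sided t-test p for
#'   distB > distA), `perm_p`.
#' @export
distanceProfile <- function(ar, conditions = NULL,
                            epoch = c("ALL", "PRE_LICK", "POST_LICK"),
                            k_dims = 3L, n_perm = 1000L, seed = 1L) {
  epoch <- match.arg(epoch)
  latA <- ar@latA; latB <- ar@latB
  if (is.null(conditions)) conditions <- sort(unique(latA@condition))
  proj <- function(coef, scores, center) {
    k <- min(k_dims, ncol(coef))
    ck <- coef[, seq_len(k), drop = FALSE]
    P <- ck %*% solve(crossprod(ck), t(ck))  # projector, rate units kept
    sweep(scores[, seq_len(nrow(ck)), drop = FALSE], 2,
          center) %*% P
  }
  spaceA <- proj(ar@xcoef, latA@scores, ar@xcenter)
  spaceB <- proj(ar@ycoef, latB@scores, ar@ycenter)
  maskFor <- function(tau) switch(epoch, ALL = rep(TRUE, length(tau)),
                                  PRE_LICK = tau < 0, POST_LICK = tau >= 0)
  distFor <- function(scores, cond, tau) {
    keep <- maskFor(tau)
    taus <- sort(unique(tau[keep]))
    vapply(taus, function(tt) {
      i1 <- which(tau == tt & cond == conditions[1])
      i2 <- which(tau == tt & cond == conditions[2])
      sqrt(sum((colMeans(scores[i1, , drop = FALSE]) -
                colMeans(scores[i2, , drop = FALSE]))^2))
    }, numeric(1))
  }
  distA <- distFor(spaceA, latA@condition, latA@tau)
  distB <- distFor(spaceB, latB@condition, latB@tau)
  obs <- mean(distB) - mean(distA)
  tt <- stats::t.test(distB, distA, alternative = "greater")
  shuffleWithin <- function(lat) {
    # permute condition labels at the trial level, preserving trial blocks
    tr <- unique(lat@trial)
    lab <- vapply(tr, function(t)
      lat@condition[match(t, lat@trial)], character(1))
    new_lab <- sample(lab)
    lat_cond <- lat@condition
    for (i in seq_along(tr)) lat_cond[lat@trial == tr[i]] <- new_lab[i]
    lat_cond
  }
  perm_stats <- withSubstream(seed, "distance_perm", function()
    vapply(seq_len(n_perm), function(p) {
      cA <- shuffleWithin(latA)
      cB <- shuffleWithin(latB)
      mean(distFor(spaceB, cB, latB@tau)) -
        mean(distFor(spaceA, cA, latA@tau))
    }, numeric(1)))
  perm_p <- (1 + sum(perm_stats >= obs)) / (n_perm + 1)
  list(distA = distA, distB = distB,
       tau = sort(unique(latA@tau[maskFor(latA@tau)])),
       mean_diff = obs, t_p = tt$p.value, perm_p = perm_p)
}
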