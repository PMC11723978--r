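#' Build a lick-phase decoding design
#'
#' One row per isolated-lick anchor; features are the per-cell mean rates in
#' the 330 ms window starting 165 ms before the lick, restricted to the
#' requested cell group; the label is the lick's phase (PRE_SOUND vs
#' POST_SOUND). Optional behavioral covariates (session post-sound lick
#' probability and modulated-cell proportion) are appended as constant
#' columns — informative only when designs are pooled across sessions.
#'
#' @param session a [SessionRecording-class].
#' @param anchors data.frame from [selectIsolatedLicks()] (both contexts).
#' @param labels per-cell class labels; required when `feature_set` is a
#'   group name.
#' @param feature_set "ALL_CELLS", "ENHANCED", "SUPPRESSED" or "NONE".
#' @param windows an [analysisWindows()].
#' @param covariates logical; append behavioral covariates.
#' @param min_rate event-rate cell floor.
#' @return list: `X` (anchors x features), `y` (factor PRE/POST),
#'   `feature_set`, `n_features`; or `NULL` if a phase has no anchors
#'   (session excluded).
#' @export
buildDesign <- function(session, anchors, labels = NULL,
                        feature_set = "ALL_CELLS",
                        windows = analysisWindows(), covariates = FALSE,
                        min_rate = 1.0) {
  if (!all(c("PRE_SOUND", "POST_SOUND") %in% anchors$context)) {
    message("buildDesign: a phase has zero anchors; session excluded")
    return(NULL)
  }
  inc <- which(includedCells(session, min_rate))
  cells <- if (feature_set == "ALL_CELLS") inc
           else intersect(inc, which(labels == feature_set))
  if (!length(cells)) {
    message("buildDesign: no cells in feature set")
    return(NULL)
  }
  wm <- .anchorWindowMeans(session, anchors$time, windows$during)
  X <- wm$matrix[, cells, drop = FALSE]
  y <- factor(ifelse(anchors$context[wm$used] == "PRE_SOUND",
                     "PRE", "POST"), levels = c("PRE", "POST"))
  if (length(unique(y)) < 2) {
    message("buildDesign: a phase lost all anchors at the window bounds")
    return(NULL)
  }
  if (covariates) {
    lp <- lickProbabilities(trialTable(session), licksHi(session), windows)
    mod_frac <- if (!is.null(labels))
      mean(labels[inc] != "NONE") else NA_real_
    X <- cbind(X, lick_prob = rep(lp$post, nrow(X)),
               mod_frac = rep(mod_frac, nrow(X)))
  }
  colnames(X) <- NULL
  list(X = X, y = y, feature_set = feature_set, n_features = ncol(X))
}

#' SMOTE-style minority oversampling
#'
#' Balances the two classes by synthesizing minority-class samples along
#' segments from existing minority samples towards their nearest minority
#' neighbors: each synthetic sample is `x_i + u * (x_nn - x_i)` with
#' `u ~ Uniform(0, 1)` and `x_nn` one of the `k = min(5, n_min - 1)`
#' nearest minority neighbors of a randomly chosen minority sample.
#' Original rows (both classes) are preserved unchanged. A minority class
#' of one falls back to duplication with tiny jitter, with a warning.
#'
#' @param X design matrix.
#' @param y binary factor labels.
#' @param k neighbor count cap (5).
#' @return list: `X`, `y` with equal class counts; originals first.
#' @export
oversampleMinority <- function(X, y, k = 5L) {
  tab <- table(y)
  if (length(tab) != 2) stop("labels must be binary")
  if (tab[1] == tab[2]) return(list(X = X, y = y))
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_need <- max(tab) - n_min
  if (n_min == 0) stop("minority class has no samples")
  Xi <- X[y == minority, , drop = FALSE]
  if (n_min == 1) {
    warning("minority class of 1: duplicating with jitter")
    sds <- pmax(apply(X, 2, stats::sd), 1e-8)
    syn <- matrix(rep(Xi[1, ], n_need), nrow = n_need, byrow = TRUE) +
      matrix(stats::rnorm(n_need * ncol(X), 0, 1e-6 * sds),
             nrow = n_need, byrow = TRUE)
  } else {
    kk <- min(k, n_min - 1)
    d <- as.matrix(stats::dist(Xi))
    diag(d) <- Inf
    nnv <- apply(d, 1, function(r) order(r)[seq_len(kk)])
    nn <- if (kk == 1) matrix(nnv, ncol = 1) else t(nnv)
    base_i <- sample.int(n_min, n_need, replace = TRUE)
    nn_i <- vapply(base_i, function(i)
      nn[i, sample.int(kk, 1)], numeric(1))
    u <- stats::runif(n_need)
    syn <- Xi[base_i, , drop = FALSE] +
      u * (Xi[nn_i, , drop = FALSE] - Xi[base_i, , drop = FALSE])
  }
  list(X = rbind(X, syn),
       y = factor(c(as.character(y), rep(minority, n_need)),
                  levels = levels(y)))
}

# Components needed to reach the cumulative variance fraction.
.pcaComponents <- function(X, variance_frac) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  cum <- cumsum(v) / sum(v)
  n_comp <- which(cum >= variance_frac)[1]
  list(pc = pc, n_comp = n_comp)
}

#' Decode lick phase from population activity
#'
#' PCA reduces the design to the leading components explaining
#' `variance_frac` (80%) of the variance; an RBF-kernel SVM is trained and
#' evaluated by stratified k-fold cross-validation; accuracy is 1 minus the
#' misclassification rate. Oversampling (when enabled) and PCA are fitted
#' on the full design before cross-validation, matching the original
#' procedure; `pca_cv = "per_fold"` refits both inside each training fold
#' (the leakage-safe variant used for calibration).
#'
#' @param X design matrix (anchors x features).
#' @param y binary factor labels.
#' @param folds CV folds (10; reduced to the smallest class count).
#' @param variance_frac PCA cumulative variance fraction (0.80).
#' @param oversample balance classes with [oversampleMinority()].
#' @param pca_cv "full" (oversample and fit PCA on the whole design before
#'   cross-validation, the original order) or "per_fold" (oversampling and
#'   PCA refit inside each training fold; test folds hold only real
#'   samples — the leakage-safe variant used for calibration).
#' @param shuffle permute labels first (the shuffled-label control).
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses the e1071
#'   default `1 / n_features`.
#' @return list: `accuracy` (mean over folds), `fold_accuracy`, `n_comp`,
#'   `folds`, `hyper` (recorded hyperparameters).
#' @export
decodePhase <- function(X, y, folds = 10L, variance_frac = 0.80,
                        oversample = TRUE, pca_cv = c("full", "per_fold"),
                        shuffle = FALSE, cost = 1, gamma = NULL) {
  pca_cv <- match.arg(pca_cv)
  if (shuffle) y <- sample(y)
  if (oversample && pca_cv == "full") {
    ov <- oversampleMinority(X, y)
    X <- ov$X; y <- ov$y
  }
  k <- min(folds, min(table(y)))
  if (k < 2) stop("need at least 2 samples per class")
  fit_predict <- function(Xtr, ytr, Xte) {
    sv <- suppressWarnings(
      e1071::svm(Xtr, ytr, kernel = "radial", cost = cost,
                 gamma = if (is.null(gamma)) 1 / ncol(Xtr) else gamma,
                 scale = TRUE))
    stats::predict(sv, Xte)
  }
  fold <- stratifiedFolds(y, k)
  acc <- numeric(k)
  if (pca_cv == "full") {
    pp <- .pcaComponents(X, variance_frac)
    Z <- pp$pc$x[, seq_len(pp$n_comp), drop = FALSE]
    n_comp <- pp$n_comp
    for (f in seq_len(k)) {
      te <- fold == f
      pred <- fit_predict(Z[!te, , drop = FALSE], y[!te],
                          Z[te, , drop = FALSE])
      acc[f] <- mean(pred == y[te])
    }
  } else {
    n_comp <- NA_integer_
    for (f in seq_len(k)) {
      te <- fold == f
      Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
      if (oversample) {
        ov <- oversampleMinority(Xtr, ytr)
        Xtr <- ov$X; ytr <- ov$y
      }
      pp <- .pcaComponents(Xtr, variance_frac)
      Ztr <- pp$pc$x[, seq_len(pp$n_comp), drop = FALSE]
      Zte <- scale(X[te, , drop = FALSE], center = pp$pc$center,
                   scale = FALSE) %*%
        pp$pc$rotation[, seq_len(pp$n_comp), drop = FALSE]
      pred <- fit_predict(Ztr, ytr, Zte)
      acc[f] <- mean(pred == y[te])
    }
  }
  list(accuracy = mean(acc), fold_accuracy = acc, n_comp = n_comp,
       folds = k,
       hyper = list(kernel = "radial", cost = cost,
                    gamma = if (is.null(gamma)) "1/n_features" else gamma,
                    variance_frac = variance_frac, pca_cv = pca_cv,
                    oversample = oversample))
}

#' Repeated decoding for a cell group
#'
#' Repeats the full decoding procedure `reps` times (100) with fresh
#' cross-validation partitions and oversampling draws, building an accuracy
#' distribution, together with the matched shuffled-label distribution.
#'
#' @param design output of [buildDesign()].
#' @param reps repetitions (100).
#' @param seed RNG seed.
#' @param ... passed to [decodePhase()].
#' @return list: `accuracy` (length `reps`), `shuffled` (length `reps`),
#'   `feature_set`.
#' @export
decodeDistribution <- function(design, reps = 100L, seed = 1L, ...) {
  withSubstream(seed, paste0("decode_", design$feature_set), function() {
    acc <- numeric(reps); shuf <- numeric(reps)
    for (r in seq_len(reps)) {
      acc[r] <- decodePhase(design$X, design$y, shuffle = FALSE, ...)$accuracy
      shuf[r] <- decodePhase(design$X, design$y, shuffle = TRUE,
                             ...)$accuracy
    }
    list(accuracy = acc, shuffled = shuf,
         feature_set = design$feature_set)
  })
}

#' Permutation comparison of two accuracy distributions
#'
#' Two-sample permutation test on the difference of mean accuracies.
#'
#' @param accA,accB accuracy vectors (e.g. from [decodeDistribution()]).
#' @param n_perm resamples (5000).
#' @param seed RNG seed.
#' @return list: `observed` (mean(accA) - mean(accB)), `p` (two-sided).
#' @export
groupComparison <- function(accA, accB, n_perm = 5000L, seed = 1L) {
  if (length(accA) != length(accB)) {
    warning("unequal rep counts; resampling to the common count")
    n <- min(length(accA), length(accB))
    withSubstream(seed, "group_cmp_resample", function() {
      accA <<- sample(accA, n)
      accB <<- sample(accB, n)
    })
  }
  obs <- mean(accA) - mean(accB)
  pooled <- c(accA, accB)
  nA <- length(accA)
  perm <- withSubstream(seed, "group_cmp", function()
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), nA)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(observed = obs, p = p)
}
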