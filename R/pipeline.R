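#' Run the full analysis pipeline
#'
#' Executes every stage over a list of sessions: behavioral summaries and
#' burst tables; enhanced/suppressed/none classification on post-sound and
#' pre-sound anchors plus sound-responsiveness; peri-lick activity
#' summaries and spatial distances; windowed noise correlations with window
#' and outcome contrasts; CCA alignment of bins 5 and 6 to bin 4 with
#' bounds and HIT-vs-LL distance profiles; and per-bin lick-phase decoding.
#' Deterministic given `config$seed`; every stage draws a named substream.
#'
#' @param config a [pipelineConfig()].
#' @param sessions list of [SessionRecording-class] objects.
#' @param out_dir optional directory for CSV outputs.
#' @return list of result tables: `behavior`, `bursts`, `classes`,
#'   `peri_lick`, `spatial`, `noise_corr`, `noise_contrasts`, `alignment`,
#'   `geometry`, `decoding`, `log`.
#' @export
runPipeline <- function(config, sessions, out_dir = NULL) {
  if (!inherits(config, "PipelineConfig")) stop("config must be a PipelineConfig")
  if (!length(sessions)) stop("usage error: empty session list")
  w <- config$windows
  log <- list()
  behavior <- list(); bursts <- list(); classes <- list()
  peri <- list(); spatial <- list(); nc_tbl <- list()
  anchors_by_session <- list()
  labels_by_session <- list()

  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    behavior[[si]] <- behaviorSummary(s, w)
    bursts[[si]] <- sessionBursts(s, config$pause_threshold)
    anc <- selectIsolatedLicks(licksLo(s), stimOnsets(s))
    anchors_by_session[[si]] <- anc
    cls_post <- withCallingHandlers(
      classifyLickModulation(s, anc, w, config$alpha, "POST_SOUND",
                             config$min_rate, config$min_anchors,
                             config$p_adjust),
      warning = function(wn) {
        log[[length(log) + 1]] <<- conditionMessage(wn)
        invokeRestart("muffleWarning")
      })
    cls_pre <- withCallingHandlers(
      classifyLickModulation(s, anc, w, config$alpha, "PRE_SOUND",
                             config$min_rate, config$min_anchors,
                             config$p_adjust),
      warning = function(wn) {
        log[[length(log) + 1]] <<- conditionMessage(wn)
        invokeRestart("muffleWarning")
      })
    snd <- withCallingHandlers(
      classifySoundResponsive(s, w, config$alpha, config$min_rate),
      warning = function(wn) {
        log[[length(log) + 1]] <<- conditionMessage(wn)
        invokeRestart("muffleWarning")
      })
    tb_post <- classTable(cls_post); tb_post$basis <- "POST_SOUND"
    tb_pre <- classTable(cls_pre); tb_pre$basis <- "PRE_SOUND"
    tb <- rbind(tb_post, tb_pre)
    tb$session <- sessionIndex(s); tb$bin <- binIndex(s)
    tb$sound_responsive <- snd$sound_responsive[tb$cell]
    tb$sound_p <- snd$sound_p[tb$cell]
    classes[[si]] <- tb
    labels <- classLabels(cls_post)
    labels_by_session[[si]] <- labels

    ps <- periLickSummary(s, anc, w, "POST_SOUND", config$min_rate)
    pc <- ps$cells
    pc$label <- labels
    pc$session <- sessionIndex(s); pc$bin <- binIndex(s)
    peri[[si]] <- pc
    log[[length(log) + 1]] <- sprintf(
      "session %d peri-lick anchors: used=%d dropped=%d",
      sessionIndex(s), ps$n_anchors_used, ps$n_anchors_dropped)

    sp <- pairwiseSpatialDistance(cellXY(s), labels,
                                  snd$sound_responsive)$summary
    sp$session <- sessionIndex(s); sp$bin <- binIndex(s)
    spatial[[si]] <- sp

    nc_tbl[[si]] <- sessionNoiseCorr(s, anc, w, labels)
  }

  behavior <- do.call(rbind, behavior)
  bursts <- do.call(rbind, bursts)
  classes <- do.call(rbind, classes)
  peri <- do.call(rbind, peri)
  spatial <- do.call(rbind, spatial)
  noise_corr <- do.call(rbind, nc_tbl)
  noise_contrasts <- corrContrasts(noise_corr)

  # geometry: pair the i-th session of bin 4 with the i-th of bins 5 and 6
  bins <- vapply(sessions, binIndex, integer(1))
  alignment <- list(); geometry <- list()
  for (b in c(5L, 6L)) {
    i4 <- which(bins == 4L); ib <- which(bins == b)
    for (k in seq_len(min(length(i4), length(ib)))) {
      seedk <- substreamSeed(config$seed, sprintf("geom_%d_%d", b, k))
      latA <- buildLatents(sessions[[i4[k]]], config$cca_m, seed = seedk)
      latB <- buildLatents(sessions[[ib[k]]], config$cca_m, seed = seedk)
      if (is.null(latA) || is.null(latB)) {
        log[[length(log) + 1]] <- sprintf(
          "geometry: bin pair (4,%d) replicate %d skipped (too few trials)",
          b, k)
        next
      }
      ar <- alignCCA(latA, latB, seed = seedk)
      bd <- ccaBounds(latA, latB, reps = config$cca_reps, seed = seedk)
      alignment[[length(alignment) + 1]] <- data.frame(
        bin_ref = 4L, bin_cmp = b, replicate = k,
        cc1 = ar@cc[1], cc2 = ar@cc[2], cc3 = ar@cc[3],
        upper1 = bd$upper[1], upper2 = bd$upper[2], upper3 = bd$upper[3],
        lower1 = bd$lower[1], lower2 = bd$lower[2], lower3 = bd$lower[3])
      for (ep in c("ALL", "PRE_LICK", "POST_LICK")) {
        dp <- distanceProfile(ar, epoch = ep, n_perm = 1000L,
                              seed = seedk)
        geometry[[length(geometry) + 1]] <- data.frame(
          bin_ref = 4L, bin_cmp = b, replicate = k, epoch = ep,
          mean_dist_ref = mean(dp$distA), mean_dist_cmp = mean(dp$distB),
          mean_diff = dp$mean_diff, t_p = dp$t_p, perm_p = dp$perm_p)
      }
    }
  }
  alignment <- if (length(alignment)) do.call(rbind, alignment) else
    data.frame()
  geometry <- if (length(geometry)) do.call(rbind, geometry) else
    data.frame()

  # decoding per session, all-cells feature set
  decoding <- list()
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    des <- buildDesign(s, anchors_by_session[[si]],
                       labels_by_session[[si]], "ALL_CELLS", w,
                       min_rate = config$min_rate)
    if (is.null(des)) {
      log[[length(log) + 1]] <- sprintf(
        "decoding: session %d excluded (missing phase anchors)",
        sessionIndex(s))
      next
    }
    seedk <- substreamSeed(config$seed,
                           sprintf("decode_%d", sessionIndex(s)))
    res <- withSubstream(seedk, "session_decode", function() {
      acc <- decodePhase(des$X, des$y, folds = config$decode_folds,
                         variance_frac = config$variance_frac)
      shf <- decodePhase(des$X, des$y, folds = config$decode_folds,
                         variance_frac = config$variance_frac,
                         shuffle = TRUE)
      list(acc = acc$accuracy, shf = shf$accuracy, n_comp = acc$n_comp)
    })
    decoding[[length(decoding) + 1]] <- data.frame(
      session = sessionIndex(s), bin = binIndex(s),
      feature_set = "ALL_CELLS", accuracy = res$acc,
      shuffled_accuracy = res$shf, n_comp = res$n_comp,
      n_anchors = length(des$y))
  }
  decoding <- if (length(decoding)) do.call(rbind, decoding) else
    data.frame()

  out <- list(behavior = behavior, bursts = bursts, classes = classes,
              peri_lick = peri, spatial = spatial,
              noise_corr = noise_corr, noise_contrasts = noise_contrasts,
              alignment = alignment, geometry = geometry,
              decoding = decoding, log = unlist(log))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tabs <- c("behavior", "bursts", "classes", "peri_lick", "spatial",
              "noise_corr", "alignment", "geometry", "decoding")
    for (tb in tabs) {
      if (is.data.frame(out[[tb]]) && nrow(out[[tb]]))
        data.table::fwrite(out[[tb]], file.path(out_dir,
                                                paste0(tb, ".csv")))
    }
    writeLines(out$log, file.path(out_dir, "pipeline.log"))
  }
  out
}
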