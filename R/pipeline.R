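#' Study presets
#'
#' \code{"full"}: 50 realizations per network type, series length N = 2048,
#' ~1000 source voxels. \code{"desk"}: 10 realizations, N = 1024, ~500
#' voxels, for desk-scale runs of the whole pipeline.
#'
#' @param preset \code{"full"} or \code{"desk"}.
#' @return named list of study parameters.
#' @export
studyPreset <- function(preset = c("full", "desk")) {
  switch(match.arg(preset),
    full = list(nRealizations = 50, N = 2048, nVoxels = 1000),
    desk = list(nRealizations = 10, N = 1024, nVoxels = 500))
}

defaultMeasure <- function(system)
  switch(system, CHM = "PMIME", CMG = "PMIME", VAR = "RCGCI")

defaultCoupling <- function(system)
  switch(system, CHM = 0.2, CMG = 0.1, VAR = NA_real_)

# candidate lags for the mixed embedding: the Mackey-Glass system couples
# through a delay of 100 time units = 25 sampling steps, so its candidate
# set must reach the delay; pure map/VAR systems use the short lags
defaultLags <- function(system)
  switch(system, CHM = 1:5, CMG = c(1:3, 24:26), VAR = 1:5)

simulateSystem <- function(system, net, N, seed) {
  switch(system,
    CHM = simulateCHM(net, N = N, seed = seed),
    CMG = simulateCMG(net, N = N, seed = seed),
    VAR = simulateVar(stabilizeVar(net), N = N, seed = seed))
}

estimateCausality <- function(ts, measure, system, seed) {
  if (measure == "PMIME")
    pmime(ts, lags = defaultLags(system), seed = seed)
  else
    rcgci(ts, pmax = max(defaultLags(system)))
}

#' Run the simulation study for one system
#'
#' For each network type (RAND, SW, SCF) and realization: generate a
#' ground-truth coupling network, simulate the system in the sensor space,
#' map to the source space through the standardized inverse and ROI
#' averaging, estimate the causality network in the requested spaces, and
#' compute the five graph metrics of the true ("initial") and estimated
#' networks. Discrimination of the three network types is then summarized
#' by the average pairwise AUROC per metric and space.
#'
#' The run is deterministic under \code{masterSeed}: every (type,
#' realization) work unit derives an order-independent sub-seed, so partial
#' or resumed runs produce identical numbers. With \code{cacheDir} set,
#' per-realization metric rows are cached as CSV and reused.
#'
#' @param system \code{"CHM"}, \code{"CMG"} or \code{"VAR"}.
#' @param measure causality measure; defaults to the system's convention
#'   (PMIME for the nonlinear CHM/CMG, RCGCI for the linear VAR).
#' @param nRealizations realizations per network type.
#' @param N series length.
#' @param K number of nodes / channels (20 by convention; must match the
#'   electrode montage used for the source space).
#' @param spaces subset of \code{c("initial", "sensor", "source")}.
#' @param nVoxels voxel count of the synthetic head model.
#' @param masterSeed master seed of the study.
#' @param networkParams per-topology overrides passed to
#'   [generateNetwork()].
#' @param cacheDir optional directory for per-realization caching.
#' @param verbose print progress.
#' @return list with \code{metrics} (one row per realization, space and
#'   type) and \code{auroc} (rows: space; columns: the five metrics).
#' @export
runSimulationStudy <- function(system = c("CHM", "CMG", "VAR"),
                               measure = NULL, nRealizations = 50, N = 2048,
                               K = 20,
                               spaces = c("initial", "sensor", "source"),
                               nVoxels = 1000, masterSeed = 1,
                               networkParams = list(), cacheDir = NULL,
                               verbose = FALSE) {
  system <- match.arg(system)
  if (is.null(measure)) measure <- defaultMeasure(system)
  spaces <- match.arg(spaces, several.ok = TRUE)
  needSource <- "source" %in% spaces
  needSensor <- needSource || "sensor" %in% spaces
  lf <- tr <- part <- NULL
  electrodes <- NULL
  if (needSource) {
    if (K > length(simulationElectrodes()))
      stop("the source-space stage supports at most the 20-electrode montage")
    electrodes <- head(simulationElectrodes(), K)
    lf <- synthesizeHeadModel(electrodes, nVoxels = nVoxels)
    tr <- buildTransform(lf)
    part <- partitionRois(lf)
  }
  rows <- list()
  for (ti in seq_along(.TOPOLOGIES)) {
    type <- .TOPOLOGIES[ti]
    for (i in seq_len(nRealizations)) {
      cacheFile <- if (!is.null(cacheDir))
        file.path(cacheDir, sprintf("%s_%s_%03d.csv", system, type, i))
      if (!is.null(cacheFile) && file.exists(cacheFile)) {
        rows[[length(rows) + 1]] <- utils::read.csv(cacheFile)
        next
      }
      sd0 <- subSeed(masterSeed, ti, i)
      net <- generateNetwork(type, K, params = networkParams[[type]] %||% list(),
                             seed = sd0)
      if (!is.na(defaultCoupling(system)))
        net <- setStrengths(net, defaultCoupling(system))
      rr <- list()
      if ("initial" %in% spaces)
        rr$initial <- computeMetrics(net, seed = subSeed(sd0, 11L, 1L))
      if (needSensor) {
        ts <- simulateSystem(system, net, N, seed = subSeed(sd0, 12L, 1L))
        if ("sensor" %in% spaces) {
          cm <- estimateCausality(ts, measure, system, seed = subSeed(sd0, 13L, 1L))
          rr$sensor <- computeMetrics(cm, seed = subSeed(sd0, 14L, 1L))
        }
        if (needSource) {
          colnames(ts@values) <- electrodes
          src <- toSourceSpace(tr, lf, part, ts)
          cm <- estimateCausality(src, measure, system, seed = subSeed(sd0, 15L, 1L))
          rr$source <- computeMetrics(cm, seed = subSeed(sd0, 16L, 1L))
        }
      }
      df <- do.call(rbind, lapply(names(rr), function(sp)
        data.frame(system = system, type = type, realization = i, space = sp,
                   as.list(rr[[sp]]), stringsAsFactors = FALSE)))
      if (!is.null(cacheFile)) {
        dir.create(dirname(cacheFile), showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(df, cacheFile, row.names = FALSE)
      }
      rows[[length(rows) + 1]] <- df
      if (verbose)
        message(sprintf("%s %s realization %d/%d done", system, type, i,
                        nRealizations))
    }
  }
  metrics <- do.call(rbind, rows)
  auroc <- aurocTable(metrics)
  list(metrics = metrics, auroc = auroc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

aurocTable <- function(metrics) {
  sp <- unique(metrics$space)
  out <- do.call(rbind, lapply(sp, function(s) {
    sub <- metrics[metrics$space == s, ]
    vals <- vapply(metricNames(), function(mn)
      averagePairwiseAuroc(sub[[mn]], sub$type), 0.0)
    data.frame(space = s, t(vals), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the windowed epoch study
#'
#' For each epoch and space: slide windows over the epoch
#' ([makeWindows()]), estimate the causality network per window, compute
#' the five graph metrics, then quantify the discrimination of the brain
#' states with the folded AUROC for the three tasks (preED vs ED, preED vs
#' postED, ED vs postED) and Welch t-tests of preED vs ED. AUROCs are
#' averaged over epochs; the t-test table lists, per metric and space, the
#' epochs significant below \code{pLevel}.
#'
#' Epochs too short to contain any fully-labelled ED window are skipped
#' with a warning.
#'
#' @param epochs list of \linkS4class{EdEpoch} objects.
#' @param spaces subset of \code{c("sensor", "source")}.
#' @param measure \code{"PMIME"} (convention) or \code{"RCGCI"}.
#' @param width,step window parameters in seconds.
#' @param nVoxels head-model size for the source space.
#' @param Lmax,kNeighbors,nSurrogates causality-estimation parameters.
#' @param masterSeed master seed.
#' @param pLevel significance level of the t-test listing.
#' @param verbose print progress.
#' @return list with \code{profiles} (per window metric rows),
#'   \code{auroc} (per space and task, averaged over epochs) and
#'   \code{ttests} (per metric and space, epochs with p below
#'   \code{pLevel}).
#' @export
runEpochStudy <- function(epochs, spaces = c("sensor", "source"),
                          measure = "PMIME", width = 2, step = 0.5,
                          nVoxels = 500, Lmax = 5, kNeighbors = 5,
                          nSurrogates = 100, masterSeed = 1, pLevel = 0.01,
                          verbose = FALSE) {
  spaces <- match.arg(spaces, several.ok = TRUE)
  stopifnot(length(epochs) >= 1)
  labels <- channelLabels(epochs[[1]]@signal)
  lf <- tr <- part <- NULL
  if ("source" %in% spaces) {
    lf <- synthesizeHeadModel(labels, nVoxels = nVoxels)
    tr <- buildTransform(lf)
    part <- partitionRois(lf)
  }
  prof <- list()
  for (e in seq_along(epochs)) {
    ep <- epochs[[e]]
    ws <- makeWindows(ep, width, step)
    if (!any(ws@windows$label == "ED")) {
      warning(sprintf("epoch %d has no ED-labelled window; skipped", e))
      next
    }
    series <- list()
    if ("sensor" %in% spaces) series$sensor <- ep@signal
    if ("source" %in% spaces) series$source <- toSourceSpace(tr, lf, part, ep@signal)
    for (sp in names(series)) {
      for (w in seq_len(nrow(ws@windows))) {
        win <- ws@windows[w, ]
        sl <- windowSlice(series[[sp]], win$start, win$end)
        sd0 <- subSeed(masterSeed, 700L + e, w)
        cm <- if (measure == "PMIME")
          pmime(sl, Lmax = Lmax, kNeighbors = kNeighbors,
                nSurrogates = nSurrogates, seed = sd0)
        else rcgci(sl, pmax = Lmax)
        mv <- computeMetrics(cm, seed = subSeed(sd0, 17L, 1L))
        prof[[length(prof) + 1]] <-
          data.frame(epoch = e, space = sp, window = w, start = win$start,
                     label = win$label, as.list(mv), stringsAsFactors = FALSE)
      }
      if (verbose) message(sprintf("epoch %d %s space done", e, sp))
    }
  }
  profiles <- do.call(rbind, prof)
  if (is.null(profiles)) stop("no usable epochs")
  tasks <- list(c("preED", "ED"), c("preED", "postED"), c("ED", "postED"))
  aur <- list()
  for (sp in unique(profiles$space)) {
    for (tk in tasks) {
      vals <- vapply(metricNames(), function(mn) {
        per <- vapply(unique(profiles$epoch), function(e) {
          sub <- profiles[profiles$epoch == e & profiles$space == sp, ]
          auroc(sub[[mn]][sub$label == tk[1]], sub[[mn]][sub$label == tk[2]])
        }, 0.0)
        mean(per, na.rm = TRUE)
      }, 0.0)
      aur[[length(aur) + 1]] <- data.frame(space = sp,
        task = paste(tk, collapse = " vs "), t(vals),
        stringsAsFactors = FALSE)
    }
  }
  tt <- list()
  for (sp in unique(profiles$space)) {
    for (mn in metricNames()) {
      sig <- vapply(unique(profiles$epoch), function(e) {
        sub <- profiles[profiles$epoch == e & profiles$space == sp, ]
        p <- suppressWarnings(
          ttestWindows(sub[[mn]][sub$label == "preED"],
                       sub[[mn]][sub$label == "ED"]))
        is.finite(p) && p < pLevel
      }, TRUE)
      tt[[length(tt) + 1]] <- data.frame(space = sp, metric = mn,
        epochs = paste(unique(profiles$epoch)[sig], collapse = " "),
        stringsAsFactors = FALSE)
    }
  }
  list(profiles = profiles, auroc = do.call(rbind, aur),
       ttests = do.call(rbind, tt))
}
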