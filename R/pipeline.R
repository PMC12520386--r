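#' Run the detection pipeline end to end
#'
#' Executes the requested stages in order, each stage reading and writing
#' on-disk artifacts (TIFF/CSV/JSON) inside the run directory, so every
#' stage is independently inspectable and re-runnable. A manifest
#' (configuration, seeds, package version) is written first; runs with
#' the same configuration and seed are reproducible artifact for
#' artifact.
#'
#' Stages: `simulate` (synthetic movies + ground truth), `atlas`
#' (docked-vesicle masks for the training movies), `targets` (3-class
#' label maps), `train` (the segmentation network; checkpoint + loss
#' log), `predict` (label maps for the held-out movies), `extract`
#' (event coordinates, mask- and border-filtered), `evaluate` (metrics
#' JSON), `photometry` (per-event F/F0 and per-movie decay fit).
#'
#' @param config a named list (or path to a YAML file) with an entry per
#'   stage plus `seed`, `stages`, `n_train_movies`, `n_test_movies`.
#'   Stage entries are passed to the corresponding parameter
#'   constructors: see [simulationParams()], [atlasParams()],
#'   [trainConfig()], [clusterParams()], [matchTolerances()].
#' @param outDir run directory (created if needed).
#' @return `outDir`, invisibly; artifacts and `metrics.json` inside.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  if (is.null(seed)) stop("config must name an explicit seed")
  stages <- config$stages
  if (is.null(stages))
    stages <- c("simulate", "atlas", "targets", "train", "predict",
                "extract", "evaluate", "photometry")
  nTrain <- config$n_train_movies %||% 2L
  nTest <- config$n_test_movies %||% 1L
  manifest <- list(package = "exopuff",
                   version = as.character(utils::packageVersion("exopuff")),
                   seed = seed, stages = stages, config = config)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- .runPaths(outDir, nTrain, nTest)

  .call2 <- function(fun, cfg) {
    cfg <- cfg[intersect(names(cfg), names(formals(fun)))]
    do.call(fun, cfg)
  }
  borderFrames <- config$extract$borderFrames %||% 25L

  if ("simulate" %in% stages) {
    for (i in seq_len(nTrain + nTest)) {
      sp <- .call2(simulationParams, config$simulate %||% list())
      sp$seed <- seed * 1000L + i
      sim <- simulateMovie(sp)
      writeMovie(sim$movie, paths$movie[i])
      writeEvents(sim$truth$events, paths$truth[i])
      writeCellMask(sim$truth$cellMask, paths$mask[i])
    }
  }
  if ("atlas" %in% stages) {
    for (i in seq_len(nTrain)) {
      if (!file.exists(paths$movie[i]))
        stop("atlas stage needs simulated movies; run 'simulate' first")
      ap <- .call2(atlasParams, config$atlas %||% list(mode = "projection"))
      det <- detectSpots(readMovie(paths$movie[i]), ap)
      mask3 <- det$mask
      if (is.matrix(mask3)) {
        writeCellMask(CellMask(mask3), paths$atlasMask[i])
      } else {
        writeLabelMap(LabelMap(array(as.integer(mask3), dim = dim(mask3))),
                      paths$atlasMask[i])
      }
      writeEvents(det$spots, paths$atlasSpots[i])
    }
  }
  if ("targets" %in% stages) {
    for (i in seq_len(nTrain)) {
      if (!file.exists(paths$atlasMask[i]))
        stop("targets stage needs spot-detector masks; run 'atlas' first")
      mv <- readMovie(paths$movie[i])
      msk <- .readAtlasMask(paths$atlasMask[i], dim(mv))
      lm <- buildLabelMap(readEvents(paths$truth[i]), msk, dim(mv))
      writeLabelMap(lm, paths$labels[i])
    }
  }
  if ("train" %in% stages) {
    datasets <- lapply(seq_len(nTrain), function(i) {
      if (!file.exists(paths$labels[i]))
        stop("train stage needs label maps; run 'targets' first")
      list(movie = readMovie(paths$movie[i]),
           labels = readLabelMap(paths$labels[i]),
           annotations = .mergeAnnotations(readEvents(paths$truth[i]),
                                           readEvents(paths$atlasSpots[i])))
    })
    tc <- .call2(trainConfig, config$train %||% list())
    tc$seed <- seed
    model <- trainSegmenter(datasets, tc)
    saveRDS(model, paths$checkpoint)
    write.csv(model@history, paths$lossLog, row.names = FALSE)
  }
  if ("predict" %in% stages) {
    if (!file.exists(paths$checkpoint))
      stop("predict stage needs a trained checkpoint; run 'train' first")
    model <- readRDS(paths$checkpoint)
    for (i in seq_len(nTest)) {
      j <- nTrain + i
      writeLabelMap(predictLabelMap(model, readMovie(paths$movie[j])),
                    paths$pred[i])
    }
  }
  if ("extract" %in% stages) {
    cp <- .call2(clusterParams, config$extract %||% list())
    for (i in seq_len(nTest)) {
      j <- nTrain + i
      if (!file.exists(paths$pred[i]))
        stop("extract stage needs predicted label maps; run 'predict' first")
      lm <- readLabelMap(paths$pred[i])
      ev <- extractEvents(lm, cp)
      ev <- filterEvents(ev, readCellMask(paths$mask[j]),
                         borderFrames = borderFrames,
                         nFrames = dim(lm)[1L])
      writeEvents(ev, paths$predEvents[i])
    }
  }
  if ("evaluate" %in% stages) {
    tol <- .call2(matchTolerances, config$evaluate %||% list())
    perMovie <- lapply(seq_len(nTest), function(i) {
      j <- nTrain + i
      if (!file.exists(paths$predEvents[i]))
        stop("evaluate stage needs extracted events; run 'extract' first")
      pred <- readEvents(paths$predEvents[i])
      mv <- readMovie(paths$movie[j])
      truth <- filterEvents(readEvents(paths$truth[j]),
                            readCellMask(paths$mask[j]),
                            borderFrames = borderFrames,
                            nFrames = nFrames(mv))
      rep <- matchEvents(pred, truth, tol)
      sc <- scores(rep)
      c(list(movie = basename(paths$movie[j]), nTp = rep$nTp,
             nFp = rep$nFp, nFn = rep$nFn,
             rateTruth = exocytosisRate(truth, nFrames(mv),
                                        frameInterval(mv)),
             ratePred = exocytosisRate(pred, nFrames(mv),
                                       frameInterval(mv))),
        sc[c("precision", "recall", "f1")])
    })
    agg <- list(nTp = sum(vapply(perMovie, `[[`, numeric(1), "nTp")),
                nFp = sum(vapply(perMovie, `[[`, numeric(1), "nFp")),
                nFn = sum(vapply(perMovie, `[[`, numeric(1), "nFn")))
    agg <- c(agg, scores(agg$nTp, agg$nFp, agg$nFn)[c("precision",
                                                      "recall", "f1")])
    jsonlite::write_json(list(perMovie = perMovie, pooled = agg),
                         paths$metrics, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if ("photometry" %in% stages) {
    for (i in seq_len(nTest)) {
      j <- nTrain + i
      mv <- readMovie(paths$movie[j])
      truth <- readEvents(paths$truth[j])
      sbr <- eventSbr(mv, truth)
      write.csv(cbind(events(truth)[, c("x", "y", "t")], sbr),
                file.path(outDir, sprintf("photometry_%02d.csv", i)),
                row.names = FALSE)
      fit <- tryCatch(decayLifetime(mv, truth), error = function(e) NULL)
      if (!is.null(fit))
        jsonlite::write_json(
          fit[c("A", "B", "tHalf", "tHalfSeconds", "nEvents",
                "degenerate")],
          file.path(outDir, sprintf("decay_%02d.json", i)),
          auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.runPaths <- function(outDir, nTrain, nTest) {
  f <- function(fmt, n) file.path(outDir, sprintf(fmt, seq_len(n)))
  list(movie = f("movie_%02d.tif", nTrain + nTest),
       truth = f("truth_%02d.csv", nTrain + nTest),
       mask = f("mask_%02d.tif", nTrain + nTest),
       atlasMask = f("atlas_mask_%02d.tif", nTrain),
       atlasSpots = f("atlas_spots_%02d.csv", nTrain),
       labels = f("labels_%02d.tif", nTrain),
       pred = f("pred_%02d.tif", nTest),
       predEvents = f("pred_events_%02d.csv", nTest),
       checkpoint = file.path(outDir, "model.rds"),
       lossLog = file.path(outDir, "loss.csv"),
       metrics = file.path(outDir, "metrics.json"))
}

# a spot-detector mask on disk is either a single 2D page (projection mode,
# broadcast over frames) or a full per-frame stack
.readAtlasMask <- function(path, gridDims) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1L && gridDims[1L] != 1L)
    return(pages[[1L]] > 0)
  l <- array(FALSE, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (i in seq_along(pages)) l[i, , ] <- pages[[i]] > 0
  l
}

# ground-truth exocytosis events + docked detector spots, one EventList
.mergeAnnotations <- function(truthEvents, dockedSpots) {
  a <- events(truthEvents)[, c("x", "y", "t", "class", "score")]
  b <- events(dockedSpots)[, c("x", "y", "t", "class", "score")]
  EventList(rbind(a, b), source = "hybrid annotations")
}

#' Evaluate prediction CSVs against ground-truth CSVs
#'
#' Convenience wrapper for an evaluation-only run: no movie or training
#' artifacts required.
#'
#' @param predictedCsv,truthCsv event CSV paths.
#' @param maskPath optional cell mask TIFF applied to both lists.
#' @param nFrames movie length (needed for border filtering).
#' @param borderFrames frames excluded at each end.
#' @param tolerances a [matchTolerances()].
#' @return list with the `MatchReport` and its [scores()].
#' @export
evaluateFiles <- function(predictedCsv, truthCsv, maskPath = NULL,
                          nFrames = NULL, borderFrames = 0L,
                          tolerances = matchTolerances()) {
  pred <- readEvents(predictedCsv)
  truth <- readEvents(truthCsv)
  if (!is.null(maskPath) || borderFrames > 0L) {
    if (is.null(nFrames)) stop("nFrames is required for filtering")
    msk <- if (!is.null(maskPath)) readCellMask(maskPath) else NULL
    pred <- filterEvents(pred, msk, borderFrames, nFrames)
    truth <- filterEvents(truth, msk, borderFrames, nFrames)
  }
  rep <- matchEvents(pred, truth, tolerances)
  list(report = rep, scores = scores(rep))
}
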