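# End-to-end desk-scale fixture: train the reduced segmenter once on six
# simulated movies and evaluate on held-out movies; the result is cached
# for the session so the detection and SBR-robustness tests share one
# training run. Problem sizes are the package's desk-scale study
# conditions (see the methods vignette).

e2eCache <- new.env(parent = emptyenv())

# amplitude giving an event F/F0 of `s` on the default background
.ampForSbr <- function(s, B0 = 100, sigma0 = 1.5) {
  g <- exp(-(-3:3)^2 / (2 * sigma0^2))
  W <- sum(outer(g, g)) / 49
  (s - 1) * B0 / W
}

e2eFixture <- function() {
  if (!is.null(e2eCache$res)) return(e2eCache$res)

  simAt <- function(seed, amplitudeRange = c(350, 1060))
    simulateMovie(simulationParams(width = 128L, height = 128L,
                                   nFrames = 300L, nEvents = 40L,
                                   amplitudeRange = amplitudeRange,
                                   seed = seed))

  trainSims <- lapply(1:6, function(i) simAt(1000 + i))
  datasets <- lapply(trainSims, function(sim) {
    det <- detectSpots(sim$movie, atlasParams(mode = "projection"))
    list(movie = sim$movie,
         labels = buildLabelMap(sim$truth$events, det$mask,
                                dim(sim$movie)),
         annotations = exopuff:::.mergeAnnotations(sim$truth$events,
                                                   det$spots))
  })
  cfg <- trainConfig(rounds = data.frame(patchSize = c(8L, 16L),
                                         maxShift = c(2L, 4L),
                                         batchSize = c(4L, 4L),
                                         nIterations = c(500L, 500L)),
                     baseFilters = 8, depth = 2, seed = 20)
  model <- trainSegmenter(datasets, cfg)

  evalOn <- function(sim) {
    pred <- predictLabelMap(model, sim$movie)
    ev <- extractEvents(pred)
    evf <- filterEvents(ev, sim$truth$cellMask, 25L, nFrames(sim$movie))
    truthf <- filterEvents(sim$truth$events, sim$truth$cellMask, 25L,
                           nFrames(sim$movie))
    list(pred = evf, truth = truthf, sim = sim,
         report = matchEvents(evf, truthf))
  }

  # held-out at the training SBR range (2--4)
  heldOut <- lapply(c(2001, 2002), function(s) evalOn(simAt(s)))
  # held-out spanning SBR ~1.2--3.2 for the robustness-vs-SBR check
  lowRange <- c(.ampForSbr(1.2), .ampForSbr(3.2))
  heldOutSbr <- lapply(c(3001, 3002), function(s)
    evalOn(simAt(s, amplitudeRange = lowRange)))

  e2eCache$res <- list(model = model, heldOut = heldOut,
                       heldOutSbr = heldOutSbr)
  e2eCache$res
}

pooledScores <- function(runs) {
  tp <- sum(vapply(runs, function(r) r$report$nTp, numeric(1)))
  fp <- sum(vapply(runs, function(r) r$report$nFp, numeric(1)))
  fn <- sum(vapply(runs, function(r) r$report$nFn, numeric(1)))
  scores(tp, fp, fn)
}

# pooled per-SBR-bin F1 over held-out runs; truth events binned by their
# analytic F/F0, false positives by their measured F/F0
pooledSbrBins <- function(runs, breaks = c(1.2, 1.6, 2.0, 3.0)) {
  agg <- NULL
  for (r in runs) {
    truthSbr <- analyticEventSbr(events(r$truth)$A, 100, 1.5)
    predSbr <- eventSbr(r$sim$movie, r$pred)$sbr
    b <- sbrBinnedMetrics(r$report, truthSbr, predSbr, breaks)
    if (is.null(agg)) agg <- b
    else agg[, c("nTp", "nFp", "nFn")] <-
        agg[, c("nTp", "nFp", "nFn")] + b[, c("nTp", "nFp", "nFn")]
  }
  agg$f1 <- with(agg, ifelse(2 * nTp + nFp + nFn > 0,
                             2 * nTp / (2 * nTp + nFp + nFn), NA_real_))
  agg
}
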