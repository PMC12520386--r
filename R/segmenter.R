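#' Training configuration for the segmentation network
#'
#' The patch-size curriculum starts small so that the rare exocytosis class
#' occupies a workable fraction of each training patch, then grows so the
#' model sees more spatial context (which lowers the false-positive rate).
#' ADAM hyper-parameters default to learning rate 1e-4 with first/second
#' moment decay 0.9/0.999; no weight regularisation is applied.
#'
#' @param rounds data.frame with columns `patchSize`, `maxShift`,
#'   `batchSize`, `nIterations` — one row per curriculum round. Patch sizes
#'   must be even, nondecreasing, and each `maxShift < patchSize/2`.
#' @param learningRate,adamBeta1,adamBeta2 ADAM hyper-parameters.
#' @param tverskyAlpha,tverskyBeta Tversky loss false-positive /
#'   false-negative weights; 0.5/0.5 reduces to the Dice loss.
#' @param baseFilters,depth network width and number of pooling stages.
#' @param seed optional RNG seed applied at the start of training.
#' @return a validated list of class `"trainConfig"`.
#' @export
trainConfig <- function(rounds = data.frame(
                          patchSize = c(8L, 16L, 32L, 48L),
                          maxShift = c(2L, 4L, 8L, 12L),
                          batchSize = c(8L, 8L, 8L, 8L),
                          nIterations = c(10000L, 10000L, 10000L, 10000L)),
                        learningRate = 1e-4,
                        adamBeta1 = 0.9, adamBeta2 = 0.999,
                        tverskyAlpha = 0.5, tverskyBeta = 0.5,
                        baseFilters = 8, depth = 2, seed = NULL) {
  stopifnot(is.data.frame(rounds),
            all(c("patchSize", "maxShift", "batchSize", "nIterations")
                %in% names(rounds)))
  if (any(rounds$patchSize %% 2 != 0))
    stop("patch sizes must be even")
  if (is.unsorted(rounds$patchSize))
    stop("patch sizes must be nondecreasing across rounds")
  if (any(rounds$maxShift >= rounds$patchSize / 2))
    stop("maxShift must be < patchSize/2")
  if (learningRate <= 0) stop("learningRate must be positive")
  if (tverskyAlpha < 0 || tverskyBeta < 0)
    stop("Tversky weights must be non-negative")
  structure(list(rounds = rounds, learningRate = learningRate,
                 adamBeta1 = adamBeta1, adamBeta2 = adamBeta2,
                 tverskyAlpha = tverskyAlpha, tverskyBeta = tverskyBeta,
                 baseFilters = baseFilters, depth = depth, seed = seed),
            class = "trainConfig")
}

#' Quantile-normalise a movie
#'
#' Affine map sending the 1st percentile of all voxel intensities to 0 and
#' the 99th to 1 (linear-interpolation percentiles over the whole movie,
#' computed once per movie). Values outside the range are not clipped.
#'
#' @param movie a [TirfMovie-class] or numeric array.
#' @param probs the two percentiles used as anchors.
#' @return numeric array of the movie's shape.
#' @export
quantileNormalize <- function(movie, probs = c(0.01, 0.99)) {
  d <- if (is(movie, "TirfMovie")) movieData(movie) else movie
  q <- quantile(d, probs = probs, names = FALSE, type = 7)
  if (q[2L] <= q[1L]) {
    warning("degenerate intensity distribution (p1 == p99); returning zeros")
    return(array(0, dim = dim(d)))
  }
  (d - q[1L]) / (q[2L] - q[1L])
}

#' Patch size at a given training iteration
#'
#' Piecewise-constant curriculum: round r's patch size holds for its
#' `nIterations` iterations (left-closed intervals); iterations beyond the
#' last round keep the final size.
#'
#' @param iteration 0-based iteration index.
#' @param rounds the `rounds` data.frame of a [trainConfig()].
#' @return patch edge length in voxels.
#' @export
curriculumPatchSize <- function(iteration, rounds) {
  stopifnot(iteration >= 0)
  edges <- cumsum(rounds$nIterations)
  idx <- findInterval(iteration, c(0, edges), rightmost.closed = FALSE)
  rounds$patchSize[min(idx, nrow(rounds))]
}

#' Sample an annotation-centred training patch
#'
#' Extracts a cubic window of side `patchSize` centred on the annotation
#' plus a uniform integer shift in `[-maxShift, maxShift]` per axis, then
#' clamped to lie fully inside the grid (no padding: borders never
#' fabricate intensities). Even windows centred at `c` span offsets
#' `[-L/2, L/2 - 1]`.
#'
#' @param movieArray normalised intensity array `(t, y, x)`.
#' @param labelArray integer label array, same shape.
#' @param annotation numeric `c(x, y, t)` 0-based coordinates.
#' @param patchSize window edge length (voxels).
#' @param maxShift maximum absolute shift per axis (voxels).
#' @return list with `intensity` and `labels` arrays of dim
#'   `(L, L, L)` ordered `(t, y, x)`, and `origin` (0-based window start,
#'   `c(t, y, x)`).
#' @export
samplePatch <- function(movieArray, labelArray, annotation, patchSize,
                        maxShift = 0L) {
  dims <- dim(movieArray)                     # (T, Y, X)
  L <- as.integer(patchSize)
  if (any(L > dims)) stop("patch larger than movie")
  ctr <- round(as.numeric(annotation))        # (x, y, t)
  ctr <- c(ctr[3L], ctr[2L], ctr[1L])         # -> (t, y, x)
  shift <- if (maxShift > 0)
    sample(seq(-maxShift, maxShift), 3L, replace = TRUE) else c(0L, 0L, 0L)
  start <- ctr + shift - L %/% 2L             # 0-based window origin
  start <- pmin(pmax(start, 0L), dims - L)
  idxT <- start[1L] + seq_len(L)
  idxY <- start[2L] + seq_len(L)
  idxX <- start[3L] + seq_len(L)
  list(intensity = movieArray[idxT, idxY, idxX, drop = FALSE],
       labels = labelArray[idxT, idxY, idxX, drop = FALSE],
       origin = start)
}

#' Apply a random (x, y)-plane dihedral augmentation
#'
#' Applies one of the 8 square symmetries (90-degree rotations times
#' mirroring) identically to an intensity/label patch pair. The temporal
#' axis is never touched: exocytosis has a directed time course, so only
#' spatial symmetries are valid augmentations.
#'
#' @param intensity,labels arrays `(t, y, x)` with square `(y, x)`
#'   footprint.
#' @param transform integer 0--7 selecting the dihedral element (0 =
#'   identity, 1--3 = rotations, 4--7 = mirrored); default: drawn from the
#'   session RNG.
#' @return list with transformed `intensity` and `labels`.
#' @export
augmentXY <- function(intensity, labels,
                      transform = sample(0:7, 1L)) {
  d <- dim(intensity)
  if (d[2L] != d[3L]) stop("(y, x) footprint must be square for rotations")
  ap <- function(a) {
    k <- transform %% 4L
    if (transform >= 4L) a <- a[, , rev(seq_len(d[3L])), drop = FALSE]
    for (i in seq_len(k)) {
      # rotate 90 deg in (y, x): new[y, x] = old[x, rev(y)]
      a <- aperm(a, c(1L, 3L, 2L))[, rev(seq_len(d[2L])), , drop = FALSE]
    }
    a
  }
  list(intensity = ap(intensity), labels = ap(labels),
       transform = transform)
}

#' Tversky loss over per-voxel class probabilities
#'
#' For each class c the Tversky index is
#' `TI_c = S_c / (S_c + alpha * FP_c + beta * FN_c)` with
#' `S_c = sum(p * g)`, `FP_c = sum(p * (1 - g))`, `FN_c = sum((1 - p) * g)`
#' and smoothing `eps`; the loss is `1 - mean_c TI_c`. `alpha = beta = 0.5`
#' is the Dice loss.
#'
#' @param probs `(nClasses x N)` matrix of per-voxel class probabilities
#'   (columns on the simplex).
#' @param target one-hot `(nClasses x N)` matrix.
#' @param alpha,beta false-positive / false-negative weights.
#' @param eps smoothing constant.
#' @param gradient if TRUE also return `dProbs`, the loss gradient.
#' @return list with `loss`, per-class `ti`, and optionally `dProbs`.
#' @export
tverskyLoss <- function(probs, target, alpha = 0.5, beta = 0.5,
                        eps = 1e-6, gradient = FALSE) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  S <- rowSums(probs * target) + eps
  FP <- rowSums(probs * (1 - target))
  FN <- rowSums((1 - probs) * target)
  D <- S + alpha * FP + beta * FN + eps
  ti <- S / D
  out <- list(loss = 1 - mean(ti), ti = ti)
  if (gradient) {
    C <- nrow(probs)
    # d TI_c / d p_ci = (g * D - S * (g + alpha*(1-g) - beta*g)) / D^2
    dTI <- (target * D - S * (target + alpha * (1 - target) -
                                beta * target)) / D^2
    out$dProbs <- -dTI / C
  }
  out
}

# chain dLoss/dProbs through the softmax to logits
.softmaxBackward <- function(probs, dProbs) {
  inner <- colSums(probs * dProbs)
  probs * sweep(dProbs, 2L, inner, "-")
}

# one-hot encode a label patch into (nClasses x N) in network voxel order
# (x fastest); patch is (t, y, x)
.patchToNet <- function(patch) {
  v <- as.vector(aperm(patch, c(3L, 2L, 1L)))   # -> x, y, t order
  matrix(v, nrow = 1L)
}

.labelsToOneHot <- function(patch, nClasses = 3L) {
  v <- as.integer(aperm(patch, c(3L, 2L, 1L)))
  oh <- matrix(0, nrow = nClasses, ncol = length(v))
  oh[cbind(v + 1L, seq_along(v))] <- 1
  oh
}

#' Train the segmentation network
#'
#' Runs the patch-size curriculum with annotation-centred sampling.
#' Training patches are drawn alternately centred on exocytosis and
#' docked-vesicle annotations (per-iteration class balancing for the rare
#' class); docked annotations are stationary, so their patch time is drawn
#' uniformly over the movie. Each patch receives a random (x, y) dihedral
#' augmentation. Optimisation is ADAM on the Tversky loss with no weight
#' regularisation.
#'
#' @param datasets list of training movies; each element a list with
#'   `movie` (a [TirfMovie-class] or a pre-normalised array), `labels` (a
#'   [LabelMap-class]) and `annotations` (an [EventList-class] holding
#'   exocytosis and optionally docked points).
#' @param config a [trainConfig()].
#' @param model optionally, a [PuffSegmenter-class] to continue training;
#'   default: a fresh [initSegmenter()].
#' @param verbose print the running loss every 50 iterations.
#' @return a trained [PuffSegmenter-class]; slot `history` logs the loss.
#' @export
trainSegmenter <- function(datasets, config = trainConfig(), model = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "trainConfig"), length(datasets) >= 1L)
  if (!is.null(config$seed)) set.seed(config$seed)
  prep <- lapply(datasets, function(ds) {
    arr <- if (is(ds$movie, "TirfMovie")) quantileNormalize(ds$movie)
           else ds$movie
    ev <- events(ds$annotations)
    list(intensity = arr, labels = labels3d(ds$labels),
         exo = ev[ev$class == "exocytosis", , drop = FALSE],
         docked = ev[ev$class == "docked", , drop = FALSE])
  })
  nExo <- sum(vapply(prep, function(p) nrow(p$exo), numeric(1)))
  if (nExo == 0L)
    stop("training dataset contains no exocytosis annotation")
  hasDocked <- vapply(prep, function(p) nrow(p$docked) > 0, logical(1))
  exoSets <- which(vapply(prep, function(p) nrow(p$exo) > 0, logical(1)))
  if (is.null(model))
    model <- initSegmenter(depth = config$depth,
                           baseFilters = config$baseFilters)
  weights <- model@weights
  adam <- .adamInit(weights)
  history <- vector("list", sum(config$rounds$nIterations))
  iterGlobal <- 0L
  for (r in seq_len(nrow(config$rounds))) {
    rd <- config$rounds[r, ]
    L <- rd$patchSize
    for (it in seq_len(rd$nIterations)) {
      grads <- NULL
      lossAcc <- 0
      for (bi in seq_len(rd$batchSize)) {
        wantDocked <- (bi %% 2L == 0L) && any(hasDocked)
        di <- if (wantDocked) sample(rep(which(hasDocked), 2L), 1L)
              else sample(rep(exoSets, 2L), 1L)
        p <- prep[[di]]
        pool <- if (wantDocked) p$docked else p$exo
        ann <- pool[sample.int(nrow(pool), 1L), ]
        dims <- dim(p$intensity)
        if (wantDocked) {
          # docked vesicles are stationary: draw the patch time uniformly
          ann$t <- sample.int(dims[1L], 1L) - 1L
        }
        sp <- samplePatch(p$intensity, p$labels, c(ann$x, ann$y, ann$t),
                          patchSize = L, maxShift = rd$maxShift)
        ag <- augmentXY(sp$intensity, sp$labels)
        x <- .patchToNet(ag$intensity)
        target <- .labelsToOneHot(ag$labels, model@nClasses)
        fw <- .segForward(model, x, dims = c(L, L, L))
        lv <- tverskyLoss(fw$probs, target, config$tverskyAlpha,
                          config$tverskyBeta, gradient = TRUE)
        dLogits <- .softmaxBackward(fw$probs, lv$dProbs)
        g <- .segBackward(model, fw$cache, dLogits)
        grads <- .addGrads(grads, g)
        lossAcc <- lossAcc + lv$loss
      }
      grads <- .scaleGrads(grads, 1 / rd$batchSize)
      st <- .adamStep(weights, grads, adam, config$learningRate,
                      config$adamBeta1, config$adamBeta2)
      weights <- st$weights
      adam <- st$state
      model@weights <- weights
      iterGlobal <- iterGlobal + 1L
      history[[iterGlobal]] <- data.frame(
        iteration = iterGlobal, round = r, patchSize = L,
        loss = lossAcc / rd$batchSize)
      if (verbose && iterGlobal %% 50L == 0L)
        message(sprintf("iter %d (patch %d): loss %.4f", iterGlobal, L,
                        lossAcc / rd$batchSize))
    }
  }
  model@history <- do.call(rbind, history[seq_len(iterGlobal)])
  model
}
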