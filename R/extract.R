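#' Mean-shift clustering parameters
#'
#' Defaults are chosen so that one rasterized tube (spatial extent about
#' +/-4 px, temporal extent 3 frames) forms a single basin of attraction.
#'
#' @param bandwidthPx flat-kernel bandwidth in (rescaled) voxels.
#' @param tScale multiplier applied to the t coordinate before clustering
#'   (temporal anisotropy).
#' @param minClusterVoxels clusters with fewer member voxels are dropped.
#' @return a validated list of class `"clusterParams"`.
#' @export
clusterParams <- function(bandwidthPx = 4.0, tScale = 1.5,
                          minClusterVoxels = 3L) {
  stopifnot(bandwidthPx > 0, tScale > 0, minClusterVoxels >= 1)
  structure(list(bandwidthPx = bandwidthPx, tScale = tScale,
                 minClusterVoxels = as.integer(minClusterVoxels)),
            class = "clusterParams")
}

# flat-kernel mean-shift over an (n x d) point matrix; returns converged
# mode positions (n x d)
.meanShiftModes <- function(P, bandwidth, maxIter = 100L, tol = 1e-3) {
  modes <- P
  h2 <- bandwidth^2
  n <- nrow(P)
  block <- max(1L, min(n, floor(2e7 / n)))
  for (iter in seq_len(maxIter)) {
    moved <- 0
    for (b0 in seq(1L, n, by = block)) {
      b1 <- min(b0 + block - 1L, n)
      sub <- modes[b0:b1, , drop = FALSE]
      # squared distances block x n
      d2 <- outer(rowSums(sub^2), rowSums(P^2), "+") -
        2 * sub %*% t(P)
      W <- d2 <= h2
      upd <- (W %*% P) / rowSums(W)
      moved <- max(moved, max(abs(upd - sub)))
      modes[b0:b1, ] <- upd
    }
    if (moved < tol) break
  }
  modes
}

#' Convert a predicted label map to event coordinates
#'
#' Runs flat-kernel mean-shift on the exocytosis-class voxel coordinates
#' in the rescaled space `(x, y, t * tScale)`; each converged basin is one
#' event, reported as the centroid (centre of mass) of its member voxels,
#' with `t` divided back by `tScale`. Clusters smaller than
#' `minClusterVoxels` are dropped.
#'
#' @param labelMap a [LabelMap-class] (or integer array) with values
#'   \{0, 1, 2\}.
#' @param params a [clusterParams()].
#' @return an [EventList-class] of continuous-coordinate exocytosis
#'   events; `score` holds the cluster voxel count.
#' @export
extractEvents <- function(labelMap, params = clusterParams()) {
  stopifnot(inherits(params, "clusterParams"))
  l <- if (is(labelMap, "LabelMap")) labels3d(labelMap) else labelMap
  idx <- which(l == 1L, arr.ind = TRUE)   # (t, y, x) 1-based
  if (nrow(idx) == 0L)
    return(EventList(source = "extracted"))
  # 0-based voxel coords in clustering space
  P <- cbind(x = idx[, 3L] - 1, y = idx[, 2L] - 1,
             t = (idx[, 1L] - 1) * params$tScale)
  modes <- .meanShiftModes(P, params$bandwidthPx)
  # merge modes closer than bandwidth / 2 into clusters
  n <- nrow(modes)
  cl <- integer(n)
  centers <- NULL
  for (i in seq_len(n)) {
    if (is.null(centers)) {
      centers <- modes[i, , drop = FALSE]
      cl[i] <- 1L
      next
    }
    d2 <- colSums((t(centers) - modes[i, ])^2)
    j <- which.min(d2)
    if (d2[j] <= (params$bandwidthPx / 2)^2) {
      cl[i] <- j
    } else {
      centers <- rbind(centers, modes[i, ])
      cl[i] <- nrow(centers)
    }
  }
  sizes <- tabulate(cl)
  keep <- which(sizes >= params$minClusterVoxels)
  if (length(keep) == 0L)
    return(EventList(source = "extracted"))
  out <- do.call(rbind, lapply(keep, function(k) {
    m <- P[cl == k, , drop = FALSE]
    data.frame(x = mean(m[, 1L]), y = mean(m[, 2L]),
               t = mean(m[, 3L]) / params$tScale,
               class = "exocytosis", score = nrow(m))
  }))
  out <- out[order(out$t, out$y, out$x), , drop = FALSE]
  EventList(out, source = "extracted")
}

#' Tiled full-movie inference
#'
#' Slides a fixed-size window over the movie and writes only each
#' window's interior (window minus `margin`) into the output, so border
#' effects from the zero padding of the convolutions stay outside the
#' reported region. The per-voxel class is the argmax of the network
#' scores.
#'
#' @param model a trained [PuffSegmenter-class].
#' @param movie a [TirfMovie-class] or numeric array.
#' @param tileDims `c(t, y, x)` interior tile size; `NA` entries default
#'   to covering the whole axis when it fits in one window.
#' @param margin `c(t, y, x)` overlap margin added on every side.
#' @param normalized set TRUE if the movie is already
#'   quantile-normalised.
#' @return a [LabelMap-class] of the movie's shape.
#' @export
predictLabelMap <- function(model, movie,
                            tileDims = c(32L, 96L, 96L),
                            margin = c(10L, 16L, 16L),
                            normalized = FALSE) {
  stopifnot(is(model, "PuffSegmenter"))
  arr <- if (is(movie, "TirfMovie")) movieData(movie) else movie
  if (!normalized) arr <- quantileNormalize(arr)
  dims <- dim(arr)                       # (T, Y, X)
  div <- 2^model@depth
  # full window sizes, clipped to the volume and made pooling-compatible
  win <- pmin(tileDims + 2L * margin, dims)
  win[2:3] <- (win[2:3] %/% div) * div
  if (any(win[2:3] < div))
    stop("movie too small for the pooling depth")
  margin[win == dims] <- 0L   # axis fits in one window: no overlap needed
  if (any(margin * 2 >= win))
    stop("margin must be smaller than half the window")
  interior <- pmax(win - 2L * margin, 1L)
  out <- array(0L, dim = dims)
  starts <- function(total, step) {
    step <- min(step, total)
    unique(pmin(seq(0L, total - 1L, by = step), total - step))
  }
  for (t0 in starts(dims[1L], interior[1L]))
    for (y0 in starts(dims[2L], interior[2L]))
      for (x0 in starts(dims[3L], interior[3L])) {
        # window origin clamped so the full window fits
        w0 <- pmin(pmax(c(t0, y0, x0) - margin, 0L), dims - win)
        sub <- arr[w0[1L] + seq_len(win[1L]),
                   w0[2L] + seq_len(win[2L]),
                   w0[3L] + seq_len(win[3L]), drop = FALSE]
        fw <- .segForward(model, .patchToNet(sub),
                          dims = c(win[3L], win[2L], win[1L]),
                          wantCache = FALSE)
        cls <- max.col(t(fw$probs), ties.method = "first") - 1L
        cls <- aperm(array(cls, dim = c(win[3L], win[2L], win[1L])),
                     c(3L, 2L, 1L))       # back to (t, y, x)
        # interior region of this tile in volume coords
        i0 <- c(t0, y0, x0)
        i1 <- pmin(i0 + interior, dims)
        sel <- lapply(1:3, function(a) (i0[a] + 1L):i1[a])
        off <- i0 - w0
        out[sel[[1L]], sel[[2L]], sel[[3L]]] <-
          cls[off[1L] + seq_len(i1[1L] - i0[1L]),
              off[2L] + seq_len(i1[2L] - i0[2L]),
              off[3L] + seq_len(i1[3L] - i0[3L]), drop = FALSE]
      }
  LabelMap(out)
}

#' Filter events by cell mask and border frames
#'
#' Keeps events whose nearest pixel lies inside the cell mask and whose
#' frame satisfies `borderFrames <= t < nFrames - borderFrames` (removing
#' the first and last frames avoids border bias: an event peaking just
#' outside the movie cannot be matched fairly). Filtering is idempotent
#' and never adds events.
#'
#' @param eventList an [EventList-class].
#' @param cellMask a [CellMask-class], or `NULL` to skip the mask test.
#' @param borderFrames number of frames excluded at each end (default 25).
#' @param nFrames total frame count of the movie.
#' @return the filtered [EventList-class].
#' @export
filterEvents <- function(eventList, cellMask = NULL, borderFrames = 25L,
                         nFrames) {
  stopifnot(is(eventList, "EventList"))
  ev <- events(eventList)
  keep <- ev$t >= borderFrames & ev$t < nFrames - borderFrames
  if (!is.null(cellMask)) {
    m <- maskData(cellMask)
    iy <- round(ev$y) + 1L
    ix <- round(ev$x) + 1L
    inb <- iy >= 1L & iy <= nrow(m) & ix >= 1L & ix <= ncol(m)
    inMask <- inb
    inMask[inb] <- m[cbind(iy[inb], ix[inb])]
    keep <- keep & inMask
  }
  EventList(ev[keep, , drop = FALSE], source = eventSource(eventList))
}
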