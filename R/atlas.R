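#' Parameters of the unsupervised spot detector
#'
#' Bright stationary spots (docked vesicles) are detected without
#' supervision by scale-normalised Laplacian-of-Gaussian (LoG) filtering,
#' automatic scale selection, and a pointwise detection threshold inferred
#' from a probability of false alarm (PFA) under local Gaussian-window
#' statistics.
#'
#' @param pfa probability of false alarm: the per-pixel chance that pure
#'   noise exceeds the threshold (default 0.001).
#' @param windowSigmaPx standard deviation (px) of the Gaussian window used
#'   for the local response statistics; should be about the size of the
#'   background structures (default 21).
#' @param minComponentPx connected components smaller than this many pixels
#'   are discarded (default 3; 8-connectivity).
#' @param scales candidate LoG standard deviations in pixels.
#' @param mode `"per_frame"` (detect on every frame) or `"projection"`
#'   (detect once on the temporal mean image — docked vesicles are
#'   stationary).
#' @return a validated list of class `"atlasParams"`.
#' @export
atlasParams <- function(pfa = 0.001, windowSigmaPx = 21,
                        minComponentPx = 3L,
                        scales = c(1, 1.5, 2, 3, 4),
                        mode = c("per_frame", "projection")) {
  mode <- match.arg(mode)
  stopifnot(pfa > 0, pfa < 0.5, windowSigmaPx > 0, minComponentPx >= 1,
            length(scales) >= 1, all(scales > 0))
  structure(list(pfa = pfa, windowSigmaPx = windowSigmaPx,
                 minComponentPx = as.integer(minComponentPx),
                 scales = scales, mode = mode),
            class = "atlasParams")
}

# zero-sum scale-normalised LoG kernel; bright blobs -> positive response
.logKernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  d <- seq(-r, r)
  g <- exp(-d^2 / (2 * sigma^2))
  G <- outer(g, g) / (2 * pi * sigma^2)
  r2 <- outer(d^2, d^2, "+")
  K <- G * (2 * sigma^2 - r2) / sigma^2   # = -sigma^2 * laplacian(G)
  K - mean(K)                             # exact zero response on constants
}

.gaussKernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- exp(-seq(-r, r)^2 / (2 * sigma^2))
  K <- outer(g, g)
  K / sum(K)
}

# convolution with replicated borders; kernels larger than the image are
# cropped centrally and re-normalised (sum-1 for averaging windows,
# zero-mean for the LoG) so small images stay well-defined
.filter2r <- function(img, K, renorm = c("none", "sum1", "zeromean")) {
  renorm <- match.arg(renorm)
  oddCap <- function(n, k) if (k <= n) k else (n - (1 - n %% 2))
  kh <- oddCap(nrow(img), nrow(K)); kw <- oddCap(ncol(img), ncol(K))
  if (kh < nrow(K) || kw < ncol(K)) {
    cy <- (nrow(K) + 1L) %/% 2L; cx <- (ncol(K) + 1L) %/% 2L
    K <- K[cy - (kh - 1L) %/% 2L + 0:(kh - 1L),
           cx - (kw - 1L) %/% 2L + 0:(kw - 1L), drop = FALSE]
    K <- switch(renorm, none = K, sum1 = K / sum(K), zeromean = K - mean(K))
  }
  out <- EBImage::imageData(
    EBImage::filter2(EBImage::Image(img), K, boundary = "replicate"))
  matrix(out, nrow(img), ncol(img))
}

#' Scale-normalised Laplacian-of-Gaussian response
#'
#' Convolves a 2D image with `sigma^2 * (-laplacian(G_sigma))`; the
#' sigma^2 normalisation makes responses comparable across scales, with the
#' maximum attained when the filter scale matches the spot size. Constant
#' images give an identically zero response.
#'
#' @param image numeric `(y, x)` matrix.
#' @param sigma LoG standard deviation in pixels.
#' @return response matrix of the image's shape.
#' @export
logResponse <- function(image, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  .filter2r(image, .logKernel(sigma), renorm = "zeromean")
}

#' Automatic LoG scale selection
#'
#' Builds the multiscale response representation and returns the scale
#' whose scale-normalised response attains the global maximum over the
#' image (one scale per image). A degenerate image with no response ties
#' all scales; the smallest is returned with a warning.
#'
#' @param image numeric `(y, x)` matrix.
#' @param scales candidate LoG standard deviations.
#' @return the selected scale.
#' @export
selectScale <- function(image, scales = c(1, 1.5, 2, 3, 4)) {
  if (length(scales) == 0L) stop("empty scale set")
  peak <- vapply(scales, function(s) max(logResponse(image, s)), numeric(1))
  if (diff(range(peak)) < 1e-12) {
    warning("degenerate image: all scales respond equally; ",
            "returning the smallest")
    return(min(scales))
  }
  scales[which.max(peak)]
}

#' Local Gaussian-window statistics of a response image
#'
#' Gaussian-weighted local mean and standard deviation,
#' `s(p) = sqrt(E_w[R^2] - E_w[R]^2)` clipped at a small positive floor.
#'
#' @param response numeric matrix.
#' @param windowSigma Gaussian window standard deviation (px).
#' @param sdFloor lower clip for the local SD.
#' @return list with `mean` and `sd` matrices.
#' @export
localStats <- function(response, windowSigma = 21, sdFloor = 1e-8) {
  if (windowSigma <= 0) stop("windowSigma must be positive")
  K <- .gaussKernel(windowSigma)
  mu <- .filter2r(response, K, renorm = "sum1")
  m2 <- .filter2r(response^2, K, renorm = "sum1")
  list(mean = mu, sd = sqrt(pmax(m2 - mu^2, sdFloor^2)))
}

#' Pointwise PFA detection threshold
#'
#' Under locally Gaussian response statistics the threshold giving a
#' per-pixel false-alarm probability `pfa` is
#' `T(p) = mu(p) + z(1 - pfa) * s(p)` with `z` the standard normal
#' quantile.
#'
#' @param meanMap,sdMap local statistics from [localStats()].
#' @param pfa probability of false alarm in (0, 0.5).
#' @return threshold matrix.
#' @export
pfaThreshold <- function(meanMap, sdMap, pfa = 0.001) {
  if (pfa <= 0 || pfa > 0.5) stop("pfa must be in (0, 0.5]")
  meanMap + qnorm(1 - pfa) * sdMap
}

# 8-connected component labelling (two-pass union-find);
# EBImage::bwlabel is 4-connected, and the minimum-size rule needs
# 8-connectivity to be deterministic for diagonal bright blobs
.label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (x in seq_len(W)) for (y in seq_len(H)) {
    if (!mask[y, x]) next
    nb <- integer(0)
    if (y > 1 && mask[y - 1, x]) nb <- c(nb, lab[y - 1, x])
    if (x > 1) {
      if (mask[y, x - 1]) nb <- c(nb, lab[y, x - 1])
      if (y > 1 && mask[y - 1, x - 1]) nb <- c(nb, lab[y - 1, x - 1])
      if (y < H && mask[y + 1, x - 1]) nb <- c(nb, lab[y + 1, x - 1])
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[y, x] <- nxt
    } else {
      roots <- vapply(unique(nb), findRoot, integer(1))
      r0 <- min(roots)
      lab[y, x] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), findRoot, integer(1))
  remap <- integer(nxt)
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  idx <- which(lab > 0L)
  lab[idx] <- remap[roots[lab[idx]]]
  lab
}

# single-frame detection: returns list(mask, spots data.frame(x, y, size))
.detectFrame <- function(image, params) {
  sigma <- suppressWarnings(selectScale(image, params$scales))
  R <- logResponse(image, sigma)
  st <- localStats(R, params$windowSigmaPx)
  keep <- R > pfaThreshold(st$mean, st$sd, params$pfa)
  lab <- .label8(keep)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < params$minComponentPx)
    if (length(drop)) {
      keep[lab %in% drop] <- FALSE
      lab[lab %in% drop] <- 0L
    }
  }
  ids <- sort(unique(lab[lab > 0L]))
  spots <- if (length(ids)) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    l <- lab[lab > 0L]
    data.frame(
      x = as.numeric(tapply(idx[, 2L] - 1, l, mean)),
      y = as.numeric(tapply(idx[, 1L] - 1, l, mean)),
      size = as.numeric(tabulate(l)[ids]))
  } else data.frame(x = numeric(0), y = numeric(0), size = numeric(0))
  list(mask = keep, spots = spots)
}

#' Detect bright spots (docked-vesicle counter-examples)
#'
#' Pixels whose LoG response at the automatically selected scale exceeds
#' the pointwise PFA threshold are kept; 8-connected components smaller
#' than `minComponentPx` pixels are discarded. In `per_frame` mode every
#' frame is processed and the 2D masks are stacked into a 3D mask; in
#' `projection` mode detection runs once on the temporal mean image
#' (appropriate because docked vesicles are stationary) and the returned
#' mask is 2D.
#'
#' @param x a [TirfMovie-class] or a 2D numeric matrix.
#' @param params an [atlasParams()].
#' @return list with `mask` (logical array: 3D `(t, y, x)` in per-frame
#'   mode on a movie, else 2D) and `spots`, an [EventList-class] of class
#'   `"docked"` component centroids (per-frame spots carry their frame as
#'   `t`; projection spots have `t = 0`; `score` holds the component
#'   size).
#' @export
detectSpots <- function(x, params = atlasParams()) {
  stopifnot(inherits(params, "atlasParams"))
  if (is.matrix(x)) {
    d <- .detectFrame(x, params)
    spots <- d$spots
    return(list(mask = d$mask,
                spots = EventList(
                  x = spots$x, y = spots$y, t = rep(0, nrow(spots)),
                  class = "docked", score = spots$size,
                  source = "atlas")))
  }
  stopifnot(is(x, "TirfMovie"))
  arr <- movieData(x)
  if (params$mode == "projection") {
    img <- apply(arr, c(2L, 3L), mean)
    d <- .detectFrame(img, params)
    return(list(mask = d$mask,
                spots = EventList(
                  x = d$spots$x, y = d$spots$y,
                  t = rep(0, nrow(d$spots)),
                  class = "docked", score = d$spots$size,
                  source = "atlas projection")))
  }
  TT <- dim(arr)[1L]
  mask <- array(FALSE, dim = dim(arr))
  allSpots <- vector("list", TT)
  for (tt in seq_len(TT)) {
    d <- .detectFrame(arr[tt, , ], params)
    mask[tt, , ] <- d$mask
    if (nrow(d$spots))
      allSpots[[tt]] <- cbind(d$spots, t = tt - 1)
  }
  spots <- do.call(rbind, allSpots)
  if (is.null(spots))
    spots <- data.frame(x = numeric(0), y = numeric(0), size = numeric(0),
                        t = numeric(0))
  list(mask = mask,
       spots = EventList(x = spots$x, y = spots$y, t = spots$t,
                         class = "docked", score = spots$size,
                         source = "atlas per-frame"))
}
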