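#' Per-event F/F0 signal-to-background ratio
#'
#' Ratio between the mean intensity in a `window x window` pixel window
#' centred on the event at the frame of peak fluorescence and the mean in
#' the same window `baselineOffset` frames earlier. Events within the
#' first `baselineOffset` frames have no baseline and come back `NA` with
#' the `flag` set; windows clipped at the image border are computed on the
#' in-bounds part and flagged.
#'
#' @param movie a [TirfMovie-class].
#' @param eventList an [EventList-class] (continuous coordinates are
#'   rounded to the nearest voxel).
#' @param window window side in pixels (default 7, i.e. 1.12 um at
#'   0.16 um/px).
#' @param baselineOffset frames between peak and baseline (default 5).
#' @return data.frame with one row per event: `sbr` and `flag`
#'   (`"ok"`, `"clipped"`, `"no_baseline"`, `"zero_baseline"`).
#' @export
eventSbr <- function(movie, eventList, window = 7L, baselineOffset = 5L) {
  stopifnot(is(movie, "TirfMovie"))
  arr <- movieData(movie)
  dims <- dim(arr)
  ev <- if (is(eventList, "EventList")) events(eventList) else eventList
  h <- (window - 1L) %/% 2L
  n <- nrow(ev)
  out <- data.frame(sbr = rep(NA_real_, n), flag = rep("ok", n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tt <- round(ev$t[i]); yy <- round(ev$y[i]); xx <- round(ev$x[i])
    if (tt < baselineOffset) {
      out$flag[i] <- "no_baseline"
      next
    }
    ys <- max(0, yy - h):min(dims[2L] - 1L, yy + h)
    xs <- max(0, xx - h):min(dims[3L] - 1L, xx + h)
    if (length(ys) < window || length(xs) < window)
      out$flag[i] <- "clipped"
    peak <- mean(arr[tt + 1L, ys + 1L, xs + 1L])
    base <- mean(arr[tt + 1L - baselineOffset, ys + 1L, xs + 1L])
    if (base <= 0) {
      out$flag[i] <- "zero_baseline"
      next
    }
    out$sbr[i] <- peak / base
  }
  out
}

#' Cell-level signal-to-background ratio
#'
#' Classic ratio of the mean intensity inside the cell mask over the mean
#' outside it, averaged over frames.
#'
#' @param movie a [TirfMovie-class].
#' @param cellMask a [CellMask-class] with both inside and outside
#'   pixels.
#' @return the ratio.
#' @export
cellSbr <- function(movie, cellMask) {
  stopifnot(is(movie, "TirfMovie"), is(cellMask, "CellMask"))
  m <- maskData(cellMask)
  if (!any(m) || all(m)) stop("mask must contain inside and outside pixels")
  arr <- movieData(movie)
  ratios <- vapply(seq_len(dim(arr)[1L]), function(tt) {
    fr <- arr[tt, , ]
    mean(fr[m]) / mean(fr[!m])
  }, numeric(1))
  mean(ratios)
}

#' Fit the exponential decay lifetime of a cell's events
#'
#' For each event with `nFramesTrace` frames of trailing data, the
#' window-mean intensity trace starting at the peak frame is normalised by
#' its peak value; traces are averaged over events, and the average is
#' fitted with `I(t) = A * exp(-t / tHalf) + B` by nonlinear least squares
#' (Levenberg--Marquardt). `tHalf` is the e-folding constant in frames.
#'
#' @param movie a [TirfMovie-class].
#' @param eventList the cell's events (ground truth or predictions;
#'   non-integer peak frames are rounded).
#' @param window window side in pixels.
#' @param nFramesTrace trace length in frames (default 16, about 5 s at
#'   0.3 s/frame).
#' @return list of class `"DecayFit"`: `A`, `B`, `tHalf` (frames),
#'   `tHalfSeconds`, `residualNorm`, `nEvents` used, the averaged
#'   `trace`, and `degenerate` (TRUE when there is no decaying component
#'   or the fit failed).
#' @export
decayLifetime <- function(movie, eventList, window = 7L,
                          nFramesTrace = 16L) {
  stopifnot(is(movie, "TirfMovie"))
  arr <- movieData(movie)
  dims <- dim(arr)
  ev <- if (is(eventList, "EventList")) events(eventList) else eventList
  h <- (window - 1L) %/% 2L
  traces <- list()
  for (i in seq_len(nrow(ev))) {
    tt <- round(ev$t[i]); yy <- round(ev$y[i]); xx <- round(ev$x[i])
    if (tt + nFramesTrace > dims[1L]) next   # needs full trailing window
    ys <- max(0, yy - h):min(dims[2L] - 1L, yy + h)
    xs <- max(0, xx - h):min(dims[3L] - 1L, xx + h)
    tr <- vapply(seq_len(nFramesTrace) - 1L, function(k)
      mean(arr[tt + k + 1L, ys + 1L, xs + 1L]), numeric(1))
    if (tr[1L] <= 0) next
    traces[[length(traces) + 1L]] <- tr / tr[1L]
  }
  if (length(traces) == 0L) stop("no usable events for lifetime fitting")
  avg <- colMeans(do.call(rbind, traces))
  tFrames <- seq_len(nFramesTrace) - 1
  a0 <- avg[1L] - avg[nFramesTrace]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-tt / tHalf) + B,
      data = data.frame(y = avg, tt = tFrames),
      start = list(A = max(a0, 1e-3), B = avg[nFramesTrace], tHalf = 5),
      lower = c(A = -Inf, B = -Inf, tHalf = 1e-6),
      upper = c(A = Inf, B = Inf, tHalf = 10 * nFramesTrace),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(A = 0, B = mean(avg), tHalf = NA_real_,
                          tHalfSeconds = NA_real_,
                          residualNorm = NA_real_,
                          nEvents = length(traces), trace = avg,
                          degenerate = TRUE), class = "DecayFit"))
  }
  cf <- coef(fit)
  degenerate <- abs(cf[["A"]]) < 1e-3
  structure(list(A = cf[["A"]], B = cf[["B"]], tHalf = cf[["tHalf"]],
                 tHalfSeconds = cf[["tHalf"]] * frameInterval(movie),
                 residualNorm = sqrt(sum(residuals(fit)^2)),
                 nEvents = length(traces), trace = avg,
                 degenerate = degenerate), class = "DecayFit")
}

#' @export
print.DecayFit <- function(x, ...) {
  cat(sprintf(
    "DecayFit over %d events: A = %.3f, B = %.3f, tHalf = %.2f frames (%.2f s)%s\n",
    x$nEvents, x$A, x$B, x$tHalf, x$tHalfSeconds,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Generate a cell mask by intensity thresholding
#'
#' Applies an automatic intensity threshold (Otsu criterion) to the first
#' frame (cell movements over a few minutes are minor, so one frame
#' suffices), keeps the largest connected component, and fills holes. The
#' mask is invariant under affine rescaling of the intensities.
#'
#' @param movie a [TirfMovie-class].
#' @return a [CellMask-class]; a constant first frame degenerates to an
#'   all-TRUE mask with a warning.
#' @export
makeCellMask <- function(movie) {
  stopifnot(is(movie, "TirfMovie"))
  fr <- movieData(movie)[1L, , ]
  rng <- range(fr)
  if (diff(rng) == 0) {
    warning("constant first frame: returning an all-TRUE mask")
    return(CellMask(matrix(TRUE, nrow(fr), ncol(fr))))
  }
  f <- (fr - rng[1L]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(f))
  bin <- f > th
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  sizes <- tabulate(as.integer(lab))
  big <- lab == which.max(sizes)
  filled <- EBImage::fillHull(EBImage::Image(big))
  CellMask(matrix(as.logical(filled), nrow(fr), ncol(fr)))
}

#' @importFrom stats residuals
NULL
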