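#' Spatiotemporal matching tolerances
#'
#' A prediction matches a ground-truth event when their Euclidean image
#' distance is at most `dxMax` pixels and the frame difference
#' `dt = t_pred - t_truth` lies in `[dtMin, dtMax]` (positive means the
#' prediction peaks after the truth; the window is asymmetric because the
#' segmentation tube extends forward from the peak). Cross-method overlap
#' uses the symmetric window `|dt| <= vennDtAbs`.
#'
#' @param dxMax spatial tolerance in pixels (default 4.5).
#' @param dtMin,dtMax temporal tolerance in frames (default -2, +5).
#' @param vennDtAbs symmetric temporal tolerance for overlap counts
#'   (default 7).
#' @return a validated list of class `"matchTolerances"`.
#' @export
matchTolerances <- function(dxMax = 4.5, dtMin = -2, dtMax = 5,
                            vennDtAbs = 7) {
  stopifnot(dxMax > 0, dtMin <= 0, dtMax >= 0, vennDtAbs >= 0)
  structure(list(dxMax = dxMax, dtMin = dtMin, dtMax = dtMax,
                 vennDtAbs = vennDtAbs), class = "matchTolerances")
}

# greedy one-to-one assignment over candidate pairs ordered by ascending
# dx (ties: ascending |dt|, then input order)
.greedyAssign <- function(pred, truth, dxMax, dtMin, dtMax) {
  np <- nrow(pred); ng <- nrow(truth)
  if (np == 0L || ng == 0L)
    return(data.frame(predIndex = integer(0), truthIndex = integer(0),
                      dx = numeric(0), dt = numeric(0)))
  dx <- sqrt(outer(pred$x, truth$x, "-")^2 + outer(pred$y, truth$y, "-")^2)
  dt <- outer(pred$t, truth$t, "-")
  cand <- which(dx <= dxMax & dt >= dtMin & dt <= dtMax, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(predIndex = integer(0), truthIndex = integer(0),
                      dx = numeric(0), dt = numeric(0)))
  cd <- data.frame(predIndex = cand[, 1L], truthIndex = cand[, 2L],
                   dx = dx[cand], dt = dt[cand])
  cd <- cd[order(cd$dx, abs(cd$dt), cd$predIndex, cd$truthIndex), ,
           drop = FALSE]
  usedP <- logical(np); usedG <- logical(ng)
  keep <- logical(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    p <- cd$predIndex[i]; g <- cd$truthIndex[i]
    if (!usedP[p] && !usedG[g]) {
      keep[i] <- TRUE
      usedP[p] <- TRUE; usedG[g] <- TRUE
    }
  }
  cd[keep, , drop = FALSE]
}

#' Match predicted events against ground truth
#'
#' Candidate pairs are all (prediction, truth) combinations within the
#' tolerances; pairs are accepted greedily in ascending spatial distance
#' (ties broken by ascending `|dt|`, then input order), each prediction
#' and each truth used at most once. TP = accepted pairs, FP = unmatched
#' predictions, FN = N_truth - TP.
#'
#' @param predicted,truth [EventList-class] objects bound to the same
#'   movie geometry.
#' @param tolerances a [matchTolerances()].
#' @return a `MatchReport`: list with `pairs` (data.frame `predIndex`,
#'   `truthIndex`, `dx`, `dt`), counts `nTp`, `nFp`, `nFn`, and the list
#'   sizes.
#' @export
matchEvents <- function(predicted, truth, tolerances = matchTolerances()) {
  stopifnot(inherits(tolerances, "matchTolerances"))
  p <- if (is(predicted, "EventList")) events(predicted) else predicted
  g <- if (is(truth, "EventList")) events(truth) else truth
  pairs <- .greedyAssign(p, g, tolerances$dxMax, tolerances$dtMin,
                         tolerances$dtMax)
  structure(list(pairs = pairs, nTp = nrow(pairs),
                 nFp = nrow(p) - nrow(pairs),
                 nFn = nrow(g) - nrow(pairs),
                 nPred = nrow(p), nTruth = nrow(g)),
            class = "MatchReport")
}

#' @export
print.MatchReport <- function(x, ...) {
  cat(sprintf("MatchReport: %d TP, %d FP, %d FN (of %d predictions, %d truths)\n",
              x$nTp, x$nFp, x$nFn, x$nPred, x$nTruth))
  invisible(x)
}

#' Detection scores from TP/FP/FN counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 TP/(2 TP + FP + FN)`. When all three counts are zero the scores
#' cannot be computed and the `undefined` flag is set.
#'
#' @param x a `MatchReport`, or the TP count.
#' @param nFp,nFn FP and FN counts when `x` is a count.
#' @return list with `precision`, `recall`, `f1`, `undefined`.
#' @export
scores <- function(x, nFp = NULL, nFn = NULL) {
  if (inherits(x, "MatchReport")) {
    nTp <- x$nTp; nFp <- x$nFp; nFn <- x$nFn
  } else {
    nTp <- x
  }
  if (any(c(nTp, nFp, nFn) < 0)) stop("counts must be non-negative")
  if (nTp == 0 && nFp == 0 && nFn == 0)
    return(list(precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                undefined = TRUE))
  list(precision = if (nTp + nFp > 0) nTp / (nTp + nFp) else 0,
       recall = if (nTp + nFn > 0) nTp / (nTp + nFn) else 0,
       f1 = 2 * nTp / (2 * nTp + nFp + nFn),
       undefined = FALSE)
}

#' Localization errors of the matched pairs
#'
#' @param report a `MatchReport`.
#' @return list with numeric vectors `dx` (px) and `dt` (frames,
#'   prediction minus truth), one entry per TP, for cumulative
#'   distribution plots.
#' @export
localizationErrors <- function(report) {
  stopifnot(inherits(report, "MatchReport"))
  list(dx = report$pairs$dx, dt = report$pairs$dt)
}

#' Cross-method overlap (Venn region counts)
#'
#' Events reported by different detection methods are considered the same
#' physical event when within `dxMax` pixels and `|dt| <= dtAbs` frames;
#' matching is greedy one-to-one by ascending spatial distance. With three
#' lists the partition proceeds pairwise in a fixed order: A vs B first,
#' then the AB pairs and the survivors of each are matched against C.
#'
#' @param listA,listB,listC [EventList-class] objects (`listC` optional).
#' @param dxMax spatial tolerance (px).
#' @param dtAbs symmetric temporal tolerance (frames).
#' @return named counts: for two lists `A`, `B`, `AB`; for three lists
#'   `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC`.
#' @export
crossMethodOverlap <- function(listA, listB, listC = NULL,
                               dxMax = 4.5, dtAbs = 7) {
  a <- if (is(listA, "EventList")) events(listA) else listA
  b <- if (is(listB, "EventList")) events(listB) else listB
  mAB <- .greedyAssign(a, b, dxMax, -dtAbs, dtAbs)
  if (is.null(listC)) {
    return(c(A = nrow(a) - nrow(mAB), B = nrow(b) - nrow(mAB),
             AB = nrow(mAB)))
  }
  cc <- if (is(listC, "EventList")) events(listC) else listC
  aOnly <- a[setdiff(seq_len(nrow(a)), mAB$predIndex), , drop = FALSE]
  bOnly <- b[setdiff(seq_len(nrow(b)), mAB$truthIndex), , drop = FALSE]
  abRep <- a[mAB$predIndex, , drop = FALSE]   # AB pairs, A coordinates
  usedC <- logical(nrow(cc))
  matchC <- function(df) {
    m <- .greedyAssign(df, cc[!usedC, , drop = FALSE], dxMax, -dtAbs, dtAbs)
    freeIdx <- which(!usedC)
    usedC[freeIdx[m$truthIndex]] <<- TRUE
    nrow(m)
  }
  nABC <- matchC(abRep)
  nAC <- matchC(aOnly)
  nBC <- matchC(bOnly)
  c(A = nrow(aOnly) - nAC, B = nrow(bOnly) - nBC, C = sum(!usedC),
    AB = nrow(abRep) - nABC, AC = nAC, BC = nBC, ABC = nABC)
}

#' Exocytosis rate in events per minute
#'
#' @param x an [EventList-class] or an event count.
#' @param nFrames movie length in frames.
#' @param frameIntervalS seconds per frame.
#' @return events per minute.
#' @examples
#' exocytosisRate(30, 1001, 0.3)  # ~5.99 events/min
#' @export
exocytosisRate <- function(x, nFrames, frameIntervalS = 0.3) {
  stopifnot(nFrames >= 1)
  n <- if (is(x, "EventList")) length(x) else x
  n / (nFrames * frameIntervalS / 60)
}

#' Cohen's d for paired samples
#'
#' The per-cell pairwise difference is `delta_i = after_i - before_i`;
#' `d = mean(delta) / sd(delta)` with the sample (n-1) standard deviation.
#' Invariant under adding a common constant to both series and under a
#' common positive rescaling.
#'
#' @param before,after equal-length paired numeric vectors (n >= 2).
#' @return list with `d`, `meanDiff`, `sdDiff`, `n`, `undefined` (TRUE
#'   when the differences have zero spread).
#' @export
cohensDPaired <- function(before, after) {
  if (length(before) != length(after)) stop("paired vectors differ in length")
  if (length(before) < 2L) stop("need at least 2 pairs")
  delta <- after - before
  s <- sd(delta)
  if (s == 0)
    return(list(d = NA_real_, meanDiff = mean(delta), sdDiff = 0,
                n = length(delta), undefined = TRUE))
  list(d = mean(delta) / s, meanDiff = mean(delta), sdDiff = s,
       n = length(delta), undefined = FALSE)
}

#' F1 per event-SBR bin
#'
#' Bins the evaluation by event signal-to-background ratio (F/F0). True
#' positives and false negatives are binned by the ground-truth event's
#' SBR; false positives, which have no ground-truth SBR, are binned by the
#' F/F0 measured from the movie at the predicted coordinates.
#'
#' @param report a `MatchReport` from [matchEvents()].
#' @param truthSbr numeric vector: SBR of each ground-truth event (same
#'   order as the truth list).
#' @param predSbr numeric vector: measured SBR of each prediction (same
#'   order as the predicted list); `NA` entries are left out of the FP
#'   binning.
#' @param breaks bin edges (left-closed, right-open).
#' @return data.frame with one row per bin: counts and `f1`.
#' @export
sbrBinnedMetrics <- function(report, truthSbr, predSbr,
                             breaks = c(1.2, 1.6, 2.0, 3.0)) {
  stopifnot(inherits(report, "MatchReport"),
            length(truthSbr) == report$nTruth,
            length(predSbr) == report$nPred)
  bin <- function(v) findInterval(v, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1L
  tpBin <- bin(truthSbr[report$pairs$truthIndex])
  fnBin <- bin(truthSbr[setdiff(seq_len(report$nTruth),
                                report$pairs$truthIndex)])
  fpIdx <- setdiff(seq_len(report$nPred), report$pairs$predIndex)
  fpBin <- bin(predSbr[fpIdx])
  fpBin <- fpBin[!is.na(fpBin)]
  out <- data.frame(lo = breaks[seq_len(nb)], hi = breaks[-1L],
                    nTp = tabulate(tpBin[tpBin >= 1 & tpBin <= nb], nb),
                    nFp = tabulate(fpBin[fpBin >= 1 & fpBin <= nb], nb),
                    nFn = tabulate(fnBin[fnBin >= 1 & fnBin <= nb], nb))
  out$f1 <- with(out, ifelse(2 * nTp + nFp + nFn > 0,
                             2 * nTp / (2 * nTp + nFp + nFn), NA_real_))
  out
}
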