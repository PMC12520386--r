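#' The (x, y, t) tube shape model
#'
#' An exocytosis event is isotropic in the image plane (a disc) and decays
#' exponentially in time, so its voxel-level footprint is modelled as a
#' 3-frame tube with decaying disc radius: radius 4 px on the annotated
#' peak frame, then 2 px and 1 px on the next two frames.
#'
#' @param frameOffsets frame offsets from the annotated peak (strictly
#'   increasing from 0).
#' @param radii disc radii in pixels (strictly decreasing).
#' @return a validated list of class `"tubeShape"`.
#' @export
tubeShape <- function(frameOffsets = c(0L, 1L, 2L), radii = c(4, 2, 1)) {
  stopifnot(length(frameOffsets) == length(radii))
  if (frameOffsets[1L] != 0 || any(diff(frameOffsets) <= 0))
    stop("frame offsets must be strictly increasing from 0")
  if (any(diff(radii) >= 0))
    stop("radii must be strictly decreasing")
  structure(list(frameOffsets = as.integer(frameOffsets), radii = radii),
            class = "tubeShape")
}

#' Rasterize one event's tube into voxel coordinates
#'
#' For each (offset k, radius r) of the shape, all pixels whose
#' centre-to-centre Euclidean distance from the event centre is `<= r`
#' (inclusive) are taken on frame `t0 + k`; voxels outside the grid are
#' clipped. Coordinates are 0-based integer pixel centres.
#'
#' @param event numeric `c(x, y, t)`; non-integer coordinates are rounded
#'   to the nearest voxel.
#' @param shape a [tubeShape()].
#' @param gridDims movie dims `c(n_frames, height, width)`.
#' @return integer matrix with columns `t`, `y`, `x` (0-based), one row
#'   per voxel.
#' @examples
#' v <- rasterizeTube(c(20, 20, 50), tubeShape(), c(200, 100, 100))
#' nrow(v)  # 67 = 49 + 13 + 5
#' @export
rasterizeTube <- function(event, shape = tubeShape(), gridDims) {
  x0 <- round(event[1L]); y0 <- round(event[2L]); t0 <- round(event[3L])
  out <- vector("list", length(shape$radii))
  for (i in seq_along(shape$radii)) {
    tt <- t0 + shape$frameOffsets[i]
    if (tt < 0 || tt >= gridDims[1L]) next
    r <- shape$radii[i]
    ri <- floor(r)
    dx <- seq(-ri, ri)
    disc <- expand.grid(dy = dx, dx = dx)
    disc <- disc[disc$dx^2 + disc$dy^2 <= r^2, , drop = FALSE]
    xs <- x0 + disc$dx; ys <- y0 + disc$dy
    ok <- xs >= 0 & xs < gridDims[3L] & ys >= 0 & ys < gridDims[2L]
    if (!any(ok)) next
    out[[i]] <- cbind(t = rep.int(tt, sum(ok)), y = ys[ok], x = xs[ok])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(integer(0), 0, 3,
                                  dimnames = list(NULL, c("t", "y", "x")))
  storage.mode(res) <- "integer"
  res
}

#' Build the 3-class training label map
#'
#' Merges docked-vesicle detections with exocytosis annotations into a
#' voxel class map: label 2 at detector-mask voxels, then label 1
#' overwrites at the rasterized event tubes (exocytosis precedence), all
#' else 0. Construction is idempotent and order-independent over events.
#'
#' @param eventList an [EventList-class]; only class `"exocytosis"` rows
#'   are rasterized.
#' @param atlasMask logical docked-vesicle mask: 3D `(t, y, x)` matching
#'   `gridDims`, 2D `(y, x)` (broadcast over frames), or `NULL` for none.
#' @param gridDims movie dims `c(n_frames, height, width)`.
#' @param shape a [tubeShape()].
#' @return a [LabelMap-class].
#' @export
buildLabelMap <- function(eventList, atlasMask = NULL, gridDims,
                          shape = tubeShape()) {
  lab <- array(0L, dim = gridDims)
  if (!is.null(atlasMask)) {
    if (is.matrix(atlasMask)) {
      if (!all(dim(atlasMask) == gridDims[2:3]))
        stop("2D atlasMask dims must match the movie frame")
      for (tt in seq_len(gridDims[1L]))
        lab[tt, , ][atlasMask] <- 2L
    } else {
      if (!all(dim(atlasMask) == gridDims))
        stop("3D atlasMask dims must match gridDims")
      lab[atlasMask > 0] <- 2L
    }
  }
  ev <- if (is(eventList, "EventList")) events(eventList) else eventList
  ev <- ev[ev$class == "exocytosis", , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    v <- rasterizeTube(c(ev$x[i], ev$y[i], ev$t[i]), shape, gridDims)
    if (nrow(v)) lab[v + 1L] <- 1L
  }
  LabelMap(lab)
}

#' Per-class voxel fractions of a label patch
#'
#' @param x a [LabelMap-class] or integer array/vector of labels.
#' @return named numeric vector of fractions for classes 0, 1, 2
#'   (summing to 1).
#' @export
classFractions <- function(x) {
  l <- if (is(x, "LabelMap")) labels3d(x) else x
  n <- tabulate(as.integer(l) + 1L, nbins = 3L)
  setNames(n / length(l), c("0", "1", "2"))
}
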