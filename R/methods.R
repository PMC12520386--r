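#' Construct a TirfMovie
#'
#' @param data numeric 3D array indexed `(t, y, x)`, or a matrix (taken as a
#'   single frame).
#' @param pixelSize micrometres per pixel.
#' @param frameInterval seconds per frame.
#' @return a validated [TirfMovie-class] object.
#' @examples
#' m <- TirfMovie(array(100, dim = c(5, 32, 64)))
#' dim(movieData(m))  # 5 32 64
#' @export
TirfMovie <- function(data, pixelSize = 0.160, frameInterval = 0.3) {
  if (is.matrix(data))
    data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  storage.mode(data) <- "double"
  new("TirfMovie", data = data, pixelSize = pixelSize,
      frameInterval = frameInterval)
}

#' Construct an EventList
#'
#' @param x,y,t numeric event coordinates (0-based pixel/frame centres).
#'   Alternatively `x` may be a data.frame with columns `x`, `y`, `t` and
#'   optionally `class`, `score`.
#' @param class event class, `"exocytosis"` (default) or `"docked"`;
#'   recycled.
#' @param score optional detector confidence; recycled.
#' @param source free-text provenance tag.
#' @return an [EventList-class].
#' @examples
#' ev <- EventList(x = c(10, 40), y = c(20, 15), t = c(100, 250))
#' nrow(events(ev))  # 2
#' @export
EventList <- function(x = numeric(), y = numeric(), t = numeric(),
                      class = "exocytosis", score = NA_real_, source = "") {
  if (is.data.frame(x)) {
    df <- x
    if (is.null(df$class)) df$class <- rep_len("exocytosis", nrow(df))
    if (is.null(df$score)) df$score <- rep_len(NA_real_, nrow(df))
    need <- c("x", "y", "t", "class", "score")
    df <- df[, c(need, setdiff(names(df), need))]
  } else {
    n <- length(x)
    df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                     t = as.numeric(t),
                     class = rep_len(as.character(class), n),
                     score = rep_len(as.numeric(score), n),
                     stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  new("EventList", events = df, source = source)
}

#' Construct a LabelMap
#'
#' @param labels integer 3D array `(t, y, x)` with values in \{0, 1, 2\}.
#' @return a [LabelMap-class].
#' @export
LabelMap <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels)
}

#' Construct a CellMask
#'
#' @param mask logical `(y, x)` matrix.
#' @return a [CellMask-class].
#' @export
CellMask <- function(mask) {
  storage.mode(mask) <- "logical"
  new("CellMask", mask = mask)
}

#' @rdname TirfMovie-class
#' @export
setMethod("movieData", "TirfMovie", function(x) x@data)

#' @rdname TirfMovie-class
#' @export
setMethod("pixelSize", "TirfMovie", function(x) x@pixelSize)

#' @rdname TirfMovie-class
#' @export
setMethod("frameInterval", "TirfMovie", function(x) x@frameInterval)

#' @rdname TirfMovie-class
#' @export
setMethod("nFrames", "TirfMovie", function(x) dim(x@data)[1L])

#' @rdname TirfMovie-class
#' @export
setMethod("dim", "TirfMovie", function(x) dim(x@data))

#' @rdname EventList-class
#' @export
setMethod("events", "EventList", function(x) x@events)

#' @rdname EventList-class
#' @export
setMethod("eventSource", "EventList", function(x) x@source)

#' @rdname EventList-class
#' @export
setMethod("length", "EventList", function(x) nrow(x@events))

#' @rdname LabelMap-class
#' @export
setMethod("labels3d", "LabelMap", function(x) x@labels)

#' @rdname LabelMap-class
#' @export
setMethod("dim", "LabelMap", function(x) dim(x@labels))

#' @rdname CellMask-class
#' @export
setMethod("maskData", "CellMask", function(x) x@mask)

#' @rdname CellMask-class
#' @export
setMethod("dim", "CellMask", function(x) dim(x@mask))

setMethod("show", "TirfMovie", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "TirfMovie: %d frames of %d x %d px (%.3f um/px, %.3f s/frame)\n",
    d[1L], d[2L], d[3L], object@pixelSize, object@frameInterval))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "EventList", function(object) {
  tab <- table(factor(object@events$class, levels = .EVENT_CLASSES))
  cat(sprintf("EventList: %d events (%d exocytosis, %d docked)%s\n",
              nrow(object@events), tab[["exocytosis"]], tab[["docked"]],
              if (nzchar(object@source))
                sprintf(" [%s]", object@source) else ""))
  if (nrow(object@events) > 0)
    print(head(object@events, 5L))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  n <- tabulate(object@labels + 1L, nbins = 3L)
  cat(sprintf("LabelMap: %d x %d x %d (t, y, x); voxels bg=%d exo=%d docked=%d\n",
              d[1L], d[2L], d[3L], n[1L], n[2L], n[3L]))
})

setMethod("show", "CellMask", function(object) {
  cat(sprintf("CellMask: %d x %d px, %.1f%% inside\n",
              nrow(object@mask), ncol(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "PuffSegmenter", function(object) {
  np <- sum(vapply(object@weights, length, numeric(1)))
  cat(sprintf(
    "PuffSegmenter: depth %d, %d base filters, %d classes, %s parameters\n",
    object@depth, object@baseFilters, object@nClasses,
    format(np, big.mark = ",")))
  if (nrow(object@history) > 0)
    cat(sprintf("  trained %d iterations, final loss %.4f\n",
                max(object@history$iteration),
                object@history$loss[nrow(object@history)]))
})
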