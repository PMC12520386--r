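#' TirfMovie: a 2D+time fluorescence movie
#'
#' Container for a single-channel TIRF time-lapse. Voxels are indexed
#' `(t, y, x)` (frame, row, column), all 1-based inside R; event coordinates
#' throughout the package are 0-based pixel centres, matching the on-disk
#' CSV dialect. Intensities are arbitrary fluorescence units, finite and
#' non-negative.
#'
#' @slot data numeric 3D array, dim `(n_frames, height, width)`.
#' @slot pixelSize micrometres per pixel (default 0.160).
#' @slot frameInterval seconds per frame (default 0.3).
#'
#' @seealso [TirfMovie()], [readMovie()], [writeMovie()]
#' @export
setClass("TirfMovie",
  representation(data = "array", pixelSize = "numeric",
                 frameInterval = "numeric"),
  prototype(pixelSize = 0.160, frameInterval = 0.3))

setValidity("TirfMovie", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must be a 3D array (t, y, x)")
  if (dim(d)[1L] < 1L)
    return("movie must have at least one frame")
  if (!all(is.finite(d)))
    return("intensities must all be finite")
  if (any(d < 0))
    return("intensities must be non-negative")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  TRUE
})

#' EventList: point annotations of membrane events
#'
#' An ordered collection of point events, each an `(x, y, t)` coordinate
#' with a class label (`"exocytosis"` or `"docked"`) and an optional
#' detector score. Coordinates are 0-based pixel/frame centres; continuous
#' values are allowed (sub-voxel centroids of predictions). Used both for
#' ground truth and for predictions.
#'
#' @slot events data.frame with columns `x`, `y`, `t`, `class`, `score`.
#' @slot source free-text provenance tag.
#'
#' @seealso [EventList()], [readEvents()], [writeEvents()]
#' @export
setClass("EventList",
  representation(events = "data.frame", source = "character"),
  prototype(source = ""))

.EVENT_CLASSES <- c("exocytosis", "docked")

setValidity("EventList", function(object) {
  ev <- object@events
  need <- c("x", "y", "t", "class", "score")
  if (!all(need %in% names(ev)))
    return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
  if (nrow(ev) > 0) {
    if (!is.numeric(ev$x) || !is.numeric(ev$y) || !is.numeric(ev$t))
      return("x, y, t must be numeric")
    if (anyNA(ev$x) || anyNA(ev$y) || anyNA(ev$t))
      return("coordinates must not contain NA")
    if (!all(ev$class %in% .EVENT_CLASSES))
      return("class must be 'exocytosis' or 'docked'")
  }
  TRUE
})

#' LabelMap: voxel-wise class map of a movie
#'
#' Integer 3D grid with the same `(t, y, x)` shape as the movie it
#' annotates. Values: 0 background, 1 exocytosis event, 2 docked vesicle.
#'
#' @slot labels integer 3D array with values in \{0, 1, 2\}.
#'
#' @seealso [buildLabelMap()], [readLabelMap()], [writeLabelMap()]
#' @export
setClass("LabelMap", representation(labels = "array"))

setValidity("LabelMap", function(object) {
  l <- object@labels
  if (length(dim(l)) != 3L)
    return("labels must be a 3D array (t, y, x)")
  if (!all(l %in% 0:2))
    return("label values must be in {0, 1, 2}")
  TRUE
})

#' CellMask: binary footprint of the cell
#'
#' Logical `(y, x)` matrix matching one movie frame; TRUE inside the cell.
#'
#' @slot mask logical matrix, dim `(height, width)`.
#'
#' @seealso [makeCellMask()], [readCellMask()], [writeCellMask()]
#' @export
setClass("CellMask", representation(mask = "matrix"))

setValidity("CellMask", function(object) {
  if (!is.logical(object@mask))
    return("mask must be logical")
  if (length(dim(object@mask)) != 2L)
    return("mask must be a 2D matrix (y, x)")
  TRUE
})

#' PuffSegmenter: the anisotropic 3-class segmentation network
#'
#' A 3D U-Net-style encoder--decoder whose max-pooling acts only on the
#' spatial `(x, y)` plane, so the temporal axis keeps full resolution (an
#' exocytosis event typically lasts only 2--3 frames). Convolutions are
#' 3x3x3; per-voxel class scores are softmax-normalised over the 3 classes.
#'
#' @slot weights list of convolution weight matrices and bias vectors.
#' @slot depth number of (x, y) pooling stages.
#' @slot baseFilters channel width of the first encoder block.
#' @slot nClasses number of output classes (3).
#' @slot history data.frame loss log of the most recent training.
#'
#' @seealso [initSegmenter()], [trainSegmenter()], [predictLabelMap()]
#' @export
setClass("PuffSegmenter",
  representation(weights = "list", depth = "numeric", baseFilters = "numeric",
                 nClasses = "numeric", history = "data.frame"),
  prototype(depth = 2, baseFilters = 8, nClasses = 3,
            history = data.frame()))

setValidity("PuffSegmenter", function(object) {
  if (object@depth < 1 || object@depth != round(object@depth))
    return("depth must be a positive integer")
  if (object@nClasses < 2)
    return("nClasses must be >= 2")
  TRUE
})
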