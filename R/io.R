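#' Read a TIRF movie from a multipage TIFF stack
#'
#' Reads a grayscale multipage TIFF into a [TirfMovie-class] with `(t, y, x)`
#' axis order. If a JSON sidecar `<path>.json` (written by [writeMovie()])
#' is present, pixel size, frame interval and the intensity scale of
#' float-valued stacks are restored from it; otherwise defaults apply.
#'
#' @param path TIFF file path.
#' @param pixelSize,frameInterval metadata defaults used when no sidecar is
#'   found.
#' @return a [TirfMovie-class].
#' @seealso [writeMovie()]
#' @export
readMovie <- function(path, pixelSize = 0.160, frameInterval = 0.3) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  meta <- .readSidecar(path)
  if (!is.null(meta$pixel_size_um)) pixelSize <- meta$pixel_size_um
  if (!is.null(meta$frame_interval_s)) frameInterval <- meta$frame_interval_s
  fixed <- identical(meta$storage, "fixed32")
  # fixed-point pages must be read back on the [0,1) scale; integer pages
  # as raw sample values
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !fixed)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("zero frames in ", path)
  if (length(dim(pages[[1L]])) != 2L)
    stop("non-grayscale input: expected single-channel pages")
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  data <- array(0, dim = c(length(pages), h, w))
  for (i in seq_along(pages)) data[i, , ] <- pages[[i]]
  if (fixed) data <- data * meta$scale
  TirfMovie(data, pixelSize = pixelSize, frameInterval = frameInterval)
}

#' Write a TIRF movie as a multipage TIFF stack
#'
#' Integer-valued movies (all values whole numbers in \[0, 65535\]) are
#' stored as 16-bit pages and roundtrip bit-exactly. Continuous movies are
#' stored as max-scaled 32-bit fixed point (relative precision about
#' 2^-32); the scale goes to the JSON sidecar together with pixel size and
#' frame interval.
#'
#' @param movie a [TirfMovie-class].
#' @param path output TIFF path; a sidecar `<path>.json` is written beside
#'   it.
#' @return `path`, invisibly.
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "TirfMovie"))
  d <- movieData(movie)
  isInt <- all(d == round(d)) && max(d) <= 65535
  meta <- list(pixel_size_um = pixelSize(movie),
               frame_interval_s = frameInterval(movie))
  if (isInt) {
    pages <- lapply(seq_len(dim(d)[1L]), function(i) d[i, , ] / 65535)
    .tryWrite(path, pages, 16L)
    meta$storage <- "uint16"
  } else {
    scale <- max(d) * (1 + 1e-9)  # keep values strictly below 1
    pages <- lapply(seq_len(dim(d)[1L]), function(i) d[i, , ] / scale)
    .tryWrite(path, pages, 32L)
    meta$storage <- "fixed32"
    meta$scale <- scale
  }
  .writeSidecar(path, meta)
  invisible(path)
}

.tryWrite <- function(path, pages, bits) {
  ok <- tryCatch({
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = bits))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write TIFF at ", path)
}

.sidecarPath <- function(path) paste0(path, ".json")

.writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
}

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
  else list()
}

#' Read an event list from CSV
#'
#' Expects a header `x,y,frame` with optional `class` and `score` columns;
#' coordinates are 0-based. Missing class defaults to `"exocytosis"`.
#'
#' @param path CSV path.
#' @param source provenance tag stored on the result (defaults to the file
#'   name).
#' @return an [EventList-class].
#' @export
readEvents <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("event file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "frame")
  if (!all(need %in% names(df)))
    stop("event CSV must have columns x,y,frame")
  if (nrow(df) > 0 && (!is.numeric(df$x) || !is.numeric(df$y) ||
                       !is.numeric(df$frame)))
    stop("non-numeric coordinates in ", path)
  out <- data.frame(x = as.numeric(df$x), y = as.numeric(df$y),
                    t = as.numeric(df$frame),
                    class = if ("class" %in% names(df)) df$class
                            else rep("exocytosis", nrow(df)),
                    score = if ("score" %in% names(df)) as.numeric(df$score)
                            else rep(NA_real_, nrow(df)),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    out <- out[0, , drop = FALSE]
  EventList(out, source = source)
}

#' Write an event list to CSV
#'
#' Column order is fixed as `x,y,frame,class,score` (score column omitted
#' when entirely missing), 0-based coordinates.
#'
#' @param eventList an [EventList-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(eventList, path) {
  stopifnot(is(eventList, "EventList"))
  ev <- events(eventList)
  out <- data.frame(x = ev$x, y = ev$y, frame = ev$t, class = ev$class,
                    stringsAsFactors = FALSE)
  if (!all(is.na(ev$score))) out$score <- ev$score
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write voxel label maps
#'
#' Label maps are stored as 8-bit multipage TIFF stacks holding the raw
#' class values \{0, 1, 2\}.
#'
#' @param path TIFF path.
#' @return [readLabelMap()]: a [LabelMap-class]; [writeLabelMap()]: `path`,
#'   invisibly.
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path)) stop("label map not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  l <- array(0L, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (i in seq_along(pages)) l[i, , ] <- pages[[i]]
  LabelMap(l)
}

#' @rdname readLabelMap
#' @param labelMap a [LabelMap-class].
#' @export
writeLabelMap <- function(labelMap, path) {
  stopifnot(is(labelMap, "LabelMap"))
  l <- labels3d(labelMap)
  if (!all(l %in% 0:2)) stop("label value outside {0,1,2}")
  pages <- lapply(seq_len(dim(l)[1L]), function(i) l[i, , ] / 255)
  .tryWrite(path, pages, 8L)
  invisible(path)
}

#' Read / write binary cell masks
#'
#' Masks are stored as single-page 8-bit TIFF images (0 outside, 255
#' inside).
#'
#' @param path TIFF path.
#' @return [readCellMask()]: a [CellMask-class]; [writeCellMask()]: `path`,
#'   invisibly.
#' @export
readCellMask <- function(path) {
  if (!file.exists(path)) stop("mask not found: ", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2L) stop("mask must be single-channel")
  CellMask(m > 0)
}

#' @rdname readCellMask
#' @param cellMask a [CellMask-class].
#' @export
writeCellMask <- function(cellMask, path) {
  stopifnot(is(cellMask, "CellMask"))
  .tryWrite(path, list(ifelse(maskData(cellMask), 255, 0) / 255), 8L)
  invisible(path)
}
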