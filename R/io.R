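#' @include utils.R
NULL

## ---------------------------------------------------------------------------
## TIFF stack / movie I/O
##
## Stacks and movies are stored as plain multi-page 16-bit TIFF. Pages of a
## multichannel stack are grouped either channel-major (all planes of channel
## 1, then channel 2, ...; the writer's layout) or plane-major (all channels
## of plane 1, then plane 2, ...). Intensities are written as integers in
## [0, 65535]; non-integer intensities are rounded on writing, so integer
## grids round-trip exactly.
## ---------------------------------------------------------------------------

.readPages <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("cannot read '", path, "' as TIFF: ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # collapse RGB-coded pages
    storage.mode(p) <- "double"
    p
  })
}

.writePages <- function(pages, path) {
  mx <- max(vapply(pages, max, 0), 0)
  if (mx > 65535)
    stop("intensities exceed the 16-bit range (max ", mx, "); rescale first")
  scaled <- lapply(pages, function(p) round(p) / 65535)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multichannel image stack from TIFF
#'
#' Reads a multi-page TIFF into an [ImageStack], assigning the given channel
#' names. The page sequence must factor into `length(channelNames)` equally
#' sized channel blocks: `pageOrder = "channel"` (default, and what
#' [writeStack()] produces) expects all planes of the first channel followed
#' by all planes of the second, corresponding to a `(channel, plane, row,
#' col)` axis layout; `pageOrder = "plane"` expects channels interleaved per
#' plane, i.e. `(plane, channel, row, col)`. A single-page 2D file is
#' promoted to one plane.
#'
#' @param path TIFF file path.
#' @param channelNames ordered character vector of channel names; its length
#'   must divide the page count exactly.
#' @param pageOrder `"channel"` or `"plane"` (see above).
#' @param voxelSize,metadata passed to [ImageStack()].
#' @return An [ImageStack].
#' @seealso [writeStack()], [readMovie()]
#' @examples
#' f <- tempfile(fileext = ".tif")
#' s <- ImageStack(list(Cy3 = array(5, c(2, 8, 8)), Cy5 = array(9, c(2, 8, 8))))
#' writeStack(s, f)
#' s2 <- readStack(f, c("Cy3", "Cy5"))
#' @export
readStack <- function(path, channelNames, pageOrder = c("channel", "plane"),
                      voxelSize = c(300, 120, 120), metadata = list()) {
  pageOrder <- match.arg(pageOrder)
  pages <- .readPages(path)
  nc <- length(channelNames)
  if (nc < 1L) stop("at least one channel name is required")
  if (length(pages) %% nc != 0L)
    stop("channel-count mismatch: ", length(pages),
         " page(s) cannot be split into ", nc, " channel(s) ('",
         paste(channelNames, collapse = "', '"), "')")
  np <- length(pages) %/% nc
  d <- dim(pages[[1L]])
  chans <- vector("list", nc)
  names(chans) <- channelNames
  for (ci in seq_len(nc)) {
    a <- array(0, c(np, d[1L], d[2L]))
    for (pi in seq_len(np)) {
      page <- if (pageOrder == "channel") (ci - 1L) * np + pi
              else (pi - 1L) * nc + ci
      a[pi, , ] <- pages[[page]]
    }
    chans[[ci]] <- a
  }
  metadata$sourceFile <- path
  ImageStack(chans, voxelSize = voxelSize, metadata = metadata)
}

#' Write an image stack to multi-page TIFF
#'
#' Pages are written channel-major (all planes of channel 1, then channel 2,
#' ...), as expected by [readStack()] with `pageOrder = "channel"`.
#' Intensities must lie in `[0, 65535]`; integer intensities round-trip
#' exactly, non-integers are rounded.
#'
#' @param stack an [ImageStack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  pages <- list()
  for (nm in channelNames(stack)) {
    a <- getChannel(stack, nm)
    for (p in seq_len(dim(a)[1L])) pages[[length(pages) + 1L]] <- a[p, , ]
  }
  .writePages(pages, path)
}

#' Read / write a TIRF movie as multi-page TIFF
#'
#' One page per time frame. The same 16-bit integer round-trip contract as
#' [writeStack()] applies.
#'
#' @param path TIFF file path.
#' @param frameInterval minutes between frames.
#' @param pixelSize pixel size in nm.
#' @return [readMovie()]: a [TirfMovie]; [writeMovie()]: `path`, invisibly.
#' @export
readMovie <- function(path, frameInterval = 2, pixelSize = 120) {
  TirfMovie(.readPages(path), frameInterval = frameInterval,
            pixelSize = pixelSize)
}

#' @rdname readMovie
#' @param movie a [TirfMovie].
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "TirfMovie"))
  .writePages(frames(movie), path)
}

## ---------------------------------------------------------------------------
## Background subtraction
## ---------------------------------------------------------------------------

#' Subtract background from every channel of a stack
#'
#' Applies a per-channel offset and clamps negative results to zero (mask
#' intensity sums must stay non-negative). Three offset rules:
#' * `"modal"` (default): the modal intensity of the channel's first plane —
#'   the typical off-cell background level;
#' * `"constant"`: the provided `value` (>= 0) for every channel;
#' * `"percentile"`: the channel's `value`-th intensity percentile, `value`
#'   in `(0, 50]`.
#'
#' The offsets used are recorded in `stackMetadata(stack)$backgroundOffsets`.
#'
#' @param stack an [ImageStack].
#' @param mode offset rule (see above).
#' @param value offset (for `"constant"`) or percentile in `(0, 50]`
#'   (for `"percentile"`); ignored for `"modal"`.
#' @return A background-subtracted [ImageStack].
#' @examples
#' s <- ImageStack(list(Cy3 = array(c(0, 10, 25), c(1, 1, 3))))
#' getChannel(subtractBackground(s, "constant", 10), "Cy3")
#' @export
subtractBackground <- function(stack, mode = c("modal", "constant",
                                               "percentile"), value = NULL) {
  stopifnot(is(stack, "ImageStack"))
  mode <- match.arg(mode)
  if (mode == "constant")
    .assertScalar(value, "value", lower = 0)
  if (mode == "percentile") {
    .assertScalar(value, "value")
    if (value <= 0 || value > 50)
      stop("'value' must be a percentile in (0, 50]")
  }
  chans <- stack@channels
  offsets <- numeric(length(chans))
  names(offsets) <- names(chans)
  for (nm in names(chans)) {
    g <- chans[[nm]]
    offset <- switch(mode,
      modal = .modalIntensity(g[1L, , ]),
      constant = value,
      percentile = as.numeric(stats::quantile(g, value / 100)))
    chans[[nm]] <- pmax(g - offset, 0)
    offsets[nm] <- offset
  }
  md <- stack@metadata
  md$backgroundOffsets <- offsets
  ImageStack(chans, voxelSize = stack@voxelSize, metadata = md)
}

## ---------------------------------------------------------------------------
## Result tables
## ---------------------------------------------------------------------------

#' Build, write and read result tables
#'
#' A result table holds one row per (image id, metric) with the condition
#' label, metric value and any auxiliary columns — the tabular output format
#' shared by all assay modules. `writeResultTable()` serializes numeric
#' columns with 17 significant digits so that `readResultTable()` reloads
#' values losslessly.
#'
#' @param imageId,condition,metric,value vectors (recycled to a common
#'   length).
#' @param ... auxiliary columns (for `resultTable()`) or further arguments.
#' @return `resultTable()`/`readResultTable()`: a data.frame;
#'   `writeResultTable()`: `path`, invisibly.
#' @examples
#' tab <- resultTable("img1", "vehicle", "cy3cy5_ratio", 0.42)
#' f <- tempfile(fileext = ".csv")
#' writeResultTable(tab, f)
#' identical(readResultTable(f)$value, tab$value)
#' @export
resultTable <- function(imageId, condition, metric, value, ...) {
  tab <- data.frame(imageId = imageId, condition = condition, metric = metric,
                    value = as.numeric(value), ...,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab[, c("imageId", "metric")]))
    stop("duplicate (imageId, metric) rows are not allowed")
  if (any(!is.finite(tab$value))) stop("metric values must be finite")
  tab
}

#' @rdname resultTable
#' @param tab a data.frame as produced by `resultTable()`.
#' @param path CSV file path.
#' @export
writeResultTable <- function(tab, path) {
  out <- tab
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname resultTable
#' @export
readResultTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("value" %in% names(tab)) tab$value <- as.numeric(tab$value)
  tab
}
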