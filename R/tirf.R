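#' @include fret.R
NULL

## Difference-of-Gaussians band-pass with the standard 1.6 sigma ratio.
.dogFilter <- function(frame, spotSigma) {
  .gaussianBlur2d(frame, spotSigma) - .gaussianBlur2d(frame, 1.6 * spotSigma)
}

#' Detect diffraction-limited spots in a single frame
#'
#' Spots are local maxima of the difference-of-Gaussians band-passed frame
#' above a threshold, pruned greedily so that no two accepted spots are
#' closer than `minSeparation` pixels (the brighter spot wins; exact
#' intensity ties are resolved by row-major position order). Positions are
#' refined by an intensity-weighted centroid of the non-negative band-passed
#' image in a `(2 * minSeparation + 1)^2` window.
#'
#' `threshold = "auto"` uses `median + 7 * mad` of the band-passed frame — a
#' robust noise-floor estimate that adapts to the acquisition; diffraction-
#' limited spots occupy a small area, so the median and mad are dominated by
#' the background.
#'
#' @param frame 2D numeric matrix.
#' @param threshold scalar on the band-passed intensity scale, or `"auto"`.
#' @param minSeparation minimum spot separation in px (>= 1).
#' @param spotSigma expected spot sigma in px (sets the band-pass scales).
#' @return data.frame with one spot per row: `row`, `col` (sub-pixel,
#'   1-based) and `intensity` (band-passed peak height).
#' @examples
#' fr <- matrix(0, 32, 32); fr[16, 20] <- 100
#' detectSpots(fr, threshold = 1)
#' @export
detectSpots <- function(frame, threshold = "auto", minSeparation = 3L,
                        spotSigma = 1.2) {
  if (!is.matrix(frame)) stop("'frame' must be a 2D matrix")
  if (minSeparation < 1) stop("'minSeparation' must be >= 1")
  dog <- .dogFilter(frame, spotSigma)
  if (identical(threshold, "auto"))
    threshold <- stats::median(dog) + 7 * stats::mad(dog)
  nr <- nrow(dog); nc <- ncol(dog)
  if (nr < 3L || nc < 3L)
    return(data.frame(row = numeric(0), col = numeric(0),
                      intensity = numeric(0)))
  ## strict interior local maxima (>= all 8 neighbours) above threshold
  core <- dog[2:(nr - 1L), 2:(nc - 1L)]
  isMax <- core > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    isMax <- isMax & core >= dog[2:(nr - 1L) + dr, 2:(nc - 1L) + dc]
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = numeric(0), col = numeric(0),
                      intensity = numeric(0)))
  peaks <- data.frame(row = idx[, 1L] + 1L, col = idx[, 2L] + 1L)
  peaks$intensity <- dog[cbind(peaks$row, peaks$col)]
  ## greedy pruning: brighter first, row-major for exact ties
  ord <- order(-peaks$intensity, peaks$row, peaks$col)
  peaks <- peaks[ord, , drop = FALSE]
  keep <- logical(nrow(peaks))
  accR <- numeric(0); accC <- numeric(0)
  for (i in seq_len(nrow(peaks))) {
    if (length(accR) == 0L ||
        min((accR - peaks$row[i])^2 + (accC - peaks$col[i])^2) >=
          minSeparation^2) {
      keep[i] <- TRUE
      accR <- c(accR, peaks$row[i]); accC <- c(accC, peaks$col[i])
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  ## centroid refinement on the clamped band-passed image
  dogPos <- pmax(dog, 0)
  w <- as.integer(minSeparation)
  for (i in seq_len(nrow(peaks))) {
    r0 <- peaks$row[i]; c0 <- peaks$col[i]
    ir <- max(1L, r0 - w):min(nr, r0 + w)
    ic <- max(1L, c0 - w):min(nc, c0 + w)
    win <- dogPos[ir, ic, drop = FALSE]
    s <- sum(win)
    if (s > 0) {
      peaks$row[i] <- sum(rowSums(win) * ir) / s
      peaks$col[i] <- sum(colSums(win) * ic) / s
    }
  }
  rownames(peaks) <- NULL
  peaks
}

#' Per-frame spot counts and percent-of-maximum timecourse
#'
#' Runs [detectSpots()] on every frame and reports the counts and the counts
#' as a percentage of the per-movie maximum (the normalization used for
#' nanocluster-formation timecourses). If no frame contains a spot, the
#' percentages are all zero.
#'
#' @param movie a [TirfMovie].
#' @param threshold,minSeparation,spotSigma passed to [detectSpots()].
#' @return A [ClusterTimecourse] (with `persistentFraction = NA`; see
#'   [classifyPersistence()]).
#' @examples
#' sim <- simulateTirfMovie(nFrames = 5, nSpots = 8, seed = 1)
#' spotCounts(countTimecourse(sim$movie))
#' @export
countTimecourse <- function(movie, threshold = "auto", minSeparation = 3L,
                            spotSigma = 1.2) {
  stopifnot(is(movie, "TirfMovie"))
  counts <- vapply(frames(movie), function(f)
    nrow(detectSpots(f, threshold, minSeparation, spotSigma)), 0L)
  pom <- if (any(counts > 0L)) counts * 100 / max(counts) else counts * 0
  new("ClusterTimecourse", counts = counts, percentOfMax = as.numeric(pom),
      persistentFraction = NA_real_)
}

#' Link per-frame spots into tracks
#'
#' Frame-to-frame linking by optimal bipartite assignment ([solveAssignment()])
#' minimizing total squared displacement among pairings within the
#' displacement gate; unmatched spots start new tracks. A track that misses
#' up to `maxGap` consecutive frames remains eligible for linking (gap
#' bridging), with the gate scaled by the number of elapsed frames.
#'
#' @param spotFrames list of per-frame spot data.frames as returned by
#'   [detectSpots()] (columns `row`, `col`, `intensity`).
#' @param maxDisplacement maximum per-frame displacement in px (> 0).
#' @param maxGap maximum number of bridged missing frames (>= 0, default 1).
#' @return List of tracks; each track is a data.frame with columns `frame`
#'   (1-based), `row`, `col`, `intensity`, frames strictly increasing.
#'   Every input spot belongs to exactly one track.
#' @examples
#' fr <- lapply(1:4, function(t)
#'   data.frame(row = c(10, 30), col = c(10 + t, 30), intensity = 1))
#' length(linkTracks(fr, maxDisplacement = 3))
#' @export
linkTracks <- function(spotFrames, maxDisplacement, maxGap = 1L) {
  .assertScalar(maxDisplacement, "maxDisplacement", 0, Inf, strict = TRUE)
  if (maxGap < 0L) stop("'maxGap' must be >= 0")
  tracks <- list()          # each: list(rows = data.frame, lastFrame, lastPos)
  BIG <- 1e12
  for (t in seq_along(spotFrames)) {
    spots <- spotFrames[[t]]
    ns <- if (is.null(spots)) 0L else nrow(spots)
    active <- which(vapply(tracks, function(tr)
      tr$lastFrame < t & tr$lastFrame >= t - 1L - maxGap, TRUE))
    assignedSpot <- rep(NA_integer_, ns)
    if (ns > 0L && length(active) > 0L) {
      cost <- matrix(BIG, length(active), ns)
      for (ai in seq_along(active)) {
        tr <- tracks[[active[ai]]]
        gate <- maxDisplacement * (t - tr$lastFrame)
        d2 <- (spots$row - tr$lastPos[1L])^2 + (spots$col - tr$lastPos[2L])^2
        ok <- d2 <= gate^2
        cost[ai, ok] <- d2[ok]
      }
      nA <- length(active)
      sq <- max(nA, ns)
      padded <- matrix(BIG, sq, sq)
      padded[seq_len(nA), seq_len(ns)] <- cost
      sol <- solveAssignment(padded)
      for (ai in seq_len(nA)) {
        j <- sol[ai]
        if (!is.na(j) && j <= ns && padded[ai, j] < BIG)
          assignedSpot[j] <- active[ai]
      }
    }
    if (ns > 0L) for (j in seq_len(ns)) {
      rec <- data.frame(frame = t, row = spots$row[j], col = spots$col[j],
                        intensity = spots$intensity[j])
      if (is.na(assignedSpot[j])) {
        tracks[[length(tracks) + 1L]] <-
          list(rows = rec, lastFrame = t, lastPos = c(spots$row[j],
                                                      spots$col[j]))
      } else {
        k <- assignedSpot[j]
        tracks[[k]]$rows <- rbind(tracks[[k]]$rows, rec)
        tracks[[k]]$lastFrame <- t
        tracks[[k]]$lastPos <- c(spots$row[j], spots$col[j])
      }
    }
  }
  lapply(tracks, `[[`, "rows")
}

#' Fraction of persistent tracks
#'
#' A track is persistent when its duration `(last frame - first frame) *
#' frameInterval` reaches `minPersistentDuration` minutes (persistence is
#' operationalized purely by duration). Returns the persistent share of all
#' tracks.
#'
#' @param tracks list of track data.frames from [linkTracks()].
#' @param frameInterval minutes per frame.
#' @param minPersistentDuration persistence cutoff in minutes (e.g. 60 for
#'   "persisted for more than 1 hr"); must not exceed the movie duration.
#' @param movieDuration total movie duration in minutes (for the cutoff
#'   sanity check); optional.
#' @return Scalar fraction in `[0, 1]`.
#' @examples
#' tr <- list(data.frame(frame = 1:31, row = 1, col = 1, intensity = 1))
#' classifyPersistence(tr, frameInterval = 2, minPersistentDuration = 60)
#' @export
classifyPersistence <- function(tracks, frameInterval,
                                minPersistentDuration,
                                movieDuration = NULL) {
  if (length(tracks) == 0L)
    stop("degenerate input: no tracks to classify")
  if (!is.null(movieDuration) && minPersistentDuration > movieDuration)
    stop("'minPersistentDuration' exceeds the movie duration")
  durations <- vapply(tracks, function(tr)
    (max(tr$frame) - min(tr$frame)) * frameInterval, 0)
  mean(durations >= minPersistentDuration)
}

#' Extract a kymograph along a line
#'
#' Builds the space--time image of a line scan: each column is one frame,
#' each row one sample position along the line (unit-pixel spacing,
#' bilinear interpolation), taking the maximum intensity across `width`
#' perpendicular offsets centered on the line.
#'
#' @param movie a [TirfMovie].
#' @param start,end line endpoints `c(row, col)` inside the frame.
#' @param width perpendicular averaging width in px (>= 1).
#' @return Matrix of size (rounded line length + 1) x nFrames.
#' @examples
#' sim <- simulateTirfMovie(nFrames = 5, nSpots = 3, seed = 1)
#' k <- kymograph(sim$movie, c(10, 10), c(10, 80))
#' dim(k)
#' @export
kymograph <- function(movie, start, end, width = 1L) {
  stopifnot(is(movie, "TirfMovie"))
  if (width < 1L) stop("'width' must be >= 1")
  d <- dim(frames(movie)[[1L]])
  for (p in list(start, end))
    if (p[1L] < 1 || p[1L] > d[1L] || p[2L] < 1 || p[2L] > d[2L])
      stop("line endpoints must lie inside the frame")
  v <- c(end[1L] - start[1L], end[2L] - start[2L])
  len <- sqrt(sum(v^2))
  if (len == 0) stop("degenerate zero-length line")
  u <- v / len
  perp <- c(-u[2L], u[1L])
  nSamp <- round(len) + 1L
  ts <- seq(0, len, length.out = nSamp)
  offs <- seq_len(width) - (width + 1) / 2
  bilinear <- function(fr, r, c) {
    r <- min(max(r, 1), d[1L]); c <- min(max(c, 1), d[2L])
    r0 <- floor(r); c0 <- floor(c)
    r1 <- min(r0 + 1L, d[1L]); c1 <- min(c0 + 1L, d[2L])
    fr <- unname(fr)
    wr <- r - r0; wc <- c - c0
    (1 - wr) * ((1 - wc) * fr[r0, c0] + wc * fr[r0, c1]) +
      wr * ((1 - wc) * fr[r1, c0] + wc * fr[r1, c1])
  }
  out <- matrix(0, nSamp, nFrames(movie))
  for (t in seq_len(nFrames(movie))) {
    fr <- frames(movie)[[t]]
    for (i in seq_len(nSamp)) {
      pt <- c(start[1L] + ts[i] * u[1L], start[2L] + ts[i] * u[2L])
      vals <- vapply(offs, function(o)
        bilinear(fr, pt[1L] + o * perp[1L], pt[2L] + o * perp[2L]), 0)
      out[i, t] <- max(vals)
    }
  }
  out
}
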