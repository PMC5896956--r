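# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately use plain per-voxel loops / exhaustive search rather
# than any code path of the package under test.

# Four-mask arithmetic by explicit per-voxel iteration.
bruteForceQuartet <- function(cy5, cy3, cy5Threshold, cy3Threshold) {
  d <- dim(cy5)
  m1 <- array(FALSE, d); m2 <- array(FALSE, d)
  m3 <- array(FALSE, d); m4 <- array(FALSE, d)
  for (p in seq_len(d[1L])) for (r in seq_len(d[2L])) for (cl in seq_len(d[3L])) {
    in1 <- cy5[p, r, cl] >= cy5Threshold
    in2 <- cy3[p, r, cl] >= cy3Threshold
    m1[p, r, cl] <- in1
    m2[p, r, cl] <- in2
    m3[p, r, cl] <- in1 && in2
    m4[p, r, cl] <- in2 && !(in1 && in2)
  }
  list(mask1 = m1, mask2 = m2, mask3 = m3, mask4 = m4)
}

# Colocalized fraction / uptake by explicit per-voxel iteration
# (no object-size filtering).
bruteForceColoc <- function(a, b, thresholdA, thresholdB) {
  d <- dim(a)
  num <- 0; den <- 0; uptake <- 0
  for (p in seq_len(d[1L])) for (r in seq_len(d[2L])) for (cl in seq_len(d[3L])) {
    inA <- a[p, r, cl] >= thresholdA
    inB <- b[p, r, cl] >= thresholdB
    if (inA) den <- den + a[p, r, cl]
    if (inA && inB) num <- num + a[p, r, cl]
    if (inB) uptake <- uptake + b[p, r, cl]
  }
  list(fraction = num / den, uptake = uptake)
}

# Exhaustive-search Otsu: evaluate the between-class variance of every
# candidate bin edge directly on the raw nonzero values.
bruteForceOtsu <- function(x, nBins = 256L) {
  v <- as.vector(x); v <- v[is.finite(v) & v != 0]
  edges <- seq(min(v), max(v), length.out = nBins + 1L)
  best <- -Inf; bestEdge <- edges[2L]
  for (e in edges[2:nBins]) {
    lo <- v[v < e]; hi <- v[v >= e]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; bestEdge <- e }
  }
  bestEdge
}

# Exhaustive minimum-cost assignment over all permutations (n <= 6).
bruteForceAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    tot <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (tot < best) best <- tot
  }
  best
}

# Greedy nearest-pair matching of detections to truth positions within a
# radius; with spot spacings well above the radius this is the optimal
# matching. Returns counts for recall/precision.
matchSpots <- function(detected, truth, radius = 2) {
  if (nrow(detected) == 0L || nrow(truth) == 0L)
    return(list(matched = 0L, nDetected = nrow(detected),
                nTruth = nrow(truth)))
  d2 <- outer(detected$row, truth[, 1L], `-`)^2 +
        outer(detected$col, truth[, 2L], `-`)^2
  matched <- 0L
  repeat {
    i <- which(d2 == min(d2), arr.ind = TRUE)[1L, ]
    if (d2[i[1L], i[2L]] > radius^2) break
    matched <- matched + 1L
    d2[i[1L], ] <- Inf
    d2[, i[2L]] <- Inf
    if (all(!is.finite(d2))) break
  }
  list(matched = matched, nDetected = nrow(detected), nTruth = nrow(truth))
}

# Random small stack fixture shared by mask-arithmetic tests.
randomSmallStack <- function(maxDims = c(4L, 16L, 16L)) {
  d <- c(sample(seq_len(maxDims[1L]), 1L),
         sample(4:maxDims[2L], 1L),
         sample(4:maxDims[3L], 1L))
  list(cy5 = array(as.double(sample(0:20, prod(d), TRUE)), d),
       cy3 = array(as.double(sample(0:20, prod(d), TRUE)), d),
       dims = d)
}
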