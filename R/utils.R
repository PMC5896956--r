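#' @include AllClasses.R
NULL

## Internal numerics shared across modules: finite-support separable Gaussian
## convolution (the kernel is renormalized so that blurring conserves total
## intensity exactly when the signal support stays >= 4 sigma from the array
## edge), modal/Otsu threshold estimation, and 3D connected components.

.gaussKernel <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  x <- seq(-radius, radius)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

## Convolve a 3D array along one axis with a symmetric kernel, zero padding.
.convAxis3d <- function(a, w, axis) {
  r <- (length(w) - 1L) %/% 2L
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  full <- lapply(d, seq_len)
  for (k in seq_along(w)) {
    s <- k - r - 1L          # shift applied to the source index
    i1 <- max(1L, 1L - s)
    i2 <- min(n, n - s)
    if (i1 > i2) next
    io <- i1:i2
    ia <- io + s
    indO <- full; indO[[axis]] <- io
    indA <- full; indA[[axis]] <- ia
    sub <- do.call(`[`, c(list(a), indA, list(drop = FALSE)))
    cur <- do.call(`[`, c(list(out), indO, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), indO, list(cur + w[k] * sub)))
  }
  out
}

## Isotropic-in-plane Gaussian blur of a (plane, row, col) array; axial sigma
## may differ (voxel units). sigma = 0 along an axis skips that axis.
.gaussianBlur3d <- function(a, sigmaXY, sigmaZ = sigmaXY) {
  if (sigmaZ > 0 && dim(a)[1L] > 1L)
    a <- .convAxis3d(a, .gaussKernel(sigmaZ), 1L)
  if (sigmaXY > 0) {
    a <- .convAxis3d(a, .gaussKernel(sigmaXY), 2L)
    a <- .convAxis3d(a, .gaussKernel(sigmaXY), 3L)
  }
  a
}

.gaussianBlur2d <- function(m, sigma) {
  a <- array(m, c(1L, nrow(m), ncol(m)))
  a <- .gaussianBlur3d(a, sigmaXY = sigma, sigmaZ = 0)
  matrix(a, nrow(m), ncol(m))
}

## Modal intensity of a vector (default background estimate): the most
## frequent rounded intensity value.
.modalIntensity <- function(x) {
  tb <- table(round(as.vector(x)))
  as.numeric(names(tb)[which.max(tb)])
}

#' Otsu threshold from the nonzero-voxel histogram
#'
#' Computes the between-class-variance-maximizing threshold over a 256-bin
#' histogram of the nonzero voxel intensities. The returned value is the lower
#' edge of the first foreground bin, so that segmenting with
#' `intensity >= threshold` reproduces the optimal class split.
#'
#' @param x numeric vector or array of intensities.
#' @param nBins number of histogram bins (default 256).
#' @return The threshold (scalar).
#' @examples
#' otsuThreshold(c(rnorm(300, 10), rnorm(300, 100)))
#' @export
otsuThreshold <- function(x, nBins = 256L) {
  v <- as.vector(x)
  v <- v[is.finite(v) & v != 0]
  if (length(v) == 0L)
    stop("degenerate input: no nonzero voxels to threshold")
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(lo)          # single intensity: everything foreground
  edges <- seq(lo, hi, length.out = nBins + 1L)
  h <- tabulate(pmin(nBins, findInterval(v, edges, rightmost.closed = TRUE)),
                nbins = nBins)
  p <- h / sum(h)
  centers <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[nBins]
  denom <- omega * (1 - omega)
  sigmaB <- ifelse(denom > 0, (muT * omega - mu)^2 / denom, -Inf)
  ## split after bin t (foreground starts at bin t+1)
  t <- which.max(sigmaB[-nBins])
  edges[t + 1L]
}

## 6-connected components of a 3D logical array; returns integer label array.
.labelComponents3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  np <- d[1L]; nr <- d[2L]; nc <- d[3L]
  lab <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      c0 <- cur - 1L
      p <- c0 %% np
      rest <- c0 %/% np
      r <- rest %% nr
      cc <- rest %/% nr
      nb <- integer(0)
      if (p > 0L) nb <- c(nb, cur - 1L)
      if (p < np - 1L) nb <- c(nb, cur + 1L)
      if (r > 0L) nb <- c(nb, cur - np)
      if (r < nr - 1L) nb <- c(nb, cur + np)
      if (cc > 0L) nb <- c(nb, cur - np * nr)
      if (cc < nc - 1L) nb <- c(nb, cur + np * nr)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- lab
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

## Chebyshev (box) binary dilation of a 3D logical array by integer radius.
.dilate3d <- function(mask, radius) {
  if (radius <= 0L) return(mask)
  d <- dim(mask)
  out <- mask
  for (axis in 1:3) {
    acc <- out
    full <- lapply(d, seq_len)
    n <- d[axis]
    for (s in c(-seq_len(radius), seq_len(radius))) {
      i1 <- max(1L, 1L - s); i2 <- min(n, n - s)
      if (i1 > i2) next
      io <- i1:i2; ia <- io + s
      indO <- full; indO[[axis]] <- io
      indA <- full; indA[[axis]] <- ia
      sub <- do.call(`[`, c(list(out), indA, list(drop = FALSE)))
      cur <- do.call(`[`, c(list(acc), indO, list(drop = FALSE)))
      acc <- do.call(`[<-`, c(list(acc), indO, list(cur | sub)))
    }
    out <- acc
  }
  out
}

## Run expr under an explicit seed without touching the caller's RNG stream;
## seed = NULL uses (and advances) the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

.assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar")
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok)
    stop("'", name, "' must be in ", if (strict) "(" else "[", lower, ", ",
         upper, if (strict) ")" else "]", " but is ", x)
  invisible(x)
}
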