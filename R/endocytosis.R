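#' @include synthetic.R
NULL

#' Segment one channel of a stack by intensity threshold
#'
#' A voxel belongs to the mask iff its intensity is greater than or equal to
#' the threshold (voxels exactly at the threshold are included — the
#' thresholds play the role of the minimal intensities of genuine staining).
#' `threshold = "otsu"` computes the threshold from the channel's
#' nonzero-voxel histogram with 256 bins (see [otsuThreshold()]).
#'
#' @param stack an [ImageStack].
#' @param channel channel name.
#' @param threshold non-negative scalar, or `"otsu"`.
#' @return `list(mask = logical array, threshold = scalar used)`.
#' @examples
#' s <- ImageStack(list(Cy5 = array(c(1, 5, 9), c(1, 1, 3))))
#' segmentChannel(s, "Cy5", 5)$mask
#' @export
segmentChannel <- function(stack, channel, threshold) {
  stopifnot(is(stack, "ImageStack"))
  g <- getChannel(stack, channel)
  if (identical(threshold, "otsu")) {
    if (all(g == 0))
      stop("degenerate input: channel '", channel,
           "' is all zero, Otsu threshold undefined")
    threshold <- otsuThreshold(g)
  } else {
    .assertScalar(threshold, "threshold", lower = 0)
  }
  list(mask = g >= threshold, threshold = threshold)
}

#' Build the four-mask quartet of the antibody-uptake assay
#'
#' Mask #1 segments the surface channel (`Cy5`), Mask #2 the internalized
#' channel (`Cy3`); Mask #3 = Mask #2 AND Mask #1 captures Cy3 signal on
#' Cy5-positive voxels (antibody bound to surface transporter through
#' incomplete Cy5 occupancy); Mask #4 = Mask #2 minus Mask #3 is the
#' corrected internalized mask. An optional Chebyshev dilation of Mask #1
#' (before the overlap) absorbs small chromatic offsets; the default radius
#' 0 uses the raw overlap.
#'
#' @param stack an [ImageStack] with `Cy5` and `Cy3` channels.
#' @param cy5Threshold,cy3Threshold scalar thresholds or `"otsu"`.
#' @param dilationRadius integer Chebyshev radius for dilating Mask #1 in
#'   the overlap step (default 0).
#' @return A [MaskQuartet].
#' @seealso [endocytosisRatio()]
#' @examples
#' sim <- simulateCellStack(internalizedFraction = 0.4, seed = 1)
#' buildMaskQuartet(sim$stack, 1e-6, 1e-6)
#' @export
buildMaskQuartet <- function(stack, cy5Threshold, cy3Threshold,
                             dilationRadius = 0L) {
  s1 <- segmentChannel(stack, "Cy5", cy5Threshold)
  s2 <- segmentChannel(stack, "Cy3", cy3Threshold)
  overlapRef <- if (dilationRadius > 0L)
    .dilate3d(s1$mask, as.integer(dilationRadius)) else s1$mask
  mask3 <- s2$mask & overlapRef
  new("MaskQuartet", mask1 = s1$mask, mask2 = s2$mask, mask3 = mask3,
      mask4 = s2$mask & !mask3,
      thresholds = c(cy5 = s1$threshold, cy3 = s2$threshold))
}

#' Compute the Cy3/Cy5 endocytosis ratio
#'
#' Integrates Cy5 intensity over Mask #1 (surface transporter) and Cy3
#' intensity over Mask #4 (corrected internalized transporter) and reports
#' their ratio, the extent-of-endocytosis readout. Quantification is
#' per image (a field typically containing several cells), not per cell.
#'
#' @param stack an [ImageStack] with `Cy5` and `Cy3` channels.
#' @param quartet a [MaskQuartet] built from this stack; if missing, it is
#'   built with `cy5Threshold`/`cy3Threshold`.
#' @param cy5Threshold,cy3Threshold thresholds used when `quartet` is
#'   missing.
#' @return An [EndocytosisResult].
#' @examples
#' sim <- simulateCellStack(internalizedFraction = 0.4, seed = 1)
#' endocytosisRatio(sim$stack, cy5Threshold = 1e-6, cy3Threshold = 1e-6)
#' @export
endocytosisRatio <- function(stack, quartet = NULL, cy5Threshold = "otsu",
                             cy3Threshold = "otsu") {
  stopifnot(is(stack, "ImageStack"))
  if (is.null(quartet))
    quartet <- buildMaskQuartet(stack, cy5Threshold, cy3Threshold)
  stopifnot(is(quartet, "MaskQuartet"))
  if (!identical(dim(quartet@mask1), dim(stack)))
    stop("quartet shape does not match the stack")
  cy5 <- sum(getChannel(stack, "Cy5")[quartet@mask1])
  cy3 <- sum(getChannel(stack, "Cy3")[quartet@mask4])
  if (cy5 == 0)
    stop("degenerate input: no surface signal (Cy5 integral over mask1 is 0)")
  new("EndocytosisResult", cy5Integrated = cy5, cy3Integrated = cy3,
      ratio = cy3 / cy5)
}

#' Fit a line to an endocytosis time-course
#'
#' Ordinary least squares of ratio on time. The linearity coefficient R^2 is
#' the squared Pearson correlation between fitted and observed ratios
#' (equivalently 1 - RSS/TSS); a constant time-course fits its own mean
#' perfectly and reports R^2 = 1 with slope 0.
#'
#' @param times time points in minutes (>= 3 distinct values).
#' @param ratios Cy3/Cy5 ratios, same length.
#' @return A [KineticsFit].
#' @examples
#' fitLinearKinetics(c(0, 60, 120), c(0, 1, 2))
#' @export
fitLinearKinetics <- function(times, ratios) {
  if (length(times) != length(ratios))
    stop("'times' and 'ratios' must have equal length")
  if (length(unique(times)) < 3L)
    stop("at least 3 distinct time points are required")
  if (stats::var(times) == 0) stop("zero variance in time points")
  fit <- stats::lm(ratios ~ times)
  co <- stats::coef(fit)
  tss <- sum((ratios - mean(ratios))^2)
  rsq <- if (tss == 0) 1 else {
    r2 <- 1 - sum(stats::residuals(fit)^2) / tss
    min(max(r2, 0), 1)
  }
  new("KineticsFit", slope = unname(co[2L]), intercept = unname(co[1L]),
      rSquared = rsq)
}
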