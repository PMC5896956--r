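#' @include endocytosis.R
NULL

#' Fraction of a protein's fluorescence in cargo-positive voxels
#'
#' Segments channel A (the protein, e.g. YFP-tagged transporter) and channel
#' B (the endosomal cargo, e.g. transferrin--TexasRed) into masks #1 and #2,
#' forms the overlap mask #3 = #1 AND #2, and reports the intensity-weighted
#' colocalized fraction `sum_A(mask3) / sum_A(mask1)` (a Manders-style
#' coefficient: asymmetric in A and B by design) together with the total
#' cargo uptake `sum_B(mask2)`.
#'
#' Because the cargo resides in punctate endosomes, the channel-B mask drops
#' connected components smaller than `minObjectSize` voxels (6-connectivity)
#' to suppress single-voxel noise. An optional Gaussian high-pass prefilter
#' (subtract a `highPassSigma`-blurred copy, clamp at 0) can be applied to
#' both channels before segmentation to emphasize puncta; it is off by
#' default.
#'
#' @param stack an [ImageStack].
#' @param channelA,channelB channel names for the protein and the cargo.
#' @param thresholdA,thresholdB scalar thresholds or `"otsu"`.
#' @param minObjectSize minimum channel-B object size in voxels (default 2;
#'   0 disables the filter).
#' @param highPassSigma sigma (voxels) of the optional high-pass prefilter;
#'   `NULL` (default) disables it.
#' @return A [ColocResult].
#' @examples
#' sim <- simulateColocStack(overlapFraction = 0.6, seed = 1)
#' colocalizedFraction(sim$stack, "YFP", "TxR", 1e-6, 1e-6)
#' @export
colocalizedFraction <- function(stack, channelA, channelB, thresholdA,
                                thresholdB, minObjectSize = 2L,
                                highPassSigma = NULL) {
  stopifnot(is(stack, "ImageStack"))
  if (!is.null(highPassSigma)) {
    .assertScalar(highPassSigma, "highPassSigma", 0, Inf, strict = TRUE)
    chans <- stack@channels
    for (nm in c(channelA, channelB)) {
      g <- getChannel(stack, nm)
      chans[[nm]] <- pmax(g - .gaussianBlur3d(g, highPassSigma), 0)
    }
    stack <- ImageStack(chans, voxelSize = stack@voxelSize,
                        metadata = stack@metadata)
  }
  mask1 <- segmentChannel(stack, channelA, thresholdA)$mask
  mask2 <- segmentChannel(stack, channelB, thresholdB)$mask
  if (minObjectSize > 0L && any(mask2)) {
    labels <- .labelComponents3d(mask2)
    sizes <- tabulate(labels[labels > 0L])
    keep <- which(sizes >= minObjectSize)
    mask2 <- array(labels %in% keep, dim(mask2))
  }
  mask3 <- mask1 & mask2
  a <- getChannel(stack, channelA)
  b <- getChannel(stack, channelB)
  denom <- sum(a[mask1])
  if (denom == 0)
    stop("degenerate input: channel '", channelA,
         "' mask carries zero intensity")
  new("ColocResult", fractionColocalized = sum(a[mask3]) / denom,
      totalCargoUptake = sum(b[mask2]))
}
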