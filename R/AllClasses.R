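#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## ImageStack
## ---------------------------------------------------------------------------

#' Multichannel 3D image stack
#'
#' The unit of all confocal quantification: a set of named channels (e.g.
#' `"Cy3"`, `"Cy5"`, `"YFP"`, `"CFP"`, `"FRET"`, `"TxR"`), each a 3D
#' non-negative intensity array in `(plane, row, col)` order, together with the
#' voxel size in nanometres and free-form metadata. All channels share one
#' shape; 2D matrices supplied to the constructor are promoted to a single
#' plane. Intensities are in arbitrary linear units of fluorescence intensity
#' (a.l.u.f.i.).
#'
#' @param channels named list of 3D numeric arrays (or 2D matrices, promoted
#'   to one plane), all of identical shape, finite and non-negative.
#' @param voxelSize numeric length-3 `(dz, dy, dx)` in nm; all positive.
#' @param metadata named list of free-form metadata.
#'
#' @return An `ImageStack` object.
#' @examples
#' s <- ImageStack(list(Cy3 = array(1, c(2, 8, 8)), Cy5 = array(2, c(2, 8, 8))))
#' channelNames(s)
#' dim(getChannel(s, "Cy5"))
#' @aliases ImageStack-class
#' @export
ImageStack <- function(channels, voxelSize = c(300, 120, 120),
                       metadata = list()) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty named list of arrays")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, c(1L, nrow(ch), ncol(ch)))
    ch
  })
  new("ImageStack", channels = channels, voxelSize = as.numeric(voxelSize),
      metadata = metadata)
}

setClass("ImageStack",
  representation(channels = "list", voxelSize = "numeric", metadata = "list"))

setValidity("ImageStack", function(object) {
  ch <- object@channels
  if (length(ch) < 1L) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  dims <- lapply(ch, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("channel grids must be 3D arrays (plane, row, col)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    return("all channel grids must share one shape")
  for (g in ch) {
    if (!all(is.finite(g))) return("intensities must be finite")
    if (any(g < 0)) return("intensities must be non-negative")
  }
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be three positive values (dz, dy, dx) in nm")
  TRUE
})

#' @rdname ImageStack
#' @param x,object an `ImageStack`.
#' @param name channel name.
#' @export
setMethod("channelNames", "ImageStack", function(x) names(x@channels))

#' @rdname ImageStack
#' @export
setMethod("getChannel", "ImageStack", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "' (have: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[name]]
})

#' @rdname ImageStack
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' @rdname ImageStack
#' @export
setMethod("stackMetadata", "ImageStack", function(x) x@metadata)

#' @rdname ImageStack
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@channels[[1L]]))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object)
  cat("ImageStack:", paste(d, collapse = " x "), "(plane x row x col)\n")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  cat("  voxel size (dz, dy, dx):",
      paste(object@voxelSize, collapse = ", "), "nm\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## TirfMovie
## ---------------------------------------------------------------------------

#' TIRF time-lapse movie
#'
#' A list of equally shaped 2D frames with the acquisition frame interval (in
#' minutes, matching the 1--2 min intervals typical of nanocluster imaging)
#' and the pixel size in nm.
#'
#' @param frames list of 2D numeric matrices, all the same shape, finite,
#'   non-negative.
#' @param frameInterval minutes between frames; > 0.
#' @param pixelSize pixel size in nm; > 0.
#' @return A `TirfMovie` object.
#' @examples
#' m <- TirfMovie(list(matrix(0, 8, 8), matrix(1, 8, 8)), frameInterval = 2)
#' nFrames(m)
#' @aliases TirfMovie-class
#' @export
TirfMovie <- function(frames, frameInterval = 2, pixelSize = 120) {
  new("TirfMovie", frames = frames, frameInterval = as.numeric(frameInterval),
      pixelSize = as.numeric(pixelSize))
}

setClass("TirfMovie",
  representation(frames = "list", frameInterval = "numeric",
                 pixelSize = "numeric"))

setValidity("TirfMovie", function(object) {
  fr <- object@frames
  if (length(fr) < 1L) return("at least one frame is required")
  if (any(!vapply(fr, is.matrix, TRUE))) return("frames must be 2D matrices")
  dims <- vapply(fr, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(dims)) != 1L) return("all frames must share one shape")
  for (f in fr) if (!all(is.finite(f))) return("intensities must be finite")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("frameInterval must be a positive scalar (minutes)")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a positive scalar (nm)")
  TRUE
})

#' @rdname TirfMovie
#' @param x,object a `TirfMovie`.
#' @export
setMethod("frames", "TirfMovie", function(x) x@frames)

#' @rdname TirfMovie
#' @export
setMethod("nFrames", "TirfMovie", function(x) length(x@frames))

#' @rdname TirfMovie
#' @export
setMethod("frameInterval", "TirfMovie", function(x) x@frameInterval)

#' @rdname TirfMovie
#' @export
setMethod("pixelSize", "TirfMovie", function(x) x@pixelSize)

setMethod("show", "TirfMovie", function(object) {
  d <- dim(object@frames[[1L]])
  cat("TirfMovie:", length(object@frames), "frames of",
      paste(d, collapse = " x "), "px\n")
  cat("  frame interval:", object@frameInterval, "min;  pixel size:",
      object@pixelSize, "nm;  duration:",
      (length(object@frames) - 1L) * object@frameInterval, "min\n")
})

## ---------------------------------------------------------------------------
## MaskQuartet
## ---------------------------------------------------------------------------

#' The four voxel masks of the antibody-uptake endocytosis assay
#'
#' Mask #1 segments the surface channel (Cy5); Mask #2 the raw internalized
#' channel (Cy3); Mask #3 is the Cy3-positive voxels that overlap Cy5-positive
#' voxels (antibody bound to residual surface transporter through incomplete
#' occupancy); Mask #4 = Mask #2 minus Mask #3 is the corrected internalized
#' mask. Constructed by [buildMaskQuartet()].
#'
#' Invariants enforced by the class: `mask3 = mask2 & mask1`,
#' `mask4 = mask2 & !mask3`, so `mask3` and `mask4` partition `mask2` and
#' `mask4` never intersects `mask1`.
#'
#' @seealso [buildMaskQuartet()], [endocytosisRatio()]
#' @aliases MaskQuartet-class
#' @name MaskQuartet
NULL

setClass("MaskQuartet",
  representation(mask1 = "array", mask2 = "array", mask3 = "array",
                 mask4 = "array", thresholds = "numeric"))

setValidity("MaskQuartet", function(object) {
  ms <- list(object@mask1, object@mask2, object@mask3, object@mask4)
  if (any(!vapply(ms, is.logical, TRUE))) return("masks must be logical")
  dims <- vapply(ms, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1L) return("masks must share one shape")
  if (any(object@mask3 & !object@mask2)) return("mask3 must be within mask2")
  if (!identical(object@mask4, object@mask2 & !object@mask3))
    return("mask4 must equal mask2 minus mask3")
  if (length(object@thresholds) != 2L)
    return("thresholds must be (cy5, cy3)")
  TRUE
})

#' @rdname MaskQuartet
#' @param x,object a `MaskQuartet`.
#' @export
setMethod("masks", "MaskQuartet", function(x)
  list(mask1 = x@mask1, mask2 = x@mask2, mask3 = x@mask3, mask4 = x@mask4))

#' @rdname MaskQuartet
#' @export
setMethod("thresholds", "MaskQuartet", function(x) x@thresholds)

setMethod("show", "MaskQuartet", function(object) {
  cat("MaskQuartet on", paste(dim(object@mask1), collapse = " x "), "voxels\n")
  cat(sprintf("  mask1 (surface Cy5):        %d voxels (threshold %.4g)\n",
              sum(object@mask1), object@thresholds[1L]))
  cat(sprintf("  mask2 (raw internalized):   %d voxels (threshold %.4g)\n",
              sum(object@mask2), object@thresholds[2L]))
  cat(sprintf("  mask3 (surface-overlap):    %d voxels\n", sum(object@mask3)))
  cat(sprintf("  mask4 (corr. internalized): %d voxels\n", sum(object@mask4)))
})

## ---------------------------------------------------------------------------
## Endocytosis / kinetics / colocalization results
## ---------------------------------------------------------------------------

#' Endocytosis-assay result
#'
#' Integrated Cy5 intensity over Mask #1 (surface), integrated Cy3 intensity
#' over Mask #4 (corrected internalized) and their ratio — the Cy3/Cy5 ratio
#' that reads out the extent of endocytosis. Produced by [endocytosisRatio()].
#'
#' @aliases EndocytosisResult-class
#' @name EndocytosisResult
NULL

setClass("EndocytosisResult",
  representation(cy5Integrated = "numeric", cy3Integrated = "numeric",
                 ratio = "numeric"))

setValidity("EndocytosisResult", function(object) {
  if (object@cy5Integrated < 0 || object@cy3Integrated < 0)
    return("integrated intensities must be non-negative")
  if (!is.finite(object@ratio) || object@ratio < 0)
    return("ratio must be finite and non-negative")
  TRUE
})

#' @rdname EndocytosisResult
#' @param x,object an `EndocytosisResult`.
#' @export
setMethod("endocytosisIndex", "EndocytosisResult", function(x) x@ratio)

#' @rdname EndocytosisResult
#' @param row.names,optional,... passed through (see [base::as.data.frame]).
#' @export
as.data.frame.EndocytosisResult <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(cy5Integrated = x@cy5Integrated, cy3Integrated = x@cy3Integrated,
             ratio = x@ratio)
}

setMethod("show", "EndocytosisResult", function(object) {
  cat("EndocytosisResult (a.l.u.f.i.)\n")
  cat(sprintf("  surface Cy5 (mask1):      %.6g\n", object@cy5Integrated))
  cat(sprintf("  internalized Cy3 (mask4): %.6g\n", object@cy3Integrated))
  cat(sprintf("  Cy3/Cy5 ratio:            %.6g\n", object@ratio))
})

#' Linear endocytosis-kinetics fit
#'
#' Ordinary least-squares line through a (time, Cy3/Cy5 ratio) time-course,
#' with the squared Pearson correlation as the linearity coefficient R^2.
#' Produced by [fitLinearKinetics()].
#'
#' @aliases KineticsFit-class
#' @name KineticsFit
NULL

setClass("KineticsFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric"))

setValidity("KineticsFit", function(object) {
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    return("slope and intercept must be finite")
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    return("rSquared must be in [0, 1]")
  TRUE
})

#' @rdname KineticsFit
#' @param x,row.names,optional,... see [base::as.data.frame].
#' @export
as.data.frame.KineticsFit <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(slope = x@slope, intercept = x@intercept, rSquared = x@rSquared)
}

setMethod("show", "KineticsFit", function(object) {
  cat(sprintf("KineticsFit: slope %.6g ratio/min, intercept %.6g, R^2 %.4f\n",
              object@slope, object@intercept, object@rSquared))
})

#' Colocalization result
#'
#' Fraction of channel-A mask intensity residing in voxels shared with the
#' channel-B mask, plus the total channel-B mask intensity (cargo uptake).
#' Produced by [colocalizedFraction()].
#'
#' @aliases ColocResult-class
#' @name ColocResult
NULL

setClass("ColocResult",
  representation(fractionColocalized = "numeric",
                 totalCargoUptake = "numeric"))

setValidity("ColocResult", function(object) {
  f <- object@fractionColocalized
  if (!is.finite(f) || f < 0 || f > 1)
    return("fractionColocalized must be in [0, 1]")
  if (object@totalCargoUptake < 0) return("uptake must be non-negative")
  TRUE
})

#' @rdname ColocResult
#' @param x,row.names,optional,... see [base::as.data.frame].
#' @export
as.data.frame.ColocResult <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(fractionColocalized = x@fractionColocalized,
             totalCargoUptake = x@totalCargoUptake)
}

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("ColocResult: fraction colocalized %.4f, cargo uptake %.6g\n",
              object@fractionColocalized, object@totalCargoUptake))
})

## ---------------------------------------------------------------------------
## FRET
## ---------------------------------------------------------------------------

#' FRET bleed-through calibration
#'
#' Donor-channel and acceptor-channel bleed-through coefficients into the FRET
#' filter channel, estimated from single-fluorophore control cells, with the
#' number of signal pixels each regression used. Constructed by
#' [fretCalibration()].
#'
#' @aliases FretCalibration-class
#' @name FretCalibration
NULL

setClass("FretCalibration",
  representation(aDonor = "numeric", bAcceptor = "numeric",
                 nPixelsUsed = "integer"))

setValidity("FretCalibration", function(object) {
  if (!is.finite(object@aDonor) || object@aDonor < 0)
    return("aDonor must be finite and >= 0")
  if (!is.finite(object@bAcceptor) || object@bAcceptor < 0)
    return("bAcceptor must be finite and >= 0")
  if (length(object@nPixelsUsed) != 2L)
    return("nPixelsUsed must hold (donor, acceptor) pixel counts")
  TRUE
})

#' @rdname FretCalibration
#' @param x,object a `FretCalibration`.
#' @export
setMethod("aDonor", "FretCalibration", function(x) x@aDonor)

#' @rdname FretCalibration
#' @export
setMethod("bAcceptor", "FretCalibration", function(x) x@bAcceptor)

setMethod("show", "FretCalibration", function(object) {
  cat(sprintf(
    "FretCalibration: a (donor) = %.4f [%d px], b (acceptor) = %.4f [%d px]\n",
    object@aDonor, object@nPixelsUsed[1L], object@bAcceptor,
    object@nPixelsUsed[2L]))
})

#' Per-ROI normalized FRET result
#'
#' Mean corrected FRET, donor (CFP) and acceptor (YFP) intensities over a
#' region of interest; FRETN = mean(FRET^C) / (mean(YFP) x mean(CFP)) in
#' reciprocal intensity units; the donor:acceptor stoichiometry ratio
#' `max(CFP, YFP)/min(CFP, YFP)`; and the inclusion flag (ratio <= 3, the
#' gate outside which FRETN becomes non-linear in the fluorophore excess).
#' Produced by [fretnRoi()].
#'
#' @aliases FretRoiResult-class
#' @name FretRoiResult
NULL

setClass("FretRoiResult",
  representation(fretcMean = "numeric", cfpMean = "numeric",
                 yfpMean = "numeric", fretn = "numeric",
                 stoichiometryRatio = "numeric", included = "logical"))

setValidity("FretRoiResult", function(object) {
  if (object@stoichiometryRatio < 1) return("stoichiometryRatio must be >= 1")
  if (object@cfpMean <= 0 || object@yfpMean <= 0)
    return("cfpMean and yfpMean must be positive")
  TRUE
})

#' @rdname FretRoiResult
#' @param x,object a `FretRoiResult`.
#' @export
setMethod("fretn", "FretRoiResult", function(x) x@fretn)

#' @rdname FretRoiResult
#' @export
setMethod("isIncluded", "FretRoiResult", function(x) x@included)

#' @rdname FretRoiResult
#' @param row.names,optional,... see [base::as.data.frame].
#' @export
as.data.frame.FretRoiResult <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(fretcMean = x@fretcMean, cfpMean = x@cfpMean,
             yfpMean = x@yfpMean, fretn = x@fretn,
             stoichiometryRatio = x@stoichiometryRatio, included = x@included)
}

setMethod("show", "FretRoiResult", function(object) {
  cat(sprintf(
    "FretRoiResult: FRETN %.6g (FRET^C %.4g / YFP %.4g x CFP %.4g), D:A %.2f%s\n",
    object@fretn, object@fretcMean, object@yfpMean, object@cfpMean,
    object@stoichiometryRatio,
    if (object@included) "" else " [excluded: stoichiometry > 3]"))
})

## ---------------------------------------------------------------------------
## TIRF timecourse
## ---------------------------------------------------------------------------

#' Per-frame nanocluster counts
#'
#' Spot counts per movie frame, the counts expressed as a percentage of the
#' maximum per-frame count, and (once tracks have been classified) the
#' fraction of tracks persisting beyond the duration cutoff. Produced by
#' [countTimecourse()]; `persistentFraction` is `NA` until filled from
#' [classifyPersistence()].
#'
#' @aliases ClusterTimecourse-class
#' @name ClusterTimecourse
NULL

setClass("ClusterTimecourse",
  representation(counts = "integer", percentOfMax = "numeric",
                 persistentFraction = "numeric"))

setValidity("ClusterTimecourse", function(object) {
  if (length(object@counts) != length(object@percentOfMax))
    return("counts and percentOfMax must have equal length")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (any(object@counts > 0)) {
    if (abs(max(object@percentOfMax) - 100) > 1e-9)
      return("percentOfMax must reach 100 when any spot exists")
  } else if (any(object@percentOfMax != 0)) {
    return("percentOfMax must be all zero when no spot exists")
  }
  pf <- object@persistentFraction
  if (!is.na(pf) && (pf < 0 || pf > 1))
    return("persistentFraction must be in [0, 1]")
  TRUE
})

#' @rdname ClusterTimecourse
#' @param x,object a `ClusterTimecourse`.
#' @export
setMethod("spotCounts", "ClusterTimecourse", function(x) x@counts)

#' @rdname ClusterTimecourse
#' @export
setMethod("percentOfMax", "ClusterTimecourse", function(x) x@percentOfMax)

#' @rdname ClusterTimecourse
#' @export
setMethod("persistentFraction", "ClusterTimecourse",
          function(x) x@persistentFraction)

setMethod("show", "ClusterTimecourse", function(object) {
  cat("ClusterTimecourse:", length(object@counts), "frames, max count",
      if (length(object@counts)) max(object@counts) else 0, "\n")
  if (!is.na(object@persistentFraction))
    cat(sprintf("  persistent fraction: %.3f\n", object@persistentFraction))
})

## ---------------------------------------------------------------------------
## Binding
## ---------------------------------------------------------------------------

#' Saturation radioligand-binding dataset
#'
#' Per-well records of ligand concentration (nM), total bound counts, and
#' paired nonspecific counts (measured in the presence of a saturating
#' unlabeled competitor), with a replicate id and a condition label.
#'
#' @param points data.frame with columns `concentration` (nM, > 0),
#'   `totalCounts` (>= 0), `nonspecificCounts` (>= 0, `NA` allowed when a
#'   concentration has a nonspecific pair in another replicate) and
#'   `replicate`.
#' @param condition condition label.
#' @return A `BindingDataset` object.
#' @examples
#' d <- simulateBindingDataset(seed = 1)
#' head(bindingPoints(d))
#' @aliases BindingDataset-class
#' @export
BindingDataset <- function(points, condition = "unspecified") {
  points <- as.data.frame(points)
  if (!"replicate" %in% names(points)) points$replicate <- 1L
  new("BindingDataset", points = points, condition = as.character(condition))
}

setClass("BindingDataset",
  representation(points = "data.frame", condition = "character"))

setValidity("BindingDataset", function(object) {
  p <- object@points
  need <- c("concentration", "totalCounts", "nonspecificCounts", "replicate")
  if (!all(need %in% names(p)))
    return(paste("points must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) == 0L) return("at least one data point is required")
  if (any(!is.finite(p$concentration)) || any(p$concentration <= 0))
    return("concentrations must be positive")
  if (any(!is.finite(p$totalCounts)) || any(p$totalCounts < 0))
    return("total counts must be finite and non-negative")
  ns <- p$nonspecificCounts
  if (any(!is.na(ns) & (!is.finite(ns) | ns < 0)))
    return("nonspecific counts must be finite and non-negative (or NA)")
  TRUE
})

#' @rdname BindingDataset
#' @param x,object a `BindingDataset`.
#' @export
setMethod("bindingPoints", "BindingDataset", function(x) x@points)

setMethod("show", "BindingDataset", function(object) {
  p <- object@points
  cat("BindingDataset ('", object@condition, "'): ", nrow(p), " wells, ",
      length(unique(p$concentration)), " concentrations, ",
      length(unique(p$replicate)), " replicate(s)\n", sep = "")
  cat("  concentrations (nM):",
      paste(sort(unique(p$concentration)), collapse = ", "), "\n")
})

#' Saturation-binding fit
#'
#' One-site saturation fit `B(c) = Bmax * c / (K_D + c)` to specific binding,
#' with Jacobian-based standard errors, the residual sum of squares and a
#' convergence flag. Produced by [fitSaturation()].
#'
#' @aliases SaturationFit-class
#' @name SaturationFit
NULL

setClass("SaturationFit",
  representation(kd = "numeric", bmax = "numeric", kdSe = "numeric",
                 bmaxSe = "numeric", rss = "numeric", converged = "logical"))

setValidity("SaturationFit", function(object) {
  if (object@converged && (object@kd <= 0 || object@bmax <= 0))
    return("kd and bmax must be positive for a converged fit")
  if (object@rss < 0) return("rss must be non-negative")
  TRUE
})

#' @rdname SaturationFit
#' @param x,object a `SaturationFit`.
#' @export
setMethod("kd", "SaturationFit", function(x) x@kd)

#' @rdname SaturationFit
#' @export
setMethod("bmax", "SaturationFit", function(x) x@bmax)

#' @rdname SaturationFit
#' @param row.names,optional,... see [base::as.data.frame].
#' @export
as.data.frame.SaturationFit <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(kd = x@kd, bmax = x@bmax, kdSe = x@kdSe, bmaxSe = x@bmaxSe,
             rss = x@rss, converged = x@converged)
}

setMethod("show", "SaturationFit", function(object) {
  cat(sprintf("SaturationFit: K_D = %.4g +/- %.3g nM, Bmax = %.5g +/- %.3g%s\n",
              object@kd, object@kdSe, object@bmax, object@bmaxSe,
              if (object@converged) "" else "  [NOT CONVERGED]"))
})
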