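#' @include colocalization.R
NULL

#' Estimate a bleed-through coefficient from a single-fluorophore control
#'
#' In a control cell expressing only the donor (or only the acceptor), any
#' FRET-channel signal is spectral bleed-through. The coefficient is the
#' slope of the zero-intercept least-squares regression of FRET-channel
#' intensity on fluorophore-channel intensity over the pixels whose
#' fluorophore intensity is at least `minIntensity` (background is assumed
#' already subtracted, so an intercept would only absorb residual offset).
#' A negative slope is clamped to 0 with a warning.
#'
#' @param control an [ImageStack] of the single-fluorophore control.
#' @param fluorophoreChannel channel of the expressed fluorophore (`"CFP"`
#'   for the donor control, `"YFP"` for the acceptor control).
#' @param fretChannel the FRET filter channel name.
#' @param minIntensity signal-pixel selection threshold (>= 0).
#' @param minPixels minimum number of signal pixels required (default 50).
#' @return `list(coefficient, nPixels)`.
#' @seealso [fretCalibration()]
#' @examples
#' sim <- simulateFretTriplet(aDonor = 0.5, seed = 1)
#' estimateBleedthrough(sim$donorOnly, "CFP", "FRET", minIntensity = 50)
#' @export
estimateBleedthrough <- function(control, fluorophoreChannel, fretChannel,
                                 minIntensity = 0, minPixels = 50L) {
  stopifnot(is(control, "ImageStack"))
  .assertScalar(minIntensity, "minIntensity", lower = 0)
  x <- as.vector(getChannel(control, fluorophoreChannel))
  y <- as.vector(getChannel(control, fretChannel))
  sel <- x >= minIntensity & x > 0
  n <- sum(sel)
  if (n < minPixels)
    stop("degenerate input: only ", n, " signal pixels (>= ", minPixels,
         " required); lower 'minIntensity'?")
  slope <- sum(x[sel] * y[sel]) / sum(x[sel]^2)
  if (slope < 0) {
    warning("negative bleed-through slope (", signif(slope, 3),
            ") clamped to 0")
    slope <- 0
  }
  list(coefficient = slope, nPixels = n)
}

#' Calibrate both bleed-through coefficients
#'
#' Runs [estimateBleedthrough()] on the donor-only and acceptor-only control
#' stacks and returns a [FretCalibration] holding the donor coefficient `a`
#' and acceptor coefficient `b` of the three-cube correction.
#'
#' @param donorControl,acceptorControl single-fluorophore control
#'   [ImageStack]s.
#' @param donorChannel,acceptorChannel,fretChannel channel names.
#' @param minIntensity,minPixels as in [estimateBleedthrough()].
#' @return A [FretCalibration].
#' @examples
#' sim <- simulateFretTriplet(aDonor = 0.5, bAcceptor = 0.2, seed = 1)
#' fretCalibration(sim$donorOnly, sim$acceptorOnly, minIntensity = 50)
#' @export
fretCalibration <- function(donorControl, acceptorControl,
                            donorChannel = "CFP", acceptorChannel = "YFP",
                            fretChannel = "FRET", minIntensity = 0,
                            minPixels = 50L) {
  don <- estimateBleedthrough(donorControl, donorChannel, fretChannel,
                              minIntensity, minPixels)
  acc <- estimateBleedthrough(acceptorControl, acceptorChannel, fretChannel,
                              minIntensity, minPixels)
  new("FretCalibration", aDonor = don$coefficient, bAcceptor = acc$coefficient,
      nPixelsUsed = c(donor = don$nPixels, acceptor = acc$nPixels))
}

#' Pixelwise corrected FRET
#'
#' The standard three-cube correction: per pixel,
#' `FRET^C = I_FRET - a * I_CFP - b * I_YFP` with the bleed-through
#' coefficients from the single-label controls. Values may be negative and
#' are retained so that ROI means stay unbiased.
#'
#' @param stack an [ImageStack] with `CFP`, `YFP` and `FRET` channels.
#' @param calib a [FretCalibration].
#' @param donorChannel,acceptorChannel,fretChannel channel names.
#' @return A numeric array of corrected FRET intensities (stack shape).
#' @examples
#' sim <- simulateFretTriplet(aDonor = 0.5, bAcceptor = 0.2, seed = 1)
#' calib <- fretCalibration(sim$donorOnly, sim$acceptorOnly, minIntensity = 50)
#' fc <- correctedFret(sim$experiment, calib)
#' @export
correctedFret <- function(stack, calib, donorChannel = "CFP",
                          acceptorChannel = "YFP", fretChannel = "FRET") {
  stopifnot(is(stack, "ImageStack"), is(calib, "FretCalibration"))
  getChannel(stack, fretChannel) -
    calib@aDonor * getChannel(stack, donorChannel) -
    calib@bAcceptor * getChannel(stack, acceptorChannel)
}

#' ROI-level normalized FRET (FRETN) with stoichiometry gating
#'
#' Averages corrected FRET, donor and acceptor intensities over a region of
#' interest and computes `FRETN = mean(FRET^C) / (mean(YFP) * mean(CFP))`
#' (reciprocal-intensity units, comparable only within one experiment's
#' acquisition settings). Because FRETN becomes non-linear when donor or
#' acceptor is in large molar excess, ROIs whose stoichiometry ratio
#' `max(CFP, YFP)/min(CFP, YFP)` exceeds 3 are flagged `included = FALSE`
#' and are excluded from group comparisons.
#'
#' @param stack an [ImageStack] with `CFP` and `YFP` channels.
#' @param fretcGrid corrected FRET array from [correctedFret()].
#' @param roi either a logical array of the stack shape, or a list with
#'   integer ranges `planes`, `rows`, `cols` describing a box.
#' @param donorChannel,acceptorChannel channel names.
#' @param maxStoichiometry inclusion gate on the donor:acceptor ratio
#'   (default 3).
#' @return A [FretRoiResult].
#' @examples
#' sim <- simulateFretTriplet(aDonor = 0.5, bAcceptor = 0.2, seed = 1)
#' calib <- fretCalibration(sim$donorOnly, sim$acceptorOnly, minIntensity = 50)
#' fc <- correctedFret(sim$experiment, calib)
#' fretnRoi(sim$experiment, fc, list(planes = 1, rows = 40:60, cols = 40:60))
#' @export
fretnRoi <- function(stack, fretcGrid, roi, donorChannel = "CFP",
                     acceptorChannel = "YFP", maxStoichiometry = 3) {
  stopifnot(is(stack, "ImageStack"))
  if (!identical(dim(fretcGrid), dim(stack)))
    stop("corrected FRET grid shape does not match the stack")
  sel <- if (is.array(roi) && is.logical(roi)) {
    if (!identical(dim(roi), dim(stack)))
      stop("ROI mask shape does not match the stack")
    roi
  } else if (is.list(roi)) {
    m <- array(FALSE, dim(stack))
    m[roi$planes, roi$rows, roi$cols] <- TRUE
    m
  } else stop("'roi' must be a logical array or a list of index ranges")
  if (!any(sel)) stop("ROI is empty")
  cfp <- mean(getChannel(stack, donorChannel)[sel])
  yfp <- mean(getChannel(stack, acceptorChannel)[sel])
  if (cfp <= 0 || yfp <= 0)
    stop("degenerate input: non-positive mean donor or acceptor intensity")
  fc <- mean(fretcGrid[sel])
  stoich <- max(cfp, yfp) / min(cfp, yfp)
  new("FretRoiResult", fretcMean = fc, cfpMean = cfp, yfpMean = yfp,
      fretn = fc / (yfp * cfp), stoichiometryRatio = stoich,
      included = stoich <= maxStoichiometry)
}

#' Compare FRETN between conditions
#'
#' Unpaired two-tailed Welch t-tests on the FRETN values of the
#' stoichiometry-included ROIs for every pair of conditions. ROIs flagged
#' `included = FALSE` never enter the comparison.
#'
#' @param groups named list: condition label -> list of [FretRoiResult]s.
#' @return data.frame with one row per condition pair: group labels, group
#'   sizes (included ROIs), mean FRETN difference, t statistic, degrees of
#'   freedom and two-tailed p value.
#' @examples
#' sim <- simulateFretTriplet(seed = 1)
#' calib <- fretCalibration(sim$donorOnly, sim$acceptorOnly, minIntensity = 50)
#' fc <- correctedFret(sim$experiment, calib)
#' rois <- lapply(list(30:40, 45:55, 60:70), function(r)
#'   fretnRoi(sim$experiment, fc, list(planes = 1, rows = r, cols = 40:60)))
#' compareFretn(list(vehicle = rois, treated = rois))
#' @export
compareFretn <- function(groups) {
  if (length(groups) < 2L || is.null(names(groups)))
    stop("'groups' must be a named list of at least two conditions")
  vals <- lapply(groups, function(g) {
    stopifnot(all(vapply(g, is, TRUE, "FretRoiResult")))
    vapply(Filter(isIncluded, g), fretn, 0)
  })
  for (nm in names(vals))
    if (length(vals[[nm]]) < 2L)
      stop("condition '", nm, "' has fewer than 2 included ROIs")
  pairs <- utils::combn(names(vals), 2L)
  out <- data.frame()
  for (k in seq_len(ncol(pairs))) {
    a <- vals[[pairs[1L, k]]]
    b <- vals[[pairs[2L, k]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else Inf),
                 parameter = c(df = length(a) + length(b) - 2),
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
    }
    out <- rbind(out, data.frame(
      groupA = pairs[1L, k], groupB = pairs[2L, k],
      nA = length(a), nB = length(b),
      meanDifference = mean(a) - mean(b),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value))
  }
  out
}
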