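#' @include tirf.R
NULL

#' Specific binding by nonspecific subtraction
#'
#' Specific binding per well is total minus the replicate-matched nonspecific
#' count at the same concentration. Wells whose own nonspecific value is
#' missing fall back to the mean nonspecific count of that concentration
#' across replicates; a concentration with no nonspecific measurement at all
#' is an error. Negative specific values are retained (not clamped) to keep
#' the downstream estimator unbiased.
#'
#' @param dataset a [BindingDataset].
#' @return data.frame with columns `concentration`, `specific`, `replicate`.
#' @examples
#' d <- simulateBindingDataset(noiseModel = "none")
#' head(specificBinding(d))
#' @export
specificBinding <- function(dataset) {
  stopifnot(is(dataset, "BindingDataset"))
  p <- bindingPoints(dataset)
  ns <- p$nonspecificCounts
  if (anyNA(ns)) {
    nsMean <- tapply(ns, p$concentration, mean, na.rm = TRUE)
    fill <- nsMean[as.character(p$concentration)]
    if (anyNA(fill[is.na(ns)])) {
      bad <- unique(p$concentration[is.na(ns) & is.na(fill)])
      stop("no nonspecific measurement for concentration(s): ",
           paste(bad, collapse = ", "))
    }
    ns[is.na(ns)] <- fill[is.na(ns)]
  }
  data.frame(concentration = p$concentration,
             specific = p$totalCounts - ns,
             replicate = p$replicate)
}

#' Fit the one-site saturation binding model
#'
#' Nonlinear least squares (Levenberg--Marquardt, via
#' [minpack.lm::nlsLM()]) of `B(c) = Bmax * c / (K_D + c)` to specific
#' binding. Start values: `Bmax0` = maximum specific count, `K_D0` = the
#' concentration whose specific count is nearest `Bmax0 / 2`; parameter
#' convergence tolerance `1e-10`; at most 500 iterations (non-convergence is
#' reported via the `converged` flag, not an error). Standard errors come
#' from the Jacobian-based covariance. Fitting is unweighted by default;
#' `weighting = "poisson"` applies `1/max(B, 1)` variance weights.
#'
#' @param specific data.frame with columns `concentration` and `specific`
#'   (e.g. from [specificBinding()]), or a [BindingDataset] (converted
#'   internally, pooling all replicates).
#' @param weighting `"none"` (default) or `"poisson"`.
#' @return A [SaturationFit].
#' @examples
#' d <- simulateBindingDataset(list(kd = 15, bmax = 1000, nsSlope = 2),
#'                             noiseModel = "none")
#' fitSaturation(d)
#' @export
fitSaturation <- function(specific, weighting = c("none", "poisson")) {
  weighting <- match.arg(weighting)
  if (is(specific, "BindingDataset")) specific <- specificBinding(specific)
  cc <- specific$concentration
  b <- specific$specific
  if (length(unique(cc)) < 4L)
    stop("at least 4 distinct concentrations are required")
  if (all(b <= 0))
    stop("degenerate input: no positive specific binding")
  bmax0 <- max(b)
  kd0 <- cc[which.min(abs(b - bmax0 / 2))]
  w <- if (weighting == "poisson") 1 / pmax(b, 1) else rep(1, length(b))
  fit <- tryCatch(
    minpack.lm::nlsLM(b ~ bmax * cc / (kd + cc),
                      start = list(bmax = bmax0, kd = kd0),
                      lower = c(bmax = 1e-12, kd = 1e-12),
                      weights = w,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500L, ptol = 1e-10, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("SaturationFit", kd = NA_real_, bmax = NA_real_,
               kdSe = NA_real_, bmaxSe = NA_real_, rss = Inf,
               converged = FALSE))
  est <- summary(fit)$coefficients
  info <- fit$convInfo
  converged <- isTRUE(info$isConv) ||
    (!is.null(info$finIter) && info$finIter < 500L)
  new("SaturationFit",
      kd = est["kd", "Estimate"], bmax = est["bmax", "Estimate"],
      kdSe = est["kd", "Std. Error"], bmaxSe = est["bmax", "Std. Error"],
      rss = sum(stats::residuals(fit)^2), converged = converged)
}

#' Compare Bmax (and K_D) between paired conditions
#'
#' Replicate-paired comparison of saturation fits between two conditions
#' (e.g. vehicle vs drug across independent experiments): percent change in
#' mean Bmax, `100 * (mean_B - mean_A) / mean_A`, with a paired two-tailed
#' t-test on the per-replicate Bmax values, and the analogous comparison for
#' K_D. Fits are paired positionally by list order (replicate order).
#'
#' @param fits named list of exactly two conditions, each a list of
#'   [SaturationFit]s of equal length (>= 3), replicate-paired.
#' @return data.frame with one row per parameter (`bmax`, `kd`): means,
#'   percent change, t statistic, df and two-tailed p value.
#' @examples
#' mk <- function(b) lapply(b, function(x)
#'   fitSaturation(simulateBindingDataset(list(kd = 15, bmax = x, nsSlope = 2),
#'                                        noiseModel = "none")))
#' compareBmax(list(vehicle = mk(c(1000, 1050, 980)),
#'                  treated = mk(c(740, 760, 720))))
#' @export
compareBmax <- function(fits) {
  if (length(fits) != 2L || is.null(names(fits)))
    stop("'fits' must be a named list of exactly two conditions")
  nA <- length(fits[[1L]]); nB <- length(fits[[2L]])
  if (nA != nB)
    stop("conditions must have equal, replicate-paired fit counts")
  if (nA < 3L) stop("at least 3 paired replicates are required")
  getPar <- function(lst, f) vapply(lst, f, 0)
  out <- data.frame()
  for (par in c("bmax", "kd")) {
    f <- if (par == "bmax") bmax else kd
    a <- getPar(fits[[1L]], f)
    b <- getPar(fits[[2L]], f)
    diffs <- b - a
    if (stats::sd(diffs) == 0) {
      tt <- list(statistic = c(t = if (all(diffs == 0)) 0 else Inf),
                 parameter = c(df = nA - 1),
                 p.value = if (all(diffs == 0)) 1 else 0)
    } else {
      tt <- stats::t.test(b, a, paired = TRUE)
    }
    out <- rbind(out, data.frame(
      parameter = par,
      meanA = mean(a), meanB = mean(b),
      percentChange = 100 * (mean(b) - mean(a)) / mean(a),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value))
  }
  attr(out, "conditions") <- names(fits)
  out
}
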