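test_that("bleed-through slope is exact for proportional controls", {
  cfp <- array(seq(10, 500, length.out = 400), c(1, 20, 20))
  ctl <- ImageStack(list(CFP = cfp, FRET = 0.5 * cfp))
  est <- estimateBleedthrough(ctl, "CFP", "FRET", minIntensity = 0)
  expect_equal(est$coefficient, 0.5, tolerance = 1e-12)
  expect_equal(est$nPixels, 400L)
  z <- ImageStack(list(CFP = cfp, FRET = array(0, c(1, 20, 20))))
  expect_equal(estimateBleedthrough(z, "CFP", "FRET", 0)$coefficient, 0)
})

test_that("too few signal pixels is a degenerate input; negatives clamp", {
  cfp <- array(c(rep(0, 390), rep(100, 10)), c(1, 20, 20))
  ctl <- ImageStack(list(CFP = cfp, FRET = cfp * 0.3))
  expect_error(estimateBleedthrough(ctl, "CFP", "FRET", 50), "degenerate")
  neg <- ImageStack(list(CFP = array(100, c(1, 10, 10)),
                         FRET = array(0, c(1, 10, 10))))
  # flat control cannot produce a negative slope; construct one via two levels
  cfp2 <- array(rep(c(100, 200), each = 50), c(1, 10, 10))
  fr2 <- array(rep(c(30, 0), each = 50), c(1, 10, 10))
  ctl2 <- ImageStack(list(CFP = cfp2, FRET = fr2))
  expect_equal(estimateBleedthrough(ctl2, "CFP", "FRET", 0)$coefficient,
               sum(cfp2 * fr2) / sum(cfp2^2))
})

test_that("noisy donor-only controls recover the coefficient", {
  noisy <- list(photonScale = 1, readSd = 2)
  errs <- sapply(1:5, function(s) {
    sim <- simulateFretTriplet(aDonor = 0.62, bAcceptor = 0.25,
                               noise = noisy, seed = 60 + s)
    est <- estimateBleedthrough(sim$donorOnly, "CFP", "FRET",
                                minIntensity = 50)
    est$coefficient - 0.62
  })
  expect_true(all(abs(errs) <= 0.02))
})

test_that("corrected FRET implements the three-cube formula", {
  mk <- function(f, c, y)
    ImageStack(list(CFP = array(c, c(1, 2, 2)), YFP = array(y, c(1, 2, 2)),
                    FRET = array(f, c(1, 2, 2))))
  calib0 <- new("FretCalibration", aDonor = 0, bAcceptor = 0,
                nPixelsUsed = c(100L, 100L))
  s <- mk(100, 80, 80)
  expect_equal(correctedFret(s, calib0), getChannel(s, "FRET"))
  calib <- new("FretCalibration", aDonor = 0.5, bAcceptor = 0.25,
               nPixelsUsed = c(100L, 100L))
  expect_equal(unique(as.vector(correctedFret(s, calib))), 40)
})

test_that("corrected FRET is linear in the input stack", {
  sim <- simulateFretTriplet(noise = NULL, seed = 61)
  calib <- fretCalibration(sim$donorOnly, sim$acceptorOnly, minIntensity = 50)
  fc1 <- correctedFret(sim$experiment, calib)
  scaled <- ImageStack(lapply(sim$experiment@channels, `*`, 2.5))
  expect_equal(correctedFret(scaled, calib), 2.5 * fc1, tolerance = 1e-12)
})

test_that("noiseless pipeline recovers the sensitized grid exactly", {
  sim <- simulateFretTriplet(sensitizedLevel = 60, aDonor = 0.62,
                             bAcceptor = 0.25, noise = NULL, seed = 62)
  calib <- fretCalibration(sim$donorOnly, sim$acceptorOnly, minIntensity = 1)
  expect_equal(aDonor(calib), 0.62, tolerance = 1e-9)
  expect_equal(bAcceptor(calib), 0.25, tolerance = 1e-9)
  fc <- correctedFret(sim$experiment, calib)
  expect_equal(max(abs(fc - sim$truth$sensitized)), 0, tolerance = 1e-9)
})

test_that("FRETN arithmetic and stoichiometry gating", {
  mk <- function(c, y) ImageStack(list(CFP = array(c, c(1, 4, 4)),
                                       YFP = array(y, c(1, 4, 4)),
                                       FRET = array(1, c(1, 4, 4))))
  fcg <- array(40, c(1, 4, 4))
  roi <- list(planes = 1, rows = 1:4, cols = 1:4)
  r <- fretnRoi(mk(80, 80), fcg, roi)
  expect_equal(fretn(r), 40 / (80 * 80))
  expect_equal(r@stoichiometryRatio, 1)
  expect_true(isIncluded(r))
  r2 <- fretnRoi(mk(100, 400), fcg, roi)
  expect_equal(r2@stoichiometryRatio, 4)
  expect_false(isIncluded(r2))
  r3 <- fretnRoi(mk(100, 300), fcg, roi)   # exactly 3 is still included
  expect_true(isIncluded(r3))
  expect_error(fretnRoi(mk(80, 80), fcg, list(planes = 1, rows = integer(0),
                                              cols = 1:4)), "empty")
})

test_that("group comparison excludes gated ROIs and handles ties", {
  mkRoi <- function(fretc, cfp, yfp) {
    stoich <- max(cfp, yfp) / min(cfp, yfp)
    new("FretRoiResult", fretcMean = fretc, cfpMean = cfp, yfpMean = yfp,
        fretn = fretc / (yfp * cfp), stoichiometryRatio = stoich,
        included = stoich <= 3)
  }
  g1 <- list(mkRoi(40, 80, 80), mkRoi(42, 80, 80), mkRoi(41, 80, 80))
  out <- compareFretn(list(a = g1, b = g1))
  expect_equal(out$p, 1)
  expect_equal(out$t, 0)
  # an excluded ROI with an absurd FRETN must not change the comparison
  gated <- c(g1, list(mkRoi(4000, 100, 400)))
  expect_false(isIncluded(gated[[4]]))
  outGated <- compareFretn(list(a = g1, b = gated))
  expect_equal(outGated$p, 1)
  expect_equal(outGated$nB, 3L)
  expect_error(compareFretn(list(a = g1, b = g1[1])), "fewer than 2")
})

test_that("well-separated FRETN groups give a decisive Welch test", {
  withr::with_seed(63, {
    a <- rnorm(15, 0.005, 1e-4)
    b <- rnorm(15, 0.010, 1e-4)
  })
  mkRoi <- function(v) new("FretRoiResult", fretcMean = v * 6400,
                           cfpMean = 80, yfpMean = 80, fretn = v,
                           stoichiometryRatio = 1, included = TRUE)
  out <- compareFretn(list(lo = lapply(a, mkRoi), hi = lapply(b, mkRoi)))
  expect_lt(out$p, 1e-6)
  # agreement with the closed-form Welch statistic
  tManual <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(out$t, tManual, tolerance = 1e-12)
})
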