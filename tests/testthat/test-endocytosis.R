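test_that("threshold segmentation is an inclusive >= comparison", {
  s <- ImageStack(list(Cy5 = array(c(1, 5, 9), c(1, 1, 3))))
  expect_equal(as.vector(segmentChannel(s, "Cy5", 5)$mask), c(FALSE, TRUE, TRUE))
  expect_true(all(segmentChannel(s, "Cy5", 0)$mask))
  expect_error(segmentChannel(s, "Cy3", 1), "no channel")
  z <- ImageStack(list(Cy5 = array(0, c(1, 2, 2))))
  expect_error(segmentChannel(z, "Cy5", "otsu"), "degenerate")
})

test_that("Otsu matches the exhaustive-search oracle on a bimodal grid", {
  set.seed(11)
  fg <- array(FALSE, c(2, 40, 40)); fg[, 10:30, 10:30] <- TRUE
  g <- array(rnorm(3200, 10, 1), c(2, 40, 40))
  g[fg] <- rnorm(sum(fg), 100, 5)
  g <- pmax(g, 0.001)
  thr <- otsuThreshold(g)
  oracle <- bruteForceOtsu(g)
  # both thresholds separate the modes; the implied masks agree
  expect_equal(g >= thr, g >= oracle)
  s <- ImageStack(list(Cy5 = g))
  mask <- segmentChannel(s, "Cy5", "otsu")$mask
  expect_gte(sum(mask & fg) / sum(fg), 0.99)
})

test_that("mask quartet handles full-overlap and disjoint extremes", {
  full <- ImageStack(list(Cy5 = array(10, c(1, 4, 4)),
                          Cy3 = array(c(0, 8), c(1, 4, 4))))
  q <- buildMaskQuartet(full, 5, 5)
  expect_false(any(masks(q)$mask4))       # all Cy3 attributed to surface
  dis <- ImageStack(list(
    Cy5 = array(rep(c(10, 0), each = 8), c(1, 4, 4)),
    Cy3 = array(rep(c(0, 10), each = 8), c(1, 4, 4))))
  q2 <- buildMaskQuartet(dis, 5, 5)
  expect_false(any(masks(q2)$mask3))
  expect_identical(masks(q2)$mask4, masks(q2)$mask2)
})

test_that("mask quartet equals the brute-force per-voxel oracle", {
  set.seed(21)
  for (i in 1:25) {
    fx <- randomSmallStack()
    s <- ImageStack(list(Cy5 = fx$cy5, Cy3 = fx$cy3))
    t5 <- sample(0:15, 1); t3 <- sample(0:15, 1)
    q <- buildMaskQuartet(s, t5, t3)
    o <- bruteForceQuartet(fx$cy5, fx$cy3, t5, t3)
    expect_identical(masks(q), o)
  }
})

test_that("mask3 and mask4 partition the mask2 intensity exactly", {
  set.seed(22)
  for (i in 1:10) {
    fx <- randomSmallStack()
    s <- ImageStack(list(Cy5 = fx$cy5, Cy3 = fx$cy3))
    q <- buildMaskQuartet(s, sample(0:15, 1), sample(0:15, 1))
    m <- masks(q)
    expect_identical(sum(fx$cy3[m$mask2]),
                     sum(fx$cy3[m$mask3]) + sum(fx$cy3[m$mask4]))
  }
})

test_that("hand-computed 1x2x2 example gives ratio 1", {
  s <- ImageStack(list(Cy5 = array(c(10, 0, 10, 0), c(1, 2, 2)),
                       Cy3 = array(c(0, 5, 0, 15), c(1, 2, 2))))
  r <- endocytosisRatio(s, cy5Threshold = 5, cy3Threshold = 5)
  expect_equal(r@cy5Integrated, 20)
  expect_equal(r@cy3Integrated, 20)
  expect_equal(endocytosisIndex(r), 1.0)
})

test_that("ratio errors when there is no surface signal", {
  s <- ImageStack(list(Cy5 = array(0, c(1, 2, 2)),
                       Cy3 = array(10, c(1, 2, 2))))
  expect_error(endocytosisRatio(s, cy5Threshold = 5, cy3Threshold = 5),
               "no surface signal")
})

test_that("ratio is invariant under common rescale, linear in Cy3 gain", {
  sim <- simulateCellStack(internalizedFraction = 0.4, noise = NULL, seed = 31)
  q <- buildMaskQuartet(sim$stack, 1e-9, 1e-9)
  r0 <- endocytosisIndex(endocytosisRatio(sim$stack, q))
  scaled <- ImageStack(lapply(sim$stack@channels, `*`, 3.7))
  # same masks survive a common positive rescale of the thresholds
  q2 <- buildMaskQuartet(scaled, 3.7e-9, 3.7e-9)
  expect_equal(endocytosisIndex(endocytosisRatio(scaled, q2)), r0,
               tolerance = 1e-12)
  cy3only <- sim$stack@channels
  cy3only$Cy3 <- cy3only$Cy3 * 2
  s3 <- ImageStack(cy3only)
  q3 <- buildMaskQuartet(s3, 1e-9, 2e-9)
  expect_equal(endocytosisIndex(endocytosisRatio(s3, q3)), 2 * r0,
               tolerance = 1e-12)
})

test_that("noise-free ratio recovers the internalized/surface budget", {
  sim <- simulateCellStack(internalizedFraction = 0.3,
                           surfaceCoplacement = 0, noise = NULL, seed = 32)
  r <- endocytosisIndex(endocytosisRatio(sim$stack, cy5Threshold = 1e-9,
                                         cy3Threshold = 1e-9))
  expect_equal(r, 0.3 / 0.7, tolerance = 0.02)
})

test_that("mean ratio increases with the internalized fraction under noise", {
  noisy <- list(photonScale = 1, readSd = 2)
  ratios <- sapply(c(0.25, 0.5), function(f) {
    mean(sapply(1:8, function(s) {
      sim <- simulateCellStack(internalizedFraction = f,
                               surfaceCoplacement = 0, noise = noisy,
                               seed = 700 + s)
      endocytosisIndex(endocytosisRatio(sim$stack, cy5Threshold = "otsu",
                                        cy3Threshold = "otsu"))
    }))
  })
  expect_gt(ratios[2], ratios[1])
})

test_that("linear kinetics fit recovers exact and degenerate lines", {
  f <- fitLinearKinetics(c(0, 60, 120), c(0, 1, 2))
  expect_equal(f@slope, 1 / 60)
  expect_equal(f@rSquared, 1)
  fc <- fitLinearKinetics(c(0, 30, 60, 90), rep(0.4, 4))
  expect_equal(fc@slope, 0)
  expect_error(fitLinearKinetics(c(0, 60), c(0, 1)), "3 distinct")
  expect_error(fitLinearKinetics(c(5, 5, 5), c(0, 1, 2)), "3 distinct")
})

test_that("noisy linear kinetics recover the slope on average", {
  times <- seq(0, 120, length.out = 9)
  slopes <- sapply(1:200, function(s) {
    withr::with_seed(s, {
      ratios <- 0.01 * times + rnorm(9, 0, 0.05)
      fitLinearKinetics(times, ratios)@slope
    })
  })
  expect_equal(mean(slopes), 0.01, tolerance = 0.05)
})
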