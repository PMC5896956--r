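noisy <- list(photonScale = 1, readSd = 2)

test_that("every generator is bit-reproducible under the same seed", {
  a <- simulateCellStack(internalizedFraction = 0.4, noise = noisy, seed = 9)
  b <- simulateCellStack(internalizedFraction = 0.4, noise = noisy, seed = 9)
  expect_identical(a$stack@channels, b$stack@channels)
  expect_identical(a$truth$endosomeCenters, b$truth$endosomeCenters)

  a <- simulateColocStack(overlapFraction = 0.5, noise = noisy, seed = 9)
  b <- simulateColocStack(overlapFraction = 0.5, noise = noisy, seed = 9)
  expect_identical(a$stack@channels, b$stack@channels)

  a <- simulateFretTriplet(noise = noisy, seed = 9)
  b <- simulateFretTriplet(noise = noisy, seed = 9)
  expect_identical(a$experiment@channels, b$experiment@channels)
  expect_identical(a$donorOnly@channels, b$donorOnly@channels)

  a <- simulateTirfMovie(nFrames = 5, nSpots = 8, seed = 9)
  b <- simulateTirfMovie(nFrames = 5, nSpots = 8, seed = 9)
  expect_identical(frames(a$movie), frames(b$movie))

  a <- simulateBindingDataset(noiseModel = "poisson", seed = 9)
  b <- simulateBindingDataset(noiseModel = "poisson", seed = 9)
  expect_identical(bindingPoints(a), bindingPoints(b))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(simulateCellStack(internalizedFraction = 0.3, seed = 5))
  expect_identical(runif(1), before)
})

test_that("cell-stack label budget is conserved through the blur", {
  sim <- simulateCellStack(internalizedFraction = 0.35,
                           surfaceCoplacement = 0.1, noise = NULL, seed = 2)
  for (ch in c("Cy5", "Cy3", "YFP"))
    expect_equal(sum(getChannel(sim$stack, ch)), sim$truth$placed[[ch]],
                 tolerance = 1e-6)
})

test_that("contradictory endosome parameters are rejected", {
  expect_error(simulateCellStack(internalizedFraction = 0, nEndosomes = 5),
               "contradictory")
  expect_error(simulateCellStack(internalizedFraction = 0.3, nEndosomes = 0),
               "contradictory")
  expect_error(simulateCellStack(internalizedFraction = 1.2, nEndosomes = 5),
               "internalizedFraction")
})

test_that("no internal label means the Cy3 channel carries only coplacement", {
  sim <- simulateCellStack(internalizedFraction = 0, nEndosomes = 0,
                           surfaceCoplacement = 0, noise = NULL, seed = 3)
  expect_true(all(getChannel(sim$stack, "Cy3") == 0))
  sim2 <- simulateCellStack(internalizedFraction = 0, nEndosomes = 0,
                            surfaceCoplacement = 0.2, noise = NULL, seed = 3)
  expect_gt(sum(getChannel(sim2$stack, "Cy3")), 0)
})

test_that("fully internalized label leaves an empty Cy5 channel", {
  sim <- simulateCellStack(internalizedFraction = 1, nEndosomes = 8,
                           surfaceCoplacement = 0, noise = NULL, seed = 4)
  expect_true(all(getChannel(sim$stack, "Cy5") == 0))
})

test_that("coloc generator respects overlap extremes", {
  sim1 <- simulateColocStack(overlapFraction = 1, noise = NULL, seed = 5)
  expect_equal(nrow(sim1$truth$loneYfpCenters), 0L)
  sim0 <- simulateColocStack(overlapFraction = 0, noise = NULL, seed = 5)
  expect_equal(nrow(sim0$truth$coCenters), 0L)
  # disjoint supports: YFP and TxR masks share no voxel at any threshold > 0
  yfp <- getChannel(sim0$stack, "YFP") > 0
  txr <- getChannel(sim0$stack, "TxR") > 0
  expect_false(any(yfp & txr))
  expect_error(simulateColocStack(overlapFraction = 1.5), "\\[0, 1]")
})

test_that("FRET triplet construction obeys the bleed-through law", {
  sim <- simulateFretTriplet(sensitizedLevel = 0, aDonor = 0.5,
                             bAcceptor = 0.3, noise = NULL, seed = 6)
  expect_equal(getChannel(sim$donorOnly, "FRET"),
               0.5 * getChannel(sim$donorOnly, "CFP"))
  expect_equal(getChannel(sim$acceptorOnly, "FRET"),
               0.3 * getChannel(sim$acceptorOnly, "YFP"))
  # with zero sensitized signal and zero coefficients: FRET channel is empty
  sim0 <- simulateFretTriplet(sensitizedLevel = 0, aDonor = 0,
                              bAcceptor = 0, noise = NULL, seed = 6)
  expect_true(all(getChannel(sim0$experiment, "FRET") == 0))
  expect_error(simulateFretTriplet(aDonor = -0.1), ">= 0")
})

test_that("TIRF truth tracks respect persistence and bounds", {
  sim <- simulateTirfMovie(nFrames = 20, nSpots = 12, persistentFraction = 1,
                           seed = 7)
  expect_true(all(vapply(sim$truth$tracks, `[[`, 0, "disappear") == 20))
  d <- dim(frames(sim$movie)[[1]])
  for (tr in sim$truth$tracks) {
    expect_gte(tr$disappear, tr$appear)
    expect_true(all(tr$positions[, 1] >= 1 & tr$positions[, 1] <= d[1]))
    expect_true(all(tr$positions[, 2] >= 1 & tr$positions[, 2] <= d[2]))
  }
  sim0 <- simulateTirfMovie(nFrames = 5, nSpots = 0, seed = 7)
  expect_length(sim0$truth$tracks, 0)
  expect_error(simulateTirfMovie(spotSigma = 0), "spotSigma")
})

test_that("binding generator matches the closed-form law", {
  tr <- list(kd = 15, bmax = 1000, nsSlope = 2)
  d <- simulateBindingDataset(tr, noiseModel = "none", replicates = 1)
  p <- bindingPoints(d)
  expect_equal(p$totalCounts - p$nonspecificCounts,
               1000 * p$concentration / (15 + p$concentration),
               tolerance = 1e-12)
  # half-saturation: at c = kd the specific part is bmax / 2
  dHalf <- simulateBindingDataset(tr, concentrations = 15,
                                  noiseModel = "none", replicates = 1)
  pH <- bindingPoints(dHalf)
  expect_equal(pH$totalCounts - pH$nonspecificCounts, 500)
  # zero nonspecific slope: nonspecific wells are exactly zero without noise
  d0 <- simulateBindingDataset(list(kd = 15, bmax = 1000, nsSlope = 0),
                               noiseModel = "none")
  expect_true(all(bindingPoints(d0)$nonspecificCounts == 0))
  expect_error(simulateBindingDataset(tr, concentrations = numeric(0)),
               "non-empty")
})
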