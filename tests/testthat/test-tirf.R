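test_that("assignment solver matches exhaustive permutation search", {
  set.seed(71)
  for (i in 1:40) {
    n <- sample(2:5, 1); m <- n + sample(0:2, 1)
    cost <- matrix(runif(n * m), n, m)
    a <- solveAssignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), bruteForceAssignment(cost),
                 tolerance = 1e-12)
    expect_false(anyDuplicated(a) > 0)
  }
  # tall problems leave surplus rows unassigned
  tall <- matrix(c(1, 100, 100, 1, 50, 50), 3, 2)
  sol <- solveAssignment(tall)
  expect_equal(sum(is.na(sol)), 1L)
})

mkBlobFrame <- function(nr, nc, positions, amp = 100, sigma = 1.2, bg = 0) {
  fr <- matrix(bg, nr, nc)
  for (k in seq_len(nrow(positions))) {
    p <- positions[k, ]
    ir <- max(1, floor(p[1]) - 5):min(nr, ceiling(p[1]) + 5)
    ic <- max(1, floor(p[2]) - 5):min(nc, ceiling(p[2]) + 5)
    fr[ir, ic] <- fr[ir, ic] + amp *
      exp(-outer((ir - p[1])^2, (ic - p[2])^2, `+`) / (2 * sigma^2))
  }
  fr
}

test_that("spot detection: blank frames, centroid accuracy, input checks", {
  expect_equal(nrow(detectSpots(matrix(0, 32, 32), threshold = 1)), 0L)
  fr <- mkBlobFrame(48, 48, matrix(c(20, 30), 1))
  sp <- detectSpots(fr, threshold = 1)
  expect_equal(nrow(sp), 1L)
  expect_lt(sqrt((sp$row - 20)^2 + (sp$col - 30)^2), 0.25)
  # sub-pixel truth position
  fr2 <- mkBlobFrame(48, 48, matrix(c(20.4, 30.7), 1))
  sp2 <- detectSpots(fr2, threshold = 1)
  expect_lt(sqrt((sp2$row - 20.4)^2 + (sp2$col - 30.7)^2), 0.25)
  expect_error(detectSpots(array(0, c(4, 4, 4))), "2D")
})

test_that("detection is translation-equivariant on noiseless frames", {
  pos <- matrix(c(15, 12, 30, 33, 22, 40), 3, 2, byrow = TRUE)
  fr <- mkBlobFrame(64, 64, pos)
  sp <- detectSpots(fr, threshold = 1)
  shifted <- mkBlobFrame(64, 64, pos + matrix(rep(c(3, 5), each = 3), 3))
  sp2 <- detectSpots(shifted, threshold = 1)
  ord <- order(sp$row); ord2 <- order(sp2$row)
  expect_equal(sp2$row[ord2], sp$row[ord] + 3, tolerance = 1e-6)
  expect_equal(sp2$col[ord2], sp$col[ord] + 5, tolerance = 1e-6)
})

test_that("pruning keeps the brighter of two close spots", {
  fr <- mkBlobFrame(48, 48, matrix(c(20, 20), 1), amp = 100) +
        mkBlobFrame(48, 48, matrix(c(22, 20), 1), amp = 50)
  sp <- detectSpots(fr, threshold = 1, minSeparation = 4)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$row - 20), 1)
})

test_that("detection on simulated frames reaches high recall and precision", {
  sim <- simulateTirfMovie(shape = c(128L, 128L), nFrames = 2, nSpots = 50,
                           persistentFraction = 1, minSeparation = 6,
                           seed = 72)
  truthPos <- t(vapply(sim$truth$tracks, function(tr) tr$positions[1, ],
                       c(0, 0)))
  sp <- detectSpots(frames(sim$movie)[[1]], "auto", minSeparation = 3,
                    spotSigma = 1.2)
  m <- matchSpots(sp, truthPos, radius = 2)
  expect_gte(m$matched / m$nTruth, 0.95)
  expect_gte(m$matched / m$nDetected, 0.95)
})

test_that("per-frame counts and percent-of-max normalization", {
  grid <- as.matrix(expand.grid(seq(10, 80, by = 14), seq(10, 80, by = 14)))
  mkF <- function(n) mkBlobFrame(96, 96, grid[seq_len(n), , drop = FALSE])
  movie <- TirfMovie(list(mkF(5), mkF(10), mkF(10)))
  tc <- countTimecourse(movie, threshold = 1)
  expect_equal(spotCounts(tc), c(5L, 10L, 10L))
  expect_equal(percentOfMax(tc), c(50, 100, 100))
  blank <- TirfMovie(list(matrix(0, 32, 32), matrix(0, 32, 32)))
  tc0 <- countTimecourse(blank, threshold = 1)
  expect_equal(spotCounts(tc0), c(0L, 0L))
  expect_equal(percentOfMax(tc0), c(0, 0))
  # percent-of-max invariant under uniform intensity rescaling
  movie2 <- TirfMovie(lapply(frames(movie), `*`, 4.2))
  tc2 <- countTimecourse(movie2, threshold = 4.2)
  expect_equal(percentOfMax(tc2), percentOfMax(tc))
})

test_that("linking resolves stationary, moving and gapped tracks", {
  still <- lapply(1:10, function(t)
    data.frame(row = c(10, 30), col = c(10, 30), intensity = 1))
  tr <- linkTracks(still, maxDisplacement = 3)
  expect_length(tr, 2L)
  expect_true(all(vapply(tr, nrow, 0L) == 10L))

  moving <- lapply(1:10, function(t)
    data.frame(row = 10, col = 10 + t, intensity = 1))
  tr2 <- linkTracks(moving, maxDisplacement = 3)
  expect_length(tr2, 1L)
  expect_equal(nrow(tr2[[1]]), 10L)

  gapped <- lapply(1:7, function(t)
    if (t == 4) data.frame(row = numeric(0), col = numeric(0),
                           intensity = numeric(0))
    else data.frame(row = 20, col = 20, intensity = 1))
  expect_length(linkTracks(gapped, maxDisplacement = 3, maxGap = 1), 1L)
  expect_length(linkTracks(gapped, maxDisplacement = 3, maxGap = 0), 2L)
})

test_that("linking conserves spots across tracks", {
  sim <- simulateTirfMovie(nFrames = 25, nSpots = 15,
                           persistentFraction = 0.4, seed = 73)
  spf <- lapply(frames(sim$movie), detectSpots, threshold = "auto",
                minSeparation = 3, spotSigma = 1.2)
  tracks <- linkTracks(spf, maxDisplacement = 4, maxGap = 1)
  expect_equal(sum(vapply(tracks, nrow, 0L)),
               sum(vapply(spf, nrow, 0L)))
  for (tr in tracks) expect_true(all(diff(tr$frame) >= 1))
})

test_that("ground-truth tracks are recovered without splits", {
  sim <- simulateTirfMovie(nFrames = 30, nSpots = 20, persistentFraction = 1,
                           diffusionStep = 0.5, minSeparation = 8, seed = 74)
  spf <- lapply(frames(sim$movie), detectSpots, threshold = "auto",
                minSeparation = 3, spotSigma = 1.2)
  tracks <- linkTracks(spf, maxDisplacement = 4, maxGap = 1)
  fullLength <- sum(vapply(tracks, function(tr)
    nrow(tr) == 30L, TRUE))
  expect_gte(fullLength / 20, 0.9)
})

test_that("persistence classification by duration", {
  mkTrack <- function(fr) data.frame(frame = fr, row = 1, col = 1,
                                     intensity = 1)
  allLong <- list(mkTrack(1:31), mkTrack(1:31))
  expect_equal(classifyPersistence(allLong, 2, 60), 1.0)
  allShort <- list(mkTrack(1:3), mkTrack(5:7))
  expect_equal(classifyPersistence(allShort, 2, 60), 0.0)
  expect_equal(classifyPersistence(c(allLong, allShort), 2, 60), 0.5)
  expect_error(classifyPersistence(list(), 2, 60), "no tracks")
  expect_error(classifyPersistence(allLong, 2, 61, movieDuration = 60),
               "exceeds")
})

test_that("kymograph renders stationary, transient and moving spots", {
  nFr <- 8
  framesL <- lapply(1:nFr, function(t) {
    fr <- mkBlobFrame(48, 48, matrix(c(24, 10 + 2 * t), 1))        # moving
    fr <- fr + mkBlobFrame(48, 48, matrix(c(24, 40), 1))           # still
    fr
  })
  movie <- TirfMovie(framesL)
  k <- kymograph(movie, c(24, 1), c(24, 48))
  expect_equal(dim(k), c(48L, nFr))
  # stationary spot: bright streak at the same row in every column
  expect_true(all(k[40, ] > 50))
  # moving spot: argmax advances ~2 px/frame
  sub <- k[1:30, ]
  am <- apply(sub, 2, which.max)
  slope <- coef(lm(am ~ seq_len(nFr)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.2)
  # transient spot: streak only during its presence
  fr2 <- lapply(1:6, function(t)
    if (t %in% 3:5) mkBlobFrame(32, 32, matrix(c(16, 16), 1))
    else matrix(0, 32, 32))
  k2 <- kymograph(TirfMovie(fr2), c(16, 1), c(16, 32))
  expect_true(all(k2[16, 3:5] > 50))
  expect_true(all(k2[16, c(1, 2, 6)] < 1e-6))
  expect_error(kymograph(movie, c(5, 5), c(5, 5)), "zero-length")
  expect_error(kymograph(movie, c(0, 1), c(5, 5)), "inside")
})
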