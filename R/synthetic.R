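#' @include io.R
NULL

## ---------------------------------------------------------------------------
## Synthetic ground-truth generators
##
## Each generator draws from a single explicitly seeded stream
## (withr::with_seed) and is a deterministic function of its arguments when
## noise is disabled (noise = NULL). Blurring uses finite-support kernels and
## all placed structures are kept >= one kernel radius away from the array
## edge, so placed intensity is conserved exactly by construction.
## ---------------------------------------------------------------------------

.applyNoise <- function(grid, noise) {
  if (is.null(noise)) return(grid)
  ps <- if (is.null(noise$photonScale)) 1 else noise$photonScale
  rsd <- if (is.null(noise$readSd)) 0 else noise$readSd
  out <- grid
  if (ps > 0)
    out <- array(stats::rpois(length(grid), ps * grid) / ps, dim(grid))
  if (rsd > 0)
    out <- out + array(stats::rnorm(length(grid), 0, rsd), dim(grid))
  pmax(out, 0)
}

## Truncated, normalized 3D Gaussian kernel (sum = 1).
.blobKernel <- function(sigma, sigmaZ = sigma, radius = ceiling(3 * sigma),
                        radiusZ = ceiling(3 * sigmaZ)) {
  kz <- exp(-(seq(-radiusZ, radiusZ))^2 / (2 * sigmaZ^2))
  kxy <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- outer(kz, outer(kxy, kxy))          # (z, y, x)
  k / sum(k)
}

## Add weight * kernel at integer voxel center; caller guarantees fit.
.addBlob <- function(grid, center, kernel, weight) {
  d <- dim(kernel)
  r <- (d - 1L) %/% 2L
  iz <- (center[1L] - r[1L]):(center[1L] + r[1L])
  iy <- (center[2L] - r[2L]):(center[2L] + r[2L])
  ix <- (center[3L] - r[3L]):(center[3L] + r[3L])
  grid[iz, iy, ix] <- grid[iz, iy, ix] + weight * kernel
  grid
}

.dilateAniso <- function(mask, radii) {
  d <- dim(mask)
  out <- mask
  for (axis in 1:3) {
    radius <- radii[axis]
    if (radius <= 0L) next
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

#' Simulate an antibody-uptake endocytosis stack
#'
#' Builds a three-channel confocal stack emulating the HA-antibody uptake
#' assay: an ellipsoidal-shell plasma membrane carries `1 - internalizedFraction`
#' of the label budget in the surface (Cy5) channel; Gaussian endosomal
#' puncta inside the cell carry `internalizedFraction` in the internalized
#' (Cy3) channel; a configurable fraction of the *surface* label is
#' additionally co-placed on membrane voxels in the Cy3 channel, emulating
#' incomplete Cy5 occupancy of surface antibody; the YFP channel carries the
#' total label. Channels are blurred with a truncated isotropic Gaussian PSF,
#' optionally Poisson-sampled and read-noise corrupted.
#'
#' Endosome centers are drawn only from voxels whose blurred support cannot
#' intersect the blurred membrane support, so with `surfaceCoplacement = 0`
#' and `noise = NULL` the Cy3/Cy5 mask ratio recovers
#' `internalizedFraction / (1 - internalizedFraction)` exactly (up to the
#' channel gain ratio).
#'
#' @param shape `(planes, rows, cols)`, each >= 8. The default 28-plane stack
#'   mirrors typical 15--30 plane confocal acquisitions.
#' @param internalizedFraction fraction of label intensity in endosomes,
#'   in `[0, 1]`.
#' @param nEndosomes number of endosomal puncta (>= 0). Contradictory
#'   combinations (`nEndosomes > 0` with `internalizedFraction = 0`, or
#'   vice versa) raise an error.
#' @param psfSigma lateral PSF sigma in voxels (> 0).
#' @param axialSigma axial PSF sigma in voxels; defaults to `psfSigma`.
#' @param endosomeSigma sigma of the Gaussian endosomal puncta, voxels.
#' @param surfaceCoplacement fraction of the surface label co-placed in the
#'   Cy3 channel on membrane voxels (incomplete-occupancy signal).
#' @param totalIntensity total label budget (a.l.u.f.i.).
#' @param channelGain named gains for `Cy5`, `Cy3`, `YFP`.
#' @param noise `NULL` for noiseless output, or
#'   `list(photonScale =, readSd =)`: intensities are scaled by
#'   `photonScale`, Poisson-sampled, rescaled, and Gaussian read noise of sd
#'   `readSd` is added (then clamped at 0).
#' @param seed integer seed for the generator's private RNG stream; `NULL`
#'   uses (and advances) the caller's stream.
#' @param voxelSize `(dz, dy, dx)` nm, recorded in the stack.
#' @return `list(stack = ImageStack with channels Cy5/Cy3/YFP, truth = list(
#'   internalizedFraction, endosomeCenters, membraneVoxels, placed))` where
#'   `placed` holds the exact pre-noise intensity placed per channel.
#' @examples
#' sim <- simulateCellStack(internalizedFraction = 0.4, seed = 1)
#' sim$truth$internalizedFraction
#' @export
simulateCellStack <- function(shape = c(28L, 72L, 72L),
                              internalizedFraction = 0.3,
                              nEndosomes = 12L,
                              psfSigma = 0.5, axialSigma = psfSigma,
                              endosomeSigma = 1.0,
                              surfaceCoplacement = 0,
                              totalIntensity = 2e5,
                              channelGain = c(Cy5 = 1, Cy3 = 1, YFP = 1),
                              noise = NULL, seed = NULL,
                              voxelSize = c(300, 120, 120)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("'shape' must be (planes, rows, cols), each >= 8")
  .assertScalar(internalizedFraction, "internalizedFraction", 0, 1)
  .assertScalar(surfaceCoplacement, "surfaceCoplacement", 0, 1)
  .assertScalar(psfSigma, "psfSigma", 0, Inf, strict = TRUE)
  if (nEndosomes > 0L && internalizedFraction == 0)
    stop("contradictory parameters: nEndosomes > 0 with internalizedFraction = 0")
  if (nEndosomes == 0L && internalizedFraction > 0)
    stop("contradictory parameters: internalizedFraction > 0 with no endosomes")
  .withSeed(seed, {
    rxy <- ceiling(4 * psfSigma)
    rz <- ceiling(4 * axialSigma)
    ctr <- (shape + 1) / 2
    semi <- c(ctr[1L] - rz - 1, ctr[2L] - rxy - 1, ctr[3L] - rxy - 1)
    if (any(semi < 2))
      stop("stack too small for the requested PSF: enlarge 'shape'")
    zz <- (seq_len(shape[1L]) - ctr[1L]) / semi[1L]
    yy <- (seq_len(shape[2L]) - ctr[2L]) / semi[2L]
    xx <- (seq_len(shape[3L]) - ctr[3L]) / semi[3L]
    rad2 <- outer(zz^2, outer(yy^2, xx^2, `+`), `+`)
    membrane <- rad2 >= 0.88^2 & rad2 <= 1
    memIdx <- which(membrane)
    if (length(memIdx) == 0L) stop("degenerate geometry: empty membrane shell")

    f <- internalizedFraction
    surfaceBudget <- (1 - f) * totalIntensity
    endoBudget <- f * totalIntensity
    coplacedBudget <- surfaceCoplacement * surfaceBudget

    cy5 <- array(0, shape)
    cy5[memIdx] <- surfaceBudget / length(memIdx)
    cy3 <- array(0, shape)
    cy3[memIdx] <- coplacedBudget / length(memIdx)

    centers <- NULL
    if (nEndosomes > 0L) {
      kern <- .blobKernel(endosomeSigma, endosomeSigma)
      re <- (dim(kern) - 1L) %/% 2L
      ## forbid endosome centers whose blurred support could touch the
      ## blurred membrane support or the array edge
      memSupport <- .dilateAniso(membrane, c(rz, rxy, rxy))
      forbid <- .dilateAniso(memSupport,
                             c(re[1L] + rz, re[2L] + rxy, re[3L] + rxy))
      inside <- rad2 <= 0.8^2 & !forbid
      bz <- re[1L] + rz + 1L; bxy <- re[2L] + rxy + 1L
      inside[c(seq_len(min(bz, shape[1L])),
               seq(max(1L, shape[1L] - bz + 1L), shape[1L])), , ] <- FALSE
      inside[, c(seq_len(bxy), seq(shape[2L] - bxy + 1L, shape[2L])), ] <- FALSE
      inside[, , c(seq_len(bxy), seq(shape[3L] - bxy + 1L, shape[3L]))] <- FALSE
      feasible <- which(inside)
      if (length(feasible) < nEndosomes)
        stop("stack too small to place ", nEndosomes,
             " endosomes clear of the membrane; enlarge 'shape'")
      sel <- sample(feasible, nEndosomes)
      centers <- arrayInd(sel, shape)
      colnames(centers) <- c("plane", "row", "col")
      w <- endoBudget / nEndosomes
      for (i in seq_len(nEndosomes))
        cy3 <- .addBlob(cy3, centers[i, ], kern, w)
    }
    yfp <- cy5 + cy3

    blur <- function(g) .gaussianBlur3d(g, sigmaXY = psfSigma,
                                        sigmaZ = axialSigma)
    chans <- list(Cy5 = channelGain[["Cy5"]] * blur(cy5),
                  Cy3 = channelGain[["Cy3"]] * blur(cy3),
                  YFP = channelGain[["YFP"]] * blur(yfp))
    chans <- lapply(chans, .applyNoise, noise = noise)
    truth <- list(
      internalizedFraction = f,
      overlapFraction = NA_real_,
      endosomeCenters = centers,
      membraneVoxels = arrayInd(memIdx, shape),
      placed = list(Cy5 = channelGain[["Cy5"]] * surfaceBudget,
                    Cy3 = channelGain[["Cy3"]] * (endoBudget + coplacedBudget),
                    YFP = channelGain[["YFP"]] * (totalIntensity + coplacedBudget)))
    list(stack = ImageStack(chans, voxelSize = voxelSize,
                            metadata = list(generator = "simulateCellStack")),
         truth = truth)
  })
}

#' Simulate a two-channel colocalization stack
#'
#' Places Gaussian puncta for a cargo channel (`TxR`, endosomal cargo) and a
#' protein channel (`YFP`) such that exactly `overlapFraction` of the total
#' YFP intensity falls on puncta co-centered with TxR puncta; the remaining
#' YFP puncta are placed with full blurred-support clearance from every TxR
#' punctum, so at `noise = NULL` the colocalized intensity fraction equals
#' `overlapFraction` exactly for any positive segmentation threshold.
#'
#' @param shape `(planes, rows, cols)`, each >= 8.
#' @param overlapFraction target fraction of YFP intensity on shared voxels,
#'   in `[0, 1]`.
#' @param nPuncta puncta per channel.
#' @param punctumSigma punctum Gaussian sigma, voxels.
#' @param psfSigma lateral/axial PSF sigma, voxels.
#' @param punctumIntensity total intensity per channel per punctum budget
#'   (a.l.u.f.i.); each channel's budget is `nPuncta * punctumIntensity`.
#' @param noise,seed,voxelSize as in [simulateCellStack()].
#' @return `list(stack = ImageStack with channels YFP/TxR, truth)`; `truth`
#'   records `overlapFraction` and the punctum centers per channel.
#' @examples
#' sim <- simulateColocStack(overlapFraction = 0.6, seed = 1)
#' sim$truth$overlapFraction
#' @export
simulateColocStack <- function(shape = c(20L, 96L, 96L), overlapFraction = 0.5,
                               nPuncta = 10L, punctumSigma = 1.0,
                               psfSigma = 0.6, punctumIntensity = 5000,
                               noise = NULL, seed = NULL,
                               voxelSize = c(300, 120, 120)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("'shape' must be (planes, rows, cols), each >= 8")
  if (overlapFraction < 0 || overlapFraction > 1)
    stop("'overlapFraction' must be in [0, 1] but is ", overlapFraction)
  if (nPuncta < 1L) stop("'nPuncta' must be >= 1")
  .withSeed(seed, {
    kern <- .blobKernel(punctumSigma, punctumSigma)
    re <- (dim(kern) - 1L) %/% 2L
    rpsf <- ceiling(4 * psfSigma)
    half <- re + rpsf                       # blurred punctum support half-width
    sep <- 2L * max(half) + 1L              # lateral clearance between centers
    margin <- half + 1L

    f <- overlapFraction
    nCo <- round(f * nPuncta)
    if (f > 0 && nCo == 0L) nCo <- 1L
    if (f < 1 && nCo == nPuncta) nCo <- nPuncta - 1L
    nDisjoint <- nPuncta - nCo
    nCenters <- nPuncta + nDisjoint         # TxR centers + lone YFP centers

    zr <- (margin[1L] + 1L):(shape[1L] - margin[1L])
    rr <- (margin[2L] + 1L):(shape[2L] - margin[2L])
    cr <- (margin[3L] + 1L):(shape[3L] - margin[3L])
    if (length(zr) < 1L || length(rr) < sep || length(cr) < sep)
      stop("stack too small for the punctum geometry; enlarge 'shape'")
    centers <- matrix(0L, nCenters, 3L,
                      dimnames = list(NULL, c("plane", "row", "col")))
    placed <- 0L
    tries <- 0L
    while (placed < nCenters) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("could not place ", nCenters, " puncta with clearance ", sep,
             "; reduce 'nPuncta' or enlarge 'shape'")
      cand <- c(sample(zr, 1L), sample(rr, 1L), sample(cr, 1L))
      ok <- placed == 0L ||
        all(pmax(abs(centers[seq_len(placed), 2L, drop = TRUE] - cand[2L]),
                 abs(centers[seq_len(placed), 3L, drop = TRUE] - cand[3L])) >= sep)
      if (ok) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }
    txrCenters <- centers[seq_len(nPuncta), , drop = FALSE]
    loneCenters <- if (nDisjoint > 0L)
      centers[nPuncta + seq_len(nDisjoint), , drop = FALSE]
    else matrix(0L, 0L, 3L)

    txr <- array(0, shape)
    for (i in seq_len(nPuncta))
      txr <- .addBlob(txr, txrCenters[i, ], kern, punctumIntensity)
    yfpBudget <- nPuncta * punctumIntensity
    yfp <- array(0, shape)
    if (nCo > 0L) {
      w <- f * yfpBudget / nCo
      for (i in seq_len(nCo)) yfp <- .addBlob(yfp, txrCenters[i, ], kern, w)
    }
    if (nDisjoint > 0L) {
      w <- (1 - f) * yfpBudget / nDisjoint
      for (i in seq_len(nDisjoint))
        yfp <- .addBlob(yfp, loneCenters[i, ], kern, w)
    }
    blur <- function(g) .gaussianBlur3d(g, sigmaXY = psfSigma,
                                        sigmaZ = psfSigma)
    chans <- lapply(list(YFP = blur(yfp), TxR = blur(txr)),
                    .applyNoise, noise = noise)
    truth <- list(overlapFraction = f,
                  coCenters = txrCenters[seq_len(nCo), , drop = FALSE],
                  loneYfpCenters = loneCenters, txrCenters = txrCenters)
    list(stack = ImageStack(chans, voxelSize = voxelSize,
                            metadata = list(generator = "simulateColocStack")),
         truth = truth)
  })
}

#' Simulate a three-cube FRET acquisition with single-label controls
#'
#' Builds the experiment stack (channels `CFP`, `YFP`, `FRET`) plus a
#' donor-only and an acceptor-only control stack sharing the same linear
#' bleed-through law. Before noise, the FRET channel is
#' `sensitized + aDonor * CFP + bAcceptor * YFP`; the controls carry one
#' fluorophore each. Donor and acceptor fields carry opposing linear
#' gradients across the cell so that the zero-intercept bleed-through
#' regression is well conditioned.
#'
#' @param shape `(planes, rows, cols)`.
#' @param sensitizedLevel scalar sensitized-emission intensity inside the
#'   cell region, or a full array of the stack shape.
#' @param aDonor,bAcceptor bleed-through coefficients (>= 0).
#' @param cfpLevel,yfpLevel mean fluorophore intensity inside the cell.
#' @param noise,seed,voxelSize as in [simulateCellStack()].
#' @return `list(experiment, donorOnly, acceptorOnly, truth)`; `truth` holds
#'   `aDonor`, `bAcceptor` and the noiseless `sensitized` grid.
#' @examples
#' sim <- simulateFretTriplet(aDonor = 0.6, bAcceptor = 0.25, seed = 1)
#' sim$truth$aDonor
#' @export
simulateFretTriplet <- function(shape = c(1L, 96L, 96L), sensitizedLevel = 60,
                                aDonor = 0.5, bAcceptor = 0.25,
                                cfpLevel = 600, yfpLevel = 600,
                                noise = NULL, seed = NULL,
                                voxelSize = c(300, 120, 120)) {
  shape <- as.integer(shape)
  if (aDonor < 0 || bAcceptor < 0)
    stop("bleed-through coefficients must be >= 0")
  .withSeed(seed, {
    ctr <- (shape + 1) / 2
    semi <- pmax(shape * 0.4, 1)
    zz <- (seq_len(shape[1L]) - ctr[1L]) / semi[1L]
    yy <- (seq_len(shape[2L]) - ctr[2L]) / semi[2L]
    xx <- (seq_len(shape[3L]) - ctr[3L]) / semi[3L]
    cell <- outer(zz^2, outer(yy^2, xx^2, `+`), `+`) <= 1
    gradX <- array(rep(0.5 + seq_len(shape[3L]) / shape[3L],
                       each = shape[1L] * shape[2L]), shape)
    gradY <- array(rep(rep(0.5 + seq_len(shape[2L]) / shape[2L],
                           each = shape[1L]), shape[3L]), shape)
    cfp <- cfpLevel * gradX * cell
    yfpF <- yfpLevel * gradY * cell
    sens <- if (is.array(sensitizedLevel)) {
      if (!identical(dim(sensitizedLevel), as.integer(shape)))
        stop("sensitized grid shape must match 'shape'")
      sensitizedLevel * cell
    } else {
      .assertScalar(sensitizedLevel, "sensitizedLevel", lower = 0)
      sensitizedLevel * cell
    }
    mkStack <- function(cfpG, yfpG, sensG, tag) {
      fret <- sensG + aDonor * cfpG + bAcceptor * yfpG
      chans <- lapply(list(CFP = cfpG, YFP = yfpG, FRET = fret),
                      .applyNoise, noise = noise)
      ImageStack(chans, voxelSize = voxelSize,
                 metadata = list(generator = "simulateFretTriplet",
                                 role = tag))
    }
    zeroes <- array(0, shape)
    list(experiment = mkStack(cfp, yfpF, sens, "experiment"),
         donorOnly = mkStack(cfp, zeroes, zeroes, "donor-only"),
         acceptorOnly = mkStack(zeroes, yfpF, zeroes, "acceptor-only"),
         truth = list(aDonor = aDonor, bAcceptor = bAcceptor,
                      sensitized = sens, cell = cell))
  })
}

#' Simulate a TIRF nanocluster movie with ground-truth tracks
#'
#' Diffraction-limited Gaussian spots on a constant background: a fraction of
#' spots is persistent (present from its appearance to the final frame),
#' the rest are transient with geometric lifetimes (memoryless, mean
#' `transientLifetime` frames). Per-frame positions follow a reflected
#' Gaussian random walk; initial positions keep a minimum mutual distance so
#' spots remain resolvable. Persistent spots appear at frame 1; transient
#' spots appear uniformly over the movie unless `appearanceFrames` overrides
#' the appearance schedule.
#'
#' @param shape `(rows, cols)` in pixels.
#' @param nFrames number of frames.
#' @param nSpots number of spots (>= 0).
#' @param persistentFraction fraction of persistent spots, in `[0, 1]`.
#' @param transientLifetime mean transient lifetime in frames.
#' @param spotSigma spot Gaussian sigma in px (> 0).
#' @param diffusionStep random-walk step sd in px/frame.
#' @param spotIntensity peak spot amplitude above background (a.l.u.f.i.).
#' @param background constant background level.
#' @param minSeparation minimum initial spot separation in px.
#' @param appearanceFrames optional integer vector (length `nSpots`) of
#'   appearance frames overriding the default schedule.
#' @param frameInterval minutes per frame; `pixelSize` nm.
#' @param noise `NULL`, or `list(photonScale =, readSd =)` as in
#'   [simulateCellStack()].
#' @param seed integer seed.
#' @return `list(movie = TirfMovie, truth = list(tracks, persistentFraction))`
#'   where each truth track is `list(appear, disappear, positions)` with a
#'   two-column `(row, col)` matrix of per-frame positions and
#'   `persistentFraction` is the realized persistent share.
#' @examples
#' sim <- simulateTirfMovie(nFrames = 10, nSpots = 5, seed = 1)
#' length(sim$truth$tracks)
#' @export
simulateTirfMovie <- function(shape = c(96L, 96L), nFrames = 60L,
                              nSpots = 30L, persistentFraction = 0.35,
                              transientLifetime = 5, spotSigma = 1.2,
                              diffusionStep = 0.3, spotIntensity = 100,
                              background = 25, minSeparation = 6,
                              appearanceFrames = NULL,
                              frameInterval = 2, pixelSize = 120,
                              noise = list(photonScale = 1, readSd = 2),
                              seed = NULL) {
  shape <- as.integer(shape)
  .assertScalar(persistentFraction, "persistentFraction", 0, 1)
  .assertScalar(spotSigma, "spotSigma", 0, Inf, strict = TRUE)
  if (nSpots < 0L) stop("'nSpots' must be >= 0")
  .withSeed(seed, {
    margin <- ceiling(3 * spotSigma) + 2
    lo <- margin + 1
    hiR <- shape[1L] - margin
    hiC <- shape[2L] - margin
    nPersistent <- round(persistentFraction * nSpots)

    tracks <- list()
    if (nSpots > 0L) {
      ## initial positions with minimum mutual distance (rejection sampling)
      pos <- matrix(0, nSpots, 2L)
      placed <- 0L
      tries <- 0L
      while (placed < nSpots) {
        tries <- tries + 1L
        if (tries > 50000L)
          stop("could not place ", nSpots, " spots with separation ",
               minSeparation, "; enlarge 'shape'")
        cand <- c(stats::runif(1, lo, hiR), stats::runif(1, lo, hiC))
        if (placed == 0L ||
            min(sqrt((pos[seq_len(placed), 1L] - cand[1L])^2 +
                     (pos[seq_len(placed), 2L] - cand[2L])^2)) >= minSeparation) {
          placed <- placed + 1L
          pos[placed, ] <- cand
        }
      }
      appear <- if (!is.null(appearanceFrames)) {
        stopifnot(length(appearanceFrames) == nSpots)
        as.integer(appearanceFrames)
      } else {
        c(rep(1L, nPersistent),
          if (nSpots > nPersistent)
            sample.int(nFrames, nSpots - nPersistent, replace = TRUE))
      }
      for (i in seq_len(nSpots)) {
        persistent <- i <= nPersistent
        a <- min(max(appear[i], 1L), nFrames)
        dis <- if (persistent) nFrames
               else min(nFrames,
                        a + stats::rgeom(1L, 1 / max(transientLifetime, 1)))
        nAct <- dis - a + 1L
        p <- matrix(0, nAct, 2L)
        p[1L, ] <- pos[i, ]
        if (nAct > 1L) for (t in 2:nAct) {
          step <- stats::rnorm(2L, 0, diffusionStep)
          nxt <- p[t - 1L, ] + step
          nxt[1L] <- min(max(nxt[1L], lo), hiR)
          nxt[2L] <- min(max(nxt[2L], lo), hiC)
          p[t, ] <- nxt
        }
        colnames(p) <- c("row", "col")
        tracks[[i]] <- list(appear = a, disappear = dis, positions = p,
                            persistent = persistent)
      }
    }

    rad <- ceiling(3 * spotSigma)
    framesL <- vector("list", nFrames)
    for (t in seq_len(nFrames)) {
      fr <- matrix(background, shape[1L], shape[2L])
      for (tr in tracks) {
        if (t < tr$appear || t > tr$disappear) next
        p <- tr$positions[t - tr$appear + 1L, ]
        ir <- max(1L, floor(p[1L]) - rad):min(shape[1L], ceiling(p[1L]) + rad)
        ic <- max(1L, floor(p[2L]) - rad):min(shape[2L], ceiling(p[2L]) + rad)
        blob <- spotIntensity *
          exp(-outer((ir - p[1L])^2, (ic - p[2L])^2, `+`) / (2 * spotSigma^2))
        fr[ir, ic] <- fr[ir, ic] + blob
      }
      if (!is.null(noise)) {
        a <- .applyNoise(array(fr, c(1L, dim(fr))), noise)
        fr <- matrix(a, dim(fr)[1L], dim(fr)[2L])
      }
      framesL[[t]] <- fr
    }
    truth <- list(tracks = tracks,
                  persistentFraction = if (nSpots > 0L) nPersistent / nSpots
                                       else NA_real_)
    list(movie = TirfMovie(framesL, frameInterval = frameInterval,
                           pixelSize = pixelSize),
         truth = truth)
  })
}

#' Simulate a saturation radioligand-binding dataset
#'
#' Total bound counts per well follow `Bmax * c / (K_D + c) + nsSlope * c`
#' plus noise; paired nonspecific wells (binding in the presence of a
#' saturating unlabeled competitor) follow `nsSlope * c` plus noise. The
#' default concentration series is the six-point 4.12--101 nM design of the
#' CFT saturation assay.
#'
#' @param truth `list(kd =, bmax =, nsSlope =)`: dissociation constant (nM),
#'   maximal specific binding (counts) and linear nonspecific slope
#'   (counts/nM); `kd` and `bmax` must be positive, `nsSlope >= 0`.
#' @param concentrations ligand concentrations in nM (all > 0, non-empty).
#' @param replicates number of replicate experiments (>= 1).
#' @param noiseModel `"none"`, `"poisson"`, or `"gaussian-cv"` (sd =
#'   `cv * mean`).
#' @param cv coefficient of variation for `"gaussian-cv"`.
#' @param condition condition label stored in the dataset.
#' @param seed integer seed.
#' @return A [BindingDataset].
#' @examples
#' d <- simulateBindingDataset(list(kd = 15, bmax = 1000, nsSlope = 2),
#'                             noiseModel = "none")
#' bindingPoints(d)[1:3, ]
#' @export
simulateBindingDataset <- function(truth = list(kd = 15, bmax = 1000,
                                                nsSlope = 2),
                                   concentrations = c(4.12, 7.25, 13.5, 26,
                                                      51, 101),
                                   replicates = 3L,
                                   noiseModel = c("none", "poisson",
                                                  "gaussian-cv"),
                                   cv = 0.05, condition = "synthetic",
                                   seed = NULL) {
  noiseModel <- match.arg(noiseModel)
  if (length(concentrations) == 0L)
    stop("'concentrations' must be a non-empty vector of nM values")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (replicates < 1L) stop("'replicates' must be >= 1")
  if (truth$kd <= 0 || truth$bmax <= 0 || truth$nsSlope < 0)
    stop("'truth' requires kd > 0, bmax > 0, nsSlope >= 0")
  .withSeed(seed, {
    rows <- expand.grid(replicate = seq_len(replicates),
                        concentration = concentrations)
    cc <- rows$concentration
    specMean <- truth$bmax * cc / (truth$kd + cc)
    nsMean <- truth$nsSlope * cc
    addNoise <- function(mu) switch(noiseModel,
      none = mu,
      poisson = stats::rpois(length(mu), mu),
      `gaussian-cv` = pmax(mu + stats::rnorm(length(mu), 0, cv * mu), 0))
    BindingDataset(
      data.frame(concentration = cc,
                 totalCounts = addNoise(specMean + nsMean),
                 nonspecificCounts = addNoise(nsMean),
                 replicate = rows$replicate),
      condition = condition)
  })
}
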