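---
title: "Quantifying membrane-transporter trafficking with EndoQuant"
author: "EndoQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-transporter trafficking with EndoQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EndoQuant)
```

EndoQuant implements five quantification procedures used to study the
endocytosis and clustering of plasma-membrane transporters (the motivating
system is the dopamine transporter, DAT, whose surface level drops sharply
when small molecules induce its oligomerization and internalization), plus
synthetic-data generators that make each procedure verifiable end to end.
This vignette is the package's account of the underlying models, the
tunable parameters, the numerical choices, and the limits of what the
synthetic benchmarks demonstrate.

## Data model and conventions

All confocal data live in an `ImageStack`: named channels, each a 3D array
in `(plane, row, col)` order with a `(dz, dy, dx)` voxel size in nm
(defaults 300 × 120 × 120 nm, matching spinning-disk acquisitions of 15–30
planes at 200–400 nm spacing). TIRF movies live in a `TirfMovie` (2D
frames, a frame interval in minutes, pixel size in nm). Indexing is
**1-based** throughout, the R convention; positions returned by the spot
detector are sub-pixel but on the same 1-based grid. Intensities are
arbitrary linear units (a.l.u.f.i.); nothing in the package assumes a
camera calibration.

Background subtraction (`subtractBackground`) precedes all mask
quantification. The acquisition protocol behind these assays records that
backgrounds were subtracted but not how, so the rule is exposed: the
default estimates a per-channel offset as the modal intensity of the first
plane (typically off-cell), with constant and percentile alternatives.
Post-subtraction negatives are clamped to 0 because the mask intensity
sums must stay non-negative.

## The antibody-uptake endocytosis assay

Surface transporter is labeled with a primary antibody before
permeabilization and stained with Cy5; internalized antibody is stained
with Cy3 after permeabilization. Four masks are built from thresholded
channels:

* Mask #1 — Cy5 ≥ t₅ (total surface transporter),
* Mask #2 — Cy3 ≥ t₃ (raw internalized signal),
* Mask #3 — Mask #2 ∧ Mask #1 (Cy3 on Cy5-positive voxels: antibody bound
  to surface transporter because Cy5 staining never saturates every
  epitope),
* Mask #4 — Mask #2 ∖ Mask #3 (corrected internalized signal).

The readout is `sum(Cy3 over #4) / sum(Cy5 over #1)`. Choices made where
the assay description is open:

* **Threshold inclusivity.** Voxels exactly at the threshold are included
  (`≥`): the thresholds are "minimal intensities" of genuine staining, so
  a voxel at the minimum is signal.
* **Manual vs automated thresholds.** The original analyses picked
  thresholds per experiment by eye. The package accepts explicit scalars
  and offers Otsu's method (computed on the 256-bin histogram of nonzero
  voxels) as the automated default for synthetic work. When an empty
  channel is possible — e.g. a time-zero point with no internalized label —
  a fixed minimal threshold above the noise floor (about 5× the read-noise
  sd) should be used for that channel across the whole series, since Otsu
  on a signal-free channel splits noise.
* **Per-image quantification.** The ratio is computed over the whole field
  (typically several cells), not per cell; no instance segmentation.
* **Mask #3 overlap rule.** The overlap is voxelwise with no dilation by
  default; a Chebyshev dilation radius is available because chromatic
  offset between far-red and red channels is real but unspecified.

Mask #3 and #4 partition Mask #2 by construction, so
`sum(Cy3, #2) = sum(Cy3, #3) + sum(Cy3, #4)` holds exactly — this identity
and exact agreement with brute-force per-voxel loops are tested
properties, not approximations.

`fitLinearKinetics` fits ratio-versus-time by OLS and reports R², the
linearity coefficient: drug-induced transporter endocytosis follows linear
kinetics over at least two hours, and R² close to 1 is the quantitative
form of that statement. For a constant series the line fits perfectly, so
R² is reported as 1 with slope 0.

## Colocalization

`colocalizedFraction` computes the intensity-weighted fraction of
channel-A mask intensity inside the channel-B mask, plus total channel-B
uptake. The measure is intentionally asymmetric (fraction of transporter
in cargo-positive endosomes, not vice versa). Because the cargo is
punctate, channel-B components smaller than `minObjectSize` voxels
(default 2, 6-connectivity) are discarded as single-voxel noise. The
original workflow deconvolved these stacks before segmentation;
deconvolution is out of scope here, and an optional Gaussian high-pass
prefilter (off by default) stands in for punctum enhancement when needed.
Results on real data will depend on that difference; the synthetic tests
do not exercise deconvolution at all.

## Sensitized-emission FRET

The three-cube correction assumes the FRET-filter image is a linear
mixture: sensitized emission plus bleed-through `a` from the donor channel
and `b` from the acceptor channel. The assay description names the two
single-fluorophore controls but not an explicit formula; the standard
two-coefficient correction FRET^C = I_FRET − a·I_CFP − b·I_YFP is adopted,
with no direct-excitation cross-terms (those cannot be identified from two
controls). Numerical choices:

* The bleed-through regression is **through the origin** on
  background-subtracted pixels at or above `minIntensity`; an intercept
  would absorb residual offset ambiguously. At least 50 signal pixels are
  required (configurable floor); a negative slope is clamped to 0 with a
  warning.
* FRET^C retains negative pixel values so that ROI means stay unbiased.
* FRETN = mean(FRET^C)/(mean(YFP)·mean(CFP)) has reciprocal-intensity
  units that depend on acquisition settings; only within-experiment
  comparisons are supported.
* ROIs with donor:acceptor stoichiometry above 3 are flagged and excluded
  from all group statistics, because FRETN is non-linear when either
  fluorophore is in large excess. ROI selection itself is explicit — the
  caller supplies boxes or masks; there is no automated "structure
  finding", which in the original workflow was manual.

Group comparisons use unpaired two-tailed Welch t-tests on included ROIs.

## TIRF nanocluster analysis

Detection: frames are band-passed with a difference of Gaussians (sigmas
`spotSigma` and 1.6·`spotSigma`, the standard blob-detection ratio), local
maxima above a threshold are pruned greedily so no two accepted spots are
closer than `minSeparation` px (brighter wins; exact ties resolved in
row-major order, making detection deterministic), and positions are
refined by intensity-weighted centroid. The automatic threshold is
`median + 7·mad` of the band-passed frame: diffraction-limited spots
occupy a small area, so median and mad estimate the noise floor robustly,
and seven robust sigmas keeps the false-positive rate per frame near zero
— important because every false positive becomes a one-frame track that
dilutes the persistent fraction. The commercial trackers used in the
original experiments required manually confirmed thresholds; this rule is
a reimplementation, not a clone, and parity with their absolute counts is
not claimed.

Linking: per frame pair, optimal bipartite assignment (a Hungarian solver,
written for this package and tested against exhaustive permutation search)
minimizes total squared displacement among pairings within
`maxDisplacement` px; unmatched spots start new tracks; tracks may bridge
up to `maxGap = 1` missing frames (blinking/noise robustness at 1–2 min
frame intervals), with the gate scaled by the elapsed frames.

Persistence is operationalized purely by track duration —
`(last − first) × frameInterval ≥ cutoff`, e.g. 60 min for "persisted for
more than 1 hr" — not by displacement, since long-lived and immobile
clusters coincide in this system; a displacement gate can be layered on by
filtering the returned tracks. `percentOfMax` normalizes per-frame counts
to the movie maximum, the usual presentation of cluster-formation
timecourses.

Kymographs sample intensity bilinearly at unit spacing along a line,
taking the maximum over a perpendicular width, one column per frame.

## Saturation binding

Specific binding is computed by subtraction (total − replicate-matched
nonspecific, the latter measured in the presence of a saturating
competitor such as 20 µM cocaine), and B(c) = Bmax·c/(K_D + c) is fit by
Levenberg–Marquardt least squares. Negative specific values are retained;
clamping them would bias the fit upward at low concentrations.
Initialization uses Bmax₀ = max specific count and K_D₀ = the
concentration nearest half of Bmax₀; tolerances are 1e-10 on parameters
with at most 500 iterations, and standard errors come from the
Jacobian-based covariance. The fit is unweighted by default — matching the
standard-package workflow these assays used — with an optional
Poisson-variance weighting. Joint fitting of total = specific + ns·c is
statistically preferable but is not the described procedure, so
subtraction is the default path. Each replicate experiment is fit
separately and conditions are compared by paired two-tailed t-tests across
replicates (the assays were run as paired vehicle/drug experiments), with
percent change in mean Bmax as the effect size.

## The synthetic generators

Each generator draws from a single explicitly seeded stream and is a
deterministic function of its parameters when noise is disabled — both are
tested contracts. The optical model is deliberately minimal: a truncated
isotropic Gaussian PSF (separate axial sigma), Poisson photon noise after
an intensity scaling, and Gaussian read noise. No vectorial PSF, no
evanescent-field depth profile, no photobleaching, no cell-shape realism.
Passing the recovery benchmarks therefore demonstrates that the *mask
arithmetic, correction formulas, estimators and trackers* are correct
under known ground truth — not that the pipeline is robust to the optics
of any particular microscope.

Key constructions:

* **Cell stacks** (`simulateCellStack`): an ellipsoidal-shell membrane
  carries `1 − f` of the label budget (Cy5), Gaussian endosomal puncta
  carry `f` (Cy3), YFP carries the total. Endosome centers are sampled
  only from voxels whose blurred support provably cannot touch the blurred
  membrane support (finite kernels make this an exact box computation), so
  with no noise and no coplacement the mask ratio equals `f/(1 − f)`
  exactly — the oracle behind the 2% recovery benchmark. A configurable
  fraction of the *surface* label is co-placed in Cy3 on membrane voxels
  to emulate incomplete Cy5 occupancy. Defaults: 28 × 72 × 72 voxels,
  12 endosomes of sigma 1 voxel, PSF sigma 0.5 voxels, total budget 2×10⁵.
* **Colocalization stacks** (`simulateColocStack`): cargo puncta plus
  protein puncta either exactly co-centered or placed with full
  blurred-support clearance, so the colocalized intensity fraction equals
  `overlapFraction` exactly in the noiseless limit for any positive
  threshold.
* **FRET triplets** (`simulateFretTriplet`): donor and acceptor fields
  with opposing linear gradients across an elliptical cell (making the
  zero-intercept regression well conditioned), FRET channel assembled from
  the bleed-through law plus a sensitized grid; matching donor-only and
  acceptor-only controls.
* **TIRF movies** (`simulateTirfMovie`): persistent spots span appearance
  to the final frame; transient lifetimes are geometric (a memoryless
  stand-in — the real lifetime distribution of short-lived clusters is
  unknown); positions follow a reflected Gaussian random walk with
  minimum initial separation. Default amplitude 100 over background 25
  with read noise 2 gives a peak SNR near 19, representative of bright
  YFP clusters in TIRF and comfortably above the detector's threshold
  margin.
* **Binding datasets** (`simulateBindingDataset`): the six-concentration
  design 4.12, 7.25, 13.5, 26, 51, 101 nM by default, with Poisson or
  constant-CV Gaussian noise on total and nonspecific wells.

## Problem sizes and verification scope

The shipped test-suite benchmarks run at desk scale, chosen so the whole
suite completes in a few minutes: 500 random stacks up to 16 × 16 × 4 for
the exact mask-arithmetic oracle; 20 seeds per overlap level for
colocalization (±0.05 recovery); 20 seeds for FRET (coefficients ±0.02,
noiseless FRET^C to 1e-9, ROI FRETN within 10%, zero-sensitized FRETN
indistinguishable from 0); 10 seeds per persistence level for TIRF
(±0.05); 200 Poisson datasets for the binding fits (median K_D error
≤ 10%, Bmax ≤ 5%) and Bmax reductions of 10–40% recovered within 5
percentage points. The headline experimental observations this pipeline is
designed to produce — strong surface down-regulation, roughly a third of
nanoclusters persisting beyond an hour, a ~26% Bmax decrease with
unchanged K_D — arise from experimental material that is not distributed
with the package, so the benchmarks exercise the *procedures* on simulated
ground truth rather than reproducing those numbers from raw data.

## Known limitations

* No deconvolution, registration, or chromatic-offset correction; the
  dilation option in the mask overlap is a blunt instrument.
* Bleed-through coefficients are assumed constant across the field;
  spatially varying spectral response is not modeled.
* The tracker has no motion model beyond the displacement gate; heavily
  crowded fields (spacings at or below the PSF) will merge detections by
  design of the pruning step.
* TIFF I/O is 16-bit integer; higher-bit-depth or proprietary microscope
  formats (.sld, .nd2) must be converted externally.
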