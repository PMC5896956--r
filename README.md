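# EndoQuant

Quantitative analysis of fluorescence-microscopy assays of plasma-membrane
transporter trafficking, built around the assays used to characterize
drug-induced endocytosis and oligomerization of the dopamine transporter
(DAT): the four-mask antibody-uptake internalization assay, voxel-mask
endosomal colocalization, sensitized-emission FRET with normalized FRET
(FRETN), TIRF nanocluster counting/tracking/persistence, and saturation
radioligand-binding (K\_D/Bmax) estimation. Every stage ships with a
ground-truth-annotated synthetic-data generator, so the full pipeline is
testable without any experimental images.

It is intended for cell biologists quantifying membrane-protein
internalization and clustering from multichannel confocal stacks, TIRF
time-lapse movies, and radioligand count data.

## The quantities the package computes

**Antibody-uptake endocytosis (Cy3/Cy5 ratio).** Surface transporter is
stained before permeabilization (Cy5), internalized transporter after
(Cy3). Background-subtracted 3D stacks are thresholded into Mask #1
(surface, Cy5) and Mask #2 (raw internalized, Cy3); Mask #3 = #2 ∧ #1
captures Cy3 bound to *surface* transporter through incomplete Cy5
occupancy, and Mask #4 = #2 ∖ #3 is the corrected internalized signal. The
extent of endocytosis is the ratio of integrated intensities

    ratio = Σ Cy3 over Mask#4 / Σ Cy5 over Mask#1

in arbitrary linear units of fluorescence intensity (a.l.u.f.i.).
Time-courses are fit by ordinary least squares with R² as the linearity
coefficient.

**Colocalization.** The fraction of a protein's mask intensity residing in
cargo-positive voxels, Σ\_A(#1 ∧ #2) / Σ\_A(#1) — an intensity-weighted
Manders-style coefficient, deliberately asymmetric in the two channels —
plus the total cargo uptake Σ\_B(#2).

**Sensitized-emission FRET.** With bleed-through coefficients *a* (donor →
FRET channel) and *b* (acceptor → FRET channel) estimated from
single-fluorophore control cells by zero-intercept regression, the
corrected FRET image is FRET^C = I\_FRET − a·I\_CFP − b·I\_YFP per pixel,
and per region of interest

    FRETN = mean(FRET^C) / (mean(YFP) × mean(CFP))

computed only where the donor:acceptor stoichiometry
max(CFP, YFP)/min(CFP, YFP) ≤ 3 (outside that range FRETN is non-linear in
the fluorophore excess and the ROI is excluded).

**TIRF nanoclusters.** Diffraction-limited spots are detected per frame as
local maxima of a difference-of-Gaussians band-pass, counted (and expressed
as percent of the per-movie maximum), linked into tracks by optimal
bipartite assignment with a displacement gate and gap bridging, and
classified as persistent when the track duration reaches a cutoff (e.g.
>1 hr). Kymographs are extracted along arbitrary lines.

**Saturation binding.** Specific binding (total − nonspecific, the latter
measured with a saturating unlabeled competitor) is fit by nonlinear least
squares to B(c) = Bmax·c/(K\_D + c); conditions are compared by paired
t-tests on per-replicate Bmax and K\_D with the percent change in mean
Bmax.

## Worked example

```r
library(EndoQuant)

# a synthetic antibody-uptake stack: 40% of the label internalized
sim   <- simulateCellStack(internalizedFraction = 0.4,
                           noise = list(photonScale = 1, readSd = 2),
                           seed = 17)
stack <- subtractBackground(sim$stack, "modal")
q     <- buildMaskQuartet(stack, "otsu", "otsu")
q
#> MaskQuartet on 28 x 72 x 72 voxels
#>   mask1 (surface Cy5):        13801 voxels (threshold 4.563)
#>   mask2 (raw internalized):   259 voxels (threshold 97.03)
#>   mask3 (surface-overlap):    3 voxels
#>   mask4 (corr. internalized): 256 voxels
endocytosisRatio(stack, q)
#> EndocytosisResult (a.l.u.f.i.)
#>   surface Cy5 (mask1):      103452
#>   internalized Cy3 (mask4): 49587.5
#>   Cy3/Cy5 ratio:            0.479331
```

The ratio approximates the internalized/surface label odds 0.4/0.6 ≈ 0.67
scaled by what the thresholds retain of each channel; with noise disabled
and thresholds near zero it recovers 2/3 to machine precision (that exact
recovery is a tested contract of the generator).

```r
d <- simulateBindingDataset(list(kd = 15, bmax = 1000, nsSlope = 2),
                            replicates = 3, noiseModel = "poisson", seed = 17)
fitSaturation(d)
#> SaturationFit: K_D = 15.05 +/- 0.608 nM, Bmax = 1024.3 +/- 13.8
```

Here the six-concentration design (4.12–101 nM) with Poisson counting
noise returns the dissociation constant within its standard error.

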