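---
title: "Quantifying amyloid plaques and plaque-associated microglia: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid plaques and plaque-associated microglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyquant)
```

## The problem

Mouse models of amyloid pathology are characterised histologically: how much
of the cortex is covered by amyloid-beta plaques, how many microglia sit
around those plaques, how activated they are, and how much amyloid they have
taken up. `amyquant` implements that quantification chain for multichannel
fluorescence sections (DAPI, 4G8, Iba1, Clec7a, BACE1, pFTAA), from raw
pixels to group-level statistics, together with a fully ground-truthed
synthetic-cohort generator so that every stage can be validated without
animal data.

## The segmentation model

Nuclei are segmented from the DAPI channel by Gaussian blur (sigma 0.72 um),
Otsu thresholding, and watershed segmentation of the Euclidean distance map
of the binary foreground; plaques from the 4G8 channel by Gaussian blur
(sigma 7.2 um), Otsu thresholding and 8-connected component labelling, after
which only objects whose area strictly exceeds 720 um^2 count as plaques.
All physical parameters are converted to pixels at run time from the
section's `pixel_size_um`, so the pipeline is resolution-independent, and
intensities are never rescaled (thresholding and mean-intensity measures are
scale-covariant).

Our Otsu implementation searches every distinct observed value and returns
the between-class-variance maximiser exactly (ties resolve to the lowest
candidate; an all-constant input returns that constant, so the foreground is
empty). This makes the threshold testable against a brute-force oracle, and
it is how the per-image Iba1 positivity call is made as well: the threshold
is computed on the vector of per-cell mean intensities of one image, and
only cells strictly above it are analysed further.

Design choices the operators leave open, fixed here for reproducibility:

* Component labelling uses 8-connectivity; region labels are numbered by
  raster order of each region's first pixel.
* The watershed is `EBImage::watershed` on the distance map, with the
  tolerance tied to the nucleus blur sigma in pixels — shallow saddles
  within one nucleus do not split it, while the saddle between two
  blur-merged nuclei does.
* Gaussian blurring uses replicate padding at the image border, so the
  effect of the boundary is confined to a band of about 3 sigma.
* The area filter is a strict inequality: a region of exactly 720 um^2 is
  discarded.

## Per-cell measurements

Expression of Iba1 and Clec7a is the mean intensity over exactly the pixels
of each segmented nuclear region. The distance from a cell to a plaque is
measured from the nucleus centre of mass to the nearest plaque *border*
pixel (a plaque pixel with a background 4-neighbour); a cell whose centre
lies inside a plaque has distance 0. Cells within 30 um of a border
(inclusive) are plaque-associated. The per-image associated-cell count is
normalised per cell by the area of that cell's nearest plaque, giving
cells per um^2 of plaque.

Radial intensity profiles are computed around the nucleus centre of mass in
annular bins (defaults: 0.5 um bins to 20 um; both are configuration keys,
since the acquisition itself does not fix them); bins with no pixels are
dropped, and normalised profiles divide by their own integral so they pool
across images. Clec7a histograms are binned image-wise on shared edges (by
default 20 bins spanning the pooled 1st-99th percentile of the analysed
cells of the run) and integral-normalised the same way.

## Pooling and statistics

All image-level metrics (scalars and curves alike) are pooled by taking the
median over each animal's images, then the mean and SEM (sd/sqrt(n), n =
animals) across the animals of a group. The statistics layer provides the
two-tailed unpaired Student t-test (a Welch option exists but is off by
default), per-bin Bonferroni correction for curve comparisons, Pearson
correlation with the t-transform p-value, one-way ANOVA with Tukey HSD, and
iterative two-sided Grubbs outlier removal at alpha = 0.05 per iteration.
Significance is starred at 0.05/0.01/0.001. The pooling deliberately
reproduces the median-then-mean rule rather than fitting a hierarchical
model; images within an animal are not treated as independent replicates
anywhere.

## The area-ratio workflow and QC

For BACE1/4G8 co-stained sections, each channel gets one fixed run-wide
threshold, `pooled mean + k * pooled SD` over all pixels of all analysed
images of that channel (k = 2 by default and recorded in the output
provenance; the conversion to greyscale is a deterministic percentile
stretch with no lossy re-encoding). The per-image readout is the stained
pixel fraction of BACE1 normalised to the stained fraction of 4G8 of the
same image; per-animal medians and group mean/SEM follow the common pooling
rule. Before the ratio is computed, image QC excludes any image whose
per-channel mean or variance falls outside mean +/- 2 SD of (i) the other
images of the same animal or (ii) the other images of the same group.
The band is inclusive and the comparison statistics are leave-one-out, so
an extreme image cannot mask itself; comparison sets smaller than 3 skip QC.
The expected false-exclusion rate of a 2 SD band is about 5% per feature
per comparison set; with several features the overall exclusion proportion
is correspondingly higher and data-dependent.

The pFTAA-style cortical burden readout applies one shared threshold to
every section and reports the percent of above-threshold pixels inside a
cortical ROI polygon. The pipeline also computes this shared-threshold
stained fraction for the 4G8 channel of every image
(`g8_stained_fraction_pct`), which is the recommended burden measure for
group comparisons — see the limitations section for why.

## Stereology

`cavalieri_area_fraction` estimates percent area covered by counting
systematic random lattice points: counting frames (90 x 90 um) are placed
on a 450 x 450 um grid with one uniform random offset, each frame holds a
10 um point lattice with a shared random sub-offset, and the estimate is
the fraction of ROI-hitting points that also hit the structure. Because
every point is uniform modulo the lattice, the estimator is unbiased for
the pixel-count truth; its spread shrinks with finer point spacing. The
cell-density estimator counts cells in 75 x 75 um frames on a 500 x 500 um
grid using the unbiased counting-frame rule (half-open frames: left/bottom
edges count, right/top "forbidden" edges do not), scales the count by the
inverse areal sampling fraction, and divides by ROI area times a
user-defined section thickness — the z-dimension collapses to that
thickness deliberately, since the quantification inputs here are 2D.

## The synthetic generator

`generate_section` renders what the analysis assumes: plaques as discs from
a homogeneous Poisson process (count intensity 60 per mm^2 at baseline)
with log-normal areas (median 1500 um^2, sdlog 0.5), a quarter of them
carrying a bright compact core (the congophilic-core stand-in); nuclei as
soft discs with microglia enriched 8-fold within 30 um of plaque borders;
an isotropic exponential Iba1 halo (decay 6 um) around microglial nuclei;
an intracellular 4G8 blob centred 4 um from the nucleus centre in
plaque-associated microglia, so the pooled 4G8 radial profile peaks near
4 um while Iba1 halves well before 8 um; bimodal Clec7a expression
(activated microglia concentrated near plaques); and a BACE1 annulus at
plaque rims. Poisson photon noise plus Gaussian read noise (SNR about 10
for nuclei) is applied last, intensities are quantised to integer camera
counts, and the ground truth is recorded before noise. Group effects act
multiplicatively on plaque count intensity (the female arm doubles the
male baseline; an IL12p40-knockout male arm at 0.42x is available), which
at the default density corresponds to roughly 10% cortical coverage at
baseline and 20% in the doubled arm — a heavy, late-stage pathology load.
The plaque density default was calibrated so that per-animal medians of
per-image burden are stable; at very sparse densities (a few plaques per
field) the median of a zero-inflated burden distribution becomes a biased
and noisy group-ratio estimator, which is a property of the pooling rule,
not of the imaging.

What the generator does *not* emulate: real plaque morphology (it draws
discs), vascular amyloid, spatial clustering of plaques, anisotropic
microglial shapes, autofluorescence gradients, or section-to-section
registration effects. Passing the recovery tests therefore validates the
pipeline's arithmetic and its statistical calibration, not its robustness
to every property of real tissue.

Determinism: every generated image derives its seed from the master seed by
a splittable counter, so regeneration is bit-identical and extending a
cohort never perturbs existing images. Seeded estimators (Cavalieri,
fractionator) save and restore the caller's RNG state.

## Numerical and degenerate-input choices

* Otsu on identical values returns that value and an empty foreground; the
  Iba1 call on a constant vector marks all cells negative.
* A plaque-free image yields sentinel (`NA`) distances, no associations,
  and is excluded (with a log entry) from plaque-associated summaries.
* Images with zero 4G8 stained fraction are dropped from the BACE1/4G8
  ratio with a warning; animals left without usable images are dropped.
* Zero pooled variance in the t-test: equal means give p = 1 by convention,
  unequal means are an error.
* A constant image cannot be contrast-stretched and is returned unchanged
  with a warning.
* Normalised curves integrate to 1 within 1e-9; a zero curve stays zero.

## Problem sizes used by the test-suite and acceptance script

Simulation-based checks run at sizes chosen to keep the full suite
desk-scale while leaving the statistical contracts intact: segmentation
recovery uses twenty 256 x 256 planted-nucleus scenes; profile geometry
pools a few hundred cells from 512 x 512 default scenes; Cavalieri
unbiasedness uses 1000 random offsets on a 2.7 mm synthetic mask (a field
several scan-grid periods wide, which the 450 um grid needs for a stable
frame sample); the end-to-end burden recovery runs replicate cohorts of
8 animals x 30 images per group at 128 x 128 px (2.88 um pixels — the same
369 um field as the default scene, coarser pixels), and the null
calibration uses several hundred reduced cohorts.

## Known limitations

* **Otsu boundary bias.** On a blurred bright object over dark background,
  the Otsu threshold settles below the edge's half-height, so segmented
  object boundaries sit outside the true edge. For a 20 um disc under the
  7.2 um plaque blur the recovered area is inflated by at least ~5%, and
  the bias grows as foreground becomes sparser. Consequences: absolute
  plaque areas carry a positive bias, and per-image Otsu area fractions
  are *differentially* biased between groups with different burdens
  (compressing group ratios by up to ~15% in our synthetic cohorts). For
  group burden comparisons use the shared-threshold stained fraction
  (`g8_stained_fraction_pct`) or the Cavalieri estimator, both of which
  apply one criterion to all groups.
* **Median pooling at low counts.** With only a handful of plaques per
  image the per-animal median burden is zero-inflated and its group ratio
  biased; the pooling rule is reproduced as published, so the cure is more
  images or larger fields, not a different estimator.
* **2D only.** Quantification runs on maximum projections; the
  fractionator's volume term is a user-supplied thickness, not an optical
  disector.
* **Watershed granularity.** Nuclei that overlap before blurring (centre
  distance below two radii) produce a plateau distance map that watershed
  cannot split; this is a property of the binary EDM approach itself.
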