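---
title: "Methods: 3D segmentation and quantification of xenografted cells in zebrafish larvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D segmentation and quantification of xenografted cells in zebrafish larvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaSeg)
```

## The problem

Xenografting fluorescently labelled leukaemia cells (e.g. Molm-13,
MDS-L) into transparent zebrafish larvae and imaging them daily by
confocal microscopy produces large multi-channel 3D datasets in which the
quantities of interest — how many viable cells a larva carries, how large
they are, where they sit, and how both change under treatment — are
buried in raw voxels.  2D analyses of flattened images conflate
overlapping cells and mistake stained apoptotic debris for viable cells.
`larvaSeg` implements a fully headless 3D pipeline: per-larva masking,
seeded watershed segmentation of individual cells, volume gating,
tumour-burden summaries, pooled density maps, and an FFT heart-rate
estimator for cardiotoxicity videos.

## The segmentation model

For one larva the pipeline runs on a calibrated multi-channel stack (one
brightfield channel, at least one fluorescence channel; voxel size
$(d_x, d_y, d_z)$ in µm):

1. **Flattening** (for inspection and for drawing the outline): the
   fluorescence channel is flattened by max projection; the brightfield
   channel by focus stacking — per pixel, the z-slice maximising local
   intensity variance in a $(2r+1)^2$ window (default $r = 5$ px,
   reflected borders) is selected.  The sharpness metric is a declared
   configuration point: focus-stacking plugins differ in their kernels,
   and local variance is the standard default.  Selection never
   interpolates, so flattened brightfield values are genuine acquired
   values.
2. **Masking**: the user-supplied larva outline and exclusion polygons
   (gut, yolk sac, iridophores — the common autofluorescence sources) are
   2D polygons in the flattened frame, extruded through z.  Voxels outside
   the larva or inside an exclusion are zeroed.  Interactive boundary
   drawing is replaced by a JSON polygon file so the pipeline is headless
   and auditable.
3. **Pre-filtering**: a 3D median filter with voxel radii
   $(r_x, r_y, r_z) = (3, 3, 2)$ (box $7 \times 7 \times 5$, reflected
   borders) suppresses noise before seed detection.
4. **Seeding**: a voxel of the filtered stack is a seed iff its intensity
   strictly exceeds the background level $B$ and is maximal in its
   $(2r_x+1)(2r_y+1)(2r_z+1)$ box; an equal-valued connected plateau
   contributes exactly one seed, at its lowest $(z, y, x)$ voxel.  $B$ is
   the user-determined background fluorescence; ties at $B$ are
   background ("cut-off" semantics).
5. **Watershed**: flooding starts from the seeds *on the masked original
   fluorescence stack* (the median-filtered stack is used only to find
   starting points) with a global priority queue ordered by descending
   intensity, FIFO among equal intensities, neighbours examined in
   ascending $(z, y, x)$ offset order, 26-connectivity by default.  A
   voxel is labelled the moment it is first reached, every reached
   supra-$B$ voxel gets a label (no watershed-line voxels), and voxels at
   or below $B$ stay background.  Touching cells therefore split along
   their intensity saddle whenever a border is detectable.  The exact
   flood order is declared because it makes the output bit-reproducible
   and testable against a brute-force priority flood.
6. **Measurement**: per label — voxel count; volume
   $V = n \cdot d_x d_y d_z$; equivalent spherical diameter
   $\mathrm{ESD} = (6V/\pi)^{1/3}$; intensity-unweighted centroid of voxel
   centres (µm); per-channel mean, integrated and maximum intensity; a
   0-based half-open bounding box; and the centroid mapped into the
   standardised larva frame.

### Choice of seeding stack versus flooding stack

Seeding from the filtered stack while flooding the raw masked stack is
the one consistent composition of "find starting points on the filtered
stack, then watershed the fluorescent stack": filtering only for seeds
keeps spurious noise maxima out, while flooding the unfiltered data keeps
measured volumes and intensities unbiased by the median.  A seed whose
raw masked intensity does not exceed $B$ cannot start a basin and is
dropped before flooding.

## Pose standardisation

Larvae are imaged in arbitrary positions; to pool coordinates across
larvae each image is mapped to a standardised larva frame built from the
outline polygon alone:

* **Orientation** is the Feret angle — the direction of the outline's
  longest vertex-pair (caliper) diameter, computed exactly on the
  polygon vertices in $[0°, 180°)$; ties take the smallest angle.
  Rotating by its negative puts the long body axis horizontal.
* **Origin** is the outline's area centroid.
* **Anterior-left**: the interior anchor — the interior point furthest
  from the boundary in the Euclidean distance transform of the rasterized
  outline, a proxy for the yolk sac, which is anterior — must land in the
  left half-plane.
* **Up/down**: aligning the long axis and fixing anterior-left still
  leaves a vertical mirror free.  It is resolved by the sign of the
  outline's vertical third moment (computed on the transformed vertices):
  the larger vertical lobe points down.  This criterion is exactly
  equivariant under rigid motions of the vertex set, unlike the anchor's
  y-coordinate, which sits close to the midline and rasterizes with
  ±1 px jitter; the anchor half-plane is used only as a tie-break for
  vertically symmetric outlines.

The resulting transform is a rotation plus optional reflection about the
vertical axis (the `flip` flag, set e.g. for larvae imaged on their other
side), with the centroid translated to the origin.  Whether the original
interactive tool mirrored larvae to a common chirality is not
documented anywhere; making the convention explicit here is what lets
pooled maps and montages be tested: all rigid poses and mirrors of one
outline must land on one canonical pose within 1 px.

Montages resample each daily image into the larva frame by
nearest-neighbour lookup — montages are visual quality control, not
quantitative output, so fidelity of individual intensities matters more
than smoothness.

## Gating, burden and comparison

Viable cells are separated from stained apoptotic bodies and debris by a
volume gate, default $V > 1000\ \mu m^3$, equivalently
$\mathrm{ESD} > 12.4\ \mu m$:

```{r esd}
esd(1000)
```

The boundary is exclusive (an object of exactly the threshold volume is
debris) — a declared decision, since "above the threshold" does not
specify the boundary case.  The default is a per-study configuration
value: in practice the threshold is read off the volume distribution of
day-of-injection images for each cell line, not fixed universally.
Per-larva summaries report the gated cell count, the gated ("filtered")
total volume and the ungated total volume; groups are compared per day by
a two-tailed Welch's t-test (via `stats::t.test`), with no
multiple-testing correction across days — matching how such series are
conventionally reported, and noted here so users can add their own
correction if they prefer.

## Density maps

Gated cells' larva-frame $(x, y)$ centroids are pooled per group and day
and rendered as an isotropic Gaussian kernel density (default bandwidth
25 µm, grid 128 × 512 over the pooled extent; the original MATLAB
plugin's kernel and bandwidth are undocumented, so both are configuration
values).  Each map is min–max normalised to $[0, 1]$ **per map**, so a map
visualises distribution only, never total burden — duplicating every
point leaves the map unchanged, which the tests assert.  Larvae are
pooled rigidly; body-length differences between larvae are not rescaled
(no nonlinear or affine warping to a reference larva), which slightly
blurs pooled maps for mixed-size clutches.

## Heart-rate estimation

A heart video (multi-page TIFF; the frame rate is a required input, as
TIFF videos carry none) is reduced to its per-frame mean intensity over a
user ROI; the trace is affinely normalised to $[-1, 1]$ (absorbing camera
gain and offset), zero-padded to the next power of two, and Fourier
transformed.  The heart rate is $60 f_{\text{peak}}$ where
$f_{\text{peak}}$ is the power argmax over bins in a physiological band,
default $(0.5, 5)$ Hz = 30–300 BPM.  The band makes "fundamental
frequency" well defined in the presence of DC offset, low-frequency
drift and harmonics.  No sub-bin peak interpolation is applied; instead
the spectral resolution $f_s/N$ is always reported (e.g. 12 s at 24 fps
gives 288 frames, padded to 512: resolution $24/512 \approx 0.047$ Hz
$\approx 2.8$ BPM).  A constant trace is reported as "no pulsatile
signal", never as a number.

## What the synthetic generator emulates — and what it does not

No imaging data are deposited for this kind of assay, so every stage is
validated against a seeded generator
(`genLarvaStack()` / `genHeartVideo()`) whose defaults define the
reference simulation conditions:

* a 160 × 80 × 32 µm field at 1 µm isotropic calibration holding a
  larva-shaped brightfield silhouette (bulged anterior "yolk", thin tail,
  ventral bias — so orientation, anchor and mirror conventions are all
  well defined);
* 5 viable-cell blobs with ESD drawn from 13–16 µm and 3 debris blobs
  with ESD from 7–8 µm, peak intensity 200, background level 50,
  additive Gaussian noise of sd 10 (5% of peak);
* optionally, touching cell pairs (centres $1.2 \times \mathrm{ESD}$
  apart, leaving a saddle of $\approx 0.27 \times$ peak between two
  distinct maxima) and broad dim autofluorescent patches, each paired
  with an exclusion polygon in the ground truth.

Objects are isotropic Gaussian blobs, and a planted object's ESD is
defined through its expected supra-$B$ voxel set
($\sigma = (\mathrm{ESD}/2)/\sqrt{2\ln(\text{peak}/B)}$), so ground truth
is stated in exactly the currency the segmentation measures.  Two sizing
constraints shape the defaults.  First, cells must clear the 1000 µm³
gate with margin: the gate corresponds to 12.4 µm ESD, and a 12–13 µm
cell would straddle it within rasterization error, so cell ESD starts at
13 µm.  Second, debris must survive the $(3,3,2)$ median pre-filter to be
countable at all: a supra-$B$ blob is erased by a $7 \times 7 \times 5$
median unless it fills more than half the box, i.e. unless its radius
exceeds ≈ 3.1 µm (ESD ≈ 6.3 µm).  Debris below that size is invisible to
this pipeline *by construction of the pipeline itself* — the generator's
7–8 µm default therefore represents the detectable debris population,
and the smallest fragments are a documented blind spot rather than a
test case.

The generator does **not** model the optics: no point-spread function,
no z-scattering elongation (real confocal stacks stretch objects along
z; all objects are affected similarly, so relative comparisons survive,
but absolute volumes are biased), no depth-dependent attenuation, no
anisotropic calibration in the defaults.  Passing the recovery suites
therefore demonstrates algorithmic correctness — exact watershed
partitioning, exact bookkeeping, correct gating arithmetic — not
robustness to every real-world acquisition artefact.

## Numerical choices and degenerate inputs

* Arrays are `[y, x, z]` with 1-based indices in R; exported CSV bounding
  boxes are 0-based half-open, and all exported coordinates are in µm.
  All scan orders and tie-breaks are defined over $(z, y, x)$.
* Border handling is half-sample symmetric reflection everywhere a
  window crosses an edge (median filter, seed search, focus variance).
* Ties: equal-intensity flooding is FIFO; seed plateaus take the lowest
  $(z, y, x)$; Feret ties (within $10^{-9}$ relative on the squared
  diameter) take the smallest angle; anchor ties take the lowest
  $(y, x)$ pixel.
* Degenerate inputs fail loudly: stacks without calibration, polygons
  with fewer than 3 vertices / zero area / self-intersections, constant
  heart traces, seeds at or below $B$, empty search bands.  An empty
  *result* (no supra-$B$ voxels, no matching cells for a density map) is
  valid output, not an error.
* 16-bit TIFF export quantizes; integer data up to 65535 round-trip
  losslessly, and the scale is recorded in the metadata sidecar.

## Problem sizes used in the validation suites

The automated suites run the full pipeline on ten 160 × 80 × 32 voxel
stacks (the generator defaults above), compare the watershed against a
brute-force priority flood on 100 random grids up to 15 × 15 × 7, the
median filter against exhaustive sliding-window medians on 6³ grids, and
sweep 20 heart rates across 60–240 BPM at 24 fps — sizes chosen so the
whole suite completes in a few minutes while still exercising every code
path at full fidelity.

## Known limitations

* Larva outlines and exclusion masks are user-supplied; there is no
  automatic larva detection.
* Only max projection is implemented for fluorescence flattening (the
  operation signature admits alternatives).
* Density maps pool larvae rigidly, without length normalisation.
* Heart videos are read as multi-page TIFF; no AVI decoding.
* No correction for z-axis scattering elongation is applied.
* Proprietary microscope formats are out of scope; TIFF/OME-TIFF only,
  with calibration from an OME-XML description, the package's JSON
  sidecar, or an explicit override — never a silent default.
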