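# larvaSeg

**3D segmentation and quantification of fluorescent cells in zebrafish
larvae.**

Zebrafish larvae xenografted with fluorescently labelled cancer cells
(e.g. the AML line Molm-13 or the MDS line MDS-L) are a fast in-vivo model
for anti-cancer drug testing: the larvae are transparent, so the injected
cells can be followed daily by confocal microscopy. The bottleneck is
analysis — in flattened 2D images overlapping cells merge and stained
apoptotic debris masquerades as viable cells. `larvaSeg` is a headless R
toolkit for the full 3D analysis of such experiments, for microscopists and
pharmacologists who need per-cell numbers out of multi-channel confocal
stacks without interactive image wrangling.

## What it does

* **Stack I/O** — calibrated multi-channel TIFF stacks (OME-XML
  descriptions or a JSON metadata sidecar; volumes are meaningless without
  µm calibration, so a stack without any calibration source is an error).
* **Flattening** — max projection for fluorescence; focus stacking
  (per-pixel sharpest slice by local variance) for brightfield.
* **Larva frame** — from an outline polygon: orientation by the Feret
  angle, a distance-transform interior anchor (yolk-sac proxy), and a
  rigid realignment to a standardised pose (anterior-left), plus daily
  montages.
* **3D seeded watershed** — the core: masking by larva outline and
  autofluorescence exclusion polygons, a 3D median pre-filter (radii
  3, 3, 2 voxels), local-maximum seeding above the background level *B*,
  and deterministic descending-intensity flooding of the raw masked stack,
  which splits touching cells at detectable intensity saddles. Per object:
  voxel count, volume, equivalent spherical diameter (ESD), centroids in
  image and larva frames, per-channel intensities.
* **Gating & burden** — viable-cell gating at volume > 1000 µm³
  (ESD > 12.4 µm) by default, volume histograms, per-larva/day burden
  summaries, Welch's t-test group comparison.
* **Density maps** — pooled larva-frame cell coordinates per group and
  day, Gaussian KDE, min–max normalised per map.
* **Heart rate** — mean-ROI intensity trace from a video, normalised to
  [−1, 1], zero-padded to a power of two, FFT; BPM = 60 × the spectral
  argmax in a physiological band, reported with its frequency resolution.
* **Synthetic data** — a seeded generator of larva stacks with ground
  truth (cells, debris, touching pairs, autofluorescent patches) and
  heartbeat videos, so the whole pipeline is testable offline.

The central quantity for gating is the equivalent spherical diameter of a
volume *V*:

ESD = (6 *V* / π)^(1/3),  so ESD(1000 µm³) ≈ 12.407 µm.

## Worked example

Generate a synthetic larva (5 cells of ESD 13–16 µm, 3 debris fragments of
ESD 7–8 µm, 5% noise), segment it, gate it, and summarise the burden:

```r
library(larvaSeg)

g <- genLarvaStack(syntheticLarvaSpec(seed = 1))
g$stack
#> ConfocalStack 'synth1' (group synthetic, 0 dpi): 2 channel(s), 80 x 160 x 32
#>   bf [brightfield]
#>   fluor [fluorescence]

cfg <- segmentationConfig(backgroundLevel = 50)
res <- segmentLarva(g$stack, g$truth$outline, g$truth$exclusions, cfg)
head(res$objects[, c("label", "voxel_count", "volume_um3", "esd_um",
                     "larva_x_um", "larva_y_um")])
#>   label voxel_count volume_um3    esd_um  larva_x_um larva_y_um
#> 1     1         263        263  7.949120  -0.4623365 -13.754628
#> 2     2         207        207  7.339344  69.1328031  -1.598551
#> 3     3        1635       1635 14.616376 -16.2961292  19.924855
#> 4     4        1328       1328 13.637449 -33.8220816   5.884988
#> 5     5        1931       1931 15.449979  49.6903651  -1.959386
#> 6     6         218        218  7.467111 -26.5927653 -19.753738

nrow(res$objects)                                  # 8 objects pre-gate
nrow(gateObjects(res$objects, volumeGate(1000)))   # 5 viable cells

rec <- larvaRecord("synth1", "control", 0, res$objects)
summarizeBurden(list(rec), volumeGate(1000))
#>   larva_id   group dpi cell_count gated_volume_um3 total_volume_um3
#> 1   synth1 control   0          5             8221             8909
```

The first two columns of the object table show why gating matters: debris
fragments (~200 µm³, ESD ~7.5 µm) and viable cells (>1300 µm³,
ESD 13.6–15.4 µm) are cleanly separated by the 1000 µm³ gate, and the
`larva_*` columns give each cell's position in the standardised larva
frame, ready for pooling into density maps.

Heart rate from a 12 s synthetic video at 24 fps:

```r
vid <- genHeartVideo(bpm = 150, fps = 24, seconds = 12, noiseSd = 0.1,
                     seed = 1)
estimateHeartRate(vid, roi = c(17, 17, 32, 32), frameRate = 24)
#> HeartRateResult: 149.1 BPM (peak 2.484 Hz, resolution 0.0469 Hz)
```

149.1 BPM is within one spectral bin (60 × 24/512 ≈ 2.8 BPM) of the
planted 150 BPM — the honest accuracy limit of a 12 s recording padded to
512 samples, which is why the resolution is always reported alongside.

## Command line

A thin wrapper is installed under `exec/`:

```sh
larvaseg synth larva --seed 1 --out stack.tif --outline outline.json
larvaseg segment --stack stack.tif --outline outline.json \
         --config config.json --out results/
larvaseg density --objects results/objects.csv --group synthetic --dpi 0 \
         --out density/
larvaseg heartrate --video video.tif --roi 17,17,32,32 --fps 24 --out hr/
```

`config.json` holds the tunables (`background_level`, `median_radii`,
`connectivity`, `gate_min_volume`, `density_bandwidth`, `band`, ...); every
command writes a provenance sidecar recording the configuration it ran
with, and identical inputs produce byte-identical outputs.

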