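---
title: "Quantifying DNA damage foci per nucleus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA damage foci per nucleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociquant)
```

## The measurement

DNA double-strand breaks recruit phosphorylated histone H2AX (γH2AX), which
immunostaining shows as compact bright puncta — *foci* — inside the nucleus.
Counting foci per nucleus, and measuring their area, is a standard readout of
DNA damage in neurons and other cells. fociquant automates this readout for
batches of paired single-channel images: a **marker** channel that identifies
the cells to analyse (DAPI, NeuN, or a transduction marker such as TDP-43)
and a **damage** channel carrying the γH2AX-style signal.

The procedure has two segmentation stages followed by per-nucleus
bookkeeping:

1. **Nuclei.** The marker image is binarized with Otsu's method — the global
   threshold $t$ maximizing the between-class variance
   $\sigma_b^2(t) = \omega_0(t)\,\omega_1(t)\,(\mu_0(t) - \mu_1(t))^2$
   of the intensity histogram — computed after discarding pixels below a
   user-chosen background cut-off. Connected components of the binary mask
   are labeled, and only components whose pixel area falls inside a
   user-chosen window count as nuclei. The area window is a marker-free
   proxy for cell type: neuronal nuclei occupy a reproducible size range, so
   debris, glial nuclei, and clumps of merged nuclei fall outside it.
2. **Foci.** The damage image is binarized with an adaptive Gaussian-C
   threshold: pixel $p$ is foreground iff its value exceeds the
   Gaussian-weighted mean of its $b \times b$ neighborhood minus an offset
   $C$. The mask is computed once over the whole image, then intersected
   with each retained nucleus; connected components of the intersection at
   least `foci_area_min` pixels large are that nucleus's foci.

Each nucleus contributes one row: focus count, mean focus area, and total
damaged area (all in pixels). Nuclei with zero foci are reported with count
0 so that group means are taken over *all* analysed cells — dropping them
would bias per-cell averages upward.

## Parameters and their meaning

| parameter | unit | default | role |
|---|---|---|---|
| `intensity_cutoff` | intensity (0–255) | 0 | background floor for marker thresholding; pixels below it are excluded from the Otsu histogram and can never be foreground |
| `marker_area_min`, `marker_area_max` | px | 1, Inf | nucleus size gate; typical neuronal windows are 1000–1300 or 1000–2500 px depending on magnification |
| `foci_area_min` | px | 1 | minimum focus size; 1 keeps everything, 3 implements a "larger than 2 px" rule |
| `connectivity` | – | 8 | neighbor rule for component labeling; 8 avoids splitting foci that touch diagonally |
| `block_size` | px (odd) | 11 | adaptive-threshold neighborhood; should comfortably exceed the focus diameter so the local mean reflects the surroundings, not the focus itself |
| `c_offset` | intensity | 2 | offset subtracted from the local mean; **larger values lower the threshold** |
| `exclude_edge_nuclei` | flag | off | drop nuclei whose bounding box touches the image border |

Two parameter interactions deserve attention.

**Cut-off versus Otsu.** The cut-off removes the background mode *before*
Otsu runs, and the returned threshold is never below the cut-off. If the
cut-off removes everything but a single intensity, no class split exists;
the image is treated as degenerate (empty mask, threshold 255, a warning —
never an error, so one blank frame cannot abort a batch).

**The sign of `c_offset`.** The adaptive threshold is
$T(p) = \text{local mean}(p) - C$. With $C > 0$ every pixel of a perfectly
flat region satisfies $v > v - C$ and becomes foreground; this convention is
inherited from the operator family the default follows, and on real,
textured microscopy backgrounds it behaves as a permissive spot detector.
On clean or synthetic backgrounds you should use $C < 0$, which demands that
a focus rise at least $|C|$ units above its local surroundings. Our
synthetic-scene analyses use `block_size = 15`, `c_offset = -25`: with the
generator's default contrast (focus 180 over background 10), the
Gaussian-kernel mass inside even the largest default focus (radius 4 px)
leaves the center pixel ≈ 40 intensity units above threshold, while flat
background sits 25 units below it — a margin that also rejects Gaussian
noise up to roughly σ = 5 (a 5σ event per pixel).

**Tie rule.** A pixel exactly equal to its local threshold is background.
Because the weighted mean is floating point, exact real-arithmetic ties
(they occur, e.g., when the edge-neighbor and corner-neighbor sums both
equal four times the center value) are resolved with a `1e-9` guard so the
decision never depends on summation order.

## The synthetic-scene generator

`generate_scene()` and `render_scene()` emulate the study inputs: elliptical
nuclei of controlled rasterized pixel area (default 1000–2500 px, the
neuronal range) on a flat background, pairwise separated by at least 2 px;
hard-disk foci (default radius 2–4 px, intensity 180 over background 10)
placed fully inside their nucleus and well separated from each other;
optional pan-nuclear damage filling a whole nucleus; optional soft
Gaussian-profile foci (ground-truth area defined at half maximum); optional
overlapping nuclei to emulate clumps. The damage channel receives seeded
additive Gaussian noise; the marker channel is rendered noise-free, which
keeps nucleus-level ground truth exact and reflects the fact that nuclear
counterstains are far cleaner than damage stains. All areas are recorded
*after* rasterization, so ground truth is exact at the pixel level, and
every random draw comes from a Mersenne-Twister stream fixed by the scene
seed, so scenes are bit-reproducible.

What the generator deliberately does **not** model: optical blur (PSF),
camera noise statistics, intensity gradients, autofluorescence, textured
chromatin, or partially overlapping foci. Passing the recovery tests
therefore demonstrates that the segmentation and bookkeeping machinery is
exact under known geometry — not that any particular parameter set is right
for a given microscope. On real data the cut-off and area windows must be
chosen from the diagnostic histograms (`suggest`/`pixel_intensity`,
`MARKER_size`), as the workflow intends.

Pan-nuclear damage is intrinsically invisible to a local-contrast detector
at its interior (a flat filled nucleus sits below its own local mean plus
$|C|$); the generator still supports it because real neurons show it, and
the ground-truth convention (one focus covering the nucleus) documents what
a perfect detector *would* report. Recovery tests run with
`pan_nuclear_fraction = 0`.

## Numerical and design choices

- **Otsu tie-break:** the smallest maximizing threshold, making batch runs
  deterministic.
- **Labeling:** run-based two-pass union-find; components are numbered in
  raster order of their first pixel, so label maps are deterministic and
  correctness is testable up to renaming against a flood-fill oracle.
- **Adaptive mask over the whole image, intersected per nucleus:**
  recomputing the threshold inside each bounding box would create block
  artifacts at crop borders.
- **Border handling:** reflect-101 (the edge pixel is not duplicated) for
  the Gaussian neighborhood.
- **Pairing rule:** marker and damage files are paired by rank after a
  byte-wise lexicographic sort of each folder — the common export
  convention; a warning is issued when stripped basenames differ.
- **Bit depth:** all arithmetic is 8-bit; deeper inputs are linearly
  rescaled at load so the maximum representable value maps to 255, and RGB
  inputs are collapsed by BT.601 luminance.
- **Rounding:** reported means are written with two decimals, rounded
  half-up; `mean_foci_area_px = 0` is the documented sentinel for nuclei
  without foci.
- **Reserved name:** an output folder named `Results` is refused, and a
  pre-existing output folder is never overwritten.

## Problem sizes used in the test-suite

The validation suite checks the thresholding operators against exhaustive
and double-loop oracles on ~300 seeded random images (32×32 to 64×64),
component labeling against a flood-fill oracle on 200 seeded masks, and
full-pipeline recovery on 20 noise-free and 20 σ=5 scenes of 512×512 px
with 5–10 nuclei (1000–2500 px) holding 0–12 foci each — the regime the
size-gating workflow targets. Duplication invariance mirrors a 16-fold
copied batch: 16× the records, bitwise-identical group mean.

## Known limitations

- Clumped nuclei are handled only by size gating (or the optional edge
  exclusion); there is no watershed splitting.
- Foci are quantified by area and count only; per-focus intensity,
  colocalization with a second marker, and group statistics are out of
  scope — the Quantification table is designed to feed any downstream
  statistics tool.
- Multi-page TIFF stacks and proprietary microscope formats are not read;
  export to single-plane JPEG/PNG/TIFF first.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_batch("demo_batch", n_images = 4, seed = 11,
                      n_nuclei = 6, noise_sigma = 5)
batch <- discover_batch("demo_batch/marker", "demo_batch/damage")

params <- analysis_params(intensity_cutoff = 10,
                          marker_area_min = 1000, marker_area_max = 2500,
                          foci_area_min = 4, block_size = 15, c_offset = -25)
run <- run_batch(batch, params, "demo_analysis")
glance(run)
tidy(run)
```
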