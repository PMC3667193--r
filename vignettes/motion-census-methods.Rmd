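---
title: "Motion-based census of microcosm populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based census of microcosm populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcensus)
```

## The problem

Counting and measuring small invertebrates (springtails, nematodes,
zooplankton, ants) in laboratory microcosms from photographs is hard to
automate when the substrate is heterogeneous: on a single image no grey-level
threshold separates a pale organism from pale debris, reflections, or bright
patches of substrate, and motionless corpses are indistinguishable from live
animals. Manual counting does not scale to hundreds of replicated boxes.

The method implemented here exploits the one property that separates the
organisms from everything else: **they move**. A handful of pictures
(typically 3–5) of the same fixed scene are reduced per pixel to a *still
background* containing only the motionless elements; removing this background
from each frame leaves a near-uniform residual that is non-zero only where
something moved. On that residual, thresholding becomes robust — a wide range
of cut-offs selects the same particles — and standard particle analysis
(connected components, areas, moment ellipses) counts and measures the
population reliably.

## The model and its assumptions

For a stack of co-registered frames $I_1, \dots, I_n$ the background is the
per-pixel Z-projection

$$B(x) = \mathop{\mathrm{stat}}_{i=1..n} I_i(x), \qquad
  \mathrm{stat} \in \{\min, \max, \mathrm{median}, \mathrm{mean}\},$$

and the residual of frame $i$ is either the clipped subtraction
$\max(I_i - B, 0)$ or the absolute difference $|I_i - B|$. The minimum
projection is exact for organisms strictly brighter than the substrate (the
darkest value at each pixel is substrate), the maximum for darker organisms,
and the median/mean degrade gracefully when contrast is marginal or lighting
drifts. The choice of subtraction vs difference is deliberately a required
configuration argument: subtraction sees only the bright side of the
substrate, the difference catches organisms that are locally either brighter
or darker, and which is appropriate depends on the imaging setup, so each
dataset must state it.

The background is exact at a pixel if and only if that pixel is organism-free
in at least one frame (*coverage*). This drives everything measurable about
stack size: at low density two or three frames give complete coverage and the
measured biosurface plateaus immediately; at high density four or five frames
are needed, and the biosurface-vs-$n$ curve keeps rising until coverage is
complete. `reliability_curve()` reproduces this experiment on prefixes of a
stack.

Assumptions, and what violates them: frames must be perfectly aligned
(`register_stack()` recovers integer-pixel translations by Fourier
cross-correlation when the camera was nudged; rotation and scale changes are
out of scope); lighting must be stable within a stack (slow drift is handled
by median/mean projections or, over long time-lapses, by
`sliding_background()`); organisms that never move — dead or dormant — are
absorbed into the background and excluded from the census (by design); moving
shadows and ripples violate the still-background assumption and appear as
particles.

## Measurements and units

Particles are maximal connected foreground components (8-connectivity by
default, matching the usual particle-analyzer convention; 4 available).
Measurements are reported in millimetres through a `scale_calibration`
(set manually, or derived from a dark reference square of known side via
`calibrate_scale()`, which Otsu-thresholds the background on the dark side
and takes $\sqrt{\text{area}}/\text{side}$).

*Area* is the pixel count over `pixels_per_mm`². *Length* is the major axis
of the ellipse sharing the component's second central moments
($4\sqrt{\lambda_{\max}}$, with the 1/12 per-pixel extent term), which
recovers the true length of elliptical bodies exactly and is the natural
"body length" for elongated animals; note it reads ~15% over the long side
for a perfect rectangle, which no organism is. *Biosurface* is the summed
particle area per frame, averaged over frames — a biomass proxy that, unlike
the raw count, does not saturate when touching animals merge into one
particle.

The size distribution uses fixed left-closed classes, by default 0.1–3 mm in
145 classes of 0.02 mm (the standard collembolan binning); out-of-range
particles are tallied separately rather than silently dropped, since neither
behaviour is self-evident.

### Density correction

Beyond roughly a thousand individuals per box, adjoining animals merge and
the raw count under-estimates density. `fit_density_calibration()` fits an
ordinary least-squares line of manually verified counts on biosurface at low
densities, and `correct_density()` projects a high-density biosurface onto
that line. The correction assumes similar-sized, non-overlapping individuals;
the raw count is always retained alongside, and no automatic switch-over
density is applied — applying the correction is a judgement call.

## Numerical choices

- Pixel coordinates are 1-based `(row, col)`, origin top-left — the native R
  matrix convention, used consistently in every returned table.
- All 8-bit arithmetic rounds half *up* (`floor(x + 0.5)`), not half-to-even:
  projections must be bit-reproducible and independent of value parity. The
  median of an even frame count is the mean of the two central order
  statistics, rounded half up.
- Otsu's threshold maximises between-class variance over all 256 splits; a
  two-level histogram makes a whole plateau of splits equally optimal, and
  the tie resolves to the plateau midpoint, placing the cut centrally between
  the classes. A constant residual (an organism-free frame) is a degenerate
  input: it raises a typed condition that the census pipeline converts into
  an honest zero count.
- Registration is integer-pixel only. Sub-pixel alignment is unnecessary at
  the image scales the method targets and would force interpolation,
  breaking the exact integer pipeline.
- Bounding boxes are half-open (max edges exclusive); bin edges are
  left-closed with the top edge closing the last bin.

## The synthetic-scene generator

`generate_scene()` produces seeded stacks with full ground truth, emulating
the structure of real microcosm images: a static substrate built from a base
grey level (default 60, a dark plaster), a random linear illumination
gradient (amplitude 20), Gaussian speckle (sd 5), and a few fixed bright
debris blobs; organisms as filled 3:1 ellipses at a positive intensity offset
(default +120, pale animals on dark substrate) whose lengths are drawn from a
stated distribution (default uniform 0.5–1.5 mm at 10 px/mm); independent
per-axis Gaussian random walks (default step sd 5 px/frame) reflecting at the
walls; i.i.d. Gaussian pixel noise (default sd 2); and optional global
illumination drift. One seeded stream is consumed in a fixed order
(substrate, organism attributes, walk steps, noise), so the same spec is
bit-reproducible and the substrate does not change when organisms are added.

What it does *not* emulate — and what passing tests therefore do not show —
are shadows cast by the organisms, motion blur, textured bodies, substrate
that itself moves (floating algae), and optical distortions. The generator
validates the geometry and logic of the pipeline, not its photometric
robustness on real images.

Validation experiments use these conditions: exact-recovery and batch tests
use 120×120 px scenes (12×12 mm at 10 px/mm) with 8 organisms of 0.6–1.2 mm
and zero noise, screened on the stated preconditions (full coverage,
organisms never touching — checked from ground truth only); the reliability
experiment uses 300×300 px scenes with 20 (low density, ~1.5% occupancy) or
200 (high density, ~14%) organisms of 1.6 mm over 8 frames; the density
correction is fitted on five scenes of 10–50 equal-sized (0.8 mm) organisms
and evaluated at 300–360, where merging under-counts by ~40% and the
corrected estimate lands within ~8% of truth. With the mean-over-frames
aggregation of biosurface, each larger prefix averages over new frames, which
adds below 1% of pixelation jitter at the plateau; the low-density curve is
therefore flat to within 1% beyond three frames, while the high-density curve
still rises by >10% from two to three frames.

## A worked example

```{r example}
sc <- generate_scene(scene_spec(seed = 7, frame_shape = c(150L, 150L),
                                n_organisms = 12, noise_sigma = 0))
cfg <- census_config(removal_mode = "subtract",
                     scale = scale_calibration(10),
                     projection = "min",
                     threshold_method = "otsu")
res <- census_box(sc$stack, cfg)
res$per_frame_counts
res$biosurface_mm2
```

## Known limitations

- Counts are per frame; no identity is maintained across frames, so
  per-frame counts can differ when animals touch transiently.
- `track_single()` follows the largest particle only — adequate for one
  animal per arena, not a multi-target tracker.
- Merged particles are not split (no watershed); the density correction is
  the supported answer at high density.
- The RGB path projects and removes channelwise and keeps per-particle mean
  colour, but segmentation always runs on the grayscale residual; colour is
  carried for downstream identification, not used for detection.
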