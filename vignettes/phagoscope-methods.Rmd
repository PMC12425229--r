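---
title: "phagoscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phagoscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters, and numerical decisions
behind `phagoscope`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and what the synthetic tests do and do not
demonstrate about real data.

## The measurement problem

The tandem mRFP-EGFP reporter distinguishes autophagosomes (green + red =
yellow puncta) from autolysosomes (red-only puncta, EGFP quenched by the
acidic lumen). A cell's shift from basal to activated autophagy therefore
shows up as a change in its red-channel punctum population: activated cells
carry more and larger red spots. The pipeline quantifies this per cell and
per time point over five hourly frames, and tracks each cell so transitions
can be read per individual rather than per population.

## Synthetic data model

`generate_sequence()` emulates the structure of annotated reporter
time-lapse data, not microscope physics.

**Cells.** Each cell is a radial-perturbation polygon: 8–16 vertices at
radii `r * (1 + p * z)`, `z ~ N(0,1)`, rasterized by piecewise-linear
interpolation of the boundary radius over angle and smoothed by a
morphological closing and opening with a 5-px disc. The perturbation
inflates the expected enclosed area by `1 + (2/3) p^2` (piecewise-linear
boundary, independent vertex noise), so the vertex radii are divided by
`sqrt(1 + (2/3) p^2)`: the expected area is then `pi * r^2` regardless of
how wiggly the outline is, which lets the morphology contrast be planted
accurately.

**Morphology contrast.** Basal cells are drawn `sqrt(1 + basal_area_excess)`
larger in radius (default `basal_area_excess = 0.1265`, planting a 12.65%
expected-area excess, the contrast reported for the annotated dataset) and
with stronger boundary perturbation (0.17 vs 0.12), which lowers their
circularity `4*pi*A/P^2` by about 5–6% relative to activated cells. The
circularity knob is calibrated, not derived: perturbation maps to
circularity only through the rasterizer and the perimeter estimator.

**Reporter rule.** Basal cells carry 1–4 puncta of radius 2–4 px rendered
identically in green and red; activated cells carry 5–10 puncta with radii
scaled by 1.6, rendered in red only. Puncta are flat discs placed fully
inside the cell mask (distance-map test) and pairwise disjoint, so the
planted per-cell punctum count and rasterized area are exact oracles for the
spot-segmentation stage.

**Dynamics.** Centroids drift with per-axis SD `motion_sd` (default 2
px/frame), clamped to keep blobs inside the image. Under starvation each
cell draws a transition frame from `round(N(2.5, 1))` clamped to 0..5 with
values at or above 5 meaning "never"; activation is irreversible. Fed cells
never transition. A division (probability 0.02 per cell per frame) replaces
the parent with two daughters at ±1 parent radius along a random axis, each
with radius `r/sqrt(2)` and a fresh track id inheriting the parent's state.

**Rendering.** Channels are background 200 counts, cytosolic reporter +600
in green and red, puncta +8000, Gaussian read noise SD 8, quantized to
integers in 0..65535 (16-bit). The transmitted-light channel is a cosmetic
cell-boundary edge map; no stage consumes it. Integer quantization plus a
pinned RNG (Mersenne-Twister / inversion) makes generation bit-for-bit
reproducible from the seed.

**What the generator does not emulate** — point-spread-function optics,
photobleaching, EGFP pH kinetics, uneven illumination, out-of-focus cells,
debris, or annotation error. Passing tests on this substrate demonstrates
the correctness of the algorithms and the internal consistency of the
pipeline, not robustness to real microscopy; the reference detector in
particular is tuned to this substrate and explicitly not claimed to work on
real images.

## Reference detection and segmentation

`reference_detect()` sums the green and red channels, smooths with a
Gaussian (`sigma = 2` px), and applies Otsu's threshold **on log10
intensities**: fluorescence spans decades (background ≈ 200, cytosol ≈ 800,
puncta ≈ 8800 counts), and on the raw scale Otsu's two-class split lands
between cytosol and puncta, segmenting spots instead of cells. Touching
cells are split by a watershed on the distance transform; the distance map
is Gaussian-smoothed (same sigma) first, suppressing spurious maxima from
boundary wiggles, with tolerance 5 px — about a third of a cell radius —
which separates genuinely touching cells without shattering irregular
single blobs. Components under `min_area = 50` px are dropped. Confidence is
the component's background contrast `1 - bg/mean`, so dim, noise-level
components fall to the 0.65 confidence filter while ordinary cells score
0.75–0.95.

Average precision uses COCO-style 101-point interpolation with the
precision envelope, pooling detections across images in descending
confidence with greedy per-image matching (ties: earlier image, lower
index). This matches the vocabulary of mAP50/mAP50-95 used by standard
detector tooling; detection-to-truth matching for AP is greedy by
confidence, deliberately distinct from the tracker's optimal assignment.
With zero ground truths AP is an error, not 0. Pixel metrics define
empty-vs-empty IoU as 1 (both masks agree there is nothing) and recall as 1
when there are no positives to find.

## Spot quantification and the activation threshold

`segment_spots()` works on the padded bounding-box window of each cell.
Pixels outside the mask are filled with the cell's median intensity before
the white top-hat (disc radius 7 px, larger than the largest punctum), so
the top-hat sees no artificial step at the cell boundary — without this the
boundary ring leaks into the spot mask. Spots are pixels above
`median + 3 * MAD` of the top-hat response inside the mask, connected
components under 4 px dropped. On noiseless synthetic frames the recovered
areas equal the planted rasterized areas exactly; with the default noise
they match to within a pixel or two.

Features are normalized by the within-replicate median and log10
transformed. The activation threshold is the type-7 (linear interpolation)
95th percentile of the fed calibration population — the first frame's fed
cells by default; "timepoint 1" in one-based display. Calibration and
scored cells must be normalized **jointly** (one replicate): normalizing a
starved population by its own median would recenter activated cells onto
the threshold. `run_pipeline()` therefore accepts raw fed calibration
values (`fed_calibration()`) and transforms them together with the scored
sequence. Cells with no segmented spots cannot be log-transformed and are
excluded and reported, not imputed — mirroring the exclusion of unsegmented
cells in the published workflow. The per-cell feature is the **maximum**
spot area (one large autolysosome is the morphological cue for activation);
total area is available by configuration.

Perimeter uses the Crofton 4-direction estimator (2×2 pixel-configuration
lookup); a plain boundary-edge-count estimator is available so circularity
figures can be re-derived under an alternative convention. Circularity is
not clipped: discrete estimators can slightly exceed 1 on small discs, and
a warning is raised beyond 1.2. Class contrasts use Welch (unequal
variance) two-sample t-tests; with identical groups the percent differences
are 0, t = 0, p = 1 by convention. Macro averaging is used for multiclass
precision/recall/F1; MCC uses the Gorodkin multiclass formula, which
reduces to the binary formula for two classes, with a zero denominator
giving 0.

## Tracking

Association solves a gated rectangular assignment problem per frame with a
natively implemented Hungarian algorithm (shortest augmenting path,
O(n³)). Forbidden pairs (centroid distance beyond the gate) are `Inf`; the
solver pads to square with a large sentinel, which yields the cheapest
assignment among those of maximal cardinality avoiding forbidden pairs.
Ties are broken toward lower row then column indices via an infinitesimal
index bias (1e-10 of the largest cost, far below any meaningful cost
difference).

The cost is
`w_s * d/D + w_f * (1 - cos)/2 + w_o * (1 - IoU)` with defaults
`(0.4, 0.4, 0.2)`, gate `D` = 3× the median detected cell diameter, and no
motion model: with five frames there is too little history to estimate
velocity, so the last observed position is the predictor. Active and
inactive tracks compete jointly for detections, inactive ones paying a
re-identification surcharge (0.1); inactive tracks never expire within a
sequence, so a cell lost for a frame resumes its own identity. An unmatched
detection becomes a division child of a matched track when its box IoU with
that track's previous box reaches `theta_div = 0.15`; daughters displaced
by one parent radius with radius `r/sqrt(2)` overlap the parent's previous
box by about 0.2 in IoU (measured median 0.24 across generated divisions),
so 0.3 — a natural first guess — would miss most genuine divisions.

The reference embedding is a deterministic descriptor: per-channel 16-bin
histograms over the mask, binned on the crop's own intensity range (gain
robustness), plus relative area, circularity, and mean intensities,
L2-normalized. It is a stand-in behind a pluggable contract (masked crop in,
fixed-length vector out); a learned encoder attaches the same way.

Tracking metrics follow the standard definitions: fragmentation is, per
true trajectory, the number of distinct predicted tracks covering it minus
one; identity switches count adjacent links within a predicted track whose
underlying true identity changes. A change from a parent to one of its
division descendants is a lineage continuation, not a switch (the tracker
is *supposed* to carry the parent track into a daughter); set
`collapse_divisions = FALSE` for the raw count.

## Pipeline determinism and reporting

All stages are deterministic given inputs and configuration; the bundle
written by `run_pipeline()` (spot table, labels, tracks, transition
summary, run log with seed and config checksum) contains no timestamps, so
reruns are byte-identical. Percent activated uses
`activated / (basal + activated) * 100`, excluding unidentified cells from
the denominator; this is configurable in the sense that unidentified counts
are reported alongside. Occlusion saliency replaces stride-grid patches
with the image's background median (not zero, to avoid out-of-distribution
artifacts) and records the clipped drop in the predicted class score; for
an additive score the grid equals the per-patch contributions exactly at
stride = patch.

## Problem sizes

The shipped tests and the acceptance script use 256-px images with ~12
cells per sequence (five frames), twenty sequences for tracker evaluation,
500 cells per class for morphology recovery (paired base radii, so the
contrast estimate is free of radius-sampling noise), and ~3,300 cells
across 60 dense puncta-free frames for class-mix recovery — sizes chosen so
each statistical check has comfortably more precision than the band it is
judged against while the whole suite runs in a few minutes on one core.

## Known limitations

* The reference detector's parameters (log-Otsu, watershed tolerance,
  minimum area) are calibrated to the generator's default geometry.
* The spot threshold rule (median + 3·MAD of the top-hat) assumes a mostly
  flat cytosolic background within the mask; strong intracellular gradients
  would require a different background model.
* The tracker has no motion model by design; for longer sequences or fast
  cells a velocity predictor and an inactive-track expiry horizon (exposed
  in configuration) would be needed.
* Circularity contrasts depend on the perimeter estimator; figures are
  comparable only within one estimator convention.
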