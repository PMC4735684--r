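---
title: "Quantifying cardiac contraction from video by block matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac contraction from video by block matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bamotion)
```

## The measurement problem

High-frame-rate phase-contrast video of a beating zebrafish heart shows the
outflow tract (bulbus arteriosus) being distended and recoiling once per
beat. The quantity of interest is not where the tissue is but how fast it
moves: a chamber whose wall has lost elasticity deforms less and for a
shorter time. `bamotion` estimates that deformation non-invasively, from the
pixels alone, with no segmentation or landmark tracking.

## The estimator

**Block matching.** Frame *t* is divided into N × N pixel blocks centred on
a grid with one anchor every *s* × *s* pixels. For each block, every integer
offset (i, j) with |i|, |j| ≤ w is scored by the mean absolute intensity
difference between the block in frame *t* and the displaced block in frame
*t − 1*; the minimising offset locates where the content came from, and its
negation is the motion vector (so rightward motion gives positive dx). The
search is exhaustive — (2w + 1)² candidates — which is exact and, at video
scale, entirely tractable: the implementation evaluates each candidate over
the whole frame at once through an integral image of absolute differences,
and a 1,024 × 512 pair takes a few seconds on one core.

Parameters, all in pixels:

| parameter | default | meaning |
|---|---|---|
| `block_size` (N) | 16 | block side; larger blocks average over more texture but blur motion boundaries |
| `max_displacement` (w) | 4 | largest recoverable per-frame displacement; the search window is N + 2w wide |
| `stride` (s) | 4 | grid spacing; the default yields 32,768 vectors on a 1,024 × 512 frame |

The defaults are the empirically chosen values of the analysis this package
reproduces; at ~580 fps acquisition, tissue rarely moves more than 4 px per
frame.

**Numerical choices.** Intensities are exact 8-bit integers and the per-block
sum of absolute differences is computed in exact integer arithmetic, so the
optimized field is bit-identical to a naive triple-loop search (a test
asserts this on random frame pairs). Ties between equal-score candidates are
broken towards the smallest |v|², then smallest dy, then smallest dx: flat,
textureless regions therefore report zero motion rather than an arbitrary
offset. Blocks are centred on their anchors (offsets −N/2 … N/2 − 1); a grid
position is *valid* only when the block **and** its whole search window lie
inside the frame. Invalid positions still count towards the grid (the
32,768 figure is pure floor arithmetic) but carry (0, 0) and are excluded
from every ROI average. No sub-pixel refinement is attempted: the estimator
is integer-valued by construction.

## From fields to kinetics

The ROI-averaged speed at one frame pair is the mean Euclidean magnitude of
the valid vectors inside the ROI — positive during both contraction and
relaxation. Each sample is timestamped at the *later* frame of its pair
(pair k → k+1 at (k+1)/frame_rate), so a speed sample reflects motion that
has just completed. With a pixel size the trace converts to µm/s
(× pixel_size × frame_rate). An ROI that momentarily contains no valid
vectors produces `NA` with a warning, never a fabricated zero.

**Event detection.** The published analysis separates "the contraction" from
the trace without stating how; the rule here is therefore a documented
design choice, not an inference of the original intent. A threshold at
`threshold_fraction` (default 0.2) of the trace maximum defines
above-threshold runs; sub-threshold gaps shorter than `min_separation`
seconds are bridged; runs are then paired into beat cycles and the *first*
run of each cycle is labelled the contraction (physiologically, outflow
tract distension follows ventricular ejection; `contraction_first = FALSE`
swaps the labels). Onset and offset are the linearly interpolated threshold
crossings; the recovered duration of a clean rectangular bump is therefore
accurate to about half a frame. Note the threshold is global: if one phase's
peak speed is below 0.2 × the other's, its runs vanish below threshold —
with the default fraction this needs a 5-fold asymmetry between contraction
and relaxation speed, outside the regimes tested here.

**Endpoints.** Contraction duration is offset − onset in seconds. The
averaged contraction deformation distance is defined as the time integral of
the average speed over the event (trapezoidal rule, interpolated endpoints):
"distance" semantics and unit analysis both favour this reading (px/frame ×
frames = px; µm/s × s = µm), and the alternative reading — mean per-frame
displacement — is simply the integral divided by the duration. Group
endpoints are compared with Welch's two-sided t-test; at n = 4 animals per
group the unequal-variance form is the safer default, with the pooled
Student variant behind `var_equal = TRUE`. When both groups are exactly
constant the statistic degenerates and is reported as t = 0, p = 1 (equal
means) or t = ±Inf, p = 0.

## What the phantom emulates — and what it does not

The validation videos are synthetic because the original recordings are not
deposited. The beating phantom is a speckle-textured disk over a static
low-contrast background; at contraction factor g ∈ [0, 1] the disk is
radially rescaled by k = 1 − A·g/R₀, so the boundary moves inward by A·g
pixels and interior displacement scales linearly with radius. Frames are
bilinear warps of a single reference texture, rounded back to 8 bits — true
sub-pixel motion exists, while the stored ground truth (exact per-pair
displacement at every grid anchor, plus the event schedule) stays exact.

The per-cycle pulse g(t) is piecewise linear: a rise over
`round(contraction_fraction × period)` frames, one zero-motion dwell frame
at full contraction, a linear fall, and at least one quiescent frame before
the next cycle, with `lead_in` static frames (default 2) opening the
sequence. The dwell and quiescent frames are deliberate: a pure
rise-then-fall triangle never lets the speed trace return to zero (at
`contraction_fraction = 0.5` the trace would be perfectly constant), making
onset and offset undefined for any threshold detector. With the dwell
frames, the true speed trace is two clean plateaus per cycle separated by
exact zeros, the ground-truth contraction duration is still
`contraction_fraction × period / frame_rate`, and duration recovery can be
asserted to within one frame. Defaults (128 × 128 px, 3 cycles of 20 frames
at 100 fps, amplitude 3 px, fraction 0.5, speckle grain 2 px) were fixed
once as a desk-scale caricature of the real acquisition and are not tuned.

Two honest caveats about what a green phantom test establishes:

* **Speed quantisation.** The standard phantom moves its boundary 3 px over
  10 frames — 0.3 px per pair — and an integer matcher correctly rounds
  that to zero. Event *timing* recovery is therefore validated on the
  ground-truth speed trace, while the full measured pipeline is validated on
  integer-translation sequences (where recovery must be exact) and on a
  fast-motion phantom (period 8, amplitude 4, per-pair motion 1–2 px) where
  all beats survive frame noise up to σ = 10. Real ~580 fps recordings sit
  in the same regime as the standard phantom per frame pair; their traces
  are similarly quantised, which averaging over thousands of ROI vectors
  mitigates but does not remove.
* **Simplified scene.** The phantom has a static background, no illumination
  drift, no out-of-plane motion and a single moving structure; real frames
  contain a beating ventricle next to the BA and the ROI placement carries
  that separation. Phantom results validate the estimator and the event
  logic, not robustness to every imaging nuisance.

## File formats and conventions

All coordinates are 0-based, x right, y down; CSV columns carry units in
their names (`gx_px`, `time_s`, `speed_px_per_frame`, …). Acquisition
metadata (frame rate, pixel size) comes only from user configuration, never
from file headers — embedded metadata in source videos proved untrustworthy.
Because no TIFF package exists in the target environment, the package
carries a minimal baseline TIFF codec (uncompressed strips; 8-bit gray
exact, 8-bit RGB to luminance, 16-bit gray rescaled full-range with a
message); it round-trips its own files bit-exactly and is cross-checked
against an independent Python reader in the test suite. Compressed or tiled
TIFFs are rejected with a clear error, and PNG input is not supported (no
zlib decoder available) — PGM serves as the second plain format.

## Limitations

Integer vectors bound speed resolution at 1 px/frame per vector; exhaustive
search cost grows with (2w + 1)², so very fast motion needs down-sampling in
time rather than a large w; heart-rate variability, ventricle–BA phase lags
and ejection fraction are out of scope. The detector assumes a roughly
alternating contraction/relaxation run structure; arrhythmic traces with
missing relaxation bumps will mislabel cycles and should be inspected with
`plot()` before trusting the event table.
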