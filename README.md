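# bamotion

Quantifies the contraction kinetics of beating heart tissue — in particular
the teleost outflow tract (bulbus arteriosus, BA) — from grayscale video, by
dense block-matching motion estimation. It is aimed at researchers recording
high-frame-rate microscopy of zebrafish hearts who want a non-invasive,
label-free readout of how strongly and for how long a chamber contracts.

## Method

For every consecutive frame pair, each N × N pixel block of the current frame
is matched against displaced copies of itself in the previous frame, over all
integer offsets (i, j) with |i|, |j| ≤ w (a search window of width N + 2w).
The match criterion is the mean absolute error

    MAE(i, j) = (1 / N²) Σ_{m,n} | f_t(m, n) − f_{t−1}(m + i, n + j) |

and the motion vector of the tissue is the negated minimising offset.
Defaults are N = 16, w = 4, with one vector every 4 × 4 pixels — on a
1,024 × 512 frame that is 32,768 vectors per pair. Over an ROI, the average
speed at one frame pair is the spatial mean of the vector magnitudes

    |V| = (1 / N_ROI) Σ_i √(x_i² + y_i²)

taken over the N_ROI valid vectors inside the ROI; contraction and
relaxation both give positive values. Contraction events are isolated from
the speed trace by thresholding (default 0.2 × trace maximum, with
interpolated threshold crossings), and each event is summarised by its
**contraction duration** (offset − onset, seconds) and its **averaged
contraction deformation distance** (the time integral of |V| over the event —
the mean path length travelled by the tissue, in pixels or µm). Per-animal
endpoint means are compared across groups with Welch's t-test.

Because real recordings of this kind are not publicly deposited, the package
ships a synthetic-phantom module: speckle textures under exact integer
translation, and a radially contracting speckle disk with exactly known
per-pair displacement fields and event schedule. All validation tests run
against these ground truths.

## Worked example

```r
library(bamotion)

# a fast-beating phantom: 3 cycles of 8 frames, 4 px contraction amplitude
ph  <- generate_beating_phantom(phantom_config(period = 8, contraction_amplitude = 4))
fit <- analyze_motion(ph$sequence, roi = ph$truth$roi)
summary(fit)
```

```
Block-matching motion analysis
  frames: 27 (128 x 128 px), fields: 26, frame rate: 100 fps
  matcher: N = 16, w = 4, stride = 4
  peak average speed: 1.326 px/frame
  contraction events: 3
  mean duration: 0.04212 s, mean deformation distance: 2.596 px

Events:
  onset_s peak_s offset_s duration_s peak_speed deformation_distance
1 0.02406   0.06  0.06617    0.04212     0.6932                2.596
2 0.10406   0.14  0.14617    0.04212     0.6932                2.596
3 0.18406   0.22  0.22617    0.04212     0.6932                2.596
```

All three beat cycles are found; each contraction lasts ~0.042 s (the
phantom's contraction phase is 4 frames at 100 fps, and the threshold
crossings add about half a frame) and moves the tissue by ~2.6 px on average
inside the ROI. `plot(fit)` draws the speed trace with the detected events
shaded.

Comparing per-animal mean durations between two groups:

```r
ctrl <- c(0.131, 0.142, 0.128, 0.139)
mo   <- c(0.055, 0.049, 0.061, 0.058)
compare_groups(ctrl, mo)
```

```
Two-group comparison (Welch Two Sample t-test)
  group A: 0.135 +/- 0.006583 (mean +/- s.d., n = 4)
  group B: 0.05575 +/- 0.005123 (mean +/- s.d., n = 4)
  t = 19, df = 5.659, P = 2.417e-06 (*P < 0.05)
```

## Command line

`inst/cli/bamotion.R` wraps the pipeline for shell use:

```sh
Rscript inst/cli/bamotion.R simulate --out phantom.tif --truth truth.csv
Rscript inst/cli/bamotion.R run --input phantom.tif --roi 12,12,104,104 \
    --frame-rate 100 --out-dir out/
```

`run` writes `motion_field.csv`, `speed_trace.csv`, `events.csv` and a
`manifest.json` echoing the configuration and record counts. Subcommands
`motion`, `trace`, `events` and `compare` expose the individual stages.
Inputs are multi-page uncompressed TIFF, PGM, or directories of single-frame
images ordered by natural numeric sort; ROIs are rectangles (`x0,y0,w,h`) or
binary mask images.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the standard beating phantom from the given seed, writes it to
TIFF, runs the installed package end to end (read → motion fields → speed
trace → event detection → CSV/manifest outputs), checks the pipeline's
internal consistency, and writes the JSON report to `--out`.
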