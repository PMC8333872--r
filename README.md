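# gazekit

Appearance-based eye tracking from consumer webcams, for psychophysics-scale
accuracy on a desk budget. Instead of infrared glints and a 3D eye model,
the approach regresses the on-screen point of gaze directly from a handful
of facial-landmark coordinates tracked in the camera frame (the kind of
per-frame `x, y, likelihood` table a markerless tracker such as DeepLabCut
emits). `gazekit` implements the full landmark-to-gaze half of that
pipeline:

- **Geometry** — screen/viewing geometry and the pixel ↔ degrees-of-visual-
  angle conversion `E_dva = arctan(E_px / d_mm · sw_mm / sw_px) · 180/π`,
  plus the square screen tilings used for spatial balancing (530 px → 15
  regions) and error mapping (160 px → 144 regions).
- **Synthetic sessions** — a geometric head/eyeball/pinhole-camera simulator
  that renders landmark tables with known ground-truth gaze for a serpentine
  smooth-pursuit calibration target, under multiple head poses, with
  landmark noise and blink-like occlusions. This replaces the camera + CNN
  stage so the whole pipeline is testable without video or GPUs.
- **Preprocessing** — pupil centres as the mean of four pupil-rim corners,
  removal of frames with any landmark likelihood below 0.7, homogeneous
  coordinate normalization by 600, per-tile spatial balancing to the
  minimum occupied-tile count, and a seeded 50/25/25
  train/validation/test split.
- **Regressor** — a 14-input, 200-hidden-unit (sigmoid), 2-output network
  trained with mini-batch SGD (batch 4), classical momentum 0.6, learning
  rate 0.03 halved every 2,000 epochs, and best-validation checkpointing
  at a 10-epoch resolution.
- **Evaluation** — per-sample errors in px and dva, `E_px = Σ√(Δx²+Δy²)/n`,
  a 30-bin error histogram with median, a 144-region error map with
  8-neighbor fill, a regression of error on screen eccentricity, and a 2D
  Gaussian kernel density (400 × 400 grid, 12 levels) of the (Δx, Δy)
  offsets.

## Worked example

```r
library(gazekit)

config <- default_pipeline_config(seed = 1, out_dir = "gazekit-run",
                                  max_epochs = 3000)
report <- run_all(config)
```

which logs, stage by stage:

```
simulate: 3564 frames (3 poses x 1188)
preprocess: 3564 frames in, 84 removed by filter (2.4%), 960 after balancing (min tile 64); split 480/240/240
train: 3000 epochs, best validation at epoch 2920 (loss 0.000468)
evaluate: n = 240 test samples, median error 1.206 dva
```

and returns a `gaze_error_report`:

```
<gaze_error_report> n = 240 test samples
  median error: 1.206 dva (45.3 px at 500 mm)
  mean error:   48.2 px
  eccentricity regression (region): slope 1.17e-04, p = 0.417
```

Reading the log: three simulated head poses (yaw −20°/0°/+20°) each follow
a one-minute-scale serpentine calibration path (1,188 frames at 30 fps);
2.4% of frames are discarded because a blink dropped some landmark
likelihood below 0.7; balancing the 530-px screen tiles to their minimum
count (64) leaves 960 samples, split 480/240/240. After 3,000 training
epochs the held-out median error is ~1.2 degrees of visual angle (≈45 px
on a 2560-px-wide screen at 500 mm) — accuracy in the range needed for
controlled attention experiments — and the error shows no significant
dependence on distance from the screen centre (p = 0.42). Per-stage
artifacts (DLC-dialect CSV, dataset, model JSON, training trace, error
report) land in `out_dir`. `plot_error_histogram(report)`,
`plot_region_map(report)` and `plot_offset_density(report)` draw the
standard accuracy figures.

A shell entry point with the same stages is installed at
`inst/scripts/gaze_pipeline.R`
(`Rscript gaze_pipeline.R run-all --seed 1 --out DIR --epochs 3000`).

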