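---
title: "Landmark-to-gaze regression: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-to-gaze regression: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gazekit` estimates the on-screen point of gaze from seven facial landmarks
tracked per webcam frame. This vignette is the package's account of the
science it implements: the model and its assumptions, what the synthetic
session generator does and does not emulate, the tunable parameters, and
the numerical decisions made where the design was genuinely open.

## The estimation model

Each frame contributes a 14-element feature vector: the `(x, y)` camera-frame
coordinates of the left and right lateral eye corners, left and right
medial corners, left and right pupil centres, and one point between the
upper lip and the philtrum, in a fixed documented order
(`feature_landmark_names()`). Pupil centres are not tracked directly but
derived as the componentwise mean of four tracked pupil-rim corners, which
averages out tracker jitter by a factor of about two. All coordinates are
divided homogeneously by 600 (the larger camera-frame dimension), which
preserves relative positions while bringing every feature into roughly
`[0, 1]`.

The regressor is deliberately shallow: 14 inputs, one fully connected
hidden layer of 200 sigmoid units, two linear outputs for the screen
coordinates. The geometric relation between landmark positions and gaze is
smooth and low-dimensional once the head pose is encoded by the rigid
landmarks (corners and lip point); a deep architecture would add capacity
where the problem has none to use. The corner/lip landmarks carry pose,
the pupil-vs-corner offsets carry eye-in-head orientation, and the network
learns the pose-dependent mapping between the two and the screen position.

Training is stochastic gradient descent with mini-batches of four,
classical (heavy-ball) momentum 0.6, initial learning rate 0.03 halved
every 2,000 epochs, for up to 15,000 epochs. The loss is the mean squared
deviation norm per sample, $\mathcal{L}_2 = \sum_i (t_i - \hat t_i)^2 / n$
with $(t - \hat t) = (\Delta x, \Delta y)$. Every 10 epochs the validation
loss is recorded and the parameter set from the best evaluation is
returned. Accuracy is reported as the mean pixel error
$E_{px} = \sum_i \sqrt{\Delta x_i^2 + \Delta y_i^2} / n$ and per-sample
errors converted to degrees of visual angle:

$$E_{dva} = \arctan\!\left(\frac{E_{px}}{d_{mm}}\cdot\frac{sw_{mm}}{sw_{px}}\right)\cdot\frac{180}{\pi}$$

with viewing distance $d_{mm}$ and screen width $sw_{mm}$/$sw_{px}$. The
conversion uses the screen *width* only, also for 2D error magnitudes and
at all screen eccentricities; no anisotropic or tangent-plane correction
is applied. This is a deliberate contract: a simple, position-independent
unit conversion rather than a local angular metric (below 2° the relation
is linear to within 0.1%, so the distinction is immaterial at the
accuracies involved).

## Screen targets

The network is trained on normalized targets: screen coordinates divided
by `target_scale` (the screen width in px, so x spans `[0, 1]` and y
`[0, 0.56]`), and predictions are multiplied back before any error is
computed. Sigmoid-hidden networks at learning rate 0.03 do not train
stably on raw-pixel targets of magnitude 10³; normalizing outputs is the
only workable reading, and every reported error is in screen pixels or dva
regardless.

## Why the trainer standardizes its input basis

The homogeneously normalized features are far from standardized: each
coordinate varies by only a few hundredths around offsets near 0.5 (a
pupil traverses ~30 px of a 600-px frame while the whole face sits near
the frame centre). With conventional $\pm 1/\sqrt{\mathrm{fan~in}}$
initialization in that raw basis, hidden pre-activations barely move, every
sigmoid operates in its linear regime, and plain SGD converges to
(and cannot leave) the linear-regression solution — about 2.2 dva on
default synthetic sessions, where the same architecture fitted by a
second-order optimizer reaches ~1.1 dva. The trainer therefore initializes
and updates the first layer in a standardized basis (per-feature z-scores
of the training set) — equivalently, a fixed diagonal preconditioner — and
maps the weights back to the raw feature basis before returning them. The
returned network consumes exactly the `assemble_features()` output; the
optimization trajectory changes, the model class and the data contract do
not. The SGD protocol itself (rates, schedule, batch size, momentum,
checkpointing) is untouched.

## What the synthetic generator emulates

There are no deposited recordings to test against, so the package carries
a geometric stand-in for the camera + landmark-tracker stage, labelled
synthetic throughout:

- **Screen and camera.** The default screen is 2560 × 1440 px
  (595 × 335 mm) viewed from 500 mm. The camera sits at the top bezel
  (screen top edge 50 mm below the camera centre), modelled as a pinhole
  with focal length 1360 px — a consumer webcam's ~70° horizontal field of
  view at 1920-px width, of which the 600 × 500 frame is a face crop. The
  subject's eyes sit at camera height, so the face projects into the frame
  without modelling camera tilt.
- **Face and eyes.** A bilaterally symmetric rigid landmark set
  (interpupillary distance 63 mm, 12-mm eyeballs — anthropometric
  conventions, not fitted values). Each eyeball performs a pure "look-at"
  rotation toward the 3D target; the four pupil-rim points are placed on a
  2-mm ring around the gaze axis, so their centroid is the pupil point by
  construction. No Listing's-law torsion, no corneal refraction, no
  eyelid/texture appearance: the regression consumes only point
  coordinates, so plausible smooth geometry is what matters.
- **Calibration stimulus.** A serpentine raster: alternating horizontal
  sweeps joined by downward increments, slowed near direction changes
  (×0.4) and sped up mid-sweep (×1.6) so that the screen edges are
  oversampled exactly as a pursuit-friendly stimulus oversamples them —
  the bias the 530-px balancing step then removes. The default base speed
  (310 px/s) makes a 5-line session last about one minute at 30 fps; the
  pipeline default (475 px/s) makes three poses total ~3,560 frames, the
  scale of the reference protocol.
- **Noise and blinks.** Isotropic Gaussian landmark noise (default SD
  1 px) and per-frame blink events (default probability 0.027) that send
  the eight pupil-point likelihoods below the 0.7 filter threshold while
  other landmarks keep likelihoods in `[0.95, 1]` — blinks occlude pupils,
  not mouths.
- **Poses.** Three head poses at yaw −20°/0°/+20° by default; rigid
  landmarks depend on pose but not on gaze, pupils on both.

What passing tests on these sessions demonstrate is that the *pipeline* —
filtering, balancing, splitting, training, checkpointing, evaluation — can
recover gaze to ~1.2 dva median from landmark streams with realistic
geometry, sampling bias, noise and dropout. What they cannot demonstrate
is robustness to everything the simulator does not model: appearance and
lighting variation, tracker biases that are correlated rather than
isotropic, head translation during a session, eyelid droop, or individual
facial geometry. Real-recording accuracy claims are outside what this
package can verify.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `viewing_distance_mm` | 500 | mm | nominal eye-screen distance; enters every dva conversion |
| `likelihood_threshold` | 0.7 | – | strict `<` drop rule; reproduces a ~2.7% removal rate at the default blink probability |
| `balance_edge_px` | 530 | px | 15 regions on the default screen; equalizes the pursuit path's edge oversampling |
| `norm_constant` | 600 | px | larger camera-frame dimension; homogeneous, shape-preserving |
| fractions | 0.50/0.25/0.25 | – | train/validation/test; floor-based, remainder to train |
| `learning_rate0`, `momentum` | 0.03, 0.6 | – | reference protocol values |
| `halve_every_epochs` | 2000 | epochs | step scheduler; `0.03·0.5^⌊e/2000⌋` |
| `batch_size` | 4 | frames | reference protocol value |
| `max_epochs` | 15000 | epochs | full protocol; 3,000 suffices on synthetic sessions (see below) |
| `validate_every_epochs` | 10 | epochs | checkpoint resolution |
| `region_edge_px` | 160 | px | 144 evaluation regions |
| KDE grid / levels | 400 / 12 | – | offset-density resolution |

## Numerical choices and degenerate inputs

- **Coordinates** are 0-based, continuous, origin top-left, y downward
  (image convention). Points exactly on the right/bottom screen edge
  belong to the last tile, so tiling is a partition.
- **Tiling** uses the ceiling rule: partial edge tiles count as regions
  (the only reading that gives 15 regions at 530 px on 2560 × 1440).
- **Balancing** takes the minimum over *occupied* tiles and warns about
  empty ones; with a full serpentine session every tile is covered.
  Filtering runs before balancing so blink frames cannot consume a tile's
  quota. Re-balancing an already balanced set with the same seed policy is
  the identity.
- **Split rounding**: validation and test sizes are floored; the remainder
  goes to training (101 → 51/25/25).
- **"Accuracy" for checkpointing** is read as validation loss (lower is
  better); no separate metric is defined. Validation cadence is in epochs.
- **Weight initialization** is uniform $\pm 1/\sqrt{\mathrm{fan~in}}$ in
  the standardized basis, biases zero, fully seeded; momentum buffers start
  at zero; the last incomplete mini-batch of an epoch is kept.
- **Divergence** (non-finite loss at an evaluation) aborts with the epoch
  and losses named rather than returning garbage.
- **Region-map fill** uses 8-connected neighbors in a single pass over the
  original occupancy; tiles with no occupied neighbor stay `NA` and are
  flagged `"undefined"` instead of being invented. Observed tiles are
  never altered.
- **Eccentricity regression** offers region-level (default, per-tile means
  vs tile-centre eccentricity) and sample-level modes; the result records
  which was used. Constant-eccentricity designs are rejected.
- **KDE bandwidth** is Scott's rule per axis, $\hat\sigma\, n^{-1/6}$,
  recorded in the result; identical offsets are rejected rather than
  producing a singular bandwidth.
- **Determinism**: one master seed derives per-stage seeds (affine hash
  modulo $2^{31}-1$), so any stage can be re-run in isolation and
  `run_all()` is bitwise reproducible.

## Problem sizes used in the tests

The default pipeline (three poses × 1,188 frames, ~960 balanced samples,
480 training) trains in well under a minute per 1,000 epochs on one CPU.
The packaged end-to-end check runs 3,000 epochs: on synthetic sessions the
validation loss reaches its plateau by ~2,500 epochs and the later
halvings only polish it, so the full 15,000-epoch schedule changes the
held-out median by little while quintupling the cost. Unit and property
tests use shorter sessions (a faster calibration target) and smaller
training budgets chosen so each property is exercised at the smallest
scale at which it is meaningful, e.g. 5-run stability at 300 epochs and
gradient checks on 20-unit networks.

## Known limitations

- The simulator's realism bounds what green tests mean (see above); in
  particular the 1-px isotropic noise model is optimistic about structured
  tracker error.
- The dva conversion is width-based and position-independent by contract;
  at large eccentricities it understates the local angular error slightly.
- The trainer is plain R; it is comfortably fast at package scale but not
  intended for datasets orders of magnitude larger.
- Camera intrinsics are fixed per session; rolling-shutter, lens
  distortion and auto-exposure artifacts are not modelled.
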