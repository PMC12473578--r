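---
title: "From inertial sensors to joint kinematics via predicted marker trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From inertial sensors to joint kinematics via predicted marker trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Optical motion capture (OMC) with the conventional gait model (the
Plug-in-Gait marker set and its pelvis/femur/tibia/foot embedding) is the
reference method for lower-limb joint kinematics, but it is confined to the
laboratory. Inertial measurement units (IMUs) travel anywhere, yet they
measure segment-frame angular velocity and specific force, not the marker
positions that forty years of validated biomechanical models consume.

`imumocap` takes the bottom-up route: a sequence network predicts the 16
lower-limb marker trajectories of the conventional gait model over one
time-normalized gait cycle from 7 body-worn IMUs (pelvis/L5, both lateral
thighs and shanks, both foot dorsa), and the conventional gait model then
computes sagittal hip, knee and ankle angles from the predicted markers
*through the identical code path used for measured markers*. Errors remain
inspectable at the marker level, and any OMC-era analysis can run downstream.

The pipeline is: zero-phase low-pass filtering, heel-strike segmentation,
101-frame time normalization, a shift-and-scale marker transform, the
network, and conventional-gait-model angle computation, evaluated under
leave-one-subject-out (LOSO) cross-validation with and without dynamic time
warping (DTW).

## Data conventions

Lab frame: x antero-posterior, y medio-lateral (to the subject's left),
z vertical; markers in mm, accelerometers in m/s², gyroscopes in deg/s.
Both streams are sampled at 100 Hz (the simulator's convention; resampling
handles other rates). A gait cycle runs heel strike to ipsilateral heel
strike and is resampled to 101 frames (0–100%). Cycles are built per side,
and both sides' cycles enter training.

Model tensors: inputs are `101 × 4 × 14` — components (x, y, z, Euclidean
magnitude) by streams (7 accelerometers then 7 gyroscopes, canonical sensor
order); targets are `101 × 3 × 16` (axes by markers, canonical marker
order).

### The marker transform

Raw marker coordinates are poorly scaled regression targets. Each cycle is
re-expressed as

```
new = (old - factor + 700) / 100        factor = (LTOE + RTOE) / 2 at frame 1
```

an affine shift to the per-axis toe midpoint of the cycle's first frame,
a +700 mm offset guaranteeing positivity, and a /100 rescale to decimeters.
Inter-marker geometry is untouched up to the 1/100 scale, and the stored
`factor` makes the inverse exact (`inverse_transform()`), so evaluation
always happens in raw mm space. The prose description of the factor
("half the distance between each foot") is read as a loose gloss of the
printed midpoint formula, which is what is implemented. The transform
asserts positivity and raises an error for coordinates beyond 700 mm of the
toe midpoint — walking at ordinary speeds stays comfortably inside this
envelope.

## The network

`build_model()` assembles, from scratch in base R matrix code (forward and
reverse passes both hand-written; no deep-learning framework is involved):

1. a stacked **LSTM encoder** (tanh) over the 101-step sequence;
2. residual **multi-head self-attention**, letting every frame attend to the
   whole cycle — gait is periodic and distal-swing frames benefit from
   seeing stance context;
3. a same-padded **1-D convolution** block (relu) refining local temporal
   features, followed by **layer normalization** — the nonnegative relu
   outputs otherwise drift a downstream recurrent cell's state over 101
   steps until tanh saturates and gradients vanish, and normalization also
   conditions the head's input;
4. an optional **LSTM decoder** stack;
5. a per-frame **linear head** producing the 48 outputs reshaped to
   `3 × 16`.

Inputs are standardized per feature with training-set statistics stored in
the model and applied identically at prediction time. Default optimization:
Adam, learning rate 0.005 (optionally decayed exponentially via
`lr_decay`), batch size 200, up to 200 epochs, all seeded and fully
deterministic on one device.

Because the exact layer inventory of the original architecture is not
pinned down, every width is exposed in `model_config()`; the defaults (two
128-unit encoder layers, 4 heads of key dimension 32, 64 filters, one
128-unit decoder layer) are scaled to the stated batch size and learning
rate. `reduced_model_config()` — one 128-unit encoder layer and a purely
convolutional decoder (attention + convolution feeding the head directly) —
is the configuration for desk-scale synthetic cohorts: on tens of training
cycles it trains several times faster than the recurrent-decoder variant at
equal or better holdout accuracy, and its batch size of 8 keeps the number
of optimizer steps on a 60–100-cycle cohort comparable to full-scale
training with batch 200 on thousands of human cycles.

### The biomechanics-aware loss

`biomech_loss()` sums four mechanically motivated terms (weights
`loss_weights()`, each ≥ 0, defaults 1):

* **global MSE** over all 48 features, frames and cycles;
* **foot MSE** — the same error restricted to ankle, heel and toe markers
  bilaterally, the hardest and most consequential markers for ankle
  kinematics (three nearly collinear points per foot driven by one sensor);
* **top-k feature MSE** (k = 24 of 48): per-feature MSEs (feature = one
  axis-marker pair, averaged over batch and time) are ranked and the worst
  half averaged, forcing the optimizer to attend to its largest systematic
  errors; the ranking is treated as fixed within a step (a standard
  subgradient);
* **temporal smoothness** — MSE between the first temporal differences of
  prediction and truth, penalizing frame-to-frame jitter while deliberately
  ignoring constant offsets (a comparison of dynamics, not a roughness
  penalty on the prediction alone).

Every component is separately retrievable for diagnostics, and the top-k
term is verified in the tests against a brute-force sort oracle.

### Early stopping

Training runs at least `min_epochs` (default 100) epochs, then stops once
the validation loss has failed to improve for `patience` (default 5)
consecutive epochs; `restore_best` returns the parameters of the best
validation epoch. The validation subject is fixed across folds (with a
designated fallback for the fold that holds the validation subject out) so
the stopping condition is uniform across the LOSO experiment.

## The conventional gait model stage

`compute_joint_angles()` runs the full chain at every frame:

* **pelvis frame** from the four pelvis markers (origin mid-ASIS,
  medio-lateral axis along RASI→LASI, antero-posterior axis orthogonalized
  toward the ASIS midpoint from the PSIS midpoint);
* **hip joint centers** by the Davis regression (offsets from leg length
  and inter-ASIS distance; coefficients as in Davis et al. 1991, the form
  the conventional gait model uses), exposed so other regressions can be
  substituted;
* **knee and ankle centers** by the chord construction: the center lies in
  the plane of proximal center, lateral joint marker and wand marker, at
  `(joint width + marker diameter) / 2` from the lateral marker, with the
  chord perpendicular to the segment's longitudinal axis, on the side
  opposite the (lateral) wand;
* **segment frames** (femur, tibia, foot), with every medio-lateral axis
  oriented to the subject's left so one Cardan extraction serves both
  sides;
* **sagittal angles** as the first Cardan rotation (flexion first, about
  the proximal medio-lateral axis); hip and knee flexion positive, ankle
  dorsiflexion positive after subtracting the static-trial offset (the
  static pose defines 0° dorsiflexion, the standard clinical convention
  and the reason the static trial exists).

Predicted markers go through `angles_from_predictions()`, which is nothing
but `inverse_transform()` plus the same chain — comparability between
measured and predicted kinematics is structural, not asserted.

Wand markers (LTHI/LTIB and friends) participate only in chord
constructions, never as frame axes. Because the hip-center regression
variant and angle offsets of the original toolchain are not fully
specified, absolute angle offsets may differ from other implementations by
a constant; closed-loop tests against the simulator are immune to this,
but cross-toolchain comparisons on real data would feel it in the
non-DTW RMSE.

## Evaluation

* **Marker RMSE** per marker-axis over each cycle's 101 frames, in cm,
  evaluated in raw mm space after the inverse transform.
* **Angle RMSE** per joint and side, in degrees, with and without DTW.
* **DTW**: squared-difference local cost, steps {(1,0), (0,1), (1,1)}, no
  band by default (101-frame series are cheap; a Sakoe-Chiba band is
  exposed). The "RMSE after DTW" series maps each reference index to the
  mean of its matched query samples; by Jensen's inequality plus path
  optimality this can never exceed the unaligned RMSE, which the report
  asserts as an invariant. DTW is applied per joint curve independently
  (the reported tables are per joint), univariate.
* **Aggregation**: per-cycle values, then subject means, then mean ± SD
  across subjects (the aggregation level is ambiguous in general practice;
  subject-mean-then-SD is implemented and stated here).
* **Pearson correlation** per joint over concatenated normalized cycles.
* **LOSO**: one model per holdout subject, fixed validation subject with
  fallback, training sets always disjoint from holdout and validation; the
  tests audit cycle-level disjointness by content hash.
* **Sensor-swap probe**: predictions with foot and shank streams
  interchanged must degrade markedly (default: swapped RMSE ≥ 1.5× nominal
  for a PASS); a model that predicts plausible gait regardless of input
  placement would be memorizing the cycle, not reading the sensors. The
  probe is skipped for untrained models.

## The synthetic gait simulator

Nothing downstream is testable without data, so the simulator is
first-class, not a fixture. It emulates:

* **Joint-angle profiles**: 6-harmonic Fourier series per joint, fit to
  textbook normative sagittal walking curves, with harmonic amplitudes
  scaled to 0.85 of the overground fit to reflect the smaller excursions of
  treadmill walking at preferred speed (this also keeps every marker within
  the ±700 mm envelope of the marker transform, which brisk overground
  excursions would violate for tall subjects). Profiles are phase-rolled at
  construction so the right heel's anterior position peaks exactly at phase
  0 — cycle starts coincide with coordinate-based heel-strike detection.
* **Forward kinematics** of a seven-segment chain (pelvis, femora, tibiae,
  feet): sagittal joint rotations plus parametric medio-lateral pelvis sway
  and vertical oscillation; frontal/transverse joint angles are fixed at 0,
  matching the sagittal scope of the angle stage. Markers are rigid in
  segment frames (the rigid-body property is tested to < 1e-6 mm); the hip
  pivot is placed by the same Davis regression the analysis uses, and the
  knee/ankle markers sit so the chord construction recovers the true
  pivots — the closed loop (generate markers → recompute angles) is exact
  to numerical precision and is the system's primary oracle, required
  below 0.5° RMSE.
* **IMU signals**, derived analytically: the gyroscope is the segment's
  angular velocity in the sensor frame (analytic Fourier derivative); the
  accelerometer is the specific force at the sensor point — numerical
  second derivative of its position minus gravity — in the sensor frame
  (strapdown convention: a motionless sensor reads +9.81 m/s² up).
* **Noise**: white accelerometer/gyroscope noise, constant per-channel
  gyroscope bias, isotropic marker jitter. Presets: `none`,
  `low` (0.15 m/s², 1 deg/s, 0.2 deg/s bias, 1 mm jitter),
  `default` (0.5 m/s², 3 deg/s, 0.5 deg/s bias, 2 mm jitter) — magnitudes
  in the range of consumer-grade IMUs and OMC residuals.
* **Cohorts**: per-subject uniform body scale (normal, σ = 4.6% ≈ a
  170.5 ± 7.9 cm cohort, clamped to ±2σ), cadence ±10%, per-joint amplitude
  variability (σ = 3%), sway variability, all drawn from per-subject seeds
  derived deterministically from the master seed — identical master seeds
  reproduce datasets bit for bit. Trials span `n_cycles + 1.5` cycle
  durations, starting half a cycle before the first right heel strike, so
  both sides carry exactly `n_cycles + 1` interior heel strikes.

What the simulator does **not** model — and hence what green tests do *not*
demonstrate about real data: soft-tissue artifact (markers and sensors are
rigidly attached), frontal/transverse joint motion, magnetometer channels
and magnetic disturbance, turning or overground path curvature,
pathological gait, asymmetries beyond the left-right phase offset, sensor
mounting misalignment, and OMC gaps (gap handling is limited to dropping
affected cycles). Synthetic cohorts are also far more homogeneous than
human ones; holdout errors here are a lower bound on what human data would
show.

## Numerical choices

* **Filtering**: 4th-order Butterworth, 6 Hz cutoff, applied
  forward-backward (zero phase). Coefficients come from `signal::butter`;
  the zero-phase application is in-package with odd-reflection padding long
  enough for the slowest pole to decay, making the filter exact on
  constants at the edges (tested to 1e-9).
* **Heel-strike detection**: local maxima of heel-minus-pelvis-centroid
  anterior position with 0.6 s minimum peak separation — the standard
  coordinate-based method for treadmill gait; validated against simulator
  ground truth to ±2 frames.
* **Resampling**: cubic spline over normalized cycle time at 101 points;
  exact on affine signals, endpoints preserved exactly.
* **Cardan extraction**: flexion–abduction–rotation sequence; only the
  sagittal component is reported; a warning is raised within 5° of gimbal
  lock (unreachable in walking).
* **Chord tie-break**: the medial side is chosen opposite the wand's
  in-plane perpendicular component, which is well-defined whenever the
  three points are non-collinear (collinearity is an error).
* **DTW ties** prefer the diagonal step during backtracking.
* **Degenerate inputs** error early and descriptively: empty coefficient
  vectors, non-positive sampling rates, non-orthonormal rotations,
  collinear chord inputs, gaps in required markers, fewer than two heel
  strikes, mismatched tensor shapes.
* **Packed cycles** (`save_cycles()`/`load_cycles()`) use R's native
  serialization with a format-version field and the transform parameters
  (offset 700, scale 100) stored alongside the per-cycle factors, so the
  inverse transform is always recoverable; version mismatches are format
  errors.

## Problem sizes

The package's own experiments run at desk scale: cohorts of 3–6 synthetic
subjects with 5–10 cycles per side, the reduced network configuration, and
40–60 training epochs per fold. The bundled acceptance script
(`scripts/acceptance.R`) runs the 6-subject LOSO at 60 epochs. These sizes
were chosen so a full LOSO completes in minutes on a single CPU core while
remaining far above the error bounds' noise floor; nothing in the
implementation is specific to them, and `model_config()` scales the same
code to full-size cohorts.

## Known limitations

* Sagittal plane only, by scope: no frontal/transverse angles, moments or
  powers.
* The angle stage requires a static trial and anthropometrics for the
  holdout subject, exactly as the conventional gait model does.
* Training is CPU-bound R matrix code: deterministic and dependency-free,
  but not fast; full-size cohorts with the default configuration are an
  overnight job rather than minutes.
* The simulator's realism limits are listed above; claims about real-world
  accuracy require real paired IMU-OMC data.
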