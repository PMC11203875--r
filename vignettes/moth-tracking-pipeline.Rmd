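---
title: "Methods: denoised 3D point-cloud tracking of free-flying moths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: denoised 3D point-cloud tracking of free-flying moths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A nocturnal moth flying in a dark arena can be observed with an
infrared-illuminated stereo camera: each disparity image converts to a
3D point cloud in the camera frame (origin at the camera, $+z$ depth,
metres). At 55 fps and indoor ranges the clouds are dominated by
non-moth points — the static net walls of the arena, transient speckle
where stereo matching briefly hallucinates a surface, and "coplanar"
artefacts in which every point of a cluster lies on a single plane
(an outline box with zero volume), concentrated near the camera's
minimum effective stereo range (~0.9 m). `mothtrack` implements a
six-stage pipeline that reduces such sequences to moth flight
trajectories and their kinematics.

## Pipeline stages and their parameters

All tunables live in `pipeline_config()`; units are metres, frames and
degrees throughout.

* **Background voxels** (`voxel_size_m = 0.05`, `n_training_frames = 4`,
  `min_occupancy_frames = 2`). A cubic grid is anchored at the camera
  origin with half-open cells, so a point exactly on a boundary belongs
  to the higher-index voxel — a deterministic tie-break. Any voxel
  occupied in at least 2 of the first 4 frames is background; its points
  are removed from every frame. The model is fixed, not rolling: the
  walls do not move, and a rolling model would eventually absorb a
  hovering moth. The four training frames are themselves filtered and
  passed downstream, but tracking starts after them by default
  (`track_from_frame = 4`).
* **Clustering** (`link_dist_m = 0.01`). Residual points are grouped
  into connected components of the "within 1 cm of some member" graph —
  single linkage, so chains of close points form one cluster whatever
  their overall span. The boundary is inclusive. The implementation is
  single-linkage agglomeration (`stats::hclust`) cut at the link
  distance, which is exactly these components; a brute-force
  connected-components oracle (thresholded distance graph, `igraph`)
  verifies the equivalence in the test suite on random frames up to
  2000 points.
* **Size window** (`min_pts = 20`, `max_pts = 900`, inclusive). Clusters
  outside this point-count window are too small or too large to be the
  moth body at these ranges. An object's position is the arithmetic mean
  of its member points; its outline box volume (OBV) is the product of
  the axis-aligned bounding-box extents.
* **Tracking** (`gate_m = 0.09`, `min_length_frames = 10`). Each object
  proposes its nearest successor in the next frame and the proposal
  stands iff the distance is within the gate. Conflicts are resolved
  nearest-first (ties by lower object index); a loser does not fall back
  to its second-nearest candidate, and unmatched detections seed new
  tracks. A single missed frame terminates a track — discontinuity is
  itself a noise signature, so no coasting or gap-bridging is attempted.
  Tracks shorter than 10 frames are discarded. At a mean flight speed of
  1.8 m/s a frame-to-frame displacement is ~3.3 cm, comfortably inside
  the 9 cm gate.
* **Prediction** (`steps_ahead = 2`). The aim point is the constant
  velocity extrapolation $c_T + s\,(c_T - c_{T-1})$. The predictor form
  is deliberately isolated behind `predict_position()` so alternatives
  can be swapped; at 55 fps the two-step lead is 36 ms on an 18 ms
  update interval.
* **Classifier** (`window_frames = 10`). Two features over the final
  window: the scalar spatial SD of the centroids (RMS distance from the
  window mean) and the population SD of the turning angles between
  consecutive displacement vectors. "SD of positions" is ambiguous for
  3-vectors; the scalar form is used because it is rotation-invariant,
  and a per-axis sample-SD variant is available via
  `extract_features(position_sd = "per_axis")` for sensitivity checks
  (the two differ only by the $n/(n-1)$ factor). Angles are in degrees;
  a zero-length displacement contributes a 0° turn by convention. The
  SVM is linear (`e1071`), fitted on standardized features and reduced
  to a five-number record `{w1, w2, b, means, sds}`; a decision value of
  exactly 0 is conservatively noise. Batch mode classifies each track
  once on its final window; `classify_mode = "sliding"` labels a track
  noise if any window does, mimicking a frame-by-frame real-time system.
* **Zero-OBV filter** (tolerance `1e-12` m³). A trajectory is removed if
  any frame's OBV is zero: all points coplanar, which a genuine
  volumetric body cannot produce. The removal log records the distance
  from the camera of the offending frame, which for simulated scenes
  clusters at the ~0.9 m near-range band.
* **Turning-angle filter** (`max_angle_deg = 110`, strict). Turns in
  $(110°, 180°]$ are reciprocating jitter; a turn of exactly 110° is
  kept.
* **IQR screen** (`fence_k = 1.5`, `max_iterations = 10`). Per
  iteration, OBV and turning-angle values are pooled over all frames of
  the currently kept trajectories and Tukey fences computed. The OBV
  fence is two-sided; the turning-angle fence is upper-only — small
  angles are smooth flight, not noise. Flagged trajectories are
  confirmed by an automated proxy (net displacement under 5 cm over the
  lifetime, or any frame discontinuity) replacing a human looking at a
  3D animation; only confirmed ones are removed, and the loop repeats
  from the outside of the distribution inward until a fixed point.
  Removal is per-trajectory; trajectories that mix genuine flight with a
  noisy tail are a known limitation of trajectory-level removal.

Stage order is background → clustering/size → tracking/TSL → SVM → OBV →
turning angle → IQR. Every stage partitions its input (kept + removed =
input), asserted at run time and in tests, and `run_pipeline()` reports
per-stage counts; `report_json()` is byte-deterministic for a fixed
config and input.

## What the simulator emulates — and what it does not

`simulate_scene()` generates labelled scenes in a 1.8 × 1.8 × 3.5 m
arena viewed by a 47.2° × 36.3° frustum at 55 fps:

* **Walls**: points sampled on the five far/side surfaces at
  `background_density` (default 60 pts/m², ~650 in-frustum points per
  frame) with a fixed 0–2 cm inward surface-texture offset and a
  per-frame jitter of `background_jitter_m = 1e-4` m. The sub-millimetre
  default reflects how static stereo geometry behaves: quantised
  disparities make background points nearly identical across frames.
  With sparse wall points each occupied voxel typically contains a
  single point, so jitter comparable to the voxel size would make
  occupancy flicker across cell boundaries and no fixed background model
  could be consistent with it.
* **Moths**: per-step speeds drawn from N(1.8, 0.3²) m/s (truncated at
  0.2), headings perturbed by ~12° per frame with a hard 40°/frame cap
  (so genuine flights never trip the 110° filter), steered smoothly away
  from walls and reflected rather than clamped so the realized speed is
  preserved; rendered each frame as a Gaussian blob (σ = 1 cm, truncated
  at 2σ, 80–400 points) that is contracted if needed so the detector
  sees one cluster. Ground truth records the realized path and per-step
  speeds.
* **Release timing**: `moth_entry_frame = 4` — the recording starts on
  the empty arena and the moth is released after the background-training
  frames, as in a release-after-record protocol. A moth present from
  frame 0 that dwells in one voxel for two of the first four frames
  trains its own voxels into the background and loses points when it
  revisits them; setting the entry frame to 0 exposes exactly that
  hazard.
* **Multiple moths**: each moth is confined to its own depth slab with a
  `moth_separation_m = 0.25` gap between slabs. This emulates
  multi-release recordings while keeping ground-truth identities
  unambiguous; it deliberately does not model close encounters, so
  identity-switch results say nothing about crossing flight paths.
* **Noise**: transient blobs live 1–60 frames, reciprocate (consecutive
  displacements nearly reverse, turning angles concentrated in
  110–180°) and stay tethered within 4.5 cm of their origin; coplanar
  artefacts carry a constant depth of exactly `near_range_m = 0.9` m, so
  one bounding-box extent is exactly zero in every frame.

Not modelled: disparity quantisation, wing-beat deformation of the blob,
photometric effects, occlusion between moths, and hovering or reverse
flight. Passing tests therefore demonstrate the pipeline's correctness
and its statistical behaviour under these idealised conditions, not
performance on real recordings.

## Numerical choices and degenerate inputs

* Clustering threshold comparisons carry a `1e-12` relative slack so
  distances equal to the link distance merge despite floating-point
  rounding; random continuous data are unaffected.
* Turning angles clamp the cosine into [−1, 1] before `acos`; zero
  length displacements yield 0°.
* Speed is undefined at a track's first frame and the turning angle at
  both endpoints; these are `NA` in `compute_kinematics()` and empty
  fields in the CSV (where the angle is reported at the frame completing
  the turn, so the first two rows are empty). Undefined values are never
  zero-filled.
* Density is undefined (NA) when OBV = 0; the OBV tolerance is absolute
  (`1e-12` m³) because simulated artefacts are exactly coplanar while
  real ones are only nearly so.
* Empty frames, single-point frames and single-class training sets are
  explicit errors or well-defined no-ops; the IQR screen warns and does
  nothing below 4 trajectories, where quartiles are meaningless.
* PLY is read in ASCII and binary little-endian dialects and written as
  binary float32; trajectory CSVs print 17 significant digits so
  read-back is bit-identical.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on simulated
data, sized for quick iteration: scenes of 40–165 frames at the default
wall density, 20-seed replicate sets for tracking and speed-recovery
checks, 200 + 200 trajectories for classifier training and held-out
evaluation, and 80–200 random frames (up to 2000 points) for the
clustering-oracle comparison. Larger scenes only change run time; the
statistical checks (3-SE speed agreement, < 2% recovery bias, ≥ 95%
held-out accuracy, zero identity switches) are already stable at these
sizes.

## Known limitations

* Two moths within 1 cm merge into one object; splitting merged bodies
  is out of scope, as is multi-hypothesis or Kalman tracking.
* Trajectory-level (rather than frame-level) removal discards mixed
  flight+noise tracks wholesale; a frame-trim mode would recover their
  clean segments.
* The classifier is trained on simulator-labelled trajectories; applying
  it to real recordings requires retraining on labels from those
  recordings.
* Real-time latency is not asserted anywhere: the timing arithmetic
  (18 ms update, 36 ms lead) is a property of the frame rate, not a
  measured compute budget.
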