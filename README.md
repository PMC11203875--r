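# mothtrack

Automatic detection and denoising of free-flying moth trajectories in 3D
point-cloud time series.

Nocturnal pests such as the cotton leafworm (*Spodoptera litura*) fly in
the dark, so their flight can be recorded only indirectly — e.g. with an
infrared-illuminated stereo camera whose disparity images are converted
to per-frame 3D point clouds. Those clouds are dominated by noise: the
arena walls, transient speckle blobs that flicker in place, and
zero-thickness "coplanar" artefacts near the camera's minimum effective
range. `mothtrack` turns such frame sequences into denoised flight
trajectories and computes flight kinematics (speed, turning angle) from
the survivors — the information a laser-based pest-control system needs
to aim a few frames ahead of a flying moth.

## The pipeline

For frames of points $p \in \mathbb{R}^3$ (metres, camera at the origin,
$+z$ = depth) observed at 55 fps:

1. **Background model** — on a cubic voxel grid (5 cm edge), any voxel
   occupied in ≥ 2 of the first 4 frames is background; its points are
   removed from all frames.
2. **Object detection** — residual points are clustered by chained
   proximity (single linkage, link distance 1 cm); clusters outside the
   20–900 point window are discarded. An object's position is the mean
   of its member points.
3. **Tracking** — objects are linked frame-to-frame to their nearest
   successor within a 9 cm gate; a missed frame terminates the track;
   tracks shorter than 10 frames (time series length, TSL) are noise.
4. **Classification** — a linear SVM over two features of the last 10
   frames, the spatial SD of the positions and the SD of the turning
   angles $\theta_t = \angle(c_t - c_{t-1},\, c_{t+1} - c_t)$, separates
   moth flight (large, smoothly directed movement) from noise (small,
   reciprocating movement).
5. **Zero-OBV filter** — a frame whose outline box volume (product of
   the axis-aligned bounding-box extents) is 0 has all points on one
   plane, a stereo artefact; such trajectories are removed.
6. **Turning-angle filter + IQR screen** — trajectories with any
   $\theta > 110°$ are reciprocating noise; an iterative Tukey-fence
   (1.5 × IQR) screen over pooled OBV and turning angle catches the
   remainder, confirmed by an automated low-movement proxy.

Speed is $\lVert c_t - c_{t-1}\rVert \cdot \mathrm{fps}$; a constant
velocity prediction $c_T + 2\,(c_T - c_{T-1})$ gives the 2-frame
(36 ms) aiming lead at the 18 ms update interval.

Because the original recordings are not public, the package ships a
labelled scene simulator (`simulate_scene()`) that reproduces the arena,
camera geometry and the noise morphologies, so every stage is testable
against ground truth.

## Worked example

```r
library(mothtrack)

scene <- simulate_scene(scene_config(rng_seed = 7))   # 165 frames, 1 moth
report <- run_pipeline(pipeline_config(seed = 0), scene$sequence)
report
#> <pipeline_report>
#>   n_frames                   165
#>   n_points_total             151678
#>   n_points_foreground        44587
#>   n_background_voxels        603
#>   n_clusters                 559
#>   n_objects_size_ok          238
#>   n_trajectories_built       4
#>   n_removed_tsl              1
#>   n_after_tsl                3
#>   n_removed_svm              2
#>   n_removed_zero_obv         0
#>   n_removed_turning_angle    0
#>   n_removed_iqr              0
#>   iqr_iterations             0
#>   n_final_trajectories       1
#>   pooled speed: 1.806 +/- 0.304 m/s (median 1.845, n = 160)

mean(na.omit(scene$truth$moth_paths$speed_mps))   # simulator ground truth
#> [1] 1.805922
```

One trajectory survives all six stages; its pooled per-frame speed
(1.806 m/s over 160 steps) matches the simulated moth's true mean
per-step speed to a fraction of a percent. `predict_position(tr, 2)`
then gives the 36 ms-ahead aim point for any tracked trajectory.

A command-line interface wrapping the same functions is installed at
`system.file("scripts/mothtrack", package = "mothtrack")` with
subcommands `simulate`, `train-classifier`, `track`, `denoise`, `stats`
and `run`.

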