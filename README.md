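# mocap3d

Markerless 3D motion capture for articulated bodies — insect legs, rodent
limbs, human joints — from synchronized multi-camera video that an
upstream detector (e.g. a DeepLabCut-style network) has already reduced
to per-frame 2D keypoint tables. The package covers everything between
detector output and kinematic analysis:

- **Camera model**: reduced pinhole with 8 free parameters per camera —
  axis-angle rotation **r**, translation **t**, a single focal length
  *f* (principal point fixed at the image center) and one radial
  distortion coefficient *k₁*, i.e. `u = A · D(P p̃)` with
  `D(x) = x (1 + k₁‖x‖²)` in normalized coordinates.
- **Calibration**: greedy covisibility-graph initialization from
  calibration-board detections, then *iterative* sparse bundle
  adjustment — 12 rounds of joint camera/point refinement restricted to
  observations with reprojection error below a threshold decaying
  geometrically from 15 px to 1 px, which outperforms a single robust
  fit when detections contain gross outliers.
- **2D filters**: rolling-median outlier removal with spline
  interpolation; exact Viterbi decoding of multi-candidate detections
  (HMM with confidence emissions, Gaussian displacement transitions,
  7 px duplicate merging, 2⁻ᵍᵃᵖ carryover across missed frames); and a
  confidence-score autoencoder (single tanh hidden layer, width = number
  of joints, Adam) that demotes confidently-hallucinated occluded
  joints.
- **Triangulation**: linear SVD/DLT, exhaustive-pair RANSAC, 3D median
  filtering, and spatiotemporally regularized triangulation minimizing

  `L = L_proj + α_time L_time + α_limb L_limb`,

  with robustified reprojection residuals, an order-k finite-difference
  temporal penalty (`α_time = β_time · γ`, where γ is the reciprocal
  mean frame step of the linear initialization, making `β_time = 2`
  unit-free) and per-limb length residuals `((‖p₁−p₂‖ − d_l)/d_l)²`
  with the lengths `d_l` estimated jointly (`α_limb = 2`).
- **Kinematics**: three-point flexion angles, intrinsic {z, y, x} Euler
  decomposition of kinematic chains into rotation/flexion/abduction,
  angular velocities, windowed gait feature matrices for manifold
  embeddings, and step-phase estimation via a zero-phase first-order
  Butterworth band-pass plus the analytic signal.
- **Synthetic scenes**: camera rings, moving calibration boards, smooth
  band-limited trajectories with controlled corruption, and rigid
  articulated walkers — so the whole pipeline is testable without any
  recorded data.
- **Pipeline**: a standardized project layout
  (`calibration/ pose-2d/ pose-2d-filtered/ pose-3d/ angles/` per
  session) with strict JSON configuration, frozen per-output config
  provenance, idempotent stage re-runs, and a CLI
  (`exec/mocap3d simulate|calibrate|filter|triangulate|angles|run`).

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects
have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` helpers.

## Worked example

Simulate a 6-camera ring observing a moving calibration board, calibrate
from scratch, and reconstruct a rigid articulated walker:

```r
library(mocap3d)

rig   <- simulate_rig(6, radius = 10, elevation = 3, focal = 600, k1 = -0.02)
board <- board_geometry()           # 6x6 squares, 0.5 mm, 2x2 mm pattern
seqs  <- simulate_board_sequence(rig, board, n_frames = 300,
                                 noise_px = 0.5, seed = 2)
cal   <- calibrate_cameras(seqs$detections, board,
                           image_sizes = lapply(rig, `[[`, "image_size"),
                           seed = 1)
glance(cal)
#> # A tibble: 1 × 5
#>   n_iter mu_start mu_end mean_error median_error
#>    <int>    <dbl>  <dbl>      <dbl>        <dbl>
#> 1     12       15      1      0.552        0.517
```

A mean reprojection error of ~0.55 px against 0.5 px injected detection
noise means the calibration has absorbed essentially all recoverable
signal (the field's rule of thumb: below 3 px is usable, below 1 px is
good). Continue to 3D and joint angles:

```r
skel <- example_skeleton(2)                       # two 4-joint legs
traj <- simulate_articulated_walker(skel, n_frames = 120, seed = 3)
cand <- simulate_detections(traj, rig, noise_px = 2,
                            outlier_frac = 0.05, seed = 4)

fit <- cand |>
  filter_keypoints_viterbi(sigma = 10) |>
  triangulate_regularized(cal$rig, skel)          # beta_time = alpha_limb = 2

fit$limb_lengths
#> # A tibble: 6 × 3
#>   joint_a    joint_b    length
#>   <chr>      <chr>       <dbl>
#> 1 leg1_hip   leg1_knee   1.20
#> 2 leg1_knee  leg1_ankle  0.999
#> 3 leg1_ankle leg1_tip    0.802
#> 4 leg2_hip   leg2_knee   1.20
#> 5 leg2_knee  leg2_ankle  0.997
#> 6 leg2_ankle leg2_tip    0.801

angles <- chain_angles(fit$traj, skel$chains[[1]],
                       body_frame = c("origin", "head", "dorsum"))
```

The recovered `limb_lengths` sit within ~0.3% of the generator's rigid
segments (1.2, 1.0, 0.8 units), and the per-frame length scatter of the
regularized trajectory is strictly smaller than for plain linear
triangulation — the point of the limb penalty.

## Layout

```
R/                 camera model, slm solver, calibration, filters,
                   triangulation, kinematics, synthetic generators,
                   pipeline, plots
exec/mocap3d       CLI over the pipeline functions
scripts/acceptance.R
tests/testthat/    oracle-based unit + property tests
vignettes/methods.Rmd   models, parameters, design decisions
```
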