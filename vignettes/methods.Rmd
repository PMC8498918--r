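---
title: "Models and methods behind mocap3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mocap3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mocap3d)
```

mocap3d reconstructs 3D kinematics of articulated bodies (insect legs,
rodent limbs, human joints) from synchronized multi-camera video that has
already been reduced to per-frame 2D keypoint detections by an upstream
detector. This vignette explains the models the package implements, the
parameters that matter, what the synthetic generators emulate, and the
design choices made where several reasonable options existed.

## Camera model

Each camera is a reduced pinhole model with **8 free parameters**: an
axis-angle rotation (3), a translation (3), a single focal length
`f = fx = fy` in pixels (1), and one radial distortion coefficient `k1`
(1). The principal point is fixed at the image center and skew is zero.
This deliberate reduction — rather than the full 5-parameter intrinsics
and 3-parameter distortion — makes calibration much better conditioned
when the calibration board does not densely cover the field of view,
which is the common situation in behavioral rigs.

Projection composes as: rigid extrinsics, perspective divide, radial
distortion `x' = x (1 + k1 r^2)` applied in *normalized* camera
coordinates, then focal/principal-point scaling. Applying the distortion
in normalized rather than pixel coordinates makes `k1` independent of
the focal length; anyone comparing `k1` numerically with software that
distorts in pixel units must rescale by `f^2`. Points at or behind the
camera plane project to missing rather than wrapping. The inverse
distortion is a fixed-point iteration (at most 20 steps, tolerance
1e-10, convergence checked to 1e-8); for the `|k1| <= 0.3`, `r <= 0.5`
regime of real lenses it converges in a handful of iterations.

## Calibration

Calibration estimates all camera parameters from corner detections of a
planar board (a checkerboard with embedded markers, so corners have
known identities even under partial occlusion). The default board is
6 × 6 squares of 0.5 mm with 0.375 mm markers — a 2 × 2 mm pattern for
small-animal rigs; all dimensions are configurable.

1. **Covisibility graph.** Camera pairs are ranked by the number of
   frames in which both see the board; edges are added greedily (skip if
   already connected), yielding a spanning tree. Calibration is possible
   iff the graph is connected; a disconnected graph is a hard error that
   names the components, since no relative pose can link them.
2. **Intrinsics.** Per camera, each board view gives a plane-to-image
   homography; with the principal point pinned at the image center, the
   orthogonality and equal-norm constraints on the first two homography
   columns each yield a closed-form estimate of `f^2`. The focal is the
   median over all valid frame estimates; `k1` starts at 0. When every
   view is fronto-parallel (a known degeneracy in which `f` and depth
   trade off exactly) the package falls back to a field-of-view prior of
   `1.2 * max(image dimension)` with a warning.
3. **Extrinsics.** The tree root sits at the identity; each neighbor is
   initialized from the relative board pose in shared frames. Per-frame
   relative rotations are averaged with a *chordal geometric median*
   (Weiszfeld iteration on the 9 matrix entries, projected back to
   SO(3)). An axis-angle median was rejected: for camera pairs nearly
   opposite each other the relative rotation is close to 180 degrees,
   where the axis-angle representation is sign-ambiguous and per-frame
   estimates cluster at antipodes whose componentwise median is
   meaningless.
4. **Bundle adjustment.** All 8-parameter cameras and all per-(frame,
   corner) 3D points are refined jointly by sparse nonlinear least
   squares on the reprojection residuals, optionally robustified
   (Huber or soft-L1, scale 10 px by default, applied elementwise so
   the cost equals the robust loss exactly).
5. **Iterative bundle adjustment.** Robust losses alone are not enough
   when outliers are gross, so the package re-runs bundle adjustment 12
   times with a reprojection-error selection threshold decaying
   geometrically from 15 px to 1 px; only observations currently fitting
   better than the threshold are adjusted, and points seen by fewer than
   two selected cameras are dropped for that round. A random subsample
   of at most 100 detected frames (seeded from the project seed) bounds
   the per-iteration cost. If a threshold empties the selection the
   previous iterate is kept and the schedule continues.

Because absolute pose is unidentifiable (gauge freedom), all quality
comparisons against ground truth are made after a similarity alignment
(`align_similarity()`). One component of the gauge — global scale — is
not even damped by the data, so after the iterative schedule the package
re-anchors scale so that triangulated inter-corner distances match the
board's known geometry. Without this anchor the scale can drift several
percent over the 12 adjustment rounds, which would corrupt any
physical-length readout downstream while leaving pixel errors unchanged.

### The sparse solver

No sparse nonlinear least-squares solver exists in the R ecosystem this
package targets, and a dense Levenberg–Marquardt is infeasible at
thousands of 3D-point parameters, so mocap3d ships a compact solver
(`slm_least_squares()`): Levenberg–Marquardt with multiplicative
damping on `diag(J'J)`, normal equations solved by sparse Cholesky. The
Jacobian is built by *colored* forward differences: parameters that
share no residual (e.g. the x coordinates of all 3D points) are
perturbed together, so a full Jacobian costs about a dozen residual
evaluations regardless of problem size. Each caller supplies the
row-incidence of every parameter; bundle adjustment uses 11 groups
(8 camera-parameter slots + 3 point coordinates), and regularized
triangulation colors points by frame phase and limb-graph adjacency.

## 2D filters

Raw detector output contains jitter, confident hallucinations of
occluded joints, and multi-frame identity swaps. Three filters address
these, in increasing order of sophistication:

- **Median filter** (`filter_keypoints_median()`): points deviating more
  than `offset_threshold` (default 20 px) from the per-joint rolling
  median (default window 13) are removed and re-interpolated with a
  cubic spline; gaps longer than the window stay missing, and
  interpolated points get score 0 so downstream stages can ignore them.
- **Viterbi filter** (`filter_keypoints_viterbi()`): per joint and
  camera, the top-n candidate detections per frame are the states of a
  hidden Markov model — emission weight is the detection confidence,
  transition weight an isotropic Gaussian on displacement (default
  `sigma` 10 px, truncated at 6 sigma to keep the trellis sparse, in
  log-domain arithmetic). Duplicates within 7 px are merged first, and
  candidates are carried over up to `max_gap` (default 5) previous
  frames with probability multiplied by `2^-gap`, which bridges missed
  detections; frames whose decoded state is a carryover are emitted as
  missing since nothing was actually observed there. The decoder is the
  exact Viterbi maximizer, verified in the tests against exhaustive path
  enumeration.
- **Autoencoder filter** (`fit_score_autoencoder()` +
  `filter_keypoints_autoencoder()`): occluded joints often receive
  *high* confidence, so per-frame score vectors are corrected by a
  single-hidden-layer tanh perceptron (hidden width = number of joints,
  sigmoid outputs, Adam optimizer, mean-squared error against the
  visibility labels). Training data are synthesized: scores drawn from
  N(1, 0.3) for visible and N(0, 0.3) for occluded joints, clipped to
  [0, 1], with 5% of scores flipped `x -> 1 - x` to mimic false
  positives/negatives. The visibility sampler is a package choice (the
  score distributions are standard, the visibility process is not):
  each joint is independently visible with probability 0.8, and 10% of
  frames hide a contiguous block of joints to mimic one body part
  leaving view. Keypoints whose corrected score falls below
  `drop_threshold` (default 0.5) are removed. The training loss,
  epoch count (default 30) and this sampler are deliberately simple;
  the tests verify > 0.9 held-out visibility accuracy, far below the
  generator's Bayes accuracy, so the property is insensitive to these
  choices.

## Triangulation

- **Linear (SVD/DLT)**: observations are undistorted to normalized
  coordinates, each camera contributes two rows to a homogeneous system,
  and the point is the smallest right singular vector. Fast, exact for
  noiseless input, fragile to outliers. Fewer than two views means a
  missing point, never a guess.
- **3D median filter**: per-coordinate rolling median across frames.
- **RANSAC-style pair search**: with a handful of cameras the number of
  camera pairs is small enough to enumerate exhaustively, so the
  "consensus" search is exact: every pair is triangulated and the point
  minimizing the two-view squared reprojection objective wins. A single
  corrupted view can then never contaminate the result.
- **Spatiotemporally regularized triangulation**
  (`triangulate_regularized()`): the flagship method minimizes

  `L = L_proj + alpha_time * L_time + alpha_limb * L_limb`

  over all 3D points and one length parameter `d_l` per limb, where
  `L_proj` robustifies per-observation reprojection residuals (Huber,
  scale 10 px by default), `L_time` penalizes order-k finite differences
  of each joint trajectory (k = 2 by default; higher order preserves
  high-frequency content better than first differences), and `L_limb`
  penalizes `((|p_j1 - p_j2| - d_l)/d_l)^2` so every limb contributes on
  the same relative scale. Only the reprojection term is robustified;
  the temporal term is a plain squared norm. The temporal weight is
  `alpha_time = beta_time * gamma` with `gamma` the reciprocal mean
  frame-to-frame displacement of the linear-triangulation
  initialization, which makes `beta_time` unit-free and transferable
  across rigs; `beta_time = 2` and `alpha_limb = 2` are the defaults.
  `d_l` starts at the median limb length of the initialization; limbs
  marked flexible in the skeleton get their residual down-weighted by
  0.5. After optimization, points with reprojection error above
  `reproj_drop` (default 20 px) are masked, and so are frames of joints
  that were never observed (the initializer interpolates them only to
  keep the optimization connected). Long recordings are processed in
  500-frame chunks with 50-frame linearly blended overlaps, keeping
  memory linear in recording length.

The same temporal machinery is exposed directly on trajectories as
`smooth_temporal()` (a sparse linear solve, since without cameras the
problem is quadratic), which is what the synthetic reconstruction
benchmark uses.

## Joint angles

`flexion_angle()` is the arccosine of the dot product of the two
*normalized* segment vectors at a joint (the normalization is required
for the expression to be a valid cosine; the dot product is clamped to
[-1, 1] before `acos`).

`chain_angles()` solves the inverse-kinematics decomposition: every
joint with a distal segment gets an orthonormal frame (z along the
distal segment, x the proximal direction orthogonalized against z), and
the relative rotation between consecutive frames is read as intrinsic
{z, y, x} Euler angles — rotation (twist), flexion, abduction. Two
conventions close the under-determination that positions alone leave:

- The first joint has no proximal segment, so its frame's x axis is
  pinned using the body frame's -z axis as a stand-in proximal
  direction. The body frame itself comes from three user-named
  reference keypoints (origin, anterior, dorsal; Gram-Schmidt per
  frame) or can be the world frame. With this pinning the relative
  rotation between consecutive frames is *exactly* `Rz(rot) Ry(theta)`,
  so the abduction channel is structurally zero; it is reported (as 0)
  only for the first joint, matching the convention that only the most
  proximal joint may abduct. Out-of-plane motion of the first segment
  appears in its rotation/flexion pair.
- The twist of the terminal segment about its own axis is unobservable
  from positions and is simply never parameterized — equivalently, the
  most distal joint cannot rotate.

Flexion is reported as `180 - theta` degrees so it coincides with the
three-point `flexion_angle()` at every interior vertex (`theta` being
the angle between consecutive segment directions); it lies in [0, 180].
Near-straight or fully folded joints (`theta` near 0 or 180) are gimbal
locked and report missing rotation. `forward_kinematics_chain()` is the
exact inverse of this extraction, which the tests exploit as a
round-trip oracle (angle recovery to 1e-6 degrees, positions to 1e-9).

For gait analysis, `build_feature_vectors()` slices angle series and
their forward-difference derivatives into windows (32 samples for
300 Hz insect data, 24 for 50 Hz human data, stride 8) and standardizes
columns; zero-variance columns are centered but left unscaled, with a
warning, rather than producing NaNs. `estimate_phase()` band-passes an
angle with a first-order Butterworth (3–60 Hz default) applied
forward-backward (zero phase) and takes the phase of the analytic
signal; the Hilbert transform is computed by the standard FFT
half-spectrum method.

## Synthetic data

The generators define the study conditions under which everything above
is validated:

- `simulate_rig()`: n cameras evenly spaced on a ring, aimed at the
  origin — the canonical arrangement around a tethered animal. Default
  geometry: radius 10, elevation 3 (world units), 832 × 632 px images,
  focal 600 px, `k1 = -0.02` (mild barrel distortion).
- `simulate_board_sequence()`: the board moves through the shared view
  volume on a low-pass-filtered random walk in pose space (rotation
  amplitude 0.9 rad, translation 15% of the rig radius; 2nd-order
  Butterworth at 0.04 cycles/sample), chosen so most frames keep the
  full board visible in several cameras. Corruption: isotropic Gaussian
  pixel noise, a fraction of detections displaced by a fixed outlier
  magnitude in a random direction, out-of-image corners dropped.
- `simulate_trajectories()`: 30 unit-variance trajectories of 500
  samples, white noise low-passed at 0.12 cycles/sample (zero-phase,
  4th-order Butterworth) — the bench signal for temporal
  regularization. `corrupt_trajectories()` adds white noise (default
  0.3 × signal sd, a package choice since only the missing rate is
  canonical) and removes 10% of samples.
- `simulate_articulated_walker()`: sinusoidal joint-angle gaits pushed
  through the forward kinematics, so limb lengths are rigid *by
  construction* — the exact assumption of the limb loss.
  `simulate_detections()` then projects the walker and corrupts it the
  way a detector would: jitter, teleporting outliers that replace the
  top candidate, dropped detections, and spurious low-score duplicate
  candidates.

What these generators do **not** emulate: correlated (non-isotropic)
detector noise, occlusion that depends on viewing geometry,
appearance-driven identity swaps between left/right limbs, rolling
shutter, or desynchronized cameras. Passing tests therefore demonstrate
correctness of the estimators under the stated statistical conditions,
not performance on any particular recording setup.

## Numerical choices and limitations

- Problem sizes in the tests and acceptance runs (300-frame calibration
  sequences subsampled to 100 frames per adjustment round, 200-pose
  board evaluations, 50–120-frame walker scenes) were chosen as the
  smallest sizes at which the estimators' asymptotic behavior is
  visible; all scale linearly if increased.
- During optimization the projection clamps depth at 1e-6 instead of
  masking points behind the camera, so residuals stay differentiable;
  the user-facing `project_points()` masks.
- The Levenberg–Marquardt damping starts at 1e-4, divides by 3 on
  acceptance and multiplies by 10 on rejection; convergence is declared
  at a relative cost decrease below 1e-8 or a relative step below
  1e-10.
- Homography null spaces are taken from the eigendecomposition of the
  normal matrix after Hartley normalization, which exists even for the
  minimal 4-point system.
- The Viterbi path restarts when no transition is feasible (all
  candidates beyond 6 sigma or an empty frame beyond the carryover
  horizon); each maximal segment is decoded independently.
- `undistort_points()` flags non-convergent points as missing with a
  warning rather than failing.
- Calibration writes JSON with 17 significant digits so a round trip is
  bit-exact.
- Known limitations: no gauge constraints inside the optimizer (hence
  the post-hoc similarity alignment and board-scale anchor), no
  multi-animal correspondence, no pictorial-structure priors, and the
  abduction channel is structurally zero under the body-axis pinning
  described above.
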