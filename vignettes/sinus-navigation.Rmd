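---
title: "Monocular endoscope-to-CT navigation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monocular endoscope-to-CT navigation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sinusnav)
```

`sinusnav` localizes a monocular endoscope inside a preoperative CT
using only the video stream and the segmented sinus surface. This
vignette records the models the package implements, the conventions and
parameters it fixes, the choices made where the design was genuinely
open, and what its synthetic test harness does and does not demonstrate.

## Coordinate conventions

All cameras are right-handed with +z along the optical axis, +x right
and +y down — the common computer-vision convention, chosen because the
PnP and epipolar machinery is most naturally written in it. Poses are
stored camera-to-world (`sn_pose`): the rotation's columns are the
camera axes in the target frame and the translation is the camera
center, so trajectories and guidance read camera centers directly;
world-to-camera forms are derived on demand. Meshes and CT-frame poses
are in millimetres; SLAM-frame quantities are unitless up to the
recovered scale. Pixels are 0-based with the origin at the top-left;
trajectories use the TUM layout (`timestamp tx ty tz qx qy qz qw`).

Distortion is Brown–Conrady with `(k1, k2, p1, p2)`; higher-order radial
terms are not modelled. Undistortion inverts the forward model by fixed
point iteration (tolerance 1e-8 px, at most 50 iterations; divergence is
reported as invalid coefficients). The CT reference view is rendered as
an ideal pinhole, so reference pixels are used as-is and only endoscopic
pixels are undistorted — a deliberate asymmetry: undistorting a pixel of
an undistorted rendering would be wrong.

## Initialization

The reference view is produced by per-pixel ray casting against the
segmented surface. The depth map stores the camera-frame z coordinate of
the first hit (not the ray length), which makes backprojection linear in
depth; misses hold `NA`, never 0, because 0 is a plausible-looking but
invalid depth that would silently poison lifting. The shaded image is a
cosmetic Lambertian headlight render: only the depth map enters any
computation, so shading fidelity is explicitly out of the contract.

Operator-picked 2D–2D correspondences between the reference view and the
first endoscopic frame are lifted through the depth map with bilinear
interpolation over the finite neighbors; a pixel whose four neighbors
all miss is dropped (interpolating across a silhouette would fabricate
depths). The first-frame pose is solved by RANSAC PnP: hypotheses from
6-point DLT camera resection, inlier threshold 2 px, confidence 0.999,
at most 1000 iterations, followed by Levenberg–Marquardt refinement on
the inlier set only (the spec of the problem leaves open whether
refinement should use all points; restricting to inliers is the robust
choice). Everything is seeded and deterministic.

## SLAM core

The tracker is an interface: any function that returns per-frame pixel
positions and visibility for window query points. The built-in oracle
tracker replays a synthetic scene's precomputed tracks; a classical
pyramidal Lucas–Kanade tracker (3 levels, 7×7 windows) is provided for
real grayscale sequences. Windows span 8 frames and advance by 4; query
points persist across subsequent windows the way online trackers carry
queries forward, and observations of the same query from overlapping
windows merge by identity. A final clamped window covers trailing
frames.

Frames accumulate in section buffers of length `lm = 12` advancing by
`lm - 1`, so consecutive sections overlap in exactly one frame. The
first section is bootstrapped by a RANSAC essential-matrix solve
(8-point hypotheses, Sampson scoring, iterative refit on the consensus
set) with the cheirality-consistent decomposition and unit-norm
translation — the monocular gauge. Inliers must also triangulate with
bounded reprojection error: under the narrow baselines of endoscopy the
epipolar test alone cannot reject points displaced along near-epipolar
directions, but their skew rays fail triangulation. Remaining frames are
posed by Huber-robust pose refinement initialized from the nearest posed
frame (a motion prior; RANSAC-DLT is the fallback), new tracks with at
least 3 visible observations are triangulated (DLT plus Gauss–Newton,
rejected over 4 px reprojection or non-positive depth or near-parallel
rays), and a short bundle adjustment stabilizes the section after each
pose/triangulate round.

Local bundle adjustment minimizes the Huber-robustified (delta = 2 px)
reprojection cost over the section keyframes and all landmarks observed
in them, keeping older keyframes fixed. It is Levenberg–Marquardt with
IRLS Huber weights and an analytic sparse Jacobian; steps are accepted
only if the robust cost does not increase, so the cost trace is
monotone. The 7-degree gauge freedom of monocular bundle adjustment is
pinned by holding the first keyframe pose fixed and restoring the norm
of the first-to-second-keyframe baseline after every accepted step (a
similarity re-normalization, which leaves the cost unchanged).
Observations at non-positive depth contribute nothing to a step and any
move that leaves points behind a camera is rejected by the cost.

After each section the map is filtered: observations reprojecting beyond
4 px are removed, landmarks with fewer than two observations are
dropped, and landmarks whose observing rays subtend less than 1 degree
of parallax are culled — their depths are essentially unconstrained, and
a handful of them can dominate any distance-based consumer of the map
(the scale estimator and registration-error evaluations most of all).
The section is then re-adjusted once. Every section frame becomes a
keyframe: the simplest deterministic reading of incremental keyframe
output; parallax-based keyframe subsampling was considered and left out
for determinism.

## Scale recovery and CT mapping

Monocular reconstruction leaves one global scale unknown. After the
first section, the landmarks observed in the first keyframe are paired
with CT surface points by casting rays from the PnP-registered
first-frame pose through the same image positions; the scale is the
ratio of the longest lines (maximum pairwise distances) of the CT and
SLAM clouds. The two maxima are taken independently in each cloud — the
natural reading of a ratio of longest lines; pairing enters only through
the correspondence construction. The estimate is recomputed at every
section event over the current bundle-refined landmark set, and a ratio
of RMS centroid distances is available behind `scale_method = "rms"` as
a robust alternative.

Because a maximum is maximally outlier-sensitive, pairs whose distance
from the first camera exceeds 3× the median in either cloud are dropped
before the ratio: on the CT side these are long grazing rays, on the
SLAM side badly-triangulated far landmarks, both of which would
otherwise set the longest line. The guard is symmetric by design — the
dominant outlier mechanism in practice is a SLAM-side landmark at
essentially unbounded depth.

The registration rotation and translation are fixed by the first-frame
PnP solve; scale updates recompute only the similarity's translation so
that the first keyframe's CT pose is exactly preserved (anchor
preservation — drifting the anchor would contradict its definition).
Only the scale is ever re-estimated after initialization. A
constant-scale mode (`constant_scale = TRUE`, scale ≡ 1) exists as an
ablation harness.

Two mapped trajectories are reported: the emission-time trajectory
(each keyframe mapped with the registration current when it was
produced — what a live consumer would have seen) and the completed
trajectory (the final map under the final registration), which is the
natural object for absolute-trajectory-error evaluation.

## Guidance

The "pointer" is the line through the camera center along the optical
axis — the only line a pivot-pointer analogy supports; its first
intersection with the anatomy is the guidance point, `NULL` when the
endoscope views free space. Triplane indices are the nearest-integer
voxel coordinates of the intersection under the volume affine, clamped
to the volume with a flag. The image-space reference mark corresponds to
the principal point.

## Evaluation

Translation error is the L2 distance of camera centers. The general
rotation error is the residual-rotation angle
`arccos((tr(R Rref^T) - 1) / 2)` with the argument clamped to [-1, 1]
(floating-point traces exceed the bounds by ulps); the rotation inverse
is the transpose since orthonormality is enforced at construction.
Per-axis errors are the angles between corresponding rotation columns;
the translation-alignment clause in their definition has no effect on
angles and is treated as such. Retrospective evaluation first fits the
closed-form (Umeyama) similarity from estimated to reference camera
centers — the evaluation a tracker-informed post-hoc registration gives
— and pose pairs are matched by nearest timestamp within half the
reference frame interval. The half-split TRE builds SLAM-to-CT 3D
correspondences by ray-casting each landmark's first observation from
the reference pose of its first observing keyframe, fits the similarity
on a seeded random half, and reports RMS distances on the fitting half
(residual) and the held-out half (TRE).

## The synthetic scene generator

Scenes emulate a sinus-corridor inspection: a tube of configurable
length (default 60 mm) and base radius (8 mm) with a smooth seeded wall
perturbation (0.8 mm amplitude), an interior trajectory advancing
0.5 mm per frame over 60 frames (within the sequence-length range of
recorded clinical inspections) with about 1 degree of orientation
jitter, a 200×200 px camera with a 67-degree field of view, 25 query
points per tracking window, Gaussian pixel noise and per-observation
dropout, a true SLAM-to-CT similarity of configurable scale (default
17), and a 2.3 mm spherical fiducial seated on the wall ahead of the
trajectory. Landmarks are sampled by ray casting from each window's
first camera, so they lie exactly on the surface and are visible at
their query frame; visibility elsewhere is decided by occlusion ray
casts.

Two generator choices deserve a note. The camera path carries a small
lateral meander (default 1 mm) about the centerline: a perfectly
straight path makes camera centers exactly collinear, and center-based
similarity alignment — the retrospective evaluation itself — is then
rotationally degenerate; no hand-held endoscope moves on a line. And the
tube's far end is open by default (`cap_far_end = TRUE` closes it),
trading forward-view tissue intersections against the extreme viewing
depths a distant end cap creates.

What passing tests on these scenes show is that the geometry, the
estimators and their couplings are implemented correctly, and that the
pipeline degrades gracefully under pixel noise and dropout. What they
cannot show is robustness to the things the generator does not emulate:
specular highlights and shadows, textureless mucosa where real trackers
fail in correlated ways, tissue deformation, endoscope withdrawal and
reinsertion, and calibration error. Depth-dependent shadow-like failure
modes can only be approximated via dropout and the far-depth outlier
mechanisms discussed above.

## Numerical choices and degenerate inputs

Orthonormality violations up to 1e-6 are repaired by projection to the
nearest rotation, beyond that rejected. Triangulation treats smallest
singular values below 1e-8 of the largest (near-parallel rays) and
identical camera centers as degenerate. RANSAC stopping uses the
standard adaptive bound with the log evaluated via `log1p` (the naive
form underflows to a spurious immediate stop at low inlier counts).
Bundle adjustment stops on a relative cost decrease below 1e-12 or 30
accepted steps; the adjust–filter–readjust cycle runs once per section.
Ray casts ignore hits closer than 1e-9 mm (self-intersection guard), and
the half-split TRE breaks ties by landmark order with a seeded uniform
split. Scale updates that fail (for example when every first-view ray
misses) retain the previous scale with a warning rather than
interrupting navigation.

Test and acceptance runs use 14–60-frame scenes with 25 query points per
window, chosen so the whole suite exercises multi-section incremental
behaviour while remaining quick to run; the stochastic checks use
medians over 10–20 fixed seeds.

## Known limitations

- Scale observability: the longest-line estimator inherits the accuracy
  of the first keyframe's landmark depths. Under 1 px noise its error is
  a few percent, and because the rotation/translation anchor is fixed,
  scale error converts directly into translation error far from the
  anchor — the dominant term in navigation-mode translation error, and
  the reason the constant-scale ablation is much worse again.
- Local-only optimization: there is no loop closure and no global bundle
  adjustment, so the map's internal scale drifts slowly across sections;
  the per-event scale updates track the first section's neighbourhood,
  not the drifted tail.
- No relocalization: withdrawal and reinsertion of the endoscope is not
  handled.
- The classical Lucas–Kanade tracker is a baseline for real sequences,
  not a replacement for a learned tracker; on low-texture tissue it will
  lose points quickly.
- Real-data formats: meshes are read from ASCII PLY/OBJ/STL only, and
  the renderer is not photorealistic by design.
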