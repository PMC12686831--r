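# sinusnav

Monocular vision-based navigation for endoscopic sinus surgery, in R.

Functional endoscopic sinus surgery is guided by a monocular endoscope;
navigation systems that localize the scope inside the preoperative CT
normally need external optical or electromagnetic trackers. `sinusnav`
implements a tracker-free alternative that uses only the endoscope video
and the segmented CT surface:

1. **Incremental monocular SLAM.** 2D point tracks from a sliding-window
   tracker (window of n = 8 frames advancing by 4; the tracker is a
   pluggable interface with a synthetic oracle and a classical pyramidal
   Lucas–Kanade implementation built in) are accumulated in section
   buffers of length *l* = 12 advancing by *l* − 1. Each section is
   bootstrapped or extended by essential-matrix / PnP solves, landmarks
   are triangulated, and poses and structure are refined by local bundle
   adjustment (Levenberg–Marquardt on a Huber-robustified reprojection
   cost with analytic sparse Jacobians; gauge fixed by the first keyframe
   pose and the first baseline norm).
2. **Semi-automated first-frame registration.** A reference view
   `(I_ct, D_ct) = render(S, T_ct)` is rendered from the CT surface S at
   an operator-chosen pose. User-picked 2D–2D correspondences between
   the reference view and the first endoscopic frame are lifted to 3D
   through the rendered depth map and a RANSAC PnP solve returns the
   first endoscopic pose in CT coordinates.
3. **Continuous monocular scale recovery.** Monocular SLAM reconstructs
   pose and structure only up to scale. Landmarks visible from the first
   keyframe are paired with CT surface points by ray-casting their image
   positions from the PnP-registered pose; the SLAM-to-CT scale is the
   ratio of the longest lines (maximum pairwise distances) of the two
   point clouds, re-estimated at every keyframe event as the
   reconstruction densifies, with an outlier guard against far-depth
   points. The registration stays anchored so the first keyframe's CT
   pose never drifts.
4. **Guidance.** Every registered pose yields the viewing-axis line, its
   first intersection with the anatomy, and triplane (axial / coronal /
   sagittal) voxel indices; streams export as TUM trajectories, JSON
   lines, and 3D Slicer markups.
5. **Evaluation.** Translation error (L2 on camera centers), the general
   rotation error `arccos((tr(R Rref^-1) - 1) / 2)`, per-axis angles,
   retrospective similarity (Umeyama) alignment, half-split target
   registration error of the SLAM point cloud, and fiducial
   point-to-mesh distances.

No clinical data ships with the package. A first-class synthetic scene
generator builds tubular sinus-like cavities, interior endoscope
trajectories, noisy sliding-window point tracks and full ground truth,
so every stage and the end-to-end pipeline are testable offline.

## Worked example

```r
library(sinusnav)

# a synthetic inspection: 60 frames through an 8 mm corridor, 1 px
# tracking noise, true SLAM-to-CT scale 17
cfg   <- scene_config(noise_sd_px = 1, seed = 7)
scene <- make_scene(cfg)
run   <- navigate_scene(scene, seed = 7)

print(run$slam$map)
#> SLAM map: 56 keyframes, 321 landmarks, 3930 observations

print(run$nav_state$registration)
#> similarity: scale 0.548233, translation (0.9801, 0.1753, 6)

head(run$scale_state$history, 3)
#>   keyframe     scale
#> 1       12 0.4904091
#> 2       23 0.5493877
#> 3       34 0.5482326
```

The registration scale is per SLAM unit: the SLAM gauge normalizes the
bootstrap baseline, so the recovered value (0.548 mm per unit here) is
the product of the configured true scale with that gauge. The history
shows the estimate settling as more structure accumulates.

```r
ref <- scene_reference_trajectory(scene, run$trajectory_ct$timestamps)
ev  <- evaluate_run(run$trajectory_ct, ref, mode = "navigation")
round(unlist(ev$summary[c("translation_mean", "translation_sd",
                          "rotation_mean", "rotation_sd")]), 3)
#> translation_mean   translation_sd    rotation_mean      rotation_sd
#>            0.807            0.744            2.195            2.083

tre <- tre_halfsplit(run$slam$map, scene$poses_ct[run$slam$map$frames + 1],
                     scene$mesh, scene$intr, seed = 7)
round(c(residual_mm = tre$residual_mm, tre_mm = tre$tre_mm), 2)
#> residual_mm      tre_mm
#>        3.37        4.22
```

In-navigation errors (poses mapped to CT as they are produced, with the
scale known at that moment) are 0.81 ± 0.74 mm and 2.2 ± 2.1° against
the ground-truth trajectory on this scene; the half-split registration
of the SLAM point cloud against the CT surface leaves a 3.4 mm residual
and a 4.2 mm target registration error on held-out points.

A thin command-line front end wraps the same functions:

```sh
sinusnav simulate --config scene.yaml --out scenedir/
sinusnav init-reg --mesh m.ply --ref-pose pose.yaml --intrinsics k.yaml \
         --corr corr.csv --seed 7 --out reg.yaml
sinusnav navigate --scene scenedir/ --seed 1 --out rundir/
sinusnav evaluate --est rundir/trajectory_ct.tum --ref scenedir/poses_ct.tum
```

(`exec/sinusnav` is installed with the package; call it via
`Rscript $(Rscript -e 'cat(system.file("exec/sinusnav", package = "sinusnav"))')`
or put it on your PATH.)

## Vignette

`vignettes/sinus-navigation.Rmd` documents the model and its
assumptions, the coordinate conventions, every tunable parameter with
units and defaults, what the synthetic scenes do and do not emulate, and
the known limitations.
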