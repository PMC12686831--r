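## Synthetic navigation scenes: a tubular cavity standing in for the
## segmented sinus corridor, an interior camera trajectory, surface
## landmarks with noisy sliding-window point tracks, a first-frame
## correspondence set against a rendered reference view, a spherical
## fiducial on the wall, and the full ground truth (CT-frame and
## SLAM-frame poses, landmarks, true SLAM-to-CT similarity). Everything is
## reproducible bit-for-bit from (config, seed).

#' Synthetic scene configuration
#'
#' Defaults describe a nasal-corridor-scale cavity explored by a slowly
#' advancing endoscope: a 60 mm tube of 8 mm base radius with gentle wall
#' undulation, 60 frames advancing 0.5 mm per frame (about 30 mm of
#' travel), a 200 x 200 px camera with a 67 degree field of view, 25 query
#' points per 8-frame tracking window, and a true SLAM-to-CT scale of 17.
#'
#' @param tube_length_mm,base_radius_mm Cavity dimensions.
#' @param perturb_amp_mm,perturb_freq Radial wall perturbation amplitude
#'   and angular/axial frequency (0 gives a perfect cylinder).
#' @param n_frames Number of frames.
#' @param frame_spacing_mm Camera advance per frame along the centerline.
#' @param jitter_deg Standard deviation of the per-frame orientation
#'   jitter about the tangent direction.
#' @param lateral_amp_mm Amplitude of the slow lateral meander of the
#'   camera path about the centerline (a perfectly straight path would
#'   make similarity-based trajectory alignment rotationally degenerate,
#'   which no hand-held endoscope motion is).
#' @param points_per_window Query points sampled per tracking window.
#' @param window_n,window_step Sliding tracking window size and step.
#' @param noise_sd_px Gaussian pixel noise added per observation coordinate.
#' @param dropout Per-observation dropout probability in `[0, 1)`.
#' @param true_scale CT millimetres per SLAM unit of the synthetic SLAM
#'   frame.
#' @param fiducial_diameter_mm Diameter of the spherical wall fiducial.
#' @param cap_far_end Close the far end of the tube with a fan of
#'   triangles (default `FALSE`, an open-ended corridor). Capping makes
#'   forward-looking views intersect tissue the way a closed cavity does,
#'   at the price of extreme viewing depths.
#' @param n_corr,corr_noise_px First-frame correspondence count and pixel
#'   noise.
#' @param ref_offset_mm Setback of the CT reference camera behind the
#'   first frame along the optical axis.
#' @param fx,fy,cx,cy,width,height Camera intrinsics (pixels).
#' @param dist Brown-Conrady coefficients of the synthetic camera.
#' @param seed Integer seed controlling every random choice.
#' @return A list of class `sn_scene_config`.
#' @export
scene_config <- function(tube_length_mm = 60, base_radius_mm = 8,
                         perturb_amp_mm = 0.8, perturb_freq = 3,
                         n_frames = 60, frame_spacing_mm = 0.5,
                         jitter_deg = 1, lateral_amp_mm = 1,
                         points_per_window = 25,
                         window_n = 8, window_step = 4,
                         noise_sd_px = 0, dropout = 0,
                         true_scale = 17, fiducial_diameter_mm = 2.3,
                         cap_far_end = FALSE,
                         n_corr = 10, corr_noise_px = 0, ref_offset_mm = 2,
                         fx = 150, fy = 150, cx = 99.5, cy = 99.5,
                         width = 200, height = 200, dist = c(0, 0, 0, 0),
                         seed = 1) {
  stopifnot(tube_length_mm > 0, base_radius_mm > 0, perturb_amp_mm >= 0,
            perturb_amp_mm < base_radius_mm, n_frames >= 2,
            frame_spacing_mm > 0, dropout >= 0, dropout < 1,
            true_scale > 0, fiducial_diameter_mm > 0, n_corr >= 4)
  cfg <- as.list(environment())
  structure(cfg, class = "sn_scene_config")
}

scene_intrinsics <- function(cfg) {
  intrinsics(cfg$fx, cfg$fy, cfg$cx, cfg$cy, cfg$width, cfg$height,
             dist = cfg$dist)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Generate the tubular cavity mesh
#'
#' A tube along +z of the configured length whose radius is modulated by a
#' smooth seeded perturbation; with zero amplitude the tube wall is a
#' perfect cylinder. The near end is open; the far end is closed by a
#' triangle fan when `cap_far_end` is set. The inner surface is visible
#' from the centerline.
#'
#' @param cfg `sn_scene_config`.
#' @param nz,ntheta Axial and angular tessellation.
#' @return An `sn_mesh`.
#' @export
make_cavity_mesh <- function(cfg, nz = 48, ntheta = 32) {
  with_seed(cfg$seed * 7 + 1, {
    phase_z <- runif(1, 0, 2 * pi)
    phase_t <- runif(1, 0, 2 * pi)
  })
  z <- seq(0, cfg$tube_length_mm, length.out = nz + 1)
  th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  grid <- expand.grid(th = th, z = z)
  r <- cfg$base_radius_mm + cfg$perturb_amp_mm *
    sin(2 * pi * cfg$perturb_freq * grid$z / cfg$tube_length_mm + phase_z) *
    cos(cfg$perturb_freq * grid$th + phase_t)
  vertices <- cbind(r * cos(grid$th), r * sin(grid$th), grid$z)
  idx <- function(i, j) (i - 1) * ntheta + ((j - 1) %% ntheta) + 1
  faces <- NULL
  fl <- vector("list", nz)
  for (i in seq_len(nz)) {
    j <- seq_len(ntheta)
    a <- idx(i, j); b <- idx(i, j + 1); c <- idx(i + 1, j); d <- idx(i + 1, j + 1)
    fl[[i]] <- rbind(cbind(a, b, c), cbind(b, d, c))
  }
  faces <- do.call(rbind, fl)
  if (isTRUE(cfg$cap_far_end)) {
    center <- nrow(vertices) + 1L
    vertices <- rbind(vertices, c(0, 0, cfg$tube_length_mm))
    ring <- (nz * ntheta) + seq_len(ntheta)
    faces <- rbind(faces, cbind(ring, c(ring[-1], ring[1]), center))
  }
  surface_mesh(vertices, faces)
}

#' Generate an interior camera trajectory
#'
#' Camera centers advance along the tube, following a slow lateral
#' meander about the centerline; the optical axis is the tube direction
#' (+z) with small seeded orientation jitter.
#'
#' @param cfg `sn_scene_config`.
#' @param z_start Centerline coordinate of the first frame.
#' @return List of CT-frame `sn_pose`.
#' @export
make_trajectory <- function(cfg, z_start = 6) {
  rand <- with_seed(cfg$seed * 7 + 2, {
    list(jit = matrix(rnorm(3 * cfg$n_frames,
                            sd = cfg$jitter_deg * pi / 180), ncol = 3),
         phase = runif(2, 0, 2 * pi))
  })
  u <- (seq_len(cfg$n_frames) - 1) / max(cfg$n_frames - 1, 1)
  lat_x <- cfg$lateral_amp_mm * sin(2 * pi * 1.5 * u + rand$phase[1])
  lat_y <- cfg$lateral_amp_mm * sin(2 * pi * 1.0 * u + rand$phase[2])
  lapply(seq_len(cfg$n_frames), function(i) {
    R <- if (cfg$jitter_deg > 0) rotvec_to_rot(rand$jit[i, ]) else diag(3)
    rigid_pose(R, c(lat_x[i], lat_y[i],
                    z_start + (i - 1) * cfg$frame_spacing_mm),
               frame = "ct")
  })
}

# Is landmark X visible (unoccluded, in bounds, in front) from pose?
landmark_visible <- function(mesh, pose, intr, X) {
  pr <- project_points(intr, pose, X)
  vis <- pr$valid
  if (!any(vis)) return(vis)
  idx <- which(vis)
  d <- X[idx, , drop = FALSE] - matrix(pose$t, length(idx), 3, byrow = TRUE)
  len <- sqrt(rowSums(d^2))
  hit <- raycast(mesh, pose$t, d / len)
  ok <- hit$hit & abs(hit$distance - len) < 1e-6 * pmax(len, 1) + 1e-9
  vis[idx] <- ok
  vis
}

#' Generate landmarks and their sliding-window point tracks
#'
#' For each tracking window, fresh query points are sampled by casting
#' rays from the window's first camera through random pixels onto the
#' cavity wall (so every landmark lies exactly on the mesh and is visible
#' at its query frame). Query points persist across subsequent windows the
#' way an online point tracker carries its queries forward: each landmark
#' is observed in every later frame until it first leaves view (out of
#' bounds or occluded), at which point the track ends. Gaussian pixel
#' noise is added per coordinate and observations are dropped out
#' independently with the configured probability (dropout leaves the
#' track alive).
#'
#' @param cfg `sn_scene_config`.
#' @param mesh `sn_mesh`.
#' @param poses CT-frame trajectory from [make_trajectory()].
#' @param intr `sn_intrinsics`.
#' @return List with `landmarks` (L x 3, CT frame), `track_window`
#'   (origin window start per landmark) and `tracks` (`sn_track_table`,
#'   track id = landmark row).
#' @export
make_observations <- function(cfg, mesh, poses, intr) {
  tcfg <- tracker_config(cfg$window_n, cfg$window_step, cfg$points_per_window)
  starts <- tracking_windows(cfg$n_frames, tcfg)
  margin <- 15
  landmarks <- NULL; track_window <- integer(0); rows <- list()
  with_seed(cfg$seed * 7 + 3, {
    for (s in starts) {
      pose_s <- poses[[s + 1]]
      # sample wall points visible from the window's first camera
      got <- NULL
      attempts <- 0
      while ((is.null(got) || nrow(got) < cfg$points_per_window) &&
             attempts < 8) {
        attempts <- attempts + 1
        px <- cbind(runif(3 * cfg$points_per_window, margin,
                          intr$width - margin),
                    runif(3 * cfg$points_per_window, margin,
                          intr$height - margin))
        ideal <- undistort_points(intr, px)
        dirs <- cbind((ideal[, 1] - intr$cx) / intr$fx,
                      (ideal[, 2] - intr$cy) / intr$fy, 1)
        dirs <- (dirs / sqrt(rowSums(dirs^2))) %*% t(pose_s$R)
        hit <- raycast(mesh, pose_s$t, dirs)
        got <- rbind(got, hit$point[hit$hit, , drop = FALSE])
      }
      if (is.null(got) || nrow(got) < 2) next
      got <- got[seq_len(min(nrow(got), cfg$points_per_window)), ,
                 drop = FALSE]
      base_id <- if (is.null(landmarks)) 0L else nrow(landmarks)
      landmarks <- rbind(landmarks, got)
      track_window <- c(track_window, rep(s, nrow(got)))
      alive <- rep(TRUE, nrow(got))
      for (f in s:(cfg$n_frames - 1)) {
        if (!any(alive)) break
        pose_f <- poses[[f + 1]]
        vis <- rep(FALSE, nrow(got))
        vis[alive] <- landmark_visible(mesh, pose_f, intr,
                                       got[alive, , drop = FALSE])
        alive <- alive & vis  # tracker loses points that leave view
        if (!any(alive)) break
        pr <- project_points(intr, pose_f, got)
        pix <- pr$pixels
        if (cfg$noise_sd_px > 0)
          pix <- pix + matrix(rnorm(length(pix), sd = cfg$noise_sd_px),
                              ncol = 2)
        seen <- alive
        if (cfg$dropout > 0)
          seen <- seen & (runif(nrow(got)) >= cfg$dropout)
        inb <- pix[, 1] >= 0 & pix[, 1] < intr$width &
          pix[, 2] >= 0 & pix[, 2] < intr$height
        keep <- alive
        rows[[length(rows) + 1]] <-
          data.frame(track_id = base_id + which(keep),
                     frame = f, x = pix[keep, 1], y = pix[keep, 2],
                     visible = (seen & inb)[keep])
      }
    }
  })
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  list(landmarks = landmarks, track_window = track_window,
       tracks = track_table(tracks))
}

# UV-sphere mesh used for the wall fiducial.
sphere_mesh <- function(center, radius, n_lat = 12, n_lon = 16) {
  lat <- seq(0, pi, length.out = n_lat + 1)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  verts <- list(c(0, 0, radius))
  for (i in 2:n_lat)
    for (j in seq_len(n_lon))
      verts[[length(verts) + 1]] <-
        radius * c(sin(lat[i]) * cos(lon[j]), sin(lat[i]) * sin(lon[j]),
                   cos(lat[i]))
  verts[[length(verts) + 1]] <- c(0, 0, -radius)
  V <- sweep(do.call(rbind, verts), 2, center, `+`)
  top <- 1L; bottom <- nrow(V)
  ring <- function(i) 1L + (i - 2L) * n_lon + seq_len(n_lon)
  faces <- list()
  r1 <- ring(2)
  faces[[1]] <- cbind(top, r1, c(r1[-1], r1[1]))
  for (i in 2:(n_lat - 1)) {
    ra <- ring(i); rb <- ring(i + 1)
    ra2 <- c(ra[-1], ra[1]); rb2 <- c(rb[-1], rb[1])
    faces[[length(faces) + 1]] <- rbind(cbind(ra, rb, rb2),
                                        cbind(ra, rb2, ra2))
  }
  rl <- ring(n_lat)
  faces[[length(faces) + 1]] <- cbind(bottom, c(rl[-1], rl[1]), rl)
  surface_mesh(V, do.call(rbind, faces))
}

#' Assemble a complete synthetic navigation scene
#'
#' Builds the cavity mesh, trajectory, landmarks and tracks, the synthetic
#' SLAM frame (the CT world mapped through the inverse of a random true
#' similarity with the configured scale), the CT reference render and the
#' first-frame correspondence file, and a spherical fiducial seated on the
#' wall ahead of the trajectory.
#'
#' @param cfg `sn_scene_config`.
#' @param render_reference_view Compute the reference render and the
#'   correspondence set (default `TRUE`; the render dominates generation
#'   time).
#' @return An object of class `sn_scene` with elements `cfg`, `intr`,
#'   `mesh`, `fiducial`, `poses_ct`, `poses_slam`, `landmarks_ct`,
#'   `landmarks_slam`, `track_window`, `tracks`, `registration_truth`
#'   (`sn_similarity`, SLAM to CT), `ref_pose`, `ref_render` (or `NULL`),
#'   `corr` (or `NULL`).
#' @export
make_scene <- function(cfg, render_reference_view = TRUE) {
  intr <- scene_intrinsics(cfg)
  mesh <- make_cavity_mesh(cfg)
  poses_ct <- make_trajectory(cfg)
  obs <- make_observations(cfg, mesh, poses_ct, intr)
  truth <- with_seed(cfg$seed * 7 + 4, {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    similarity_transform(cfg$true_scale, quat_to_rot(q), runif(3, -30, 30))
  })
  inv <- similarity_invert(truth)
  poses_slam <- lapply(poses_ct, function(p)
    apply_similarity_pose(inv, p, frame = "slam"))
  landmarks_slam <- apply_similarity_points(inv, obs$landmarks)
  # fiducial sphere seated on the wall ahead of the trajectory
  z_fid <- min(poses_ct[[cfg$n_frames]]$t[3] + 8,
               cfg$tube_length_mm - cfg$fiducial_diameter_mm)
  th_fid <- with_seed(cfg$seed * 7 + 5, runif(1, 0, 2 * pi))
  wall <- raycast(mesh, c(0, 0, z_fid),
                  c(cos(th_fid), sin(th_fid), 0))
  fid_center <- as.numeric(wall$point[1, ])
  fiducial <- sphere_mesh(fid_center, cfg$fiducial_diameter_mm / 2)
  ref_render <- NULL; corr <- NULL; ref_pose <- NULL
  axis0 <- as.numeric(poses_ct[[1]]$R[, 3])
  ref_pose <- rigid_pose(poses_ct[[1]]$R,
                         poses_ct[[1]]$t - cfg$ref_offset_mm * axis0,
                         frame = "ct")
  if (render_reference_view) {
    ref_render <- render_reference(mesh, ref_pose, intr)
    corr <- make_reference_correspondences(cfg, mesh, ref_render, ref_pose,
                                           poses_ct[[1]], intr)
  }
  structure(list(cfg = cfg, intr = intr, mesh = mesh, fiducial = fiducial,
                 fiducial_center = fid_center,
                 poses_ct = poses_ct, poses_slam = poses_slam,
                 landmarks_ct = obs$landmarks,
                 landmarks_slam = landmarks_slam,
                 track_window = obs$track_window, tracks = obs$tracks,
                 registration_truth = truth, ref_pose = ref_pose,
                 ref_render = ref_render, corr = corr),
            class = "sn_scene")
}

#' @export
print.sn_scene <- function(x, ...) {
  cat(sprintf(paste0("synthetic scene: %d frames, %d landmarks, %d track ",
                     "rows, true scale %.3g, seed %d\n"),
              x$cfg$n_frames, nrow(x$landmarks_ct), nrow(x$tracks),
              x$cfg$true_scale, x$cfg$seed))
  invisible(x)
}

# First-frame correspondences: integer reference pixels with finite depth
# whose surface point is visible in frame 0. At integer pixels the
# bilinear depth lookup is exact, so lifting reproduces the surface point
# to machine precision.
make_reference_correspondences <- function(cfg, mesh, ref_render, ref_pose,
                                           pose0, intr) {
  d <- ref_render$depth
  h <- nrow(d); w <- ncol(d)
  margin <- 15
  cand <- which(is.finite(d), arr.ind = TRUE)  # (row=y+1, col=x+1)
  cand <- cand[cand[, 1] > margin & cand[, 1] <= h - margin &
                 cand[, 2] > margin & cand[, 2] <= w - margin, , drop = FALSE]
  with_seed(cfg$seed * 7 + 6, {
    ord <- sample.int(nrow(cand))
    picked <- NULL
    for (i in ord) {
      x_ct <- c(cand[i, 2] - 1, cand[i, 1] - 1)
      X <- backproject_pixels(intr, ref_pose, x_ct, d[cand[i, 1], cand[i, 2]])
      if (!landmark_visible(mesh, pose0, intr, X)) next
      pr <- project_points(intr, pose0, X)
      x_rgb <- pr$pixels[1, ]
      if (cfg$corr_noise_px > 0)
        x_rgb <- x_rgb + rnorm(2, sd = cfg$corr_noise_px)
      if (any(x_rgb < 0) || x_rgb[1] >= intr$width || x_rgb[2] >= intr$height)
        next
      picked <- rbind(picked, c(x_ct, x_rgb))
      if (nrow(picked) >= cfg$n_corr) break
    }
    if (is.null(picked) || nrow(picked) < 4)
      stop("could not generate enough reference correspondences")
    correspondence_set(data.frame(x_ct = picked[, 1], y_ct = picked[, 2],
                                  x_rgb = picked[, 3], y_rgb = picked[, 4]))
  })
}

#' Oracle tracker over a synthetic scene
#'
#' Returns a tracker function for [track_section()] that replays the
#' scene's precomputed noisy tracks window by window: a window reports
#' every track whose query point was issued at or before the window start
#' and that is still alive in the window. Query-point identity is the
#' landmark id, so merging the overlapping windows reconstructs the
#' scene's track table.
#'
#' @param scene `sn_scene`.
#' @return A function `tracker(frame_indices)`.
#' @export
make_oracle_tracker <- function(scene) {
  tracks <- as.data.frame(scene$tracks)
  origin <- scene$track_window
  function(win) {
    ids <- which(origin <= win[1])
    tracks[tracks$track_id %in% ids & tracks$frame %in% win, ]
  }
}

## ---- scene serialization ---------------------------------------------------

pose_to_list <- function(p) list(quaternion_xyzw = as.list(rot_to_quat(p$R)),
                                 translation = as.list(p$t))
pose_from_list <- function(l, frame) rigid_pose(quat_to_rot(unlist(l$quaternion_xyzw)),
                                                unlist(l$translation), frame)

#' Write / read a scene bundle on disk
#'
#' Plain-text bundle: `mesh.ply`, `fiducial.ply`, `poses_ct.tum`,
#' `poses_slam.tum`, `tracks.csv`, `corr.csv` (when present),
#' `landmarks.csv`, `config.yaml`, `truth.yaml`. The reference render is
#' not stored; it is recomputed from the mesh and reference pose.
#'
#' @param scene `sn_scene`.
#' @param dir Output directory (created if needed).
#' @return `read_scene` returns the reconstructed `sn_scene` (with
#'   `ref_render = NULL`; pass `render = TRUE` to recompute it).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ply_mesh(scene$mesh, file.path(dir, "mesh.ply"))
  write_ply_mesh(scene$fiducial, file.path(dir, "fiducial.ply"))
  n <- length(scene$poses_ct)
  write_tum(list(timestamps = 0:(n - 1), poses = scene$poses_ct),
            file.path(dir, "poses_ct.tum"))
  write_tum(list(timestamps = 0:(n - 1), poses = scene$poses_slam),
            file.path(dir, "poses_slam.tum"))
  write_tracks(scene$tracks, file.path(dir, "tracks.csv"))
  if (!is.null(scene$corr))
    write_correspondences(scene$corr, file.path(dir, "corr.csv"))
  lmk <- data.frame(track_id = seq_len(nrow(scene$landmarks_ct)),
                    window = scene$track_window,
                    x = scene$landmarks_ct[, 1], y = scene$landmarks_ct[, 2],
                    z = scene$landmarks_ct[, 3])
  write.csv(format(lmk, digits = 17, trim = TRUE), file.path(dir, "landmarks.csv"),
            row.names = FALSE, quote = FALSE)
  yaml::write_yaml(unclass(scene$cfg), file.path(dir, "config.yaml"),
                   precision = 17)
  yaml::write_yaml(
    list(registration = list(scale = scene$registration_truth$s,
                             quaternion_xyzw = as.list(rot_to_quat(scene$registration_truth$R)),
                             translation_mm = as.list(scene$registration_truth$t)),
         ref_pose = pose_to_list(scene$ref_pose),
         fiducial_center_mm = as.list(scene$fiducial_center)),
    file.path(dir, "truth.yaml"), precision = 17)
  invisible(dir)
}

#' @rdname write_scene
#' @param render Recompute the reference render and correspondences on
#'   reading (default `FALSE`).
#' @export
read_scene <- function(dir, render = FALSE) {
  cfg <- do.call(scene_config, yaml::read_yaml(file.path(dir, "config.yaml")))
  truth_y <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  truth <- similarity_transform(truth_y$registration$scale,
                                quat_to_rot(unlist(truth_y$registration$quaternion_xyzw)),
                                unlist(truth_y$registration$translation_mm))
  lmk <- read.csv(file.path(dir, "landmarks.csv"))
  corr_path <- file.path(dir, "corr.csv")
  scene <- structure(list(
    cfg = cfg, intr = scene_intrinsics(cfg),
    mesh = load_mesh(file.path(dir, "mesh.ply")),
    fiducial = load_mesh(file.path(dir, "fiducial.ply")),
    fiducial_center = unlist(truth_y$fiducial_center_mm),
    poses_ct = read_tum(file.path(dir, "poses_ct.tum"), frame = "ct")$poses,
    poses_slam = read_tum(file.path(dir, "poses_slam.tum"), frame = "slam")$poses,
    landmarks_ct = as.matrix(lmk[, c("x", "y", "z")]),
    landmarks_slam = NULL,
    track_window = lmk$window,
    tracks = read_tracks(file.path(dir, "tracks.csv")),
    registration_truth = truth,
    ref_pose = pose_from_list(truth_y$ref_pose, "ct"),
    ref_render = NULL, corr = NULL), class = "sn_scene")
  scene$landmarks_slam <- apply_similarity_points(similarity_invert(truth),
                                                  scene$landmarks_ct)
  if (file.exists(corr_path)) scene$corr <- read_correspondences(corr_path)
  if (render) {
    scene$ref_render <- render_reference(scene$mesh, scene$ref_pose,
                                         scene$intr)
  }
  scene
}

#' Ground-truth SLAM map of a scene
#'
#' Builds an `sn_slam_map` directly from the scene truth: SLAM-frame
#' keyframe poses, SLAM-frame landmark positions, and the (possibly noisy)
#' tracked observations. Useful for exercising the scale-recovery and
#' evaluation modules independently of the SLAM estimator.
#'
#' @param scene `sn_scene`.
#' @param keyframes 0-based frame indices to include (default: all).
#' @param min_obs Minimum visible observations for a landmark to be kept.
#' @return An `sn_slam_map` in the synthetic SLAM frame.
#' @export
truth_slam_map <- function(scene, keyframes = NULL, min_obs = 2) {
  if (is.null(keyframes)) keyframes <- 0:(scene$cfg$n_frames - 1)
  tr <- as.data.frame(scene$tracks)
  tr <- tr[tr$visible & tr$frame %in% keyframes, ]
  cnt <- table(tr$track_id)
  keep_ids <- as.integer(names(cnt[cnt >= min_obs]))
  tr <- tr[tr$track_id %in% keep_ids, ]
  lm_ids <- sort(unique(tr$track_id))
  obs <- data.frame(landmark = match(tr$track_id, lm_ids),
                    kf = match(tr$frame, keyframes),
                    x = tr$x, y = tr$y)
  slam_map(keyframes, scene$poses_slam[keyframes + 1],
           scene$landmarks_slam[lm_ids, , drop = FALSE], obs,
           track_id = lm_ids)
}
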