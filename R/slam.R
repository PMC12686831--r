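## Incremental monocular SLAM core: sliding-window point tracking through a
## pluggable tracker, section-buffer accumulation, essential-matrix
## two-view bootstrap, DLT triangulation and local bundle adjustment over
## each section. Frame indices are 0-based throughout (matching the track
## table); keyframe indices into the map are 1-based.

#' Sliding-window tracker configuration
#'
#' @param window_n Frames per tracking window (default 8).
#' @param window_step Frames advanced between windows (default 4); must be
#'   smaller than `window_n` so consecutive windows overlap.
#' @param points_per_window Query points sampled per window.
#' @return A list of class `sn_tracker_config`.
#' @export
tracker_config <- function(window_n = 8, window_step = 4,
                           points_per_window = 25) {
  stopifnot(window_n >= 1, window_step >= 1, window_step < window_n,
            points_per_window >= 1)
  structure(list(window_n = as.integer(window_n),
                 window_step = as.integer(window_step),
                 points_per_window = as.integer(points_per_window)),
            class = "sn_tracker_config")
}

#' Construct / validate a track table
#'
#' Long-format table of 2D point tracks: one row per (track, frame)
#' observation with columns `track_id, frame, x, y, visible`. Frames are
#' 0-based; pixels use the top-left origin.
#'
#' @param df Data frame with the five columns above.
#' @return The validated data frame with class `sn_track_table`.
#' @export
track_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("track_id", "frame", "x", "y", "visible")
  if (!all(need %in% names(df))) stop("track table needs columns ",
                                      paste(need, collapse = ","))
  df <- df[, need]
  df$track_id <- as.integer(df$track_id)
  df$frame <- as.integer(df$frame)
  df$visible <- as.logical(df$visible)
  class(df) <- c("sn_track_table", "data.frame")
  df
}

#' @rdname track_table
#' @param path CSV path (`track_id,frame,x,y,visible`).
#' @export
read_tracks <- function(path) track_table(read.csv(path))

#' @rdname track_table
#' @param tracks An `sn_track_table`.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(as.data.frame(tracks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Window start frames of the sliding tracker
#'
#' Windows advance by `window_step`; when trailing frames would otherwise
#' stay uncovered, one extra window clamped to the end of the stream is
#' appended (an online tracker keeps sliding until the sequence ends).
#'
#' @param n_frames Number of frames in the stream.
#' @param cfg `sn_tracker_config`.
#' @return Integer vector of 0-based window start frames.
#' @export
tracking_windows <- function(n_frames, cfg) {
  if (n_frames < cfg$window_n) return(0L)
  last <- n_frames - cfg$window_n
  starts <- seq(0L, last, by = cfg$window_step)
  if (starts[length(starts)] < last) starts <- c(starts, as.integer(last))
  starts
}

#' Run a tracker over all sliding windows and merge the results
#'
#' The tracker is a function `tracker(frame_indices)` returning a track
#' table restricted to those frames, with globally meaningful track ids
#' (query-point identity): observations of the same id from overlapping
#' windows are merged, keeping the first occurrence of each (track, frame)
#' pair. Out-of-bounds pixels are marked invisible.
#'
#' @param tracker Tracker function (see [make_oracle_tracker()],
#'   [make_klt_tracker()]).
#' @param n_frames Number of frames.
#' @param cfg `sn_tracker_config`.
#' @param intr `sn_intrinsics` used for the bounds check.
#' @return An `sn_track_table`.
#' @export
track_section <- function(tracker, n_frames, cfg, intr) {
  if (n_frames < 2) stop("tracking requires at least 2 frames")
  starts <- tracking_windows(n_frames, cfg)
  pieces <- lapply(starts, function(s) {
    win <- s:min(s + cfg$window_n - 1L, n_frames - 1L)
    as.data.frame(tracker(win))
  })
  all <- do.call(rbind, pieces)
  all <- all[!duplicated(all[, c("track_id", "frame")]), ]
  oob <- all$x < 0 | all$x >= intr$width | all$y < 0 | all$y >= intr$height
  all$visible <- all$visible & !oob & is.finite(all$x) & is.finite(all$y)
  all <- all[order(all$track_id, all$frame), ]
  rownames(all) <- NULL
  track_table(all)
}

#' Section-buffer frame ranges
#'
#' Section k covers frames `[k*(lm-1), k*(lm-1)+lm-1]`; consecutive
#' sections overlap in exactly one frame. Trailing frames that cannot fill
#' a section are dropped; a stream shorter than `lm` yields a single
#' truncated section (at least 2 frames) with a warning.
#'
#' @param n_frames Number of frames.
#' @param lm Section buffer length (must exceed the tracking window).
#' @return List of integer vectors of 0-based frame indices.
#' @export
accumulate_section <- function(n_frames, lm) {
  stopifnot(lm >= 2)
  if (n_frames < lm) {
    if (n_frames < 2) stop("need at least 2 frames")
    warning("stream shorter than the section buffer; emitting one truncated section")
    return(list(0:(n_frames - 1L)))
  }
  k_max <- floor((n_frames - lm) / (lm - 1))
  lapply(0:k_max, function(k) (k * (lm - 1L)):(k * (lm - 1L) + lm - 1L))
}

## ---- map container ---------------------------------------------------------

#' SLAM map: keyframe poses plus landmarks with 2D observations
#'
#' @param frames Integer vector of 0-based frame indices, one per keyframe.
#' @param poses List of `sn_pose` (SLAM frame), one per keyframe.
#' @param landmarks L x 3 matrix of landmark positions (SLAM units).
#' @param observations Data frame `landmark, kf, x, y`: `landmark` is a
#'   1-based row of `landmarks`, `kf` a 1-based keyframe index.
#' @param track_id Optional integer vector mapping landmarks to track ids.
#' @param gauge_norm Norm of the first-to-second keyframe baseline pinned
#'   by the bundle-adjustment gauge (`NA` before the first adjustment).
#' @return An object of class `sn_slam_map`.
#' @export
slam_map <- function(frames, poses, landmarks, observations,
                     track_id = NULL, gauge_norm = NA_real_) {
  stopifnot(length(frames) == length(poses))
  landmarks <- if (is.null(landmarks)) matrix(0, 0, 3) else as_points(landmarks)
  observations <- as.data.frame(observations)
  if (nrow(observations) > 0) {
    stopifnot(all(c("landmark", "kf", "x", "y") %in% names(observations)))
    if (max(observations$kf) > length(poses) || min(observations$kf) < 1)
      stop("observation keyframe index out of range")
    if (nrow(landmarks) > 0 && max(observations$landmark) > nrow(landmarks))
      stop("observation landmark index out of range")
  }
  structure(list(frames = as.integer(frames), poses = poses,
                 landmarks = landmarks, observations = observations,
                 track_id = track_id, gauge_norm = gauge_norm),
            class = "sn_slam_map")
}

#' @export
print.sn_slam_map <- function(x, ...) {
  cat(sprintf("SLAM map: %d keyframes, %d landmarks, %d observations\n",
              length(x$poses), nrow(x$landmarks), nrow(x$observations)))
  invisible(x)
}

obs_per_landmark <- function(map) {
  tabulate(map$observations$landmark, nbins = nrow(map$landmarks))
}

## ---- two-view bootstrap ----------------------------------------------------

eight_point_E <- function(ya, yb) {
  # Hartley-normalized linear estimate of the essential matrix from
  # normalized image coordinates; yb' E ya = 0.
  norm8 <- function(y) {
    mu <- colMeans(y)
    d <- sqrt(rowSums(sweep(y, 2, mu)^2))
    s <- sqrt(2) / max(mean(d), 1e-12)
    T <- rbind(c(s, 0, -s * mu[1]), c(0, s, -s * mu[2]), c(0, 0, 1))
    list(y = cbind(sweep(y, 2, mu) * s, 1), T = T)
  }
  na <- norm8(ya); nb <- norm8(yb)
  A <- cbind(nb$y[, 1] * na$y, nb$y[, 2] * na$y, na$y)
  sv <- svd(A, nu = 0, nv = 9)
  Eh <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  E <- t(nb$T) %*% Eh %*% na$T
  se <- svd(E)
  # enforce the essential-matrix singular-value structure (1, 1, 0)
  se$u %*% diag(c(1, 1, 0)) %*% t(se$v)
}

sampson_dist <- function(E, ya, yb) {
  xa <- cbind(ya, 1); xb <- cbind(yb, 1)
  Ex <- xa %*% t(E)
  Etx <- xb %*% E
  num <- rowSums(xb * Ex)^2
  den <- Ex[, 1]^2 + Ex[, 2]^2 + Etx[, 1]^2 + Etx[, 2]^2
  num / pmax(den, 1e-300)
}

#' Two-view bootstrap: relative pose and initial structure
#'
#' Estimates the essential matrix between two frames from their shared
#' tracks (RANSAC over 8-point samples, Sampson-distance scoring), selects
#' the cheirality-consistent decomposition, and triangulates the inlier
#' tracks. The translation is normalized to unit length (the monocular
#' gauge); the returned pose is the camera-to-world pose of `frame_b` in
#' `frame_a`'s camera frame.
#'
#' @param tracks `sn_track_table` (pixels are undistorted internally).
#' @param intr `sn_intrinsics`.
#' @param frame_a,frame_b 0-based frame indices.
#' @param threshold_px Inlier threshold in pixels (default 2).
#' @param seed RNG seed.
#' @param max_iter RANSAC iterations (default 500).
#' @return List with `pose_b` (`sn_pose`), `points` (k x 3 triangulated
#'   landmarks), `track_ids` (their track ids) and `inlier_track_ids`
#'   (the consistent set: epipolar inliers that also triangulate with a
#'   bounded reprojection error and positive depth in both views).
#' @export
bootstrap_two_view <- function(tracks, intr, frame_a, frame_b,
                               threshold_px = 2, seed = 1, max_iter = 500) {
  ta <- tracks[tracks$frame == frame_a & tracks$visible, ]
  tb <- tracks[tracks$frame == frame_b & tracks$visible, ]
  shared <- intersect(ta$track_id, tb$track_id)
  if (length(shared) < 8) stop("two-view bootstrap needs at least 8 shared tracks")
  pa <- as.matrix(ta[match(shared, ta$track_id), c("x", "y")])
  pb <- as.matrix(tb[match(shared, tb$track_id), c("x", "y")])
  pa <- undistort_points(intr, pa); pb <- undistort_points(intr, pb)
  ya <- cbind((pa[, 1] - intr$cx) / intr$fx, (pa[, 2] - intr$cy) / intr$fy)
  yb <- cbind((pb[, 1] - intr$cx) / intr$fx, (pb[, 2] - intr$cy) / intr$fy)
  n <- length(shared)
  thr <- (threshold_px / mean(c(intr$fx, intr$fy)))^2
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  best_inl <- NULL; best_cnt <- -1
  for (it in seq_len(max_iter)) {
    idx <- sample.int(n, 8)
    E <- eight_point_E(ya[idx, , drop = FALSE], yb[idx, , drop = FALSE])
    d <- sampson_dist(E, ya, yb)
    inl <- d <= thr
    if (sum(inl) > best_cnt) { best_cnt <- sum(inl); best_inl <- inl }
    if (best_cnt == n) break
  }
  if (best_cnt < 8) stop("two-view bootstrap found no 8-point consensus")
  # iteratively refit on the consensus set until the inlier set is stable;
  # a single refit can retain outliers the contaminated hypothesis admitted
  inl <- best_inl
  for (refit in 1:5) {
    E <- eight_point_E(ya[inl, , drop = FALSE], yb[inl, , drop = FALSE])
    d <- sampson_dist(E, ya, yb)
    inl_new <- d <= thr
    if (identical(inl_new, inl)) break
    inl <- inl_new
    if (sum(inl) < 8) stop("two-view bootstrap found no 8-point consensus")
  }
  # decompose; x_b = R x_a + t up to scale, four candidates
  se <- svd(E)
  W <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  U <- se$u; V <- se$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  cands <- list()
  for (Rc in list(U %*% W %*% t(V), U %*% t(W) %*% t(V)))
    for (tc in list(U[, 3], -U[, 3]))
      cands[[length(cands) + 1]] <- list(R = Rc, t = tc)
  pose_a <- rigid_pose(frame = "slam")
  score <- function(cand) {
    pose_b <- rigid_pose(t(cand$R), as.numeric(-t(cand$R) %*% cand$t),
                         frame = "slam")
    idx <- which(inl)
    pts <- matrix(NA_real_, length(idx), 3)
    ok <- logical(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      # reprojection-checked triangulation: skew rays (points the epipolar
      # test cannot reject under narrow baselines) fail here
      tri <- try_triangulate(list(pose_a, pose_b),
                             rbind(pa[i, ], pb[i, ]), intr,
                             reproj_px = threshold_px)
      if (is.null(tri)) next
      za <- tri$point[3]
      zb <- (cand$R %*% tri$point + cand$t)[3]
      if (za > 0 && zb > 0) { ok[j] <- TRUE; pts[j, ] <- tri$point }
    }
    list(n = sum(ok), pose_b = pose_b, pts = pts, ok = ok)
  }
  scored <- lapply(cands, score)
  counts <- vapply(scored, `[[`, 0, "n")
  best <- scored[[which.max(counts)]]
  if (max(counts) < 8 || max(counts) < 0.75 * sum(inl))
    stop("degenerate two-view geometry (pure rotation or planar ambiguity); ",
         "choose a different frame pair")
  keep <- which(inl)[best$ok]
  list(pose_b = best$pose_b,
       points = best$pts[best$ok, , drop = FALSE],
       track_ids = shared[keep],
       inlier_track_ids = shared[keep])
}

## ---- triangulation ---------------------------------------------------------

try_triangulate <- function(poses, pixels, intr, reproj_px = Inf) {
  res <- tryCatch(triangulate_point(poses, pixels, intr, reproj_px = reproj_px),
                  error = function(e) NULL)
  res
}

#' Triangulate a landmark from two or more observations
#'
#' Linear DLT solution refined by Gauss-Newton on the reprojection error.
#' Signals an error for degenerate geometry (identical camera centers /
#' near-parallel rays) and when any observation ends up behind a camera or
#' reprojects worse than `reproj_px`.
#'
#' @param poses List of camera-to-world `sn_pose`, one per observation.
#' @param pixels n x 2 matrix of (undistorted) pixels.
#' @param intr `sn_intrinsics`.
#' @param reproj_px Acceptance threshold on the per-observation
#'   reprojection error (default `Inf`).
#' @return List with `point` (length-3), `rms_px`.
#' @export
triangulate_point <- function(poses, pixels, intr, reproj_px = Inf) {
  n <- length(poses)
  stopifnot(n >= 2, nrow(pixels) == n)
  centers <- trajectory_centers(poses)
  if (max(dist(centers)) < 1e-12) stop("degenerate: identical camera centers")
  A <- matrix(0, 2 * n, 4)
  for (i in seq_len(n)) {
    R_wc <- t(poses[[i]]$R)
    t_wc <- as.numeric(-R_wc %*% poses[[i]]$t)
    P <- cbind(R_wc, t_wc)
    xn <- (pixels[i, 1] - intr$cx) / intr$fx
    yn <- (pixels[i, 2] - intr$cy) / intr$fy
    A[2 * i - 1, ] <- xn * P[3, ] - P[1, ]
    A[2 * i, ] <- yn * P[3, ] - P[2, ]
  }
  sv <- svd(A, nu = 0, nv = 4)
  if (abs(sv$v[4, 4]) < 1e-12 || sv$d[3] < 1e-8 * sv$d[1])
    stop("degenerate triangulation geometry (near-parallel rays)")
  X <- sv$v[1:3, 4] / sv$v[4, 4]
  # Gauss-Newton refinement of the 3D point on reprojection error
  for (it in 1:15) {
    r <- numeric(2 * n); J <- matrix(0, 2 * n, 3)
    for (i in seq_len(n)) {
      R_wc <- t(poses[[i]]$R)
      xc <- as.numeric(R_wc %*% (X - poses[[i]]$t))
      if (xc[3] <= 1e-12) { r[] <- NA; break }
      u <- intr$fx * xc[1] / xc[3] + intr$cx
      v <- intr$fy * xc[2] / xc[3] + intr$cy
      r[c(2 * i - 1, 2 * i)] <- c(u - pixels[i, 1], v - pixels[i, 2])
      dpix <- rbind(c(intr$fx / xc[3], 0, -intr$fx * xc[1] / xc[3]^2),
                    c(0, intr$fy / xc[3], -intr$fy * xc[2] / xc[3]^2))
      J[c(2 * i - 1, 2 * i), ] <- dpix %*% R_wc
    }
    if (any(is.na(r))) break
    H <- crossprod(J) + 1e-12 * diag(3)
    step <- tryCatch(solve(H, -crossprod(J, r)), error = function(e) NULL)
    if (is.null(step)) break
    X_new <- X + as.numeric(step)
    X <- X_new
    if (sqrt(sum(step^2)) < 1e-14) break
  }
  # acceptance checks: positive depth everywhere, bounded reprojection
  errs <- numeric(n)
  for (i in seq_len(n)) {
    xc <- as.numeric(t(poses[[i]]$R) %*% (X - poses[[i]]$t))
    if (xc[3] <= 0) stop("triangulated point behind a camera")
    u <- intr$fx * xc[1] / xc[3] + intr$cx
    v <- intr$fy * xc[2] / xc[3] + intr$cy
    errs[i] <- sqrt((u - pixels[i, 1])^2 + (v - pixels[i, 2])^2)
  }
  if (any(errs > reproj_px)) stop("triangulation rejected: reprojection ",
                                  signif(max(errs), 3), " px")
  list(point = X, rms_px = sqrt(mean(errs^2)))
}

## ---- local bundle adjustment ----------------------------------------------

huber_rho <- function(e, delta) {
  ifelse(e <= delta, 0.5 * e^2, delta * (e - 0.5 * delta))
}

# Build the (residual, analytic Jacobian) system for the current BA
# state as a sparse matrix. State: world-to-camera rotations/translations
# per keyframe, landmarks. Parameters: per free keyframe a left rotation
# increment (3) and a translation increment (3); per free landmark a
# position increment (3). Column layout: [6 per free keyframe][3 per free
# landmark]; rows come in (u, v) pairs per observation.
ba_system <- function(Rwc, twc, X, obs, intr, free_kf, free_lm) {
  n_obs <- nrow(obs)
  kf_col <- match(obs$kf, free_kf)      # NA when the keyframe is fixed
  lm_col <- match(obs$landmark, free_lm)
  n_par <- 6 * length(free_kf) + 3 * length(free_lm)
  r <- numeric(2 * n_obs)
  trip_i <- vector("list", 0); trip_j <- vector("list", 0)
  trip_x <- vector("list", 0)
  push <- function(i, j, x) {
    trip_i[[length(trip_i) + 1]] <<- i
    trip_j[[length(trip_j) + 1]] <<- j
    trip_x[[length(trip_x) + 1]] <<- x
  }
  for (k in unique(obs$kf)) {
    sel <- which(obs$kf == k)
    l <- obs$landmark[sel]
    R <- Rwc[[k]]; tw <- twc[[k]]
    cam <- X[l, , drop = FALSE] %*% t(R)
    cam <- sweep(cam, 2, tw, `+`)
    x <- cam[, 1]; y <- cam[, 2]; z <- cam[, 3]
    # observations at non-positive depth contribute nothing to the step
    # (the robust cost rejects moves that keep points behind the camera)
    z <- ifelse(z <= 1e-9, NA_real_, z)
    u <- intr$fx * x / z + intr$cx
    v <- intr$fy * y / z + intr$cy
    r[2 * sel - 1] <- ifelse(is.na(z), 0, u - obs$x[sel])
    r[2 * sel] <- ifelse(is.na(z), 0, v - obs$y[sel])
    a1 <- ifelse(is.na(z), 0, intr$fx / z)
    a3 <- ifelse(is.na(z), 0, -intr$fx * x / z^2)
    b2 <- ifelse(is.na(z), 0, intr$fy / z)
    b3 <- ifelse(is.na(z), 0, -intr$fy * y / z^2)
    z <- ifelse(is.na(z), 1, z)  # keep arithmetic below finite
    kc <- kf_col[sel][1]
    if (!is.na(kc)) {
      # xc(dw, dt) = exp([dw]) Rwc X + twc + dt; v = Rwc X = xc - twc
      v1 <- x - tw[1]; v2 <- y - tw[2]; v3 <- z - tw[3]
      rowsu <- rep(2 * sel - 1, 6); rowsv <- rep(2 * sel, 6)
      cols <- rep(6 * (kc - 1) + 1:6, each = length(sel))
      push(rowsu, cols, c(a3 * v2, a1 * v3 - a3 * v1, -a1 * v2,
                          a1, rep(0, length(sel)), a3))
      push(rowsv, cols, c(-b2 * v3 + b3 * v2, -b3 * v1, b2 * v1,
                          rep(0, length(sel)), b2, b3))
    }
    lc <- lm_col[sel]
    ok <- !is.na(lc)
    if (any(ok)) {
      so <- sel[ok]; lco <- lc[ok]
      # d xc / dX = Rwc; pixel rows are a1*R[1,] + a3*R[3,] etc.
      Ju <- cbind(a1[ok] * R[1, 1] + a3[ok] * R[3, 1],
                  a1[ok] * R[1, 2] + a3[ok] * R[3, 2],
                  a1[ok] * R[1, 3] + a3[ok] * R[3, 3])
      Jv <- cbind(b2[ok] * R[2, 1] + b3[ok] * R[3, 1],
                  b2[ok] * R[2, 2] + b3[ok] * R[3, 2],
                  b2[ok] * R[2, 3] + b3[ok] * R[3, 3])
      base <- 6 * length(free_kf) + 3 * (lco - 1)
      cols <- c(base + 1, base + 2, base + 3)
      push(rep(2 * so - 1, 3), cols, as.numeric(Ju))
      push(rep(2 * so, 3), cols, as.numeric(Jv))
    }
  }
  J <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(2 * n_obs, n_par))
  list(r = r, J = J)
}

ba_apply_step <- function(Rwc, twc, X, step, free_kf, free_lm) {
  for (j in seq_along(free_kf)) {
    k <- free_kf[j]
    dw <- step[6 * (j - 1) + 1:3]
    dt <- step[6 * (j - 1) + 4:6]
    Rwc[[k]] <- rotvec_to_rot(dw) %*% Rwc[[k]]
    twc[[k]] <- twc[[k]] + dt
  }
  if (length(free_lm) > 0) {
    off <- 6 * length(free_kf)
    X[free_lm, ] <- X[free_lm, ] +
      matrix(step[(off + 1):(off + 3 * length(free_lm))], ncol = 3, byrow = TRUE)
  }
  list(Rwc = Rwc, twc = twc, X = X)
}

ba_cost <- function(Rwc, twc, X, obs, intr, delta) {
  total <- 0
  for (k in unique(obs$kf)) {
    sel <- obs$kf == k
    cam <- X[obs$landmark[sel], , drop = FALSE] %*% t(Rwc[[k]])
    cam <- sweep(cam, 2, twc[[k]], `+`)
    z <- cam[, 3]
    if (any(z <= 1e-12)) return(Inf)
    u <- intr$fx * cam[, 1] / z + intr$cx
    v <- intr$fy * cam[, 2] / z + intr$cy
    e <- sqrt((u - obs$x[sel])^2 + (v - obs$y[sel])^2)
    total <- total + sum(huber_rho(e, delta))
  }
  total
}

#' Local bundle adjustment over a section of keyframes
#'
#' Jointly refines the poses of the section keyframes and the positions of
#' every landmark observed in the section, minimizing the Huber-robustified
#' reprojection error by Levenberg-Marquardt with analytic Jacobians.
#' Keyframes outside the section are held fixed, as are the first keyframe
#' pose and the scale gauge (the norm of the first-to-second keyframe
#' baseline, restored after every accepted step). The robust cost is
#' non-increasing across accepted steps.
#'
#' @param map `sn_slam_map` (observation pixels must be undistorted).
#' @param section_kf Integer vector of 1-based keyframe indices to optimize.
#' @param intr `sn_intrinsics`.
#' @param robust_delta_px Huber threshold in pixels (default 2).
#' @param max_iter Maximum accepted LM iterations (default 30).
#' @param tol Relative cost-decrease stopping tolerance.
#' @return List with `map` (refined), `mean_reproj_px`, `cost_trace`
#'   (robust cost after each accepted step) and `converged`.
#' @export
local_bundle_adjust <- function(map, section_kf, intr, robust_delta_px = 2,
                                max_iter = 30, tol = 1e-12) {
  stopifnot(length(map$poses) >= 2)
  section_kf <- sort(unique(as.integer(section_kf)))
  free_kf <- setdiff(section_kf, 1L)  # first keyframe pinned (gauge)
  Rwc <- lapply(map$poses, function(p) t(p$R))
  twc <- lapply(map$poses, function(p) as.numeric(-t(p$R) %*% p$t))
  X <- map$landmarks
  obs_all <- map$observations
  lm_in_section <- sort(unique(obs_all$landmark[obs_all$kf %in% section_kf]))
  nobs_lm <- tabulate(obs_all$landmark, nbins = nrow(X))
  free_lm <- lm_in_section[nobs_lm[lm_in_section] >= 2]
  # residuals: every observation of a free landmark, plus observations of
  # fixed landmarks in free keyframes
  use <- obs_all$landmark %in% free_lm | obs_all$kf %in% free_kf
  obs <- obs_all[use, , drop = FALSE]
  if (nrow(obs) > 0) {
    z0 <- vapply(seq_len(nrow(obs)), function(i)
      (Rwc[[obs$kf[i]]] %*% X[obs$landmark[i], ] + twc[[obs$kf[i]]])[3],
      numeric(1))
    if (any(z0 <= 1e-9)) obs <- obs[z0 > 1e-9, , drop = FALSE]
  }
  if (nrow(obs) == 0 || (length(free_kf) == 0 && length(free_lm) == 0))
    return(list(map = map, mean_reproj_px = NA_real_, cost_trace = numeric(0),
                converged = TRUE))
  gauge_norm <- map$gauge_norm
  if (!is.finite(gauge_norm)) {
    c0 <- -as.numeric(t(Rwc[[1]]) %*% twc[[1]])
    c1 <- -as.numeric(t(Rwc[[2]]) %*% twc[[2]])
    gauge_norm <- sqrt(sum((c1 - c0)^2))
  }
  renorm <- function(Rwc, twc, X) {
    c0 <- -as.numeric(t(Rwc[[1]]) %*% twc[[1]])
    c1 <- -as.numeric(t(Rwc[[2]]) %*% twc[[2]])
    s <- gauge_norm / sqrt(sum((c1 - c0)^2))
    if (!is.finite(s) || abs(s - 1) < 1e-15) return(list(Rwc = Rwc, twc = twc, X = X))
    for (k in seq_along(Rwc)) {
      ck <- -as.numeric(t(Rwc[[k]]) %*% twc[[k]])
      ck <- c0 + s * (ck - c0)
      twc[[k]] <- as.numeric(-Rwc[[k]] %*% ck)
    }
    X <- sweep(sweep(X, 2, c0) * s, 2, c0, `+`)
    list(Rwc = Rwc, twc = twc, X = X)
  }
  delta <- robust_delta_px
  cost0 <- ba_cost(Rwc, twc, X, obs, intr, delta)
  trace <- numeric(0)
  lambda <- 1e-6
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sys <- ba_system(Rwc, twc, X, obs, intr, free_kf, free_lm)
    # IRLS Huber weights on the 2-vector residual norm per observation
    en <- sqrt(sys$r[c(TRUE, FALSE)]^2 + sys$r[c(FALSE, TRUE)]^2)
    w <- ifelse(en <= delta, 1, delta / pmax(en, 1e-300))
    sw <- sqrt(rep(w, each = 2))
    Jw <- Matrix::Diagonal(x = sw) %*% sys$J
    rw <- sys$r * sw
    H <- Matrix::crossprod(Jw)
    g <- as.numeric(Matrix::crossprod(Jw, rw))
    accepted <- FALSE
    for (tries in 1:10) {
      step <- tryCatch(
        suppressWarnings(as.numeric(
          Matrix::solve(H + lambda * Matrix::Diagonal(nrow(H)), -g))),
        error = function(e) NULL)
      if (!is.null(step) && !anyNA(step) && all(is.finite(step))) {
        new <- ba_apply_step(Rwc, twc, X, as.numeric(step), free_kf, free_lm)
        new <- renorm(new$Rwc, new$twc, new$X)
        cost1 <- ba_cost(new$Rwc, new$twc, new$X, obs, intr, delta)
        if (is.finite(cost1) && cost1 <= cost0) {
          Rwc <- new$Rwc; twc <- new$twc; X <- new$X
          improvement <- cost0 - cost1
          cost0 <- cost1
          trace <- c(trace, cost1)
          lambda <- max(lambda / 4, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) break
    if (improvement <= tol * (cost0 + 1e-300)) { converged <- TRUE; break }
  }
  poses <- lapply(seq_along(Rwc), function(k)
    rigid_pose(t(Rwc[[k]]), as.numeric(-t(Rwc[[k]]) %*% twc[[k]]),
               frame = map$poses[[k]]$frame))
  out <- slam_map(map$frames, poses, X, obs_all, track_id = map$track_id,
                  gauge_norm = gauge_norm)
  err <- reprojection_errors(out, intr)
  list(map = out, mean_reproj_px = mean(err$error_px), cost_trace = trace,
       converged = converged || length(trace) > 0)
}

#' Per-observation reprojection errors of a SLAM map
#'
#' @param map `sn_slam_map`.
#' @param intr `sn_intrinsics`.
#' @return Data frame `landmark, kf, error_px`.
#' @export
reprojection_errors <- function(map, intr) {
  obs <- map$observations
  err <- numeric(nrow(obs))
  for (k in unique(obs$kf)) {
    sel <- obs$kf == k
    pr <- project_points(intr, map$poses[[k]],
                         map$landmarks[obs$landmark[sel], , drop = FALSE])
    err[sel] <- sqrt(rowSums((pr$pixels -
                                as.matrix(obs[sel, c("x", "y")]))^2))
  }
  data.frame(landmark = obs$landmark, kf = obs$kf, error_px = err)
}

## ---- incremental SLAM driver ----------------------------------------------

#' Run incremental sliding-window SLAM over a tracked sequence
#'
#' Consumes a precomputed track table (see [track_section()]), accumulates
#' section buffers of length `lm` advancing by `lm - 1`, bootstraps the
#' first section from a two-view essential-matrix solve, poses the
#' remaining frames by robust PnP against the growing landmark set,
#' triangulates new tracks, and refines each section by local bundle
#' adjustment. Every section frame becomes a keyframe. After each section,
#' observations reprojecting beyond `outlier_px` are removed and landmarks
#' left with fewer than two observations are dropped. One event is emitted
#' per completed section.
#'
#' @param tracks `sn_track_table`.
#' @param intr `sn_intrinsics`.
#' @param n_frames Number of frames in the stream (defaults to
#'   `max(tracks$frame) + 1`).
#' @param lm Section buffer length (default 12; must exceed the tracking
#'   window).
#' @param seed Integer seed for all RANSAC draws.
#' @param min_track_len Minimum visible observations for a track to become
#'   a landmark (default 3).
#' @param outlier_px Post-adjustment observation rejection threshold
#'   (default 4 px).
#' @param triangulation_px Reprojection acceptance threshold at
#'   triangulation time (default 4 px).
#' @param min_parallax_deg Landmarks whose observing rays subtend less
#'   than this angle are culled after each section (default 1 degree);
#'   their depths are unconstrained.
#' @param robust_delta_px Huber threshold inside bundle adjustment.
#' @param ba_max_iter LM iteration cap per section.
#' @return List of class `sn_slam_result`: `map` (final `sn_slam_map`,
#'   first keyframe pose identity), `events` (one per section: `section`,
#'   `frames`, `new_kf` indices, keyframe poses and a map snapshot), and
#'   `trajectory` (timestamps = keyframe frame indices, SLAM-frame poses).
#' @export
run_slam <- function(tracks, intr, n_frames = NULL, lm = 12, seed = 1,
                     min_track_len = 3, outlier_px = 4,
                     triangulation_px = 4, min_parallax_deg = 1,
                     robust_delta_px = 2, ba_max_iter = 30) {
  tracks <- as.data.frame(tracks)
  tracks <- tracks[tracks$visible, ]
  if (is.null(n_frames)) n_frames <- max(tracks$frame) + 1L
  if (any(intr$dist != 0)) {
    und <- undistort_points(intr, as.matrix(tracks[, c("x", "y")]))
    tracks$x <- und[, 1]; tracks$y <- und[, 2]
  }
  len <- table(tracks$track_id)
  tracks <- tracks[tracks$track_id %in%
                     as.integer(names(len[len >= min_track_len])), ]
  sections <- accumulate_section(n_frames, lm)
  map <- NULL
  events <- list()
  for (si in seq_along(sections)) {
    frames_sec <- sections[[si]]
    if (si == 1) {
      map <- slam_bootstrap_section(tracks, intr, frames_sec,
                                    triangulation_px, seed)
    } else {
      map <- slam_extend_section(map, tracks, intr, frames_sec,
                                 triangulation_px, seed + si)
    }
    kf_idx <- match(frames_sec, map$frames)
    kf_idx <- kf_idx[!is.na(kf_idx)]
    ba <- local_bundle_adjust(map, kf_idx, intr,
                              robust_delta_px = robust_delta_px,
                              max_iter = ba_max_iter)
    map <- slam_filter(ba$map, intr, outlier_px, min_parallax_deg)
    # re-adjust after outlier removal so the section leaves a clean state
    kf_idx <- kf_idx[kf_idx <= length(map$poses)]
    ba <- local_bundle_adjust(map, kf_idx, intr,
                              robust_delta_px = robust_delta_px,
                              max_iter = ba_max_iter)
    map <- slam_filter(ba$map, intr, outlier_px, min_parallax_deg)
    new_kf <- if (si == 1) seq_along(map$frames) else
      which(map$frames %in% setdiff(frames_sec, sections[[si - 1]]))
    events[[si]] <- list(section = si, frames = frames_sec,
                         new_kf = new_kf,
                         new_poses = map$poses[new_kf],
                         mean_reproj_px = ba$mean_reproj_px,
                         map = map)
  }
  structure(list(map = map, events = events,
                 trajectory = list(timestamps = as.numeric(map$frames),
                                   poses = map$poses)),
            class = "sn_slam_result")
}

# Bootstrap the first section: two-view solve + PnP for remaining frames.
slam_bootstrap_section <- function(tracks, intr, frames_sec,
                                   triangulation_px, seed) {
  fa <- frames_sec[1]
  boot <- NULL; fb <- NA_integer_
  for (f in rev(frames_sec[-1])) {
    boot <- tryCatch(bootstrap_two_view(tracks, intr, fa, f, seed = seed),
                     error = function(e) NULL)
    if (!is.null(boot) && nrow(boot$points) >= 8) { fb <- f; break }
    boot <- NULL
  }
  if (is.null(boot))
    stop("SLAM bootstrap failed on the first section: no usable frame pair")
  frames <- c(fa, fb)
  poses <- list(rigid_pose(frame = "slam"), boot$pose_b)
  landmarks <- boot$points
  track_id <- boot$track_ids
  obs <- make_obs(tracks, track_id, frames, seq_along(frames))
  map <- slam_map(frames, poses, landmarks, obs, track_id = track_id)
  # refine the two-view seed before growing: the linear essential-matrix
  # solution is not a maximum-likelihood estimate under pixel noise
  map <- local_bundle_adjust(map, 1:2, intr, max_iter = 10)$map
  grow_section(map, tracks, intr, frames_sec, triangulation_px, seed)
}

slam_extend_section <- function(map, tracks, intr, frames_sec,
                                triangulation_px, seed) {
  grow_section(map, tracks, intr, frames_sec, triangulation_px, seed)
}

make_obs <- function(tracks, track_id, frames, kf_of_frame) {
  sel <- tracks[tracks$track_id %in% track_id & tracks$frame %in% frames, ]
  data.frame(landmark = match(sel$track_id, track_id),
             kf = kf_of_frame[match(sel$frame, frames)],
             x = sel$x, y = sel$y)
}

# Pose every unposed frame of the section by PnP against current
# landmarks, then triangulate eligible new tracks and stabilize with a
# short bundle adjustment; repeat until stable. Interleaving adjustment
# with frame insertion keeps the landmark set accurate enough for the
# next PnP round under observation noise.
grow_section <- function(map, tracks, intr, frames_sec, triangulation_px,
                         seed) {
  map <- sort_map(map)
  repeat {
    todo <- setdiff(frames_sec, map$frames)
    if (length(todo) == 0) break
    progress <- FALSE
    for (f in todo[order(vapply(todo, function(f)
      min(abs(map$frames - f)), numeric(1)))]) {
      tf <- tracks[tracks$frame == f, ]
      li <- match(tf$track_id, map$track_id)
      ok <- !is.na(li)
      if (sum(ok) < 4) next
      prior <- map$poses[[which.min(abs(map$frames - f))]]
      fit <- refine_pose_robust(prior, map$landmarks[li[ok], , drop = FALSE],
                                as.matrix(tf[ok, c("x", "y")]), intr,
                                threshold_px = max(6, triangulation_px))
      if (is.null(fit) && sum(ok) >= 6)
        fit <- tryCatch(
          pnp_register(map$landmarks[li[ok], , drop = FALSE],
                       as.matrix(tf[ok, c("x", "y")]), intr,
                       threshold_px = max(6, triangulation_px),
                       max_iter = 200, seed = seed + f, frame = "slam"),
          error = function(e) NULL)
      if (is.null(fit)) next
      map$frames <- c(map$frames, f)
      map$poses <- c(map$poses, list(fit$pose))
      kf_new <- length(map$poses)
      sel <- which(ok)[fit$inliers]
      if (length(sel) > 0)
        map$observations <- rbind(map$observations,
                                  data.frame(landmark = li[sel], kf = kf_new,
                                             x = tf$x[sel], y = tf$y[sel]))
      progress <- TRUE
    }
    map <- triangulate_new_tracks(map, tracks, intr, frames_sec,
                                  triangulation_px)
    map <- sort_map(map)
    if (progress) {
      sec_kf <- match(intersect(frames_sec, map$frames), map$frames)
      ba <- local_bundle_adjust(map, sec_kf, intr, max_iter = 8)
      map <- ba$map
    } else break
  }
  map
}

sort_map <- function(map) {
  ord <- order(map$frames)
  remap <- match(seq_along(map$frames), ord)
  map$observations$kf <- remap[map$observations$kf]
  slam_map(map$frames[ord], map$poses[ord], map$landmarks,
           map$observations, track_id = map$track_id,
           gauge_norm = map$gauge_norm)
}

triangulate_new_tracks <- function(map, tracks, intr, frames_sec,
                                   triangulation_px) {
  cand <- tracks[tracks$frame %in% map$frames &
                   !(tracks$track_id %in% map$track_id), ]
  if (nrow(cand) == 0) return(map)
  counts <- table(cand$track_id)
  for (tid in as.integer(names(counts[counts >= 2]))) {
    rows <- cand[cand$track_id == tid, ]
    kf <- match(rows$frame, map$frames)
    tri <- try_triangulate(map$poses[kf],
                           as.matrix(rows[, c("x", "y")]), intr,
                           reproj_px = triangulation_px)
    if (is.null(tri)) next
    map$landmarks <- rbind(map$landmarks, matrix(tri$point, 1, 3))
    map$track_id <- c(map$track_id, tid)
    map$observations <- rbind(map$observations,
                              data.frame(landmark = nrow(map$landmarks),
                                         kf = kf, x = rows$x, y = rows$y))
  }
  map
}

# Remove outlier observations, under-observed landmarks, and landmarks
# whose observing rays subtend too little parallax: their depth is
# essentially unconstrained and a few of them can dominate any
# distance-based consumer of the map (scale estimation, registration
# error evaluation).
slam_filter <- function(map, intr, outlier_px, min_parallax_deg = 1) {
  err <- reprojection_errors(map, intr)
  keep_obs <- err$error_px <= outlier_px
  obs <- map$observations[keep_obs, , drop = FALSE]
  nobs <- tabulate(obs$landmark, nbins = nrow(map$landmarks))
  ok <- nobs >= 2
  if (min_parallax_deg > 0 && any(ok)) {
    cos_lim <- cos(min_parallax_deg * pi / 180)
    centers <- trajectory_centers(map$poses)
    for (l in which(ok)) {
      kfs <- obs$kf[obs$landmark == l]
      dirs <- sweep(centers[kfs, , drop = FALSE], 2, map$landmarks[l, ])
      dirs <- dirs / sqrt(rowSums(dirs^2))
      if (min(tcrossprod(dirs)) > cos_lim) ok[l] <- FALSE
    }
  }
  keep_lm <- which(ok)
  obs <- obs[obs$landmark %in% keep_lm, , drop = FALSE]
  obs$landmark <- match(obs$landmark, keep_lm)
  slam_map(map$frames, map$poses,
           map$landmarks[keep_lm, , drop = FALSE], obs,
           track_id = map$track_id[keep_lm], gauge_norm = map$gauge_norm)
}
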