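# SLAM core: sliding windows, section buffers, two-view bootstrap,
# triangulation, local bundle adjustment, incremental driver.

test_that("12 frames with n=8/step=4 yield windows {0-7} and {4-11}", {
  cfg <- tracker_config(8, 4, 10)
  expect_equal(tracking_windows(12, cfg), c(0L, 4L))
  expect_equal(tracking_windows(16, cfg), c(0L, 4L, 8L))
})

test_that("section buffers advance by lm-1 with single-frame overlaps", {
  s <- accumulate_section(23, 12)
  expect_equal(s[[1]], 0:11)
  expect_equal(s[[2]], 11:22)
  # degenerate lm=2: every consecutive frame pair
  s2 <- accumulate_section(5, 2)
  expect_equal(s2, list(0:1, 1:2, 2:3, 3:4))
  # combinatorial check of the index arithmetic for several (F, lm)
  for (F in c(12, 25, 60, 61)) for (lm in c(5, 12)) {
    secs <- accumulate_section(F, lm)
    expect_equal(length(secs), floor((F - lm) / (lm - 1)) + 1)
    for (k in seq_along(secs)) {
      expect_equal(length(secs[[k]]), lm)
      if (k > 1) expect_equal(secs[[k]][1], secs[[k - 1]][lm])
    }
  }
  expect_warning(accumulate_section(8, 12), "truncated")
})

test_that("the oracle tracker merged over windows reproduces the scene tracks", {
  scene <- small_scene()
  cfg <- tracker_config(scene$cfg$window_n, scene$cfg$window_step,
                        scene$cfg$points_per_window)
  merged <- track_section(make_oracle_tracker(scene), scene$cfg$n_frames,
                          cfg, scene$intr)
  a <- as.data.frame(merged)
  b <- as.data.frame(scene$tracks)
  a <- a[order(a$track_id, a$frame), ]; b <- b[order(b$track_id, b$frame), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("noiseless oracle tracks equal exact landmark projections", {
  scene <- small_scene()
  tr <- as.data.frame(scene$tracks)
  tr <- tr[tr$visible, ][1:200, ]
  for (f in unique(tr$frame)) {
    sel <- tr[tr$frame == f, ]
    px <- project_points(scene$intr, scene$poses_ct[[f + 1]],
                         scene$landmarks_ct[sel$track_id, , drop = FALSE])
    expect_lt(max(abs(px$pixels - as.matrix(sel[, c("x", "y")]))), 1e-9)
  }
})

test_that("two-view bootstrap recovers exact relative geometry", {
  scene <- small_scene()
  boot <- bootstrap_two_view(scene$tracks, scene$intr, 0, 7, seed = 2)
  truth_a <- scene$poses_slam[[1]]; truth_b <- scene$poses_slam[[8]]
  rel_R <- t(truth_a$R) %*% truth_b$R
  rel_t <- as.numeric(t(truth_a$R) %*% (truth_b$t - truth_a$t))
  rel_t <- rel_t / sqrt(sum(rel_t^2))
  expect_lt(sqrt(sum(rot_to_rotvec(boot$pose_b$R %*% t(rel_R))^2)), 1e-6)
  tb <- boot$pose_b$t / sqrt(sum(boot$pose_b$t^2))
  expect_lt(acos(min(1, abs(sum(tb * rel_t)))), 1e-6)
  expect_equal(sqrt(sum(boot$pose_b$t^2)), 1, tolerance = 1e-9)
  # cheirality: all triangulated points in front of both cameras
  za <- boot$points[, 3]
  pb <- sweep(boot$points, 2, boot$pose_b$t) %*% boot$pose_b$R
  expect_true(all(za > 0 & pb[, 3] > 0))
})

test_that("bootstrap inlier set matches the epipolar-residual oracle", {
  scene <- small_scene()
  intr <- scene$intr
  tr <- as.data.frame(scene$tracks)
  set.seed(41)
  shared <- intersect(tr$track_id[tr$frame == 0 & tr$visible],
                      tr$track_id[tr$frame == 7 & tr$visible])
  pa <- scene$poses_slam[[1]]; pb <- scene$poses_slam[[8]]
  # displacements of points near the epipole are indistinguishable from a
  # change of translation direction at this baseline, so outliers are
  # injected only on tracks well away from it
  ep <- project_points(intr, pb, matrix(pa$t, 1))$pixels
  far <- vapply(shared, function(tid) {
    r <- tr[tr$track_id == tid & tr$frame == 7, ]
    sqrt((r$x - ep[1])^2 + (r$y - ep[2])^2) > 60
  }, logical(1))
  bad <- sort(sample(shared[far], floor(length(shared) * 0.25)))
  R_rel <- t(pb$R) %*% pa$R                      # world-to-cam composition
  t_rel <- as.numeric(t(pb$R) %*% (pa$t - pb$t))
  E <- matrix(c(0, -t_rel[3], t_rel[2], t_rel[3], 0, -t_rel[1],
                -t_rel[2], t_rel[1], 0), 3, 3, byrow = TRUE) %*% R_rel
  # displace outliers along the epipolar normal so they are unambiguous
  for (tid in bad) {
    ra <- tr[tr$track_id == tid & tr$frame == 0, ]
    rb_i <- which(tr$track_id == tid & tr$frame == 7)
    ya <- c((ra$x - intr$cx) / intr$fx, (ra$y - intr$cy) / intr$fy, 1)
    l <- E %*% ya                                 # epipolar line in view b
    nrm <- c(l[1], l[2]) / sqrt(l[1]^2 + l[2]^2)  # line normal (image)
    tr[rb_i, c("x", "y")] <- tr[rb_i, c("x", "y")] + 40 * nrm
  }
  boot <- bootstrap_two_view(track_table(tr), scene$intr, 0, 7, seed = 2)
  expect_true(all(!(bad %in% boot$inlier_track_ids)))
  expect_setequal(boot$inlier_track_ids, setdiff(shared, bad))
})

test_that("bootstrap needs at least 8 shared tracks", {
  scene <- small_scene()
  tr <- as.data.frame(scene$tracks)
  tr <- tr[tr$track_id <= 5, ]
  expect_error(bootstrap_two_view(track_table(tr), scene$intr, 0, 7),
               "8 shared")
})

test_that("triangulation recovers exact points and flags degeneracy", {
  intr <- default_intr()
  pa <- rigid_pose(); pb <- rigid_pose(diag(3), c(2, 0, 0))
  X <- c(1, 2, 10)
  px <- rbind(project_points(intr, pa, X)$pixels,
              project_points(intr, pb, X)$pixels)
  tri <- triangulate_point(list(pa, pb), px, intr)
  expect_lt(max(abs(tri$point - X)), 1e-9)
  expect_error(triangulate_point(list(pa, pa), px, intr), "degenerate")
})

test_that("triangulation matches a brute-force reprojection-cost grid", {
  set.seed(43)
  intr <- default_intr()
  poses <- list(rigid_pose(), rigid_pose(diag(3), c(3, 0, 0)),
                rigid_pose(rotvec_to_rot(c(0, 0.05, 0)), c(0, 3, 1)))
  X <- c(0.5, -0.8, 12)
  px <- do.call(rbind, lapply(poses, function(p)
    project_points(intr, p, X)$pixels)) + matrix(rnorm(6), 3, 2)
  tri <- triangulate_point(poses, px, intr)
  cost <- function(Y) {
    sum(vapply(seq_along(poses), function(i) {
      pr <- project_points(intr, poses[[i]], Y)$pixels
      sum((pr - px[i, ])^2)
    }, numeric(1)))
  }
  # coarse grid around the truth; the refined solution must beat it
  grid <- as.matrix(expand.grid(x = seq(-0.5, 1.5, 0.1),
                                y = seq(-1.8, 0.2, 0.1),
                                z = seq(10, 14, 0.2)))
  grid_costs <- apply(grid, 1, cost)
  best_grid <- grid[which.min(grid_costs), ]
  expect_lte(cost(tri$point), min(grid_costs) + 1e-12)
  expect_lt(max(abs(tri$point - best_grid)), 0.2)  # within grid resolution
})

test_that("bundle adjustment recovers a perturbed noiseless configuration", {
  scene <- small_scene()
  map <- truth_slam_map(scene, keyframes = 0:7)
  set.seed(44)
  pm <- map
  for (k in 2:length(pm$poses)) {
    p <- pm$poses[[k]]
    pm$poses[[k]] <- rigid_pose(rotvec_to_rot(rnorm(3, sd = 0.002)) %*% p$R,
                                p$t * (1 + rnorm(3, sd = 0.01)))
  }
  pm$landmarks <- pm$landmarks * (1 + matrix(rnorm(length(pm$landmarks),
                                                   sd = 0.01),
                                             nrow(pm$landmarks)))
  ba <- local_bundle_adjust(pm, seq_along(pm$poses), scene$intr,
                            max_iter = 60)
  expect_lt(ba$mean_reproj_px, 1e-6)
  # cost is non-increasing across accepted steps
  expect_true(all(diff(ba$cost_trace) <= 1e-9))
  # ground truth recovered up to the (fixed) gauge
  al <- umeyama_alignment(t(sapply(ba$map$poses, `[[`, "t")),
                          t(sapply(map$poses, `[[`, "t")))
  mapped <- apply_similarity_points(al, t(sapply(ba$map$poses, `[[`, "t")))
  expect_lt(max(abs(mapped - t(sapply(map$poses, `[[`, "t")))), 1e-5)
})

test_that("the analytic BA Jacobian matches central differences", {
  scene <- small_scene()
  map <- truth_slam_map(scene, keyframes = 0:5)
  set.seed(45)
  Rwc <- lapply(map$poses, function(p) t(p$R))
  twc <- lapply(map$poses, function(p) as.numeric(-t(p$R) %*% p$t))
  X <- map$landmarks * (1 + rnorm(length(map$landmarks), sd = 0.01))
  obs <- map$observations[1:80, ]
  free_kf <- 2:4
  free_lm <- sort(unique(obs$landmark))[1:10]
  sys <- sinusnav:::ba_system(Rwc, twc, X, obs, scene$intr, free_kf, free_lm)
  resid_at <- function(delta) {
    st <- sinusnav:::ba_apply_step(Rwc, twc, X, delta, free_kf, free_lm)
    sinusnav:::ba_system(st$Rwc, st$twc, st$X, obs, scene$intr,
                         free_kf, free_lm)$r
  }
  n_par <- 6 * length(free_kf) + 3 * length(free_lm)
  h <- 1e-6
  Jnum <- sapply(seq_len(n_par), function(j) {
    d <- numeric(n_par)
    d[j] <- h
    (resid_at(d) - resid_at(-d)) / (2 * h)
  })
  Jana <- as.matrix(sys$J)
  denom <- max(abs(Jnum))
  expect_lt(max(abs(Jana - Jnum)) / denom, 1e-5)
})

test_that("incremental SLAM recovers a noiseless scene up to similarity", {
  scene <- cached_scene("slam40", scene_config(n_frames = 40, seed = 13))
  sl <- run_slam(scene$tracks, scene$intr, n_frames = 40, lm = 12, seed = 3)
  expect_equal(length(sl$events), floor((40 - 12) / 11) + 1)
  # gauge: first keyframe pose is the identity in every snapshot
  for (ev in sl$events) {
    expect_lt(max(abs(ev$map$poses[[1]]$R - diag(3))), 1e-12)
    expect_lt(max(abs(ev$map$poses[[1]]$t)), 1e-12)
  }
  # map growth is monotone
  kfs <- vapply(sl$events, function(e) length(e$map$poses), numeric(1))
  lms <- vapply(sl$events, function(e) nrow(e$map$landmarks), numeric(1))
  expect_true(all(diff(kfs) >= 0) && all(diff(lms) >= 0))
  ref <- list(timestamps = sl$trajectory$timestamps,
              poses = scene$poses_ct[sl$map$frames + 1])
  ev <- evaluate_run(sl$trajectory, ref, mode = "retrospective")
  expect_lt(ev$summary$ate_rmse, 1e-4)
})

test_that("SLAM is deterministic and invariant to the world frame", {
  scene <- cached_scene("slam40", scene_config(n_frames = 40, seed = 13))
  # a different true similarity (scale + rigid offset) leaves the image
  # tracks unchanged, so the SLAM map must be identical
  scene2 <- cached_scene("slam40b",
                         scene_config(n_frames = 40, seed = 13,
                                      true_scale = 3))
  expect_equal(as.data.frame(scene$tracks), as.data.frame(scene2$tracks))
  s1 <- run_slam(scene$tracks, scene$intr, n_frames = 40, seed = 3)
  s2 <- run_slam(scene2$tracks, scene2$intr, n_frames = 40, seed = 3)
  expect_equal(s1$map$landmarks, s2$map$landmarks)
  expect_equal(t(sapply(s1$map$poses, `[[`, "t")),
               t(sapply(s2$map$poses, `[[`, "t")))
})

test_that("under 1 px noise most retained observations reproject within 4 px", {
  scene <- cached_scene("slam20n",
                        scene_config(n_frames = 20, noise_sd_px = 1,
                                     dropout = 0.05, seed = 14))
  sl <- run_slam(scene$tracks, scene$intr, n_frames = 20, seed = 3)
  err <- reprojection_errors(sl$map, scene$intr)
  expect_gte(mean(err$error_px <= 4), 0.95)
})
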