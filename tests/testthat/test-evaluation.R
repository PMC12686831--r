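# Error metrics, similarity alignment, half-split TRE, fiducial distance.

test_that("translation error is the L2 distance of camera centers", {
  expect_equal(translation_error(rigid_pose(), rigid_pose()), 0)
  expect_equal(translation_error(rigid_pose(diag(3), c(0, 0, 0)),
                                 rigid_pose(diag(3), c(3, 4, 0))), 5)
  set.seed(61)
  for (rep in 1:20) {
    a <- random_pose(); b <- random_pose()
    expect_equal(translation_error(a, b), sqrt(sum((a$t - b$t)^2)))
  }
})

test_that("general rotation error matches the quaternion geodesic oracle", {
  expect_equal(rotation_error_general(diag(3), diag(3)), 0)
  Rz30 <- rotvec_to_rot(c(0, 0, 30 * pi / 180))
  expect_equal(rotation_error_general(Rz30, diag(3)), 30, tolerance = 1e-9)
  set.seed(62)
  for (rep in 1:1000) {
    R1 <- random_rotation(); R2 <- random_rotation()
    got <- rotation_error_general(R1, R2)
    q1 <- rot_to_quat(R1); q2 <- rot_to_quat(R2)
    oracle <- 2 * acos(min(1, abs(sum(q1 * q2)))) * 180 / pi
    expect_lt(abs(got - oracle), 1e-9)
  }
})

test_that("general rotation error is symmetric and left-invariant", {
  set.seed(63)
  for (rep in 1:20) {
    R1 <- random_rotation(); R2 <- random_rotation(); L <- random_rotation()
    expect_equal(rotation_error_general(R1, R2),
                 rotation_error_general(R2, R1), tolerance = 1e-9)
    expect_equal(rotation_error_general(L %*% R1, L %*% R2),
                 rotation_error_general(R1, R2), tolerance = 1e-8)
  }
})

test_that("per-axis rotation errors are the column angles", {
  expect_equal(unname(rotation_error_per_axis(diag(3), diag(3))),
               c(0, 0, 0))
  th <- 25
  Rz <- rotvec_to_rot(c(0, 0, th * pi / 180))
  expect_equal(unname(rotation_error_per_axis(Rz, diag(3))), c(th, th, 0),
               tolerance = 1e-9)
  set.seed(64)
  for (rep in 1:50) {
    R1 <- random_rotation(); R2 <- random_rotation()
    got <- rotation_error_per_axis(R1, R2)
    for (a in 1:3)
      expect_equal(unname(got[a]),
                   acos(max(-1, min(1, sum(R1[, a] * R2[, a])))) * 180 / pi)
  }
  # all four angles are zero iff the rotations are equal
  R <- random_rotation()
  expect_true(all(rotation_error_per_axis(R, R) == 0) &&
                rotation_error_general(R, R) == 0)
  R2 <- rotvec_to_rot(c(1e-3, 0, 0)) %*% R
  expect_true(any(rotation_error_per_axis(R2, R) > 0) ||
                rotation_error_general(R2, R) > 0)
})

test_that("similarity alignment recovers a known transform exactly", {
  set.seed(65)
  pts <- matrix(rnorm(60, sd = 5), ncol = 3)
  Tm <- similarity_transform(2, rotvec_to_rot(c(10 * pi / 180, 0, 0)),
                             c(1, 2, 3))
  fit <- umeyama_alignment(pts, apply_similarity_points(Tm, pts))
  expect_equal(fit$s, 2, tolerance = 1e-9)
  expect_lt(max(abs(fit$R - Tm$R)), 1e-9)
  expect_lt(max(abs(fit$t - Tm$t)), 1e-9)
  self <- umeyama_alignment(pts, pts)
  expect_equal(self$s, 1, tolerance = 1e-12)
  expect_lt(max(abs(self$R - diag(3))), 1e-9)
  expect_error(umeyama_alignment(matrix(rep(1:3, 3), 3, 3, byrow = FALSE),
                                 pts[1:3, ]), "degenerate|collinear")
})

test_that("the alignment is the least-squares optimum (perturbation check)", {
  set.seed(66)
  pts <- matrix(rnorm(45, sd = 5), ncol = 3)
  target <- apply_similarity_points(
    similarity_transform(1.4, random_rotation(), rnorm(3)), pts) +
    matrix(rnorm(45, sd = 0.2), ncol = 3)
  fit <- umeyama_alignment(pts, target)
  rss <- function(Tm) sum((apply_similarity_points(Tm, pts) - target)^2)
  base <- rss(fit)
  for (rep in 1:40) {
    pert <- similarity_transform(fit$s * exp(rnorm(1, sd = 0.02)),
                                 rotvec_to_rot(rnorm(3, sd = 0.02)) %*% fit$R,
                                 fit$t + rnorm(3, sd = 0.05))
    expect_gte(rss(pert), base - 1e-9)
  }
})

test_that("evaluate_run returns zeros for identical trajectories", {
  set.seed(67)
  traj <- list(timestamps = 0:9,
               poses = lapply(1:10, function(i) random_pose(frame = "ct")))
  ev <- evaluate_run(traj, traj, mode = "navigation")
  expect_equal(ev$summary$translation_mean, 0)
  expect_equal(ev$summary$rotation_mean, 0)
  expect_equal(nrow(ev$per_pose), 10)
})

test_that("retrospective evaluation is invariant to a similarity transform", {
  set.seed(68)
  ref <- list(timestamps = 0:11, poses = lapply(1:12, function(i)
    rigid_pose(random_rotation(), c(rnorm(2), i), frame = "ct")))
  Tm <- similarity_transform(3, random_rotation(), rnorm(3, sd = 10))
  est <- list(timestamps = 0:11,
              poses = lapply(ref$poses, function(p)
                apply_similarity_pose(Tm, p)))
  ev <- evaluate_run(est, ref, mode = "retrospective")
  expect_lt(ev$summary$translation_mean, 1e-9)
  expect_lt(ev$summary$rotation_mean, 1e-6)
  # navigation mode sees the full offset
  ev2 <- evaluate_run(est, ref, mode = "navigation")
  expect_gt(ev2$summary$translation_mean, 1)
})

test_that("pose pairing drops unmatched timestamps and errors on disjoint", {
  a <- list(timestamps = c(0, 1, 2, 50),
            poses = lapply(1:4, function(i) rigid_pose()))
  b <- list(timestamps = c(0, 1, 2),
            poses = lapply(1:3, function(i) rigid_pose()))
  ev <- evaluate_run(a, b, mode = "navigation")
  expect_equal(ev$summary$n, 3)
  expect_equal(ev$summary$dropped, 1)
  c <- list(timestamps = c(100, 101), poses = lapply(1:2, function(i) rigid_pose()))
  expect_error(evaluate_run(c, b), "overlap")
})

test_that("half-split TRE is near zero on noiseless scenes and seeded", {
  scene <- small_scene()
  map <- truth_slam_map(scene)
  ref_poses <- scene$poses_ct
  tre <- tre_halfsplit(map, ref_poses, scene$mesh, scene$intr, seed = 9)
  expect_lt(tre$residual_mm, 1e-6)
  expect_lt(tre$tre_mm, 1e-6)
  tre2 <- tre_halfsplit(map, ref_poses, scene$mesh, scene$intr, seed = 9)
  expect_equal(tre$residual_mm, tre2$residual_mm)
  expect_equal(tre$n_pairs, tre2$n_pairs)
  tre3 <- tre_halfsplit(map, ref_poses, scene$mesh, scene$intr, seed = 10)
  expect_false(identical(tre$residual_mm, tre3$residual_mm))
  # recovered registration matches the scene truth
  expect_equal(tre$registration$s, scene$registration_truth$s,
               tolerance = 1e-6)
})

test_that("residual does not exceed TRE in expectation on noisy maps", {
  scene <- cached_scene("slam20n",
                        scene_config(n_frames = 20, noise_sd_px = 1,
                                     dropout = 0.05, seed = 14))
  map <- truth_slam_map(scene)
  # perturb landmarks to emulate reconstruction noise
  set.seed(71)
  res <- sapply(1:12, function(sd0) {
    m2 <- map
    m2$landmarks <- m2$landmarks +
      matrix(rnorm(length(m2$landmarks), sd = 0.02), nrow(m2$landmarks))
    tre <- tre_halfsplit(m2, scene$poses_ct, scene$mesh, scene$intr,
                         seed = sd0)
    c(tre$residual_mm, tre$tre_mm)
  })
  expect_lte(median(res[1, ]), median(res[2, ]))
})

test_that("fiducial distances delegate to the point-to-mesh oracle", {
  sph <- sinusnav:::sphere_mesh(c(0, 0, 0), 1.15, n_lat = 24, n_lon = 32)
  on_surface <- sph$vertices[5, ]
  fd <- fiducial_distance(rbind(on_surface, c(0, 0, 1.15 + 1.3)), sph)
  expect_equal(fd$distances_mm[1], 0, tolerance = 1e-9)
  expect_equal(fd$distances_mm[2], 1.3, tolerance = 2e-3)  # faceting error
  expect_equal(fd$mean_mm, mean(fd$distances_mm))
  o <- oracle_point_mesh(sph, c(0.3, 0.2, 2))
  expect_equal(fiducial_distance(matrix(c(0.3, 0.2, 2), 1), sph)$mean_mm, o,
               tolerance = 1e-9)
})
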