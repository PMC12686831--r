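# Camera model, rigid/similarity transforms and their file formats.

test_that("projection maps the optical axis to the principal point", {
  intr <- intrinsics(1, 1, 0.5, 0.5, 2, 2)
  pr <- project_points(intr, rigid_pose(), rbind(c(0, 0, 1), c(0, 0, 250)))
  expect_equal(pr$pixels, matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_true(all(pr$valid))
})

test_that("projection flags points behind the camera and out of bounds", {
  intr <- default_intr()
  pr <- project_points(intr, rigid_pose(),
                       rbind(c(0, 0, -5), c(50, 0, 10), c(0.1, 0, 10)))
  expect_equal(pr$valid, c(FALSE, FALSE, TRUE))
})

test_that("projection matches the homogeneous-matrix oracle on random scenes", {
  set.seed(42)
  intr <- default_intr()
  for (rep in 1:20) {
    pose <- random_pose(scale = 5)
    # points in front of the camera: z in (1, 9) in the camera frame
    cam <- cbind(matrix(rnorm(10, sd = 2), ncol = 2), runif(5, 1, 9))
    pts <- sweep(cam %*% t(pose$R), 2, pose$t, `+`)
    # oracle: x ~ K [R|t]_wc X via explicit 4x4 products
    Twc <- solve(pose_to_mat(pose))
    K <- rbind(c(intr$fx, 0, intr$cx), c(0, intr$fy, intr$cy), c(0, 0, 1))
    hom <- cbind(pts, 1) %*% t(Twc[1:3, ])
    expected <- (hom / hom[, 3]) %*% t(K)
    got <- project_points(intr, pose, pts)$pixels
    keep <- hom[, 3] > 1e-9
    expect_lt(max(abs(got[keep, 1:2] - expected[keep, 1:2])), 1e-9)
  }
})

test_that("project and backproject are mutually inverse", {
  set.seed(7)
  intr <- default_intr()
  pose <- random_pose(scale = 3)
  px <- cbind(runif(1000, 0, 199), runif(1000, 0, 199))
  depth <- runif(1000, 0.5, 60)
  pts <- backproject_pixels(intr, pose, px, depth)
  back <- project_points(intr, pose, pts)$pixels
  expect_lt(max(abs(back - px)), 1e-6)
})

test_that("backproject of the principal point runs along the optical axis", {
  intr <- default_intr()
  p <- backproject_pixels(intr, rigid_pose(), c(intr$cx, intr$cy), 10)
  expect_equal(as.numeric(p), c(0, 0, 10), tolerance = 1e-12)
  expect_error(backproject_pixels(intr, rigid_pose(), c(0, 0), 0),
               "positive")
})

test_that("undistortion inverts the forward Brown-Conrady model", {
  intr0 <- default_intr()
  px <- cbind(runif(200, 10, 190), runif(200, 10, 190))
  expect_identical(undistort_points(intr0, px), px)  # zero coefficients
  intr <- default_intr(dist = c(-0.2, 0.03, 1e-3, -5e-4))
  # forward-model oracle written out locally
  k <- intr$dist
  xn <- (px[, 1] - intr$cx) / intr$fx; yn <- (px[, 2] - intr$cy) / intr$fy
  r2 <- xn^2 + yn^2
  rad <- 1 + k[1] * r2 + k[2] * r2^2
  xd <- xn * rad + 2 * k[3] * xn * yn + k[4] * (r2 + 2 * xn^2)
  yd <- yn * rad + k[3] * (r2 + 2 * yn^2) + 2 * k[4] * xn * yn
  distorted <- cbind(intr$fx * xd + intr$cx, intr$fy * yd + intr$cy)
  back <- undistort_points(intr, distorted)
  expect_lt(max(abs(back - px)), 1e-6)
  # the principal point is a fixed point
  pp <- undistort_points(intr, c(intr$cx, intr$cy))
  expect_equal(as.numeric(pp), c(intr$cx, intr$cy), tolerance = 1e-9)
})

test_that("pose composition and inversion match the 4x4 matrix oracle", {
  set.seed(3)
  for (rep in 1:25) {
    a <- random_pose(); b <- random_pose(); c <- random_pose()
    expect_lt(max(abs(pose_to_mat(pose_compose(a, b)) -
                        pose_to_mat(a) %*% pose_to_mat(b))), 1e-12)
    expect_lt(max(abs(pose_to_mat(pose_invert(a)) -
                        solve(pose_to_mat(a)))), 1e-9)
    # group: identity, associativity
    id <- pose_compose(a, pose_invert(a))
    expect_lt(max(abs(pose_to_mat(id) - diag(4))), 1e-9)
    lhs <- pose_compose(pose_compose(a, b), c)
    rhs <- pose_compose(a, pose_compose(b, c))
    expect_lt(max(abs(pose_to_mat(lhs) - pose_to_mat(rhs))), 1e-9)
  }
})

test_that("pose constructor repairs small orthonormality violations only", {
  R <- diag(3) + matrix(rnorm(9, sd = 1e-8), 3, 3)
  p <- rigid_pose(R, c(0, 0, 0))
  expect_lt(max(abs(crossprod(p$R) - diag(3))), 1e-12)
  expect_error(rigid_pose(diag(3) * 1.5, c(0, 0, 0)), "orthonormal")
})

test_that("similarity transforms act consistently on points and poses", {
  set.seed(5)
  expect_equal(as.numeric(apply_similarity_points(
    similarity_transform(2), c(1, 1, 1))), c(2, 2, 2))
  id <- similarity_transform()
  p <- random_pose()
  expect_equal(apply_similarity_pose(id, p)$t, p$t)
  # projective invariance: projecting mapped points with the mapped pose
  # equals projecting the originals with the original pose
  intr <- default_intr()
  for (rep in 1:10) {
    Tm <- similarity_transform(runif(1, 0.2, 5), random_rotation(), rnorm(3))
    pose <- random_pose(scale = 2)
    pts <- sweep(matrix(rnorm(30, sd = 2), ncol = 3), 2, pose$t + 5, `+`)
    a <- project_points(intr, pose, pts)$pixels
    b <- project_points(intr, apply_similarity_pose(Tm, pose),
                        apply_similarity_points(Tm, pts))$pixels
    expect_lt(max(abs(a - b)), 1e-7)
  }
})

test_that("similarity preserves angles and scales pairwise distances", {
  set.seed(6)
  Tm <- similarity_transform(3.5, random_rotation(), rnorm(3))
  pts <- matrix(rnorm(30), ncol = 3)
  mapped <- apply_similarity_points(Tm, pts)
  expect_equal(as.numeric(dist(mapped)), 3.5 * as.numeric(dist(pts)),
               tolerance = 1e-12)
  inv <- similarity_invert(Tm)
  back <- apply_similarity_points(inv, mapped)
  expect_lt(max(abs(back - pts)), 1e-12)
})

test_that("quaternion and rotation-vector conversions round-trip", {
  set.seed(8)
  for (rep in 1:50) {
    R <- random_rotation()
    expect_lt(max(abs(quat_to_rot(rot_to_quat(R)) - R)), 1e-12)
    expect_lt(max(abs(rotvec_to_rot(rot_to_rotvec(R)) - R)), 1e-9)
  }
})

test_that("TUM trajectory files round-trip", {
  set.seed(9)
  traj <- list(timestamps = c(0, 1.5, 3),
               poses = lapply(1:3, function(i) random_pose(frame = "ct")))
  path <- withr::local_tempfile(fileext = ".tum")
  write_tum(traj, path)
  back <- read_tum(path, frame = "ct")
  expect_equal(back$timestamps, traj$timestamps)
  for (i in 1:3) {
    expect_lt(max(abs(back$poses[[i]]$R - traj$poses[[i]]$R)), 1e-9)
    expect_lt(max(abs(back$poses[[i]]$t - traj$poses[[i]]$t)), 1e-12)
  }
})

test_that("intrinsics YAML round-trips with units and distortion", {
  intr <- default_intr(dist = c(-0.1, 0.01, 0, 2e-4))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_intrinsics(intr, path)
  back <- read_intrinsics(path)
  expect_equal(back$fx, intr$fx)
  expect_equal(back$dist, intr$dist)
  expect_error(intrinsics(-1, 1, 0, 0, 10, 10))
  expect_error(intrinsics(1, 1, 20, 0, 10, 10), "principal")
})
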