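# Mesh handling: I/O formats, ray casting, depth rendering, distances,
# voxel geometry. Compiled kernels are checked against independent
# R-level oracles defined in the helper.

test_that("a unit cube PLY loads with 8 vertices and 12 faces", {
  cube <- unit_cube_mesh()
  path <- withr::local_tempfile(fileext = ".ply")
  write_ply_mesh(cube, path)
  back <- load_mesh(path)
  expect_equal(nrow(back$vertices), 8)
  expect_equal(nrow(back$faces), 12)
  expect_equal(back$vertices, cube$vertices, ignore_attr = TRUE)
})

test_that("OBJ and STL encodings of the cube load to identical geometry", {
  cube <- unit_cube_mesh()
  obj <- withr::local_tempfile(fileext = ".obj")
  writeLines(c(apply(cube$vertices, 1, function(v)
    paste("v", paste(v, collapse = " "))),
    apply(cube$faces, 1, function(f)
      paste("f", paste(f, collapse = " ")))), obj)
  stl <- withr::local_tempfile(fileext = ".stl")
  stl_lines <- c("solid cube")
  for (f in seq_len(nrow(cube$faces))) {
    stl_lines <- c(stl_lines, "facet normal 0 0 0", "outer loop",
                   apply(cube$vertices[cube$faces[f, ], ], 1, function(v)
                     paste("vertex", paste(v, collapse = " "))),
                   "endloop", "endfacet")
  }
  writeLines(c(stl_lines, "endsolid cube"), stl)
  m_obj <- load_mesh(obj)
  m_stl <- load_mesh(stl)
  # canonicalized comparison: identical triangle soups up to ordering
  canon <- function(m) {
    tri <- t(apply(m$faces, 1, function(f)
      as.numeric(t(m$vertices[f, ][order(m$vertices[f, 1],
                                         m$vertices[f, 2],
                                         m$vertices[f, 3]), ]))))
    tri[do.call(order, as.data.frame(tri)), ]
  }
  expect_equal(canon(m_obj), canon(cube))
  expect_equal(canon(m_stl), canon(cube))
})

test_that("empty or malformed mesh files are rejected", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(character(0), path)
  expect_error(load_mesh(path))
  expect_error(load_mesh("does-not-exist.ply"), "not found")
  expect_error(surface_mesh(matrix(0, 3, 3), matrix(c(1, 2, 5), 1)), "range")
})

test_that("raycast hits a facing plane and misses parallel geometry", {
  plane <- plane_mesh(z = 10)
  hit <- raycast(plane, c(0, 0, 0), c(0, 0, 1))
  expect_true(hit$hit[1])
  expect_equal(hit$distance[1], 10)
  expect_equal(as.numeric(hit$point[1, ]), c(0, 0, 10))
  miss <- raycast(plane, c(500, 0, 0), c(0, 0, 1))
  expect_false(miss$hit[1])
  expect_error(raycast(plane, c(0, 0, 0), c(0, 0, 0)), "zero")
  expect_error(raycast(plane, c(0, 0, 0), c(0, 0, 2)), "unit")
})

test_that("raycast agrees with the exhaustive R-level oracle", {
  scene <- small_scene()
  set.seed(21)
  n_bad <- 0
  for (i in 1:300) {
    o <- c(runif(1, -2, 2), runif(1, -2, 2), runif(1, 2, 30))
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    got <- raycast(scene$mesh, o, d)
    exp <- oracle_raycast(scene$mesh, o, d)
    if (is.null(exp)) {
      expect_false(got$hit[1])
    } else {
      expect_true(got$hit[1])
      expect_lt(abs(got$distance[1] - exp$distance), 1e-9)
      expect_lt(max(abs(got$point[1, ] - exp$point)), 1e-9)
    }
  }
})

test_that("reference render depth equals per-pixel raycasts (z-depth)", {
  scene <- small_scene()
  intr <- scene$intr
  rr <- render_reference(scene$mesh, scene$ref_pose, intr)
  expect_equal(dim(rr$depth), c(intr$height, intr$width))
  set.seed(22)
  px <- cbind(sample(0:(intr$width - 1), 200, TRUE),
              sample(0:(intr$height - 1), 200, TRUE))
  for (i in 1:200) {
    dir_cam <- c((px[i, 1] - intr$cx) / intr$fx,
                 (px[i, 2] - intr$cy) / intr$fy, 1)
    len <- sqrt(sum(dir_cam^2))
    dir <- as.numeric(scene$ref_pose$R %*% (dir_cam / len))
    o <- oracle_raycast(scene$mesh, scene$ref_pose$t, dir)
    d <- rr$depth[px[i, 2] + 1, px[i, 1] + 1]
    if (is.null(o)) expect_false(is.finite(d))
    else expect_lt(abs(d - o$distance / len), 1e-6)  # ray length -> z
  }
})

test_that("a camera looking at a frontal plane renders constant axial depth", {
  intr <- default_intr()
  rr <- render_reference(plane_mesh(z = 10, s = 1000), rigid_pose(), intr)
  expect_equal(rr$depth[round(intr$cy) + 1, round(intr$cx) + 1], 10,
               tolerance = 1e-9)
  # z-depth (not ray length) is constant over the whole frontal plane
  expect_lt(max(abs(rr$depth - 10), na.rm = TRUE), 1e-6)
})

test_that("a camera facing away from all geometry renders all-miss", {
  intr <- default_intr()
  away <- rigid_pose(quat_to_rot(c(1, 0, 0, 0)), c(0, 0, 0))  # 180 deg about x
  expect_warning(rr <- render_reference(plane_mesh(z = 10), away, intr),
                 "missed")
  expect_true(all(!is.finite(rr$depth)))
})

test_that("point-to-mesh distance matches the brute-force oracle", {
  scene <- small_scene()
  tri <- surface_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                      matrix(c(1, 2, 3), 1))
  expect_equal(point_to_mesh_distance(tri, c(0.5, 0.5, 1)), 1)
  expect_equal(point_to_mesh_distance(tri, c(0, 0, 0)), 0)
  set.seed(23)
  pts <- cbind(runif(100, -12, 12), runif(100, -12, 12), runif(100, 0, 60))
  got <- point_to_mesh_distance(scene$mesh, pts)
  for (i in 1:100)
    expect_lt(abs(got[i] - oracle_point_mesh(scene$mesh, pts[i, ])), 1e-9)
  # zero exactly on vertices
  expect_lt(max(point_to_mesh_distance(scene$mesh,
                                       scene$mesh$vertices[1:20, ])), 1e-12)
})

test_that("raycast distance is monotone non-increasing as triangles are added", {
  plane_far <- plane_mesh(z = 20)
  both <- merge_meshes(plane_far, plane_mesh(z = 10))
  d1 <- raycast(plane_far, c(0, 0, 0), c(0, 0, 1))$distance[1]
  d2 <- raycast(both, c(0, 0, 0), c(0, 0, 1))$distance[1]
  expect_lte(d2, d1)
  expect_equal(d2, 10)
})

test_that("world/voxel conversions invert each other", {
  geom <- volume_geometry(diag(4), c(64, 64, 64))
  expect_equal(world_to_voxel(geom, c(3, 4, 5)), matrix(c(3, 4, 5), 1))
  half <- volume_geometry(diag(c(0.5, 0.5, 0.5, 1)), c(64, 64, 64))
  expect_equal(world_to_voxel(half, c(1, 1, 1)), matrix(2, 1, 3))
  set.seed(24)
  A <- diag(4); A[1:3, 1:3] <- matrix(rnorm(9), 3) + diag(3) * 2
  A[1:3, 4] <- rnorm(3)
  g <- volume_geometry(A, c(10, 20, 30))
  pts <- matrix(rnorm(60), ncol = 3)
  expect_lt(max(abs(voxel_to_world(g, world_to_voxel(g, pts)) - pts)), 1e-9)
  expect_error(volume_geometry(matrix(0, 4, 4), c(1, 1, 1)), "singular")
})

test_that("bilinear depth lookup is exact at pixel centers and NA off-mesh", {
  intr <- default_intr()
  rr <- render_reference(plane_mesh(z = 7, s = 1000), rigid_pose(), intr)
  expect_equal(depth_at(rr, c(50, 60)), rr$depth[61, 51])
  expect_true(is.na(depth_at(rr, c(-5, 10))))
})
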