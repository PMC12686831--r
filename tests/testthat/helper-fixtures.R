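# Shared fixtures, built in code. Scenes are cached per test run.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, cfg, ...) {
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- make_scene(cfg, ...)
  .scene_cache[[key]]
}

# A small noiseless scene shared across module tests.
small_scene <- function() {
  cached_scene("small", scene_config(n_frames = 14, seed = 11))
}

# Random rotation matrix via normalized quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  quat_to_rot(q / sqrt(sum(q^2)))
}

random_pose <- function(scale = 1, frame = "world") {
  rigid_pose(random_rotation(), rnorm(3, sd = scale), frame = frame)
}

default_intr <- function(dist = c(0, 0, 0, 0)) {
  intrinsics(150, 150, 99.5, 99.5, 200, 200, dist = dist)
}

# Two axis-aligned triangles forming the square [-s, s]^2 at height z
# (normal along +z).
plane_mesh <- function(z = 10, s = 100) {
  surface_mesh(rbind(c(-s, -s, z), c(s, -s, z), c(s, s, z), c(-s, s, z)),
               rbind(c(1, 2, 3), c(1, 3, 4)))
}

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

# Independent Moller-Trumbore oracle in plain R (nearest hit over all
# triangles), written against the textbook formulation.
oracle_raycast <- function(mesh, origin, dir) {
  best <- Inf; hit <- NULL
  for (f in seq_len(nrow(mesh$faces))) {
    v0 <- mesh$vertices[mesh$faces[f, 1], ]
    e1 <- mesh$vertices[mesh$faces[f, 2], ] - v0
    e2 <- mesh$vertices[mesh$faces[f, 3], ] - v0
    p <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * p)
    if (abs(det) < 1e-14) next
    s <- origin - v0
    u <- sum(s * p) / det
    if (u < 0 || u > 1) next
    q <- c(s[2] * e1[3] - s[3] * e1[2],
           s[3] * e1[1] - s[1] * e1[3],
           s[1] * e1[2] - s[2] * e1[1])
    v <- sum(dir * q) / det
    if (v < 0 || u + v > 1) next
    t <- sum(e2 * q) / det
    if (t > 1e-9 && t < best) { best <- t; hit <- origin + t * dir }
  }
  if (is.null(hit)) NULL else list(point = hit, distance = best)
}

# Independent point-to-triangle distance oracle: unconstrained
# least-squares in barycentric coordinates, falling back to the three
# clamped edge projections when the minimizer is outside the triangle.
oracle_point_triangle <- function(p, a, b, c) {
  e1 <- b - a; e2 <- c - a; d <- p - a
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- c(sum(e1 * d), sum(e2 * d))
  uv <- tryCatch(solve(G, rhs), error = function(e) c(-1, -1))
  if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) {
    q <- a + uv[1] * e1 + uv[2] * e2
    return(sqrt(sum((p - q)^2)))
  }
  edge_dist <- function(u, v) {
    w <- v - u
    t <- max(0, min(1, sum((p - u) * w) / sum(w * w)))
    sqrt(sum((p - (u + t * w))^2))
  }
  min(edge_dist(a, b), edge_dist(a, c), edge_dist(b, c))
}

oracle_point_mesh <- function(mesh, p) {
  min(vapply(seq_len(nrow(mesh$faces)), function(f)
    oracle_point_triangle(p, mesh$vertices[mesh$faces[f, 1], ],
                          mesh$vertices[mesh$faces[f, 2], ],
                          mesh$vertices[mesh$faces[f, 3], ]), numeric(1)))
}

# 4x4 homogeneous matrix oracle for pose algebra.
pose_to_mat <- function(p) rbind(cbind(p$R, p$t), c(0, 0, 0, 1))

# Cached full navigation run on the 40-frame noiseless scene.
cached_scene_run <- function(scene) {
  if (is.null(.scene_cache[["run40"]]))
    .scene_cache[["run40"]] <- navigate_scene(scene, seed = 3)
  .scene_cache[["run40"]]
}
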