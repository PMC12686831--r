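## CT surface handling: mesh container and I/O, depth rendering,
## ray-mesh intersection and point-to-mesh distance (compiled kernels).
## Mesh coordinates are declared millimetres; no unit autodetection is
## attempted, because silently guessed units are the classic navigation bug.

#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `sn_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || any(!is.finite(vertices)))
    stop("vertices must be a finite n x 3 matrix")
  if (ncol(faces) != 3 || nrow(faces) < 1)
    stop("mesh must have at least one triangular face")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "sn_mesh")
}

#' @export
print.sn_mesh <- function(x, ...) {
  cat(sprintf("surface mesh: %d vertices, %d faces (mm)\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Load a surface mesh from PLY, OBJ or STL (ASCII)
#'
#' The format is chosen by file extension. Units are assumed to be
#' millimetres. Quad faces in OBJ/PLY are fan-triangulated.
#'
#' @param path Path to a `.ply`, `.obj` or `.stl` file.
#' @return An `sn_mesh`.
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
                 ply = read_ply_mesh(path),
                 obj = read_obj_mesh(path),
                 stl = read_stl_mesh(path),
                 stop("unsupported mesh format: ", ext))
  mesh
}

read_ply_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(trimws(lines[1]), "ply"))
    stop("not a PLY file (or empty): ", path)
  end_header <- which(trimws(lines) == "end_header")[1]
  if (is.na(end_header)) stop("malformed PLY header")
  header <- lines[seq_len(end_header)]
  if (any(grepl("^format\\s+binary", header)))
    stop("binary PLY is not supported; export ASCII")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", header, value = TRUE)[1]))
  if (is.na(nv) || nv < 1) stop("PLY without vertices")
  body <- lines[(end_header + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vert_tok <- strsplit(trimws(body[seq_len(nv)]), "[[:space:]]+")
  vertices <- do.call(rbind, lapply(vert_tok, function(v) as.numeric(v[1:3])))
  faces <- NULL
  if (!is.na(nf) && nf > 0) {
    face_tok <- strsplit(trimws(body[nv + seq_len(nf)]), "[[:space:]]+")
    faces <- do.call(rbind, lapply(face_tok, function(v) {
      n <- as.integer(v[1])
      idx <- as.integer(v[2:(1 + n)]) + 1L
      if (n == 3) matrix(idx, 1, 3)
      else do.call(rbind, lapply(2:(n - 1), function(k) c(idx[1], idx[k], idx[k + 1])))
    }))
  }
  if (is.null(faces)) stop("PLY has no faces")
  surface_mesh(vertices, faces)
}

read_obj_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(flines) == 0) stop("empty or faceless OBJ: ", path)
  vertices <- do.call(rbind, lapply(strsplit(trimws(vlines), "[[:space:]]+"),
                                    function(v) as.numeric(v[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(flines), "[[:space:]]+"), function(v) {
    idx <- as.integer(vapply(strsplit(v[-1], "/"), `[[`, "", 1))
    if (length(idx) == 3) matrix(idx, 1, 3)
    else do.call(rbind, lapply(2:(length(idx) - 1),
                               function(k) c(idx[1], idx[k], idx[k + 1])))
  }))
  surface_mesh(vertices, faces)
}

read_stl_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^\\s*solid", lines[1]))
    stop("binary or empty STL not supported; export ASCII: ", path)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) stop("malformed STL")
  coords <- do.call(rbind, lapply(strsplit(trimws(vlines), "[[:space:]]+"),
                                  function(v) as.numeric(v[2:4])))
  # deduplicate shared vertices so geometry matches indexed formats
  key <- apply(coords, 1, function(r) paste(format(r, digits = 17), collapse = "_"))
  uid <- match(key, unique(key))
  vertices <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(vertices, faces)
}

#' Write a surface mesh as ASCII PLY
#'
#' @param mesh An `sn_mesh`.
#' @param path Output path.
#' @export
write_ply_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1, function(f)
    paste(c(3, f - 1L), collapse = " ")), con)
  invisible(path)
}

#' Write a point cloud as ASCII PLY
#'
#' @param points n x 3 matrix.
#' @param path Output path.
#' @export
write_ply_points <- function(points, path) {
  points <- as_points(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(points)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  writeLines(apply(points, 1, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = " ")), con)
  invisible(path)
}

#' Merge two meshes into one (disjoint union)
#'
#' @param a,b `sn_mesh` objects.
#' @return An `sn_mesh` containing both surfaces.
#' @export
merge_meshes <- function(a, b) {
  surface_mesh(rbind(a$vertices, b$vertices),
               rbind(a$faces, b$faces + nrow(a$vertices)))
}

## ---- ray casting -----------------------------------------------------------

#' Cast rays against a mesh
#'
#' Nearest ray-triangle intersection with parameter `t > 1e-9`
#' (self-intersection guard). Directions must be unit vectors.
#'
#' @param mesh `sn_mesh`.
#' @param origins n x 3 matrix (or length-3 vector) of ray origins (mm).
#' @param directions n x 3 matrix (or length-3 vector) of unit directions.
#' @return List with `hit` (logical), `distance` (mm, `NA` on miss),
#'   `point` (n x 3, `NA` rows on miss) and `face` (1-based triangle index).
#' @export
raycast <- function(mesh, origins, directions) {
  origins <- as_points(origins)
  directions <- as_points(directions)
  if (nrow(origins) == 1 && nrow(directions) > 1)
    origins <- origins[rep(1, nrow(directions)), , drop = FALSE]
  stopifnot(nrow(origins) == nrow(directions))
  n <- sqrt(rowSums(directions^2))
  if (any(n < 1e-12)) stop("zero-length ray direction")
  if (any(abs(n - 1) > 1e-9)) stop("ray directions must be unit vectors")
  res <- cpp_raycast(mesh$vertices, mesh$faces, origins, directions, 1e-9)
  list(hit = !is.na(res$t), distance = res$t, point = res$point,
       face = res$face)
}

#' Unsigned point-to-mesh distances
#'
#' Exact distance to the nearest point on any triangle (face interior,
#' edge or vertex).
#'
#' @param mesh `sn_mesh`.
#' @param points n x 3 matrix (or length-3 vector).
#' @return Numeric vector of distances (mm).
#' @export
point_to_mesh_distance <- function(mesh, points) {
  points <- as_points(points)
  cpp_closest_point(mesh$vertices, mesh$faces, points)$distance
}

## ---- reference rendering ---------------------------------------------------

#' Render a CT reference view (shaded image + depth map)
#'
#' Casts one ray per pixel from the camera center. The depth map stores the
#' camera-frame z coordinate of the first surface hit (not the ray length);
#' pixels whose ray misses all geometry hold `NA`. The image is a cosmetic
#' Lambertian shading with a headlight at the camera center; only the depth
#' map participates in downstream computation. Distortion is ignored: the
#' reference view is an ideal pinhole rendering.
#'
#' @param mesh `sn_mesh` in the pose's frame.
#' @param pose_ct Camera-to-world `sn_pose` of the reference camera.
#' @param intr `sn_intrinsics` (width x height define the raster).
#' @return An object of class `sn_render` with `image` and `depth`, both
#'   `height x width` matrices (row = image y), plus the `pose` and `intr`
#'   used.
#' @export
render_reference <- function(mesh, pose_ct, intr) {
  w <- intr$width; h <- intr$height
  px <- as.matrix(expand.grid(x = 0:(w - 1), y = 0:(h - 1)))
  dirs_cam <- cbind((px[, 1] - intr$cx) / intr$fx,
                    (px[, 2] - intr$cy) / intr$fy, 1)
  len <- sqrt(rowSums(dirs_cam^2))
  dirs_world <- (dirs_cam / len) %*% t(pose_ct$R)
  res <- raycast(mesh, matrix(pose_ct$t, nrow(dirs_world), 3, byrow = TRUE),
                 dirs_world)
  # convert ray length to camera-frame z via the cosine factor
  zdepth <- res$distance / len
  depth <- matrix(zdepth, nrow = h, ncol = w, byrow = TRUE)
  shade <- rep(0, nrow(px))
  hit <- res$hit
  if (any(hit)) {
    f <- res$face[hit]
    v0 <- mesh$vertices[mesh$faces[f, 1], , drop = FALSE]
    v1 <- mesh$vertices[mesh$faces[f, 2], , drop = FALSE]
    v2 <- mesh$vertices[mesh$faces[f, 3], , drop = FALSE]
    nrm <- vec_cross(v1 - v0, v2 - v0)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    shade[hit] <- abs(rowSums(nrm * dirs_world[hit, , drop = FALSE]))
  } else {
    warning("reference render: all rays missed the mesh")
  }
  image <- matrix(shade, nrow = h, ncol = w, byrow = TRUE)
  structure(list(image = image, depth = depth, pose = pose_ct, intr = intr),
            class = "sn_render")
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Bilinear depth lookup in a reference render
#'
#' Interpolates depth at continuous 0-based pixel coordinates over the
#' finite neighbors; returns `NA` when all four neighbors are misses (the
#' caller is expected to drop such pixels rather than invent a depth).
#'
#' @param render `sn_render`.
#' @param pixels n x 2 matrix of 0-based pixel coordinates.
#' @return Numeric vector of depths (mm), `NA` where undefined.
#' @export
depth_at <- function(render, pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2, byrow = TRUE)
  d <- render$depth
  h <- nrow(d); w <- ncol(d)
  vapply(seq_len(nrow(pixels)), function(i) {
    x <- pixels[i, 1]; y <- pixels[i, 2]
    x0 <- floor(x); y0 <- floor(y)
    if (x0 < 0 || y0 < 0 || x0 > w - 1 || y0 > h - 1) return(NA_real_)
    x1 <- min(x0 + 1, w - 1); y1 <- min(y0 + 1, h - 1)
    fx <- x - x0; fy <- y - y0
    vals <- c(d[y0 + 1, x0 + 1], d[y0 + 1, x1 + 1],
              d[y1 + 1, x0 + 1], d[y1 + 1, x1 + 1])
    wts <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
    ok <- is.finite(vals)
    if (!any(ok)) return(NA_real_)
    sum(vals[ok] * wts[ok]) / sum(wts[ok])
  }, numeric(1))
}

#' Export a reference render
#'
#' Writes the shaded image as PNG (requires the `png` package) and the
#' depth map as a plain-text TSV of depths in mm (`NA` for misses).
#'
#' @param render `sn_render`.
#' @param image_path,depth_path Output paths (either may be `NULL`).
#' @export
write_render <- function(render, image_path = NULL, depth_path = NULL) {
  if (!is.null(image_path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to write the shaded image")
    png::writePNG(render$image / max(render$image, 1e-12), image_path)
  }
  if (!is.null(depth_path))
    write.table(render$depth, depth_path, sep = "\t", row.names = FALSE,
                col.names = FALSE)
  invisible(render)
}

## ---- CT volume geometry ----------------------------------------------------

#' CT volume geometry (voxel-to-world affine)
#'
#' @param affine 4x4 invertible voxel-to-world matrix (mm).
#' @param dims Length-3 positive integer volume dimensions.
#' @return An object of class `sn_volume_geometry`.
#' @export
volume_geometry <- function(affine, dims) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)), all(is.finite(affine)))
  if (abs(det(affine)) < 1e-12) stop("singular voxel-to-world affine")
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims > 0))
  structure(list(affine = affine, dims = dims), class = "sn_volume_geometry")
}

#' Convert between world (mm) and continuous voxel coordinates
#'
#' Voxel indices are 0-based and continuous; rounding/clamping is the
#' caller's concern (see [guidance_record()]).
#'
#' @param geom `sn_volume_geometry`.
#' @param points n x 3 matrix.
#' @return n x 3 matrix of coordinates.
#' @export
world_to_voxel <- function(geom, points) {
  points <- as_points(points)
  hom <- cbind(points, 1) %*% t(solve(geom$affine))
  hom[, 1:3, drop = FALSE]
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(geom, points) {
  points <- as_points(points)
  hom <- cbind(points, 1) %*% t(geom$affine)
  hom[, 1:3, drop = FALSE]
}
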