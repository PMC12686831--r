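## Guidance projection: the viewing-axis line through the camera center
## (the optical axis, playing the role of a pivot pointer), its first
## intersection with the anatomy, and the CT triplane voxel indices
## centered at that intersection.

#' Viewing-axis ray of a CT-frame camera pose
#'
#' Origin is the camera center; direction is the optical axis (+z camera
#' axis, third column of the rotation) expressed in the CT frame.
#'
#' @param ct_pose `sn_pose` in CT coordinates.
#' @return List with `origin` and `direction` (unit).
#' @export
viewing_axis_ray <- function(ct_pose) {
  list(origin = ct_pose$t, direction = as.numeric(ct_pose$R[, 3]))
}

#' Intersection of the viewing axis with the anatomy
#'
#' Nearest ray-mesh hit along the viewing axis; `NULL` when the endoscope
#' views free space.
#'
#' @param mesh `sn_mesh` of the anatomy (optionally merged with fiducial
#'   geometry).
#' @param ray List with `origin` and unit `direction` (see
#'   [viewing_axis_ray()]).
#' @return Length-3 intersection point (mm) or `NULL`.
#' @export
tissue_intersection <- function(mesh, ray) {
  res <- raycast(mesh, ray$origin, ray$direction)
  if (!res$hit[1]) return(NULL)
  as.numeric(res$point[1, ])
}

#' Guidance record for one keyframe event
#'
#' Combines the CT-frame pose, the tissue-intersection point and (when a
#' volume geometry is supplied) the nearest-integer triplane voxel indices
#' of the intersection, clamped to the volume with a flag.
#'
#' @param ct_pose `sn_pose` in CT coordinates.
#' @param mesh `sn_mesh`.
#' @param geom `sn_volume_geometry` or `NULL`.
#' @param frame Frame index attached to the record.
#' @return List `frame, pose (quaternion_xyzw, translation_mm),
#'   intersection_mm (or NULL), ijk (or NULL), clamped`.
#' @export
guidance_record <- function(ct_pose, mesh, geom = NULL, frame = NA) {
  p <- tissue_intersection(mesh, viewing_axis_ray(ct_pose))
  ijk <- NULL; clamped <- FALSE
  if (!is.null(p) && !is.null(geom)) {
    v <- round(as.numeric(world_to_voxel(geom, p)))
    vc <- pmin(pmax(v, 0), geom$dims - 1)
    clamped <- any(vc != v)
    ijk <- as.integer(vc)
  }
  list(frame = frame,
       pose = list(quaternion_xyzw = rot_to_quat(ct_pose$R),
                   translation_mm = ct_pose$t),
       intersection_mm = p, ijk = ijk, clamped = clamped)
}

#' Write guidance records as JSON lines
#'
#' One JSON object per record, suitable for streaming consumers.
#'
#' @param records List of records from [guidance_record()].
#' @param path Output path.
#' @export
write_guidance_jsonl <- function(records, path) {
  lines <- vapply(records, function(r)
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export intersection points as a 3D Slicer markups fiducial file
#'
#' Minimal markups JSON (one fiducial list) holding the guidance
#' intersection points in mm.
#'
#' @param points n x 3 matrix of points (mm, CT/world frame).
#' @param path Output path (`.mrk.json` by convention).
#' @param labels Optional character labels.
#' @export
write_slicer_markups <- function(points, path, labels = NULL) {
  points <- as_points(points)
  if (is.null(labels)) labels <- sprintf("F-%d", seq_len(nrow(points)))
  cps <- lapply(seq_len(nrow(points)), function(i)
    list(id = as.character(i), label = labels[i],
         position = as.numeric(points[i, ]),
         orientation = c(1, 0, 0, 0, 1, 0, 0, 0, 1)))
  doc <- list(
    `@schema` = "https://raw.githubusercontent.com/slicer/slicer/master/Modules/Loadable/Markups/Resources/Schema/markups-schema-v1.0.3.json",
    markups = list(list(type = "Fiducial", coordinateSystem = "LPS",
                        controlPoints = cps)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
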