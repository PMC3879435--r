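#' Rigid pose of a specimen relative to its anatomical frame
#'
#' A pose is a rotation about the anatomical frame origin, parameterised by
#' three angles in degrees about the fixed (extrinsic) anatomical axes,
#' composed in the order X, then Y, then Z. The identity pose has all angles
#' zero. Rotations are always applied about the frame origin, never about a
#' detector contact point.
#'
#' @param theta_x,theta_y,theta_z Rotation angles in degrees about the
#'   anteroposterior (X), superoinferior (Y) and mediolateral (Z) axes.
#' @return An object of class `rigid_pose`.
#' @examples
#' rigid_pose(0, 0, 6)
#' @export
rigid_pose <- function(theta_x = 0, theta_y = 0, theta_z = 0) {
  ang <- c(theta_x, theta_y, theta_z)
  if (!all(is.finite(ang))) stop("pose angles must be finite", call. = FALSE)
  structure(list(theta_x = theta_x, theta_y = theta_y, theta_z = theta_z),
            class = "rigid_pose")
}

#' @export
format.rigid_pose <- function(x, ...) {
  sprintf("<rigid_pose: %+.2f, %+.2f, %+.2f deg (X, Y, Z)>",
          x$theta_x, x$theta_y, x$theta_z)
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

is_identity_pose <- function(pose) {
  pose$theta_x == 0 && pose$theta_y == 0 && pose$theta_z == 0
}

rot_x <- function(deg) {
  r <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(r), sin(r),
           0, -sin(r), cos(r)), 3, 3)
}

rot_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r),
           0, 1, 0,
           sin(r), 0, cos(r)), 3, 3)
}

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0,
           -sin(r), cos(r), 0,
           0, 0, 1), 3, 3)
}

#' Rotation matrix of a rigid pose
#'
#' Extrinsic composition about the fixed anatomical axes in the order
#' X, then Y, then Z: `R = Rz %*% Ry %*% Rx`. Column vectors are rotated as
#' `R %*% v`.
#'
#' @param pose A [rigid_pose()].
#' @return A 3x3 orthonormal rotation matrix.
#' @export
pose_rotation <- function(pose) {
  rot_z(pose$theta_z) %*% rot_y(pose$theta_y) %*% rot_x(pose$theta_x)
}

#' Anatomical coordinate frame of an ankle specimen
#'
#' Origin at the geometric centre of the talus; X anteroposterior (positive
#' anterior), Y superoinferior (positive superior/proximal), Z mediolateral
#' (positive medial). The axes must be orthonormal and right-handed with
#' `axis_z = axis_x x axis_y`.
#'
#' @param origin Numeric length-3, mm.
#' @param axis_x,axis_y,axis_z Unit direction vectors; `axis_z` defaults to
#'   the cross product of the other two.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0),
                             axis_x = c(1, 0, 0),
                             axis_y = c(0, 1, 0),
                             axis_z = NULL) {
  origin <- as.numeric(origin)
  axis_x <- as.numeric(axis_x); axis_y <- as.numeric(axis_y)
  if (is.null(axis_z)) axis_z <- cross3(axis_x, axis_y)
  axis_z <- as.numeric(axis_z)
  stopifnot(length(origin) == 3, length(axis_x) == 3,
            length(axis_y) == 3, length(axis_z) == 3)
  B <- cbind(axis_x, axis_y, axis_z)
  if (max(abs(crossprod(B) - diag(3))) > 1e-8)
    stop("frame axes must be orthonormal", call. = FALSE)
  if (det(B) < 0)
    stop("frame axes must be right-handed (axis_z = axis_x x axis_y)",
         call. = FALSE)
  structure(list(origin = origin, axis_x = axis_x, axis_y = axis_y,
                 axis_z = axis_z), class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame: origin (%.3f, %.3f, %.3f) mm>\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

frame_basis <- function(frame) {
  cbind(frame$axis_x, frame$axis_y, frame$axis_z)
}

#' Apply a rigid pose to a model
#'
#' Rotates the model about the anatomical frame origin. Meshes and landmark
#' sets are rotated analytically (coordinates updated in place); voxel volumes
#' carry the pose as metadata that the DRR ray caster applies to its sample
#' positions, so no resampling loss is ever incurred.
#'
#' @param x A [surface_mesh()], [voxel_volume()], landmark tibble
#'   (columns `x`, `y`, `z`) or an N x 3 coordinate matrix.
#' @param pose A [rigid_pose()].
#' @param frame An [anatomical_frame()] giving the rotation centre and axes.
#' @return An object of the same type as `x`, rotated.
#' @export
apply_pose <- function(x, pose, frame) UseMethod("apply_pose")

rotate_points <- function(pts, pose, frame) {
  if (is_identity_pose(pose)) return(pts)
  B <- frame_basis(frame)
  R_world <- B %*% pose_rotation(pose) %*% t(B)
  ctr <- frame$origin
  swept <- sweep(pts, 2, ctr)
  out <- swept %*% t(R_world)
  sweep(out, 2, ctr, `+`)
}

#' @export
apply_pose.matrix <- function(x, pose, frame) {
  stopifnot(ncol(x) == 3)
  rotate_points(x, pose, frame)
}

#' @export
apply_pose.surface_mesh <- function(x, pose, frame) {
  x$vertices <- rotate_points(x$vertices, pose, frame)
  x
}

#' @export
apply_pose.data.frame <- function(x, pose, frame) {
  stopifnot(all(c("x", "y", "z") %in% names(x)))
  pts <- rotate_points(as.matrix(x[, c("x", "y", "z")]), pose, frame)
  x$x <- pts[, 1]; x$y <- pts[, 2]; x$z <- pts[, 3]
  x
}

#' @export
apply_pose.voxel_volume <- function(x, pose, frame) {
  old <- x$pose
  if (is.null(old) || is_identity_pose(old)) {
    x$pose <- pose
  } else {
    # compose: new world rotation after old; store the combined 3x3 directly
    x$pose_matrix <- pose_rotation(pose) %*% volume_pose_matrix(x)
    x$pose <- NULL
  }
  x$pose_frame <- frame
  x
}

volume_pose_matrix <- function(vol) {
  if (!is.null(vol$pose_matrix)) return(vol$pose_matrix)
  if (is.null(vol$pose)) return(diag(3))
  pose_rotation(vol$pose)
}

#' Compute the anatomical frame from a talus mesh
#'
#' The frame origin is the area-weighted surface centroid of the talus (the
#' package's proxy for the "geometric centre" of the bone); the axes are the
#' canonical anatomical directions, i.e. the mesh is expected to be expressed
#' in (or already aligned with) the anatomical orientation.
#'
#' @param talus_mesh A [surface_mesh()] of the talus.
#' @return An [anatomical_frame()].
#' @export
compute_anatomical_frame <- function(talus_mesh) {
  stopifnot(inherits(talus_mesh, "surface_mesh"))
  if (nrow(talus_mesh$vertices) == 0 || nrow(talus_mesh$faces) == 0)
    stop("talus mesh is empty", call. = FALSE)
  anatomical_frame(origin = mesh_centroid(talus_mesh))
}
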