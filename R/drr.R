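#' Projection geometry of the simulated radiography system
#'
#' Pinhole (central projection) model: a point X-ray source, a flat detector
#' plane with orthonormal in-plane axes `u` and `v`, source-to-image distance
#' `sid` (default 1000 mm, the focus one metre from the image plane), and a
#' square pixel grid centred on the principal point (the foot of the
#' perpendicular from the source).
#'
#' @param source World position of the X-ray source, mm.
#' @param det_origin World position of the principal point on the detector.
#' @param u_axis,v_axis Orthonormal in-plane detector axes.
#' @param pixel_spacing Detector pixel pitch, mm.
#' @param image_size Image size in pixels (length 1 or 2: `nu`, `nv`).
#' @param view View tag, `"ML"` or `"AP"`.
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(source, det_origin, u_axis, v_axis,
                                pixel_spacing = 0.35, image_size = 512,
                                view = "custom") {
  u_axis <- u_axis / sqrt(sum(u_axis^2))
  v_axis <- v_axis / sqrt(sum(v_axis^2))
  if (abs(sum(u_axis * v_axis)) > 1e-9)
    stop("detector axes must be orthonormal", call. = FALSE)
  n <- cross3(u_axis, v_axis)
  sid <- sum((source - det_origin) * n)
  if (abs(sid) <= 0) stop("source must be off the detector plane", call. = FALSE)
  if (sid < 0) { n <- -n; sid <- -sid }
  image_size <- rep(as.integer(image_size), length.out = 2)
  structure(list(source = as.numeric(source),
                 det_origin = as.numeric(det_origin),
                 u_axis = u_axis, v_axis = v_axis, normal = n, sid = sid,
                 pixel_spacing = pixel_spacing,
                 nu = image_size[1], nv = image_size[2], view = view),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("<projection_geometry %s: SID %.1f mm, %dx%d px @ %.3f mm>\n",
              x$view, x$sid, x$nu, x$nv, x$pixel_spacing))
  invisible(x)
}

#' Standard-pose imaging geometry for the M/L and A/P views
#'
#' M/L (lateral) view: the detector plane is normal to the mediolateral axis
#' and touches the most lateral point of the fibula (the lateral malleolus);
#' the source sits on the medial side at the source-to-image distance, with
#' the principal ray passing through the most medial point of the tibia
#' (the medial malleolus). A/P (frontal) view: the detector is normal to the
#' anteroposterior axis and touches the most posterior bone point offset by
#' a configurable heel stand-in thickness; the principal ray passes through
#' the midpoint of the inter-malleolar axis.
#'
#' @param view `"ML"` or `"AP"`.
#' @param meshes Named list of bone meshes (standard pose).
#' @param frame The [anatomical_frame()].
#' @param landmarks 3D landmark tibble holding `TibMed` and `FibLat`.
#' @param sid Source-to-image distance, mm.
#' @param pixel_spacing,image_size Detector settings.
#' @param heel_offset A/P only: posterior soft-tissue/calcaneus stand-in
#'   thickness between the most posterior bone point and the detector, mm.
#' @return A [projection_geometry()].
#' @export
make_standard_geometry <- function(view, meshes, frame, landmarks,
                                   sid = 1000, pixel_spacing = 0.35,
                                   image_size = 512, heel_offset = 40) {
  view <- toupper(view)
  if (!view %in% c("ML", "AP"))
    stop("view must be \"ML\" or \"AP\"", call. = FALSE)
  B <- frame_basis(frame)
  allv <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  fv <- to_frame(allv, frame)
  tibmed <- to_frame(rbind(lm_point(landmarks, "TibMed")), frame)[1, ]
  fiblat <- to_frame(rbind(lm_point(landmarks, "FibLat")), frame)[1, ]
  if (view == "ML") {
    z_det <- min(fv[, 3])
    det_f <- c(tibmed[1], tibmed[2], z_det)
    src_f <- c(tibmed[1], tibmed[2], z_det + sid)
    u_f <- c(1, 0, 0); v_f <- c(0, 1, 0)
  } else {
    x_det <- min(fv[, 1]) - heel_offset
    mid <- (tibmed + fiblat) / 2
    det_f <- c(x_det, mid[2], mid[3])
    src_f <- c(x_det + sid, mid[2], mid[3])
    u_f <- c(0, 0, 1); v_f <- c(0, 1, 0)
  }
  to_world <- function(p) frame$origin + as.numeric(B %*% p)
  dir_world <- function(d) as.numeric(B %*% d)
  projection_geometry(to_world(src_f), to_world(det_f),
                      dir_world(u_f), dir_world(v_f),
                      pixel_spacing = pixel_spacing,
                      image_size = image_size, view = view)
}

#' Central projection of 3D points onto the detector
#'
#' @param p Length-3 point or N x 3 matrix, world mm.
#' @param geom A [projection_geometry()].
#' @return `(u, v)` detector coordinates in mm (vector or N x 2 matrix).
#' @export
project_point <- function(p, geom) {
  single <- !is.matrix(p)
  P <- if (single) matrix(p, 1) else p
  S <- geom$source; n <- geom$normal
  depth <- as.numeric((P - matrix(S, nrow(P), 3, byrow = TRUE)) %*% n)
  # points must lie strictly between the source and (at most on) the detector
  if (any(depth >= 0))
    stop("point at or behind the X-ray source cannot be projected",
         call. = FALSE)
  t <- -geom$sid / depth
  Q <- matrix(S, nrow(P), 3, byrow = TRUE) +
    (P - matrix(S, nrow(P), 3, byrow = TRUE)) * t
  rel <- Q - matrix(geom$det_origin, nrow(P), 3, byrow = TRUE)
  uv <- cbind(u = as.numeric(rel %*% geom$u_axis),
              v = as.numeric(rel %*% geom$v_axis))
  if (single) uv[1, ] else uv
}

#' Depth of points from the detector plane
#' @inheritParams project_point
#' @return Distance(s) from the detector plane toward the source, mm.
#' @export
projection_depth <- function(p, geom) {
  P <- if (is.matrix(p)) p else matrix(p, 1)
  as.numeric((P - matrix(geom$det_origin, nrow(P), 3, byrow = TRUE)) %*%
               geom$normal)
}

#' Project a posed 3D landmark set onto the detector
#'
#' Applies the rigid pose about the anatomical frame, then central
#' projection; names are preserved and provenance is `"projected"`.
#'
#' @param lm Landmark tibble (`name`, `x`, `y`, `z`).
#' @param pose A [rigid_pose()].
#' @param geom A [projection_geometry()].
#' @param frame The [anatomical_frame()].
#' @return Tibble with columns `name`, `u`, `v`, `depth`, `provenance`.
#' @export
project_landmarks <- function(lm, pose, geom, frame = anatomical_frame()) {
  posed <- apply_pose(lm, pose, frame)
  pts <- as.matrix(posed[, c("x", "y", "z")])
  uv <- project_point(pts, geom)
  tibble::tibble(name = lm$name, u = uv[, 1], v = uv[, 2],
                 depth = projection_depth(pts, geom),
                 provenance = "projected")
}

#' Render a digitally reconstructed radiograph
#'
#' For every detector pixel, integrates the volume's attenuation along the
#' source-to-pixel ray (midpoint rule at a fixed nominal step, trilinear
#' interpolation). The rigid pose is applied by mapping the ray sample
#' positions through the inverse rotation, so the volume is never resampled.
#' Pixel intensities are raw line integrals (mm x attenuation units); rays
#' that miss the volume give exactly 0.
#'
#' @param volume A [voxel_volume()].
#' @param pose A [rigid_pose()] (composed with any pose already carried by
#'   the volume).
#' @param geom A [projection_geometry()].
#' @param frame The [anatomical_frame()] about which the pose rotates.
#' @param step Ray sampling step in mm; default half the smallest voxel
#'   dimension.
#' @return An object of class `drr_image`: `pixels` (nu x nv matrix),
#'   `pixel_spacing`, `geom`, `view`, `pose`.
#' @export
cast_drr <- function(volume, pose = rigid_pose(), geom,
                     frame = anatomical_frame(), step = NULL) {
  if (is.null(step)) step <- min(volume$spacing) / 2
  if (step <= 0) stop("ray step must be > 0", call. = FALSE)
  B <- frame_basis(frame)
  R_world <- B %*% pose_rotation(pose) %*% t(B)
  R_total <- R_world %*% volume_pose_matrix(volume)
  pix <- cast_drr_cpp(as.numeric(volume$values), dim(volume$values),
                      volume$spacing, volume$origin,
                      t(R_total), frame$origin,
                      geom$source, geom$det_origin,
                      geom$u_axis, geom$v_axis,
                      geom$pixel_spacing, geom$nu, geom$nv, step)
  structure(list(pixels = pix, pixel_spacing = geom$pixel_spacing,
                 geom = geom, view = geom$view, pose = pose),
            class = "drr_image")
}

#' @export
print.drr_image <- function(x, ...) {
  cat(sprintf("<drr_image %s: %d x %d px, max intensity %.3f>\n",
              x$view, nrow(x$pixels), ncol(x$pixels), max(x$pixels)))
  invisible(x)
}

# (u, v) mm coordinates of the pixel centres of a DRR
drr_pixel_axes <- function(img) {
  nu <- nrow(img$pixels); nv <- ncol(img$pixels); ps <- img$pixel_spacing
  list(u = (seq_len(nu) - (nu + 1) / 2) * ps,
       v = (seq_len(nv) - (nv + 1) / 2) * ps)
}

#' Write a DRR to disk (16-bit PNG and/or float TIFF)
#'
#' @param img A `drr_image`.
#' @param path Output path ending in `.png` (windowed 16-bit) or `.tif`
#'   (lossless float).
#' @return `path`, invisibly.
#' @export
write_drr <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  m <- t(img$pixels)[rev(seq_len(ncol(img$pixels))), , drop = FALSE]
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to write PNG output", call. = FALSE)
    rng <- range(m)
    scaled <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF output", call. = FALSE)
    tiff::writeTIFF(m / max(max(m), 1e-12), path, bits.per.sample = 32L)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}
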