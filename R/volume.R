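#' Voxelised attenuation volume
#'
#' A 3D scalar grid of attenuation values (arbitrary units, >= 0) with
#' per-axis voxel spacing and a world origin. The convention is
#' node-centred: the world position of voxel `(i, j, k)` (0-based) is
#' `origin + spacing * (i, j, k)`, i.e. `origin` is the centre of voxel
#' `(0, 0, 0)`.
#'
#' @param values 3D numeric array, finite and >= 0.
#' @param spacing Per-axis voxel size in mm, all > 0.
#' @param origin World position (mm) of the centre of voxel (0,0,0).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("voxel spacing must be > 0", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("attenuation values must be finite and >= 0", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin,
                 pose = NULL, pose_frame = NULL),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' World coordinate of a voxel index
#' @param vol A [voxel_volume()].
#' @param ijk 0-based voxel index (length 3 or N x 3 matrix).
#' @return World coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- if (is.matrix(ijk)) ijk else matrix(ijk, ncol = 3)
  sweep(sweep(ijk, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

# ---- volume file I/O -------------------------------------------------------

#' Read / write attenuation volumes (MHD/RAW, NIfTI)
#'
#' MHD/RAW is written directly (MET_FLOAT or MET_DOUBLE element types);
#' NIfTI (.nii / .nii.gz) goes through the RNifti package, carrying spacing
#' through pixdim and the origin through the sform.
#'
#' @param path File path ending in `.mhd`, `.nii` or `.nii.gz`.
#' @param vol A [voxel_volume()].
#' @param type Raw element type for MHD output, `"double"` or `"float"`.
#' @return `read_volume()` returns a [voxel_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path, call. = FALSE)
  lp <- tolower(path)
  if (grepl("\\.mhd$", lp)) return(read_mhd(path))
  if (grepl("\\.nii(\\.gz)?$", lp)) return(read_nifti_volume(path))
  stop("unsupported volume format: ", basename(path), call. = FALSE)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, type = c("double", "float")) {
  type <- match.arg(type)
  lp <- tolower(path)
  if (grepl("\\.mhd$", lp)) {
    write_mhd(vol, path, type)
  } else if (grepl("\\.nii(\\.gz)?$", lp)) {
    write_nifti_volume(vol, path)
  } else {
    stop("unsupported volume format: ", basename(path), call. = FALSE)
  }
  invisible(path)
}

write_mhd <- function(vol, path, type = "double") {
  raw_path <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
  d <- dim(vol$values)
  et <- if (type == "double") "MET_DOUBLE" else "MET_FLOAT"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("Offset = %.10g %.10g %.10g",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    sprintf("ElementType = %s", et),
    sprintf("ElementDataFile = %s", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$values), con,
           size = if (type == "double") 8 else 4, endian = "little")
}

read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("malformed MHD: missing field '", key, "'", call. = FALSE)
    vals[i]
  }
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  if (length(d) != 3 || any(is.na(d)))
    stop("malformed MHD: bad DimSize", call. = FALSE)
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  origin <- if ("Offset" %in% keys)
    as.numeric(strsplit(get("Offset"), "\\s+")[[1]]) else c(0, 0, 0)
  et <- get("ElementType")
  sz <- switch(et, MET_DOUBLE = 8, MET_FLOAT = 4, MET_SHORT = 2, MET_UCHAR = 1,
               stop("malformed MHD: unsupported ElementType ", et, call. = FALSE))
  what <- if (sz >= 4) "numeric" else "integer"
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  if (!file.exists(raw_path))
    stop("malformed MHD: ElementDataFile not found: ", raw_path, call. = FALSE)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  n <- prod(d)
  v <- readBin(con, what, n = n, size = sz, endian = "little",
               signed = sz > 1)
  if (length(v) != n)
    stop("malformed MHD: raw data shorter than DimSize implies", call. = FALSE)
  voxel_volume(array(as.numeric(v), dim = d), spacing, origin)
}

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  xf <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  voxel_volume(vals, sp, origin)
}

# ---- frame / pose YAML sidecars -------------------------------------------

#' Read / write anatomical frames and poses as YAML sidecars
#' @param frame An [anatomical_frame()]; `pose` a [rigid_pose()].
#' @param pose A [rigid_pose()] or NULL.
#' @param path YAML file path.
#' @return `read_frame_yaml()` returns a list with elements `frame` and
#'   `pose` (pose may be NULL).
#' @export
write_frame_yaml <- function(frame, path, pose = NULL) {
  obj <- list(origin = frame$origin,
              axis_X = frame$axis_x, axis_Y = frame$axis_y,
              axis_Z = frame$axis_z)
  if (!is.null(pose))
    obj <- c(obj, list(theta_X = pose$theta_x, theta_Y = pose$theta_y,
                       theta_Z = pose$theta_z))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_frame_yaml
#' @export
read_frame_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  frame <- anatomical_frame(obj$origin, obj$axis_X, obj$axis_Y, obj$axis_Z)
  pose <- if (!is.null(obj$theta_X))
    rigid_pose(obj$theta_X, obj$theta_Y, obj$theta_Z) else NULL
  list(frame = frame, pose = pose)
}
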