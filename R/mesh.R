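#' Triangulated bone surface mesh
#'
#' @param vertices N x 3 numeric matrix of world coordinates in mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param label Bone name, one of `"tibia"`, `"fibula"`, `"talus"` (or a
#'   combined label such as `"tibia_fibula"`).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, label = "bone") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop("face indices out of range", call. = FALSE)
    # drop degenerate (zero-area) faces
    a <- face_areas(vertices, faces)
    faces <- faces[a > 1e-12, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh '%s': %d vertices, %d faces>\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_areas <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - v1
  e2 <- vertices[faces[, 3], , drop = FALSE] - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  v1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v1
  e2 <- v[f[, 3], , drop = FALSE] - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

#' Area-weighted vertex normals of a mesh
#' @param mesh A [surface_mesh()].
#' @return N x 3 matrix of unit normals (rows for unreferenced vertices are 0).
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- face_normals(mesh)
  a <- face_areas(v, f)
  n <- matrix(0, nrow(v), 3)
  w <- fn * a
  for (k in 1:3) {
    for (j in 1:3) {
      acc <- rowsum(w[, j], f[, k], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      n[idx, j] <- n[idx, j] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

# vertices adjacent to at least one face whose (frame-space) normal
# Y-component satisfies the predicate; robust at corner vertices where
# area-weighted vertex normals are dominated by large lateral faces
vertices_with_face_normal <- function(mesh, frame, predicate) {
  fn <- face_normals(mesh) %*% frame_basis(frame)
  hit <- predicate(fn[, 2])
  flag <- logical(nrow(mesh$vertices))
  flag[as.vector(mesh$faces[hit, , drop = FALSE])] <- TRUE
  flag
}

#' Area-weighted surface centroid of a mesh
#'
#' The mean of the face centroids weighted by face area; used as the
#' "geometric centre" of a bone when defining the anatomical frame.
#'
#' @param mesh A [surface_mesh()].
#' @return Numeric length-3, mm.
#' @export
mesh_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0) stop("mesh has no faces", call. = FALSE)
  a <- face_areas(v, f)
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  colSums(cen * a) / sum(a)
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh A [surface_mesh()] that is closed and consistently oriented.
#' @return Signed volume in mm^3 (positive for outward-oriented surfaces).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v3[, 2] * v2[, 3]) -
      v2[, 1] * (v1[, 2] * v3[, 3] - v3[, 2] * v1[, 3]) +
      v3[, 1] * (v1[, 2] * v2[, 3] - v2[, 2] * v1[, 3])) / 6
}

#' Merge several meshes into one
#' @param ... [surface_mesh()] objects (or a single list of them).
#' @param label Label for the merged mesh.
#' @return A [surface_mesh()].
#' @export
merge_meshes <- function(..., label = "merged") {
  ms <- list(...)
  if (length(ms) == 1 && !inherits(ms[[1]], "surface_mesh")) ms <- ms[[1]]
  verts <- do.call(rbind, lapply(ms, `[[`, "vertices"))
  off <- cumsum(c(0, vapply(ms, function(m) nrow(m$vertices), 0L)))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o, ms, off[-length(off)]))
  surface_mesh(verts, faces, label = label)
}

translate_mesh <- function(mesh, shift) {
  mesh$vertices <- sweep(mesh$vertices, 2, shift, `+`)
  mesh
}

# ---- mesh file I/O ---------------------------------------------------------

#' Read / write triangle meshes (binary STL, ASCII PLY)
#'
#' Format is chosen from the file extension. STL stores per-triangle vertex
#' triplets; on reading, coincident vertices are merged back exactly.
#'
#' @param path File path ending in `.stl` or `.ply`.
#' @param mesh A [surface_mesh()].
#' @param label Bone label to attach to the mesh read from file.
#' @return `read_mesh()` returns a [surface_mesh()]; `write_mesh()` returns
#'   `path` invisibly.
#' @export
read_mesh <- function(path, label = "bone") {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = read_stl(path, label),
    ply = read_ply(path, label),
    stop("unsupported mesh format: .", ext, call. = FALSE))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = write_stl(mesh, path),
    ply = write_ply(mesh, path),
    stop("unsupported mesh format: .", ext, call. = FALSE))
  invisible(path)
}

write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "anklemorph binary STL"))[1:80]
  writeBin(header, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  fn <- face_normals(mesh)
  v <- mesh$vertices
  # 12 floats + 2-byte attribute per triangle
  tri <- matrix(0, 12, nf)
  tri[1:3, ] <- t(fn)
  tri[4:6, ] <- t(v[mesh$faces[, 1], , drop = FALSE])
  tri[7:9, ] <- t(v[mesh$faces[, 2], , drop = FALSE])
  tri[10:12, ] <- t(v[mesh$faces[, 3], , drop = FALSE])
  for (i in seq_len(nf)) {
    writeBin(as.numeric(tri[, i]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

read_stl <- function(path, label) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(nf) || is.na(nf) || nf < 0)
    stop("malformed STL: bad triangle count field", call. = FALSE)
  verts <- matrix(0, nf * 3, 3)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(vals) < 12)
      stop("malformed STL: truncated triangle record ", i, call. = FALSE)
    readBin(con, "raw", 2)
    verts[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  key <- apply(verts, 1, function(r) paste(format(r, digits = 17), collapse = ","))
  uid <- match(key, unique(key))
  uv <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(uv, faces, label = label)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment label %s", mesh$label),
               sprintf("element vertex %d", nv),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1,
                   function(r) paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1,
                   function(r) paste(c(3L, r), collapse = " ")), con)
}

read_ply <- function(path, label) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("malformed PLY: missing 'ply' magic line", call. = FALSE)
  hend <- match("end_header", lines)
  if (is.na(hend)) stop("malformed PLY: no end_header", call. = FALSE)
  head <- lines[1:hend]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", head, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", head, value = TRUE)))
  if (!length(nv) || !length(nf))
    stop("malformed PLY: missing element vertex/face counts", call. = FALSE)
  lab <- grep("^comment label ", head, value = TRUE)
  if (length(lab)) label <- sub("^comment label ", "", lab[1])
  vl <- lines[(hend + 1):(hend + nv)]
  verts <- matrix(as.numeric(unlist(strsplit(vl, " +"))), ncol = 3, byrow = TRUE)
  fl <- lines[(hend + nv + 1):(hend + nv + nf)]
  fm <- matrix(as.integer(unlist(strsplit(fl, " +"))), ncol = 4, byrow = TRUE)
  surface_mesh(verts, fm[, 2:4, drop = FALSE] + 1L, label = label)
}
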