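# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# fast-profile phantom (coarse voxels) with volume
fast_phantom <- function() {
  cached("fast_phantom",
         generate_phantom(phantom_spec(voxel_spacing = 1.25), raster = TRUE))
}

# same phantom, meshes only
mesh_phantom <- function() {
  cached("mesh_phantom", generate_phantom(raster = FALSE))
}

fast_geometry <- function(view, ph = fast_phantom()) {
  cached(paste0("geom_", view), {
    lm3 <- fast_landmarks3d(ph)
    make_standard_geometry(view, ph$meshes, ph$frame, lm3,
                           image_size = 192, pixel_spacing = 0.7)
  })
}

fast_landmarks3d <- function(ph = fast_phantom()) {
  cached("lm3", attr(measure_phantom_3d(ph), "landmarks"))
}

fast_profile3d <- function(ph = fast_phantom()) {
  cached("prof3", measure_phantom_3d(ph))
}

profile_value <- function(prof, parameter) {
  prof$value[prof$parameter == parameter]
}

# small cohort of mesh-only phantoms for recovery properties
small_cohort <- function(n = 20, seed = 11) {
  cached(paste0("cohort_", n, "_", seed),
         generate_cohort(n, seed = seed, raster = FALSE))
}

# Pure-R fine-step trilinear ray integrator: the independent oracle for the
# compiled DRR caster. Integrates the unposed volume along the world segment
# p0 -> p1 with the given step, midpoint rule.
oracle_ray_integral <- function(vol, p0, p1, step = min(vol$spacing) / 10) {
  d <- dim(vol$values)
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(1L, ceiling(len / step))
  t <- (seq_len(n) - 0.5) / n
  pts <- outer(t, p1 - p0) + matrix(p0, n, 3, byrow = TRUE)
  g <- sweep(sweep(pts, 2, vol$origin), 2, vol$spacing, `/`)
  acc <- numeric(n)
  inside <- g[, 1] >= 0 & g[, 2] >= 0 & g[, 3] >= 0 &
    g[, 1] <= d[1] - 1 & g[, 2] <= d[2] - 1 & g[, 3] <= d[3] - 1
  if (any(inside)) {
    gi <- g[inside, , drop = FALSE]
    i0 <- pmin(floor(gi[, 1]), d[1] - 2); fx <- gi[, 1] - i0
    j0 <- pmin(floor(gi[, 2]), d[2] - 2); fy <- gi[, 2] - j0
    k0 <- pmin(floor(gi[, 3]), d[3] - 2); fz <- gi[, 3] - k0
    at <- function(di, dj, dk)
      vol$values[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
    val <-
      at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
      at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
      at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
      at(1, 1, 0) * fx * fy * (1 - fz) +
      at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
      at(1, 0, 1) * fx * (1 - fy) * fz +
      at(0, 1, 1) * (1 - fx) * fy * fz +
      at(1, 1, 1) * fx * fy * fz
    acc[inside] <- val
  }
  sum(acc) * len / n
}

# one-pixel DRR: integral along the ray from the source to the pixel at
# detector coordinates (u, v) mm
drr_at_uv <- function(vol, geom, u, v, step) {
  nu1 <- projection_geometry(geom$source,
                             geom$det_origin + u * geom$u_axis + v * geom$v_axis,
                             geom$u_axis, geom$v_axis,
                             pixel_spacing = geom$pixel_spacing,
                             image_size = 1, view = geom$view)
  img <- cast_drr(vol, rigid_pose(), nu1, step = step)
  img$pixels[1, 1]
}
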