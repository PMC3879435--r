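#' Parametric specification of a synthetic ankle phantom
#'
#' The phantom is an idealised constructive-solid-geometry ankle: the distal
#' tibia is a block with a concave cylindrical mortise cut, anterior/posterior
#' profile creases and a medial malleolus column; the fibula is a lateral
#' malleolus column; the talus is a cylinder-segment trochlea with raised
#' medial/lateral crests. Every one of the fourteen morphological parameters
#' is a closed-form function of the specification, so the generated phantom
#' carries exact ground truth.
#'
#' Defaults are the cohort means of the emulated study population
#' (see [ankle_cohort_defaults()]).
#'
#' @param tial Tibial arc length (mortise chord A-B), mm.
#' @param tisr Tibial sagittal radius (mortise arc radius), mm.
#' @param apa Anteroposterior inclination of the mortise chord, degrees.
#' @param mtith Maximal tibial thickness (A/P extent C-D), mm.
#' @param mda Longitudinal distance between A and the most anterior profile
#'   point C, mm.
#' @param mdv Longitudinal distance between the mortise vertex V and the most
#'   posterior profile point D, mm.
#' @param tiw Tibial mortise M/L width, mm.
#' @param malw Malleolar width (most lateral fibula to most medial tibia), mm.
#' @param mlati Frontal tilt of the inter-malleolar tip line, degrees.
#' @param taal Trochlea tali central arc length, mm.
#' @param tar Trochlea tali central radius, mm.
#' @param taw Trochlea tali width (medial to lateral crest), mm.
#' @param mlata Frontal tilt of the trochlea crest vertex line, degrees.
#' @param crest_height Height of the trochlea crests above the central dome, mm.
#' @param joint_gap Radiolucent gap between trochlea and mortise, mm.
#' @param shaft_height Height of the tibial shaft stub above the mortise
#'   vertex, mm.
#' @param mal_drop Distal drop of the medial malleolus tip below the anterior
#'   mortise ledge, mm.
#' @param bevel_deg Inward bevel of the anterior/posterior tibial faces away
#'   from the profile creases, degrees (makes C and D unique).
#' @param attenuation_bone,attenuation_background Attenuation levels.
#' @param soft_level Optional soft-tissue attenuation; 0 disables the shell.
#' @param soft_margin Soft-tissue shell margin around the bones, mm.
#' @param voxel_spacing Rasterisation voxel size, mm (isotropic default
#'   0.625 to match clinical CT; use 1.25 for a fast profile).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tial = 28.41, tisr = 29.07, apa = 7.86,
                         mtith = 42.44, mda = 10.21, mdv = 3.15,
                         tiw = 32.84, malw = 62.60, mlati = 12.59,
                         taal = 33.55, tar = 20.57, taw = 19.89,
                         mlata = 2.31,
                         crest_height = 6, joint_gap = 2,
                         shaft_height = 25, mal_drop = 12, bevel_deg = 6,
                         attenuation_bone = 1, attenuation_background = 0,
                         soft_level = 0, soft_margin = 3,
                         voxel_spacing = 0.625) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  p <- unlist(x[phantom_parameter_names()])
  cat(paste(sprintf("  %-6s %8.3f", names(p), p), collapse = "\n"), "\n")
  invisible(x)
}

phantom_parameter_names <- function() {
  c("tial", "tisr", "apa", "mtith", "mda", "mdv", "tiw", "malw", "mlati",
    "taal", "tar", "taw", "mlata")
}

# maps spec fields to the reported parameter symbols
parameter_symbols <- function() {
  c(tial = "TiAL", tisr = "TiSR", apa = "APA", mtith = "MTiTh",
    mda = "MDA", mdv = "MDV", tiw = "TiW", malw = "MalW", mlati = "MLATi",
    taal = "TaAL", tar = "TaR", taw = "TaW", mlata = "MLATa")
}

#' Validate a phantom specification
#'
#' Checks the geometric feasibility invariants; stops with a message naming
#' the first violated invariant.
#'
#' @param spec A [phantom_spec()] (or plain list with the same fields).
#' @return `TRUE` invisibly.
#' @export
validate_phantom_spec <- function(spec) {
  fail <- function(msg) stop("invalid phantom spec: ", msg, call. = FALSE)
  lens <- c("tial", "tisr", "mtith", "mda", "mdv", "tiw", "malw",
            "taal", "tar", "taw", "crest_height", "joint_gap",
            "shaft_height", "mal_drop")
  for (f in lens) if (!is.finite(spec[[f]]) || spec[[f]] <= 0)
    fail(paste0(f, " must be > 0"))
  if (spec$taw >= spec$malw) fail("trochlea width must be < malleolar width")
  if (abs(spec$mlata) > 20) fail("talar frontal tilt must be within +/-20 deg")
  if (abs(spec$mlati) > 20) fail("malleolar frontal tilt must be within +/-20 deg")
  if (spec$crest_height >= spec$tar)
    fail("crest height must be < trochlea radius (self-intersecting crests)")
  dy <- spec$taw * tan(spec$mlata * pi / 180)
  if (spec$crest_height + min(dy, 0) < 0.3)
    fail("talar tilt drops the medial crest below the dome")
  if (spec$tial >= 2 * spec$tisr * sin(1.3))
    fail("tibial arc length incompatible with sagittal radius (arc > 149 deg)")
  phi_ti <- asin(spec$tial / (2 * spec$tisr))
  delta <- spec$apa * pi / 180
  if (phi_ti <= abs(delta) + 0.02)
    fail("mortise inclination exceeds the arc half-angle (vertex leaves the arc)")
  if (spec$taal / (2 * spec$tar) > 1.3)
    fail("trochlea arc length incompatible with radius (arc > 149 deg)")
  if (1.5 * spec$taw >= spec$tiw)
    fail("trochlea (crests included) must be narrower than the mortise width")
  if (spec$mda < 1) fail("mda must be >= 1 mm")
  if (spec$mdv < 0.5) fail("mdv must be >= 0.5 mm")
  g <- try(phantom_geometry_core(spec), silent = TRUE)
  if (inherits(g, "try-error"))
    fail(attr(g, "condition")$message)
  invisible(TRUE)
}

# All derived construction geometry, before recentring on the talus centroid.
phantom_geometry_core <- function(spec) {
  s <- spec
  d2r <- pi / 180
  phi_ti <- asin(s$tial / (2 * s$tisr))
  delta <- s$apa * d2r
  phi_ta <- s$taal / (2 * s$tar)
  b <- s$taw / 2
  dy <- s$taw * tan(s$mlata * d2r)
  r_c <- s$tar
  r_l <- s$tar + s$crest_height
  r_m <- s$tar + s$crest_height + dy
  y_c <- 0  # dome centre before recentring
  dome_top <- y_c + max(r_l, r_m)
  y_cm <- dome_top + s$joint_gap - s$tisr
  a1 <- delta + phi_ti   # anterior arc end angle (from the vertical)
  a2 <- delta - phi_ti   # posterior arc end angle (negative)
  xa <- s$tisr * sin(a1); ya <- y_cm + s$tisr * cos(a1)
  xb <- s$tisr * sin(a2); yb <- y_cm + s$tisr * cos(a2)
  yV <- y_cm + s$tisr
  cx0 <- s$tisr * cos(phi_ti) * sin(delta)  # mortise chord midpoint x
  x_C <- cx0 + s$mtith / 2
  x_D <- cx0 - s$mtith / 2
  y_C <- ya + s$mda
  y_D <- yV - s$mdv
  y_top <- yV + s$shaft_height
  tanb <- tan(s$bevel_deg * d2r)
  if (y_C > y_top - 2) stop("anterior crease reaches the shaft top", call. = FALSE)
  if (y_D > y_top - 2) stop("posterior crease reaches the shaft top", call. = FALSE)
  x_al <- x_C - (y_C - ya) * tanb
  if (x_al <= xa + 0.5)
    stop("anterior profile too thin for the mortise arc", call. = FALSE)
  x_pl <- x_D + abs(yb - y_D) * tanb
  if (x_pl >= xb - 0.5)
    stop("posterior profile too thin for the mortise arc", call. = FALSE)
  # malleoli
  mal_half_x <- min(10, s$mtith / 2 - 1)
  fib_half_x <- min(8, s$mtith / 2 - 1)
  z_in <- s$tiw / 2
  z_out <- s$malw / 2
  if (z_out <= z_in + 2) stop("malleolar width must exceed mortise width + 4 mm",
                              call. = FALSE)
  z_tip_m <- (z_in + z_out) / 2
  z_tip_f <- -z_tip_m
  y_tt <- ya - s$mal_drop
  y_ft <- y_tt - (z_tip_m - z_tip_f) * tan(s$mlati * d2r)
  list(spec = s, phi_ti = phi_ti, delta = delta, phi_ta = phi_ta,
       b = b, dy = dy, r_c = r_c, r_l = r_l, r_m = r_m, y_c = y_c,
       y_cm = y_cm, a1 = a1, a2 = a2, xa = xa, ya = ya, xb = xb, yb = yb,
       yV = yV, cx0 = cx0, x_C = x_C, x_D = x_D, y_C = y_C, y_D = y_D,
       y_top = y_top, tanb = tanb, x_al = x_al, x_pl = x_pl,
       mal_half_x = mal_half_x, fib_half_x = fib_half_x,
       z_in = z_in, z_out = z_out, z_tip_m = z_tip_m, z_tip_f = z_tip_f,
       y_tt = y_tt, y_ft = y_ft,
       y_bot = y_c - 0.9 * s$tar, roof_drop = 0.15,
       arc_step = 1.5 * d2r)
}

# ---- polygon helpers -------------------------------------------------------

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ensure_ccw <- function(poly) {
  if (polygon_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  else poly
}

point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cond <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cond)
    j <- i
  }
  inside
}

# ear-clipping triangulation of a simple CCW polygon; returns index triples
ear_clip <- function(poly) {
  n <- nrow(poly)
  idx <- seq_len(n)
  tris <- matrix(0L, 0, 3)
  guard <- 0
  while (length(idx) > 3) {
    guard <- guard + 1
    if (guard > 10 * n) stop("polygon triangulation failed", call. = FALSE)
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      ip <- idx[if (k == 1) m else k - 1]
      ic <- idx[k]
      inx <- idx[if (k == m) 1 else k + 1]
      ax <- poly[ip, 1]; ay <- poly[ip, 2]
      bx <- poly[ic, 1]; by <- poly[ic, 2]
      cx <- poly[inx, 1]; cy <- poly[inx, 2]
      cross <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
      if (cross <= 1e-12) next  # reflex or degenerate
      others <- setdiff(idx, c(ip, ic, inx))
      if (length(others)) {
        px <- poly[others, 1]; py <- poly[others, 2]
        d1 <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
        d2 <- (cx - bx) * (py - by) - (cy - by) * (px - bx)
        d3 <- (ax - cx) * (py - cy) - (ay - cy) * (px - cx)
        if (any(d1 > -1e-12 & d2 > -1e-12 & d3 > -1e-12)) next
      }
      tris <- rbind(tris, c(ip, ic, inx))
      idx <- idx[-k]
      clipped <- TRUE
      break
    }
    if (!clipped) stop("polygon triangulation failed (no ear found)",
                       call. = FALSE)
  }
  rbind(tris, idx)
}

# Extrude a stack of compatible rings (same vertex count) along z.
# rings: list of n x 2 polygons (CCW); z_stations: increasing z values.
extrude_rings <- function(rings, z_stations, label = "bone") {
  k <- length(z_stations)
  n <- nrow(rings[[1]])
  verts <- do.call(rbind, Map(function(r, z) cbind(r, z), rings, z_stations))
  faces <- matrix(0L, 0, 3)
  for (s in seq_len(k - 1)) {
    o0 <- (s - 1) * n; o1 <- s * n
    i <- seq_len(n); ii <- c(seq_len(n)[-1], 1L)
    faces <- rbind(faces,
                   cbind(o0 + i, o0 + ii, o1 + ii),
                   cbind(o0 + i, o1 + ii, o1 + i))
  }
  tri_bot <- ear_clip(rings[[1]])
  tri_top <- ear_clip(rings[[k]])
  faces <- rbind(faces,
                 tri_bot[, c(1, 3, 2), drop = FALSE],        # -z cap
                 tri_top[, c(1, 2, 3), drop = FALSE] + (k - 1) * n)  # +z cap
  surface_mesh(verts, faces, label = label)
}

# Vertical column (box) with a pyramidal distal tip.
column_with_tip <- function(x_range, z_range, y_top, y_base, tip, label) {
  xr <- sort(x_range); zr <- sort(z_range)
  vt <- rbind(c(xr[1], y_top, zr[1]), c(xr[2], y_top, zr[1]),
              c(xr[2], y_top, zr[2]), c(xr[1], y_top, zr[2]))
  vb <- rbind(c(xr[1], y_base, zr[1]), c(xr[2], y_base, zr[1]),
              c(xr[2], y_base, zr[2]), c(xr[1], y_base, zr[2]))
  verts <- rbind(vt, vb, tip)
  ap <- 9L
  faces <- rbind(
    c(1, 2, 3), c(1, 3, 4),                 # top cap (+y): wound for outward
    c(5, 7, 6), c(5, 8, 7),                 # placeholder; sides replace below
    c(1, 5, 6), c(1, 6, 2),                 # z = zr[1] side
    c(2, 6, 7), c(2, 7, 3),                 # x = xr[2] side
    c(3, 7, 8), c(3, 8, 4),                 # z = zr[2] side
    c(4, 8, 5), c(4, 5, 1),                 # x = xr[1] side
    c(5, ap, 6), c(6, ap, 7), c(7, ap, 8), c(8, ap, 5))  # pyramid
  faces <- faces[-(3:4), , drop = FALSE]    # no bottom cap: pyramid closes it
  m <- surface_mesh(verts, faces, label = label)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# ---- cross-sections --------------------------------------------------------

tibia_cross_section <- function(g) {
  n1 <- max(2, ceiling(abs(g$a1) / g$arc_step) + 1)
  n2 <- max(2, ceiling(abs(g$a2) / g$arc_step) + 1)
  a_st <- c(seq(g$a1, 0, length.out = n1),
            seq(0, g$a2, length.out = n2)[-1])
  arc <- cbind(g$spec$tisr * sin(a_st), g$y_cm + g$spec$tisr * cos(a_st))
  if (g$y_D < g$yb - 1e-9) {
    post <- rbind(c(g$x_D + (g$yb - g$y_D) * g$tanb, g$yb),
                  c(g$x_D, g$y_D))
  } else {
    post <- rbind(c(g$x_D + (g$y_D - g$yb) * g$tanb, g$yb),
                  c(g$x_D, g$y_D))
  }
  poly <- rbind(arc,
                post,
                c(g$x_D + (g$y_top - g$y_D) * g$tanb, g$y_top),
                c(g$x_C - (g$y_top - g$y_C) * g$tanb, g$y_top),
                c(g$x_C, g$y_C),
                c(g$x_al, g$ya))
  ensure_ccw(poly)
}

talus_cross_section <- function(g, r) {
  phi <- g$phi_ta
  k <- max(1, ceiling(phi / g$arc_step))
  a_st <- seq(phi, -phi, length.out = 2 * k + 1)
  arc <- cbind(r * sin(a_st), g$y_c + r * cos(a_st))
  w <- g$spec$tar * sin(phi)  # constant body half-width (central radius)
  poly <- rbind(arc,
                c(-w, g$y_bot),
                c(w, g$y_bot))
  ensure_ccw(poly)
}

tibia_z_stations <- function(g) {
  half <- g$spec$tiw / 2
  n <- max(2L, ceiling(half / 2))
  pos <- seq(0, half, length.out = n + 1)
  c(-rev(pos), pos[-1])
}

# ---- phantom assembly ------------------------------------------------------

#' Generate a synthetic ankle phantom
#'
#' Builds analytic triangle meshes of the distal tibia (with medial
#' malleolus), fibula and talus, the anatomical frame (origin at the talus
#' area centroid), the ground-truth landmark set and the ground-truth
#' morphometric profile, and (optionally) a rasterised attenuation volume.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer stored with the phantom for provenance (the
#'   construction itself is deterministic).
#' @param raster If `TRUE`, rasterise the attenuation volume at
#'   `spec$voxel_spacing`.
#' @return An object of class `ankle_phantom`: a list with `meshes` (tibia,
#'   fibula, talus), `frame`, `truth_landmarks`, `truth_profile`, `volume`
#'   (or NULL), and the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 0L, raster = TRUE) {
  validate_phantom_spec(spec)
  g <- phantom_geometry_core(spec)

  # --- talus: three z-bands (lateral crest, central dome, medial crest)
  b <- g$b; rd <- g$roof_drop
  band <- function(radii, zs) {
    rings <- lapply(radii, function(r) talus_cross_section(g, r))
    extrude_rings(rings, zs, label = "talus")
  }
  talus <- merge_meshes(
    band(c(g$r_l - rd, g$r_l, g$r_l - rd), c(-1.5 * b, -b, -0.5 * b)),
    band(c(g$r_c, g$r_c, g$r_c), c(-0.5 * b, 0, 0.5 * b)),
    band(c(g$r_m - rd, g$r_m, g$r_m - rd), c(0.5 * b, b, 1.5 * b)),
    label = "talus")

  # --- tibia block + medial malleolus
  zs <- tibia_z_stations(g)
  tib_poly <- tibia_cross_section(g)
  block <- extrude_rings(rep(list(tib_poly), length(zs)), zs, label = "tibia")
  mal <- column_with_tip(c(g$cx0 - g$mal_half_x, g$cx0 + g$mal_half_x),
                         c(g$z_in, g$z_out), g$y_top, g$ya,
                         c(g$cx0, g$y_tt, g$z_tip_m), "tibia")
  tibia <- merge_meshes(block, mal, label = "tibia")

  # --- fibula (lateral malleolus column)
  fibula <- column_with_tip(c(g$cx0 - g$fib_half_x, g$cx0 + g$fib_half_x),
                            c(-g$z_out, -g$z_in), g$y_top, g$ya,
                            c(g$cx0, g$y_ft, g$z_tip_f), "fibula")

  # --- recentre on the talus area centroid (anatomical frame origin)
  shift <- -mesh_centroid(talus)
  talus <- translate_mesh(talus, shift)
  tibia <- translate_mesh(tibia, shift)
  fibula <- translate_mesh(fibula, shift)
  g$shift <- shift
  frame <- anatomical_frame(origin = c(0, 0, 0))

  truth <- phantom_truth_landmarks(g)
  truth[, c("x", "y", "z")] <-
    sweep(as.matrix(truth[, c("x", "y", "z")]), 2, shift, `+`)
  profile <- phantom_truth_profile(g)

  ph <- structure(list(meshes = list(tibia = tibia, fibula = fibula,
                                     talus = talus),
                       frame = frame, truth_landmarks = truth,
                       truth_profile = profile, volume = NULL,
                       spec = spec, seed = seed, geom = g),
                  class = "ankle_phantom")
  if (raster) ph$volume <- rasterize_phantom(ph)
  ph
}

#' @export
print.ankle_phantom <- function(x, ...) {
  cat("<ankle_phantom>\n")
  for (m in x$meshes) print(m)
  if (!is.null(x$volume)) print(x$volume)
  invisible(x)
}

# ground-truth landmarks consistent with the meshing stations and the
# deterministic lexicographic tie-break used by the extractors
phantom_truth_landmarks <- function(g) {
  s <- g$spec; b <- g$b
  zs <- tibia_z_stations(g)
  slab_half <- 0.05 * s$tiw
  zAB <- min(zs[abs(zs) <= slab_half + 1e-9])
  phi <- g$phi_ta
  Fx <- function(r) r * sin(phi); Fy <- function(r) g$y_c + r * cos(phi)
  landmark_set(
    name = c("A", "B", "V", "C", "D",
             "TiWa_m", "TiWa_l", "TiWp_m", "TiWp_l",
             "FibLat", "TibMed", "FibDist", "TibDist",
             "F_c", "G_c", "H_c", "F_m", "G_m", "H_m",
             "F_l", "G_l", "H_l", "TaVert_m", "TaVert_l"),
    x = c(g$xa, g$xb, 0, g$x_C, g$x_D,
          g$xa, g$xa, g$xb, g$xb,
          g$cx0 - g$fib_half_x, g$cx0 - g$mal_half_x, g$cx0, g$cx0,
          Fx(g$r_c), -Fx(g$r_c), 0, Fx(g$r_m), -Fx(g$r_m), 0,
          Fx(g$r_l), -Fx(g$r_l), 0, 0, 0),
    y = c(g$ya, g$yb, g$yV, g$y_C, g$y_D,
          g$ya, g$ya, g$yb, g$yb,
          g$ya, g$ya, g$y_ft, g$y_tt,
          Fy(g$r_c), Fy(g$r_c), g$y_c + g$r_c,
          Fy(g$r_m), Fy(g$r_m), g$y_c + g$r_m,
          Fy(g$r_l), Fy(g$r_l), g$y_c + g$r_l,
          g$y_c + g$r_m, g$y_c + g$r_l),
    z = c(zAB, zAB, zAB, -s$tiw / 2, -s$tiw / 2,
          s$tiw / 2, -s$tiw / 2, s$tiw / 2, -s$tiw / 2,
          -s$malw / 2, s$malw / 2, g$z_tip_f, g$z_tip_m,
          0, 0, 0, b, b, b, -b, -b, -b, b, -b))
}

phantom_truth_profile <- function(g) {
  s <- g$spec
  taw_seg <- sqrt(s$taw^2 + g$dy^2)
  # inclination angles (and the A-B gap) are reported as magnitudes, so a
  # negative tilt draw has a positive ground truth
  morphometric_profile(
    values = c(TiAL = s$tial, TiSR = s$tisr,
               APG = s$tial * abs(sin(g$delta)), APA = abs(s$apa),
               MTiTh = s$mtith, MDA = s$mda, MDV = s$mdv,
               TiW = s$tiw, MalW = s$malw, MLATi = abs(s$mlati),
               TaAL = s$taal, TaR = s$tar, TaW = taw_seg,
               MLATa = abs(s$mlata)),
    provenance = "3D-truth")
}

#' Morphometric profile container
#'
#' A tibble with one row per parameter: `parameter`, `value`, `units`
#' (mm or deg) and `provenance` (`"3D"`, `"2D-ML"`, `"2D-AP"` or
#' `"3D-truth"`).
#'
#' @param values Named numeric vector of parameter values.
#' @param provenance Provenance tag.
#' @return A tibble.
#' @export
morphometric_profile <- function(values, provenance = "3D") {
  units <- ifelse(names(values) %in% c("APA", "MLATi", "MLATa"), "deg", "mm")
  tibble::tibble(parameter = names(values), value = as.numeric(values),
                 units = units, provenance = provenance)
}

# ---- rasterisation ---------------------------------------------------------

#' Rasterise a phantom into an attenuation volume
#'
#' Voxels inside any bone solid receive the bone attenuation; an optional
#' soft-tissue shell (an inflated bounding slab) receives `soft_level`.
#'
#' @param phantom An [generate_phantom()] result.
#' @param spacing Voxel spacing (mm), default taken from the spec.
#' @param margin Empty margin around the bones, mm.
#' @return A [voxel_volume()].
#' @export
rasterize_phantom <- function(phantom, spacing = NULL, margin = 4) {
  g <- phantom$geom; s <- g$spec
  if (is.null(spacing)) spacing <- s$voxel_spacing
  spacing <- rep(as.numeric(spacing), length.out = 3)
  allv <- do.call(rbind, lapply(phantom$meshes, `[[`, "vertices"))
  lo <- apply(allv, 2, min) - margin
  hi <- apply(allv, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  # voxel centres in the *construction* coordinates (undo the centring shift)
  xs <- lo[1] + spacing[1] * (seq_len(dims[1]) - 1) - g$shift[1]
  ys <- lo[2] + spacing[2] * (seq_len(dims[2]) - 1) - g$shift[2]
  zs <- lo[3] + spacing[3] * (seq_len(dims[3]) - 1) - g$shift[3]
  vals <- array(0, dim = dims)
  if (s$soft_level > 0) {
    sm <- s$soft_margin
    ix <- xs >= min(allv[, 1] - g$shift[1]) - sm & xs <= max(allv[, 1] - g$shift[1]) + sm
    iy <- ys >= min(allv[, 2] - g$shift[2]) - sm & ys <= max(allv[, 2] - g$shift[2]) + sm
    iz <- zs >= min(allv[, 3] - g$shift[3]) - sm & zs <= max(allv[, 3] - g$shift[3]) + sm
    vals[ix, iy, iz] <- s$soft_level
  }
  grid2 <- expand.grid(x = xs, y = ys)
  fill_block <- function(poly, z_lo, z_hi) {
    mask <- matrix(point_in_polygon(grid2$x, grid2$y, poly), dims[1], dims[2])
    kz <- which(zs >= z_lo & zs <= z_hi)
    for (k in kz) {
      sl <- vals[, , k]
      sl[mask] <- s$attenuation_bone
      vals[, , k] <<- sl
    }
  }
  # tibia block and talus bands
  fill_block(tibia_cross_section(g), -s$tiw / 2, s$tiw / 2)
  b <- g$b
  fill_block(talus_cross_section(g, g$r_l), -1.5 * b, -0.5 * b)
  fill_block(talus_cross_section(g, g$r_c), -0.5 * b, 0.5 * b)
  fill_block(talus_cross_section(g, g$r_m), 0.5 * b, 1.5 * b)
  # malleolar columns with pyramidal tips
  fill_column <- function(xc, half_x, z_lo, z_hi, y_base, tip_y, tip_z) {
    ixc <- which(abs(xs - xc) <= half_x)
    izc <- which(zs >= z_lo & zs <= z_hi)
    iyc <- which(ys >= y_base & ys <= g$y_top)
    vals[ixc, iyc, izc] <<- s$attenuation_bone
    # pyramid: shrink both extents linearly toward the tip
    iyp <- which(ys >= tip_y & ys < y_base)
    half_z <- (z_hi - z_lo) / 2; zc <- (z_hi + z_lo) / 2
    for (k in iyp) {
      f <- (ys[k] - tip_y) / (y_base - tip_y)
      ixp <- which(abs(xs - xc) <= half_x * f)
      izp <- which(abs(zs - zc) <= half_z * f)
      vals[ixp, k, izp] <<- s$attenuation_bone
    }
  }
  fill_column(g$cx0, g$mal_half_x, g$z_in, g$z_out, g$ya, g$y_tt, g$z_tip_m)
  fill_column(g$cx0, g$fib_half_x, -g$z_out, -g$z_in, g$ya, g$y_ft, g$z_tip_f)
  voxel_volume(vals, spacing, lo)
}

# analytic solid volume of the phantom (same idealisation as the raster)
phantom_solid_volume <- function(phantom) {
  g <- phantom$geom; s <- g$spec
  area <- function(poly) abs(polygon_area(poly))
  b <- g$b
  tib <- area(tibia_cross_section(g)) * s$tiw
  tal <- (area(talus_cross_section(g, g$r_l)) +
            area(talus_cross_section(g, g$r_c)) +
            area(talus_cross_section(g, g$r_m))) * b
  col_vol <- function(half_x, z_lo, z_hi, y_base, tip_y) {
    base <- 2 * half_x * (z_hi - z_lo)
    base * (g$y_top - y_base) + base * (y_base - tip_y) / 3
  }
  mal <- col_vol(g$mal_half_x, g$z_in, g$z_out, g$ya, g$y_tt)
  fib <- col_vol(g$fib_half_x, -g$z_out, -g$z_in, g$ya, g$y_ft)
  tib + tal + mal + fib
}
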