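#' Extract tibial/fibular landmarks from a mesh in the anatomical frame
#'
#' The mortise (distal concave articular surface) is identified among
#' downward-facing vertices of a central sagittal slab and refined by a
#' trimmed circle fit in the sagittal plane; its anterior/posterior extremes
#' give A and B, its most proximal point V. C and D are the global
#' anterior/posterior extremes of the tibial profile, the malleolar extrema
#' come from the per-bone mediolateral extremes, and the most distal points
#' per bone feed the frontal malleolar tilt.
#'
#' All extremal choices break exact ties lexicographically on ascending
#' (x, y, z), so the extraction is deterministic.
#'
#' @param tibia_mesh,fibula_mesh [surface_mesh()] objects expressed in the
#'   anatomical frame (the fibula may be omitted if merged into the tibia
#'   mesh under a different label; here the two meshes are kept separate).
#' @param frame An [anatomical_frame()].
#' @param config Classification settings: `normal_y_max` (upper bound on the
#'   vertex normal Y-component for "downward-facing"), `slab_frac` (central
#'   sagittal slab width as a fraction of the mortise width), `fit_tol`
#'   (inlier distance for the trimmed mortise circle fit, mm).
#' @return A list: `landmarks` (tibble), `mortise_points` (slab inliers, for
#'   the radius fit), `mortise_fit` (circle fit), `mortise_all` (full-width
#'   mortise vertices).
#' @export
extract_tibial_landmarks <- function(tibia_mesh, fibula_mesh, frame,
                                     config = morphometry_config()) {
  pts <- to_frame(tibia_mesh$vertices, frame)
  fpts <- to_frame(fibula_mesh$vertices, frame)
  # downward-facing but not exactly horizontal: the flat distal ledges are
  # not articular surface, and for shallow mortise arcs their corner points
  # are nearly cotangent to the arc circle, so they must never enter the fit
  down <- vertices_with_face_normal(
    tibia_mesh, frame,
    function(ny) ny < config$normal_y_max & ny > -0.99999)
  if (!any(down)) stop("no downward-facing tibial vertices found", call. = FALSE)
  # pass 1: rough mortise cylinder from a fixed 2 mm sagittal window
  rough <- which(down & abs(pts[, 3] - stats::median(pts[down, 3])) <= 2)
  if (length(rough) < 5) stop("no vertices classified as mortise", call. = FALSE)
  fit0 <- fit_circle_trimmed(pts[rough, 1:2, drop = FALSE],
                             tol = config$fit_tol)
  d_all <- sqrt((pts[, 1] - fit0$center[1])^2 + (pts[, 2] - fit0$center[2])^2)
  on_cyl <- down & abs(d_all - fit0$radius) <= config$fit_tol
  mortise_all <- pts[on_cyl, , drop = FALSE]
  if (nrow(mortise_all) < 5)
    stop("no vertices classified as mortise", call. = FALSE)
  # pass 2: central sagittal slab sized from the fitted mortise width
  zr <- range(mortise_all[, 3])
  slab_half <- config$slab_frac / 2 * diff(zr)
  zmid <- mean(zr)
  cand <- which(on_cyl & abs(pts[, 3] - zmid) <= slab_half + 1e-9)
  if (length(cand) < 5) stop("no vertices classified as mortise", call. = FALSE)
  fit <- fit_circle_trimmed(pts[cand, 1:2, drop = FALSE], tol = config$fit_tol)
  mortise_slab <- pts[cand[fit$inliers], , drop = FALSE]
  A <- extremal_point(mortise_slab, 1, TRUE)
  B <- extremal_point(mortise_slab, 1, FALSE)
  V <- extremal_point(mortise_slab, 2, TRUE)
  edge_tol <- 1e-6 + 1e-6 * abs(A[1])
  ant_edge <- mortise_all[abs(mortise_all[, 1] - A[1]) <= edge_tol, , drop = FALSE]
  post_edge <- mortise_all[abs(mortise_all[, 1] - B[1]) <= edge_tol, , drop = FALSE]
  TiWa_m <- extremal_point(ant_edge, 3, TRUE)
  TiWa_l <- extremal_point(ant_edge, 3, FALSE)
  TiWp_m <- extremal_point(post_edge, 3, TRUE)
  TiWp_l <- extremal_point(post_edge, 3, FALSE)
  C <- extremal_point(pts, 1, TRUE)
  D <- extremal_point(pts, 1, FALSE)
  TibMed <- extremal_point(pts, 3, TRUE)
  FibLat <- extremal_point(fpts, 3, FALSE)
  TibDist <- extremal_point(pts, 2, FALSE)
  FibDist <- extremal_point(fpts, 2, FALSE)
  coords <- rbind(A, B, V, C, D, TiWa_m, TiWa_l, TiWp_m, TiWp_l,
                  FibLat, TibMed, FibDist, TibDist)
  lm <- landmark_set(c("A", "B", "V", "C", "D", "TiWa_m", "TiWa_l",
                       "TiWp_m", "TiWp_l", "FibLat", "TibMed",
                       "FibDist", "TibDist"),
                     coords[, 1], coords[, 2], coords[, 3])
  list(landmarks = lm, mortise_points = mortise_slab, mortise_fit = fit,
       mortise_all = mortise_all)
}

#' Extract talar landmarks from a mesh in the anatomical frame
#'
#' The trochlea is the set of upward-facing dome vertices; its mediolateral
#' extent is cut into medial/central/lateral thirds, and each slab yields its
#' most anterior (F), most posterior (G) and most proximal (H) points. The
#' crest slabs' proximal points double as the trochlea vertex line for the
#' frontal tilt.
#'
#' @inheritParams extract_tibial_landmarks
#' @param talus_mesh [surface_mesh()] of the talus.
#' @return A list: `landmarks` (tibble), `trochlea_points` (list of per-slab
#'   dome vertices, names `m`, `c`, `l`).
#' @export
extract_talar_landmarks <- function(talus_mesh, frame,
                                    config = morphometry_config()) {
  pts <- to_frame(talus_mesh$vertices, frame)
  up <- vertices_with_face_normal(talus_mesh, frame,
                                  function(ny) ny > config$normal_y_min_up)
  if (!any(up)) stop("no upward-facing talar dome vertices found", call. = FALSE)
  dome <- pts[up, , drop = FALSE]
  zr <- range(dome[, 3])
  third <- diff(zr) / 3
  lo_c <- zr[1] + third; hi_c <- zr[1] + 2 * third
  tol <- 1e-6 * max(1, diff(zr))
  slabs <- list(
    l = dome[dome[, 3] <= lo_c + tol, , drop = FALSE],
    c = dome[dome[, 3] > lo_c + tol & dome[, 3] < hi_c - tol, , drop = FALSE],
    m = dome[dome[, 3] >= hi_c - tol, , drop = FALSE])
  for (nm in names(slabs))
    if (nrow(slabs[[nm]]) < 3)
      stop("degenerate trochlea: no dome vertices in the ", nm, " slab",
           call. = FALSE)
  pick <- function(slab) rbind(extremal_point(slab, 1, TRUE),
                               extremal_point(slab, 1, FALSE),
                               extremal_point(slab, 2, TRUE))
  P <- rbind(pick(slabs$c), pick(slabs$m), pick(slabs$l))
  TaVert_m <- extremal_point(slabs$m, 2, TRUE)
  TaVert_l <- extremal_point(slabs$l, 2, TRUE)
  coords <- rbind(P, TaVert_m, TaVert_l)
  lm <- landmark_set(c("F_c", "G_c", "H_c", "F_m", "G_m", "H_m",
                       "F_l", "G_l", "H_l", "TaVert_m", "TaVert_l"),
                     coords[, 1], coords[, 2], coords[, 3])
  list(landmarks = lm, trochlea_points = slabs)
}

#' Tuning constants for the automatic landmark extraction
#'
#' @param normal_y_max Vertices with normal Y-component below this are
#'   "downward-facing" (mortise candidates).
#' @param normal_y_min_up Vertices with normal Y-component above this are
#'   "upward-facing" (trochlea candidates).
#' @param slab_frac Width of the central sagittal slab used for the mortise
#'   arc, as a fraction of the mortise mediolateral extent.
#' @param fit_tol Inlier tolerance of the trimmed circle fits, mm.
#' @param variant Which trochlea slab feeds the reported scalar TaAL/TaR/TaW
#'   (`"c"` central, `"m"` medial or `"l"` lateral).
#' @return A named list of settings.
#' @export
morphometry_config <- function(normal_y_max = -0.2, normal_y_min_up = 0.3,
                               slab_frac = 0.1, fit_tol = 0.5,
                               variant = "c") {
  list(normal_y_max = normal_y_max, normal_y_min_up = normal_y_min_up,
       slab_frac = slab_frac, fit_tol = fit_tol,
       variant = match.arg(variant, c("c", "m", "l")))
}

to_frame <- function(pts, frame) {
  sweep(pts, 2, frame$origin) %*% frame_basis(frame)
}

angle_to_axis <- function(d_along, d_long) {
  atan2(abs(d_long), abs(d_along)) * 180 / pi
}

#' Compute the fourteen morphological parameters from 3D landmarks
#'
#' Applies the geometric definitions in the anatomical frame: chord lengths,
#' axis-component gaps, inclination angles against the anatomical axes, and
#' circle-fit radii / arc lengths for the articular surfaces.
#'
#' @param landmarks Landmark tibble containing all required names.
#' @param mortise_points N x 3 matrix of mortise-arc points (central slab),
#'   for the sagittal radius fit.
#' @param trochlea_points Named list (`m`, `c`, `l`) of per-slab dome points,
#'   for the talar radius fits.
#' @param config [morphometry_config()].
#' @return A [morphometric_profile()] tibble (provenance `"3D"`), with the
#'   landmark snapshot in attribute `"landmarks"` and fit residuals in
#'   attribute `"fits"`.
#' @export
measure_3d <- function(landmarks, mortise_points, trochlea_points,
                       config = morphometry_config()) {
  need <- c("A", "B", "V", "C", "D", "TiWa_m", "TiWa_l", "TiWp_m", "TiWp_l",
            "FibLat", "TibMed", "FibDist", "TibDist",
            "F_c", "G_c", "H_c", "F_m", "G_m", "H_m", "F_l", "G_l", "H_l",
            "TaVert_m", "TaVert_l")
  missing <- setdiff(need, landmarks$name)
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- function(nm) lm_point(landmarks, nm)
  A <- p("A"); B <- p("B"); V <- p("V"); C <- p("C"); D <- p("D")
  mort_fit <- fit_circle_sagittal(mortise_points[, 1:2, drop = FALSE])
  va <- config$variant
  ta_fit <- lapply(trochlea_points, function(sl)
    fit_circle_sagittal(sl[, 1:2, drop = FALSE]))
  arc_len <- function(v) arc_length_three_points(
    p(paste0("F_", v))[1:2], p(paste0("H_", v))[1:2], p(paste0("G_", v))[1:2])
  taw_seg <- function(pair) {
    w <- sqrt(sum((p(paste0(pair, "_m")) - p(paste0(pair, "_l")))^2))
    w
  }
  tiw_a <- sqrt(sum((p("TiWa_m") - p("TiWa_l"))^2))
  tiw_p <- sqrt(sum((p("TiWp_m") - p("TiWp_l"))^2))
  tilt <- p("TibDist") - p("FibDist")
  ta_tilt <- p("TaVert_m") - p("TaVert_l")
  values <- c(
    TiAL = sqrt(sum((A - B)^2)),
    TiSR = mort_fit$radius,
    APG = abs(A[2] - B[2]),
    APA = angle_to_axis(A[1] - B[1], A[2] - B[2]),
    MTiTh = abs(C[1] - D[1]),
    MDA = abs(A[2] - C[2]),
    MDV = abs(V[2] - D[2]),
    TiW = (tiw_a + tiw_p) / 2,
    MalW = abs(p("FibLat")[3] - p("TibMed")[3]),
    MLATi = angle_to_axis(tilt[3], tilt[2]),
    TaAL = arc_len(va),
    TaR = ta_fit[[va]]$radius,
    TaW = taw_seg("H"),
    MLATa = angle_to_axis(ta_tilt[3], ta_tilt[2]))
  prof <- morphometric_profile(values, provenance = "3D")
  attr(prof, "landmarks") <- landmarks
  attr(prof, "fits") <- list(mortise = mort_fit, trochlea = ta_fit)
  prof
}

#' Full 3D morphometry of a phantom (or measured specimen meshes)
#'
#' Convenience wrapper: extracts tibial and talar landmarks and measures all
#' fourteen parameters.
#'
#' @param phantom An `ankle_phantom` (or a list with `meshes` and `frame`).
#' @param config [morphometry_config()].
#' @return A [morphometric_profile()] tibble with attributes as in
#'   [measure_3d()].
#' @export
measure_phantom_3d <- function(phantom, config = morphometry_config()) {
  tib <- extract_tibial_landmarks(phantom$meshes$tibia, phantom$meshes$fibula,
                                  phantom$frame, config)
  tal <- extract_talar_landmarks(phantom$meshes$talus, phantom$frame, config)
  lm <- dplyr::bind_rows(tib$landmarks, tal$landmarks)
  measure_3d(lm, tib$mortise_points, tal$trochlea_points, config)
}
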