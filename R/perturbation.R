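#' Rotation pivot of a positioning perturbation
#'
#' Positioning errors arise while the limb rests on the detector, so by
#' default study perturbations rotate the specimen about the anatomical axes
#' through the detector contact point: the bone point closest to the image
#' plane (the lateral malleolus for the M/L view, the posterior heel
#' stand-in for the A/P view), projected onto the plane. `pivot = "origin"`
#' instead rotates about the anatomical frame origin (the talus centre).
#'
#' @param phantom An `ankle_phantom`.
#' @param geom A [projection_geometry()].
#' @param pivot `"contact"` or `"origin"`.
#' @return An [anatomical_frame()] whose origin is the rotation centre.
#' @export
pose_pivot_frame <- function(phantom, geom, pivot = c("contact", "origin")) {
  pivot <- match.arg(pivot)
  frame <- phantom$frame
  if (pivot == "origin") return(frame)
  allv <- do.call(rbind, lapply(phantom$meshes, `[[`, "vertices"))
  d <- projection_depth(allv, geom)
  cand <- allv[d <= min(d) + 1e-6, , drop = FALSE]
  # the limb pivots on its support: take the most distal contact vertex
  fc <- to_frame(cand, phantom$frame)
  p <- cand[order(fc[, 2], fc[, 1], fc[, 3])[1], ]
  contact <- p - projection_depth(p, geom) * geom$normal
  anatomical_frame(origin = contact, axis_x = frame$axis_x,
                   axis_y = frame$axis_y, axis_z = frame$axis_z)
}

#' Measure one specimen's 2D profile for a given pose and view
#'
#' Projects the specimen's 3D landmarks under the pose (rotating about
#' `pivot_frame`, by default the detector contact point), labels them on the
#' DRR (rendered when `render = TRUE`) and measures the view's parameters.
#'
#' @param phantom An `ankle_phantom` (volume required when `render = TRUE`).
#' @param pose A [rigid_pose()].
#' @param geom A [projection_geometry()] for the view.
#' @param landmarks3d 3D landmark tibble (defaults to the automatically
#'   extracted landmarks).
#' @param config [morphometry_config()].
#' @param render Render the DRR and use its contours for the radius fits.
#' @param capture_radius Snap radius for [label_landmarks_2d()], mm.
#' @param step Ray step for the DRR, mm.
#' @param pivot_frame Rotation-centre frame (see [pose_pivot_frame()]);
#'   defaults to the detector contact point of `geom`.
#' @return A [morphometric_profile()] tibble for the view, or rows with
#'   `NA` values if a landmark leaves the imaging frustum.
#' @export
measure_pose_2d <- function(phantom, pose, geom, landmarks3d = NULL,
                            config = morphometry_config(), render = TRUE,
                            capture_radius = 0, step = NULL,
                            pivot_frame = NULL) {
  if (is.null(landmarks3d)) landmarks3d <- phantom$truth_landmarks
  if (is.null(pivot_frame)) pivot_frame <- pose_pivot_frame(phantom, geom)
  proj <- try(project_landmarks(landmarks3d, pose, geom, pivot_frame),
              silent = TRUE)
  if (inherits(proj, "try-error")) {
    prof <- measure_view_2d_names(geom$view)
    return(tibble::tibble(parameter = prof, value = NA_real_,
                          units = NA_character_,
                          provenance = paste0("2D-", geom$view)))
  }
  contours <- NULL
  if (render) {
    if (is.null(phantom$volume))
      stop("phantom has no rasterised volume; call rasterize_phantom() first",
           call. = FALSE)
    img <- cast_drr(phantom$volume, pose, geom, pivot_frame, step = step)
    contours <- try(detect_bone_contours(img), silent = TRUE)
    if (inherits(contours, "try-error")) contours <- NULL
  }
  lm2d <- label_landmarks_2d(contours, proj, capture_radius)
  measure_view_2d(lm2d, geom$view, contours, config)
}

measure_view_2d_names <- function(view) {
  if (toupper(view) == "ML")
    c("TiAL", "TiSR", "APG", "APA", "MTiTh", "MDA", "MDV", "TaAL", "TaR")
  else c("TiW", "MalW", "MLATi", "TaW", "MLATa")
}

#' Systematic pose-sensitivity sweep
#'
#' From the standard pose, rotates the specimen by up to `max_angle` degrees
#' at 1-degree intervals in both directions about each anatomical axis
#' (37 distinct poses per view, the standard pose shared across axes),
#' measures the view's 2D parameters at every pose, and reports the percent
#' error relative to the standard-pose 2D value.
#'
#' @inheritParams measure_pose_2d
#' @param view `"ML"` or `"AP"`.
#' @param max_angle Sweep amplitude in degrees.
#' @param geom Optional [projection_geometry()]; built from the phantom's
#'   standard pose if omitted.
#' @param ... Passed to [make_standard_geometry()] when `geom` is NULL.
#' @return A tibble of class `sensitivity_table`: `parameter`, `axis`
#'   (`"X"`, `"Y"`, `"Z"`), `angle` (deg), `value`, `pct_error`; attribute
#'   `n_poses` records the number of distinct poses rendered.
#' @export
sensitivity_sweep <- function(phantom, view, max_angle = 6, geom = NULL,
                              landmarks3d = NULL,
                              config = morphometry_config(), render = TRUE,
                              capture_radius = 0, step = NULL,
                              pivot = c("contact", "origin"), ...) {
  if (is.null(landmarks3d)) landmarks3d <- phantom$truth_landmarks
  if (is.null(geom))
    geom <- make_standard_geometry(view, phantom$meshes, phantom$frame,
                                   landmarks3d, ...)
  pf <- pose_pivot_frame(phantom, geom, match.arg(pivot))
  angles <- seq(-max_angle, max_angle, by = 1)
  base <- measure_pose_2d(phantom, rigid_pose(), geom, landmarks3d,
                          config, render, capture_radius, step, pf)
  n_poses <- 1L
  rows <- list()
  for (axis in c("X", "Y", "Z")) {
    for (th in angles) {
      if (th == 0) {
        prof <- base
      } else {
        pose <- switch(axis,
                       X = rigid_pose(theta_x = th),
                       Y = rigid_pose(theta_y = th),
                       Z = rigid_pose(theta_z = th))
        prof <- measure_pose_2d(phantom, pose, geom, landmarks3d,
                                config, render, capture_radius, step, pf)
        n_poses <- n_poses + 1L
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = prof$parameter, axis = axis, angle = th,
        value = prof$value,
        pct_error = 100 * (prof$value - base$value) / base$value)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$pct_error[out$angle == 0] <- 0
  attr(out, "n_poses") <- n_poses
  attr(out, "view") <- toupper(view)
  class(out) <- c("sensitivity_table", class(out))
  out
}

#' Polynomial trend test of a sensitivity curve
#'
#' Fits `error = b1 * angle + b2 * angle^2` (zero intercept, since the error
#' is 0 at the standard pose by definition) and classifies the trend as
#' quadratic, linear or none by coefficient significance at alpha = 0.05.
#'
#' @param angles Perturbation angles, degrees (>= 5 distinct values).
#' @param errors Percent errors at those angles.
#' @param alpha Significance level.
#' @return A list: `class` (`"linear"`, `"quadratic"` or `"none"`),
#'   `b1`, `b2`, `p_linear`, `p_quadratic`.
#' @export
trend_test <- function(angles, errors, alpha = 0.05) {
  keep <- is.finite(angles) & is.finite(errors)
  angles <- angles[keep]; errors <- errors[keep]
  if (length(angles) < 5)
    stop("need at least 5 angle points for the trend test", call. = FALSE)
  if (all(abs(errors) < 1e-12))
    return(list(class = "none", b1 = 0, b2 = 0,
                p_linear = NA_real_, p_quadratic = NA_real_))
  fit <- stats::lm(errors ~ 0 + angles + I(angles^2))
  cf <- suppressWarnings(summary(fit))$coefficients
  getp <- function(term) if (term %in% rownames(cf)) cf[term, 4] else NA_real_
  getb <- function(term) if (term %in% rownames(cf)) cf[term, 1] else 0
  p1 <- getp("angles"); p2 <- getp("I(angles^2)")
  # a term only counts if it is significant AND its contribution over the
  # sweep rises above numerical noise (exact fits give ~0 residuals and
  # meaningless p-values on the vanishing term)
  scale <- max(abs(errors))
  rng <- max(abs(angles))
  lin_real <- abs(getb("angles")) * rng > 1e-6 * scale
  quad_real <- abs(getb("I(angles^2)")) * rng^2 > 1e-6 * scale
  sig <- function(p) !is.finite(p) || p < alpha
  cls <- if (quad_real && sig(p2)) "quadratic"
  else if (lin_real && sig(p1)) "linear"
  else "none"
  list(class = cls, b1 = getb("angles"), b2 = getb("I(angles^2)"),
       p_linear = p1, p_quadratic = p2)
}

#' Trend classification for every parameter/axis of a sensitivity table
#' @param table A `sensitivity_table` from [sensitivity_sweep()].
#' @return Tibble: `parameter`, `axis`, `trend`, `b1`, `b2`, p-values.
#' @export
sensitivity_trends <- function(table) {
  dplyr::group_by(table, .data$parameter, .data$axis) |>
    dplyr::summarise(res = list(trend_test(.data$angle, .data$pct_error)),
                     .groups = "drop") |>
    dplyr::mutate(trend = purrr::map_chr(.data$res, "class"),
                  b1 = purrr::map_dbl(.data$res, "b1"),
                  b2 = purrr::map_dbl(.data$res, "b2"),
                  p_linear = purrr::map_dbl(.data$res, "p_linear"),
                  p_quadratic = purrr::map_dbl(.data$res, "p_quadratic")) |>
    dplyr::select(-"res")
}

#' Draw a random pose set for the repeatability/correction experiments
#'
#' Each rotational component is drawn independently and uniformly in
#' `[-bound_deg, +bound_deg]`.
#'
#' @param bound_deg Amplitude bound, degrees.
#' @param n Number of poses (default 10).
#' @param seed RNG seed.
#' @return A list of [rigid_pose()] objects with attributes `bound`, `seed`.
#' @export
random_pose_set <- function(bound_deg, n = 10, seed = 1L) {
  stopifnot(bound_deg > 0, n >= 1)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  ang <- matrix(stats::runif(3 * n, -bound_deg, bound_deg), ncol = 3)
  poses <- lapply(seq_len(n), function(i)
    rigid_pose(ang[i, 1], ang[i, 2], ang[i, 3]))
  attr(poses, "bound") <- bound_deg
  attr(poses, "seed") <- seed
  poses
}

#' Repeatability experiment: measurement matrix over random poses
#'
#' Measures every specimen's 2D parameters at each pose of its random pose
#' set, for one view, producing the specimen-by-pose matrix per parameter
#' that feeds [icc_3k()].
#'
#' @param cohort List of phantoms (>= 2; volumes required when
#'   `render = TRUE`).
#' @param view `"ML"` or `"AP"`.
#' @param pose_sets A list (one element per specimen) of pose lists, e.g.
#'   from [random_pose_set()].
#' @param landmarks3d Optional list of per-specimen 3D landmark tibbles.
#' @inheritParams measure_pose_2d
#' @param ... Passed to [make_standard_geometry()].
#' @return A long tibble: `specimen`, `pose_id`, `parameter`, `value`
#'   (NA where a landmark left the frustum).
#' @export
repeatability_experiment <- function(cohort, view, pose_sets,
                                     landmarks3d = NULL,
                                     config = morphometry_config(),
                                     render = TRUE, capture_radius = 0,
                                     step = NULL, ...) {
  if (length(cohort) < 2)
    stop("repeatability needs at least 2 specimens", call. = FALSE)
  stopifnot(length(pose_sets) == length(cohort))
  rows <- list()
  for (i in seq_along(cohort)) {
    ph <- cohort[[i]]
    lm3 <- if (is.null(landmarks3d)) ph$truth_landmarks else landmarks3d[[i]]
    geom <- make_standard_geometry(view, ph$meshes, ph$frame, lm3, ...)
    for (j in seq_along(pose_sets[[i]])) {
      prof <- measure_pose_2d(ph, pose_sets[[i]][[j]], geom, lm3,
                              config, render, capture_radius, step)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        specimen = i, pose_id = j,
        parameter = prof$parameter, value = prof$value)
    }
  }
  dplyr::bind_rows(rows)
}

#' Wide specimen-by-pose matrix for one parameter
#' @param measurements Long tibble from [repeatability_experiment()].
#' @param parameter Parameter symbol.
#' @return Numeric matrix (specimens x poses).
#' @export
measurement_matrix <- function(measurements, parameter) {
  w <- measurements[measurements$parameter == parameter, ] |>
    tidyr::pivot_wider(names_from = "pose_id", values_from = "value")
  m <- as.matrix(w[, setdiff(names(w), c("specimen", "parameter"))])
  rownames(m) <- w$specimen
  m
}
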