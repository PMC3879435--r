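#' Detect bone contours on a DRR
#'
#' Gradient-magnitude edge map (central differences) thresholded at a
#' fraction of its maximum and linked into connected contours; coordinates
#' are returned in detector millimetres.
#'
#' @param img A `drr_image`.
#' @param threshold_frac Edge threshold as a fraction of the maximum gradient
#'   magnitude.
#' @return A tibble with columns `contour` (component id), `u`, `v` (mm) and
#'   `grad` (gradient magnitude per mm).
#' @export
detect_bone_contours <- function(img, threshold_frac = 0.2) {
  px <- img$pixels
  if (length(px) == 0 || max(px) <= 0)
    stop("no edges found: image is empty", call. = FALSE)
  ps <- img$pixel_spacing
  gu <- px * 0; gv <- px * 0
  nu <- nrow(px); nv <- ncol(px)
  gu[2:(nu - 1), ] <- (px[3:nu, ] - px[1:(nu - 2), ]) / (2 * ps)
  gv[, 2:(nv - 1)] <- (px[, 3:nv] - px[, 1:(nv - 2)]) / (2 * ps)
  g <- sqrt(gu^2 + gv^2)
  thr <- threshold_frac * max(g)
  if (thr <= 0) stop("no edges found: flat image", call. = FALSE)
  mask <- g > thr
  if (!any(mask)) stop("no edges found above threshold", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  idx <- which(mask, arr.ind = TRUE)
  ax <- drr_pixel_axes(img)
  tibble::tibble(contour = as.integer(labm[mask]),
                 u = ax$u[idx[, 1]], v = ax$v[idx[, 2]],
                 grad = g[mask]) |>
    dplyr::arrange(.data$contour, .data$u, .data$v)
}

#' Label 2D landmarks from projected 3D landmarks
#'
#' Each projected landmark is snapped to the nearest detected contour point
#' within a capture radius; with radius 0 (the default) the projected
#' position is used unchanged. Ties are broken by contour index, then point
#' order, so labeling is deterministic. A landmark with no contour point in
#' range falls back to its projected position.
#'
#' @param contours Contour tibble from [detect_bone_contours()] (may be NULL
#'   when `capture_radius = 0`).
#' @param projected Projected landmark tibble from [project_landmarks()].
#' @param capture_radius Snap radius in mm.
#' @return A landmark tibble with updated `u`, `v` and `provenance`
#'   (`"detected"` where snapped, `"projected"` otherwise).
#' @export
label_landmarks_2d <- function(contours, projected, capture_radius = 0) {
  out <- projected
  out$provenance <- "projected"
  if (capture_radius <= 0 || is.null(contours) || nrow(contours) == 0)
    return(out)
  for (i in seq_len(nrow(out))) {
    d2 <- (contours$u - out$u[i])^2 + (contours$v - out$v[i])^2
    j <- which(d2 <= capture_radius^2)
    if (!length(j)) next
    j <- j[order(d2[j], contours$contour[j], j)][1]
    out$u[i] <- contours$u[j]; out$v[i] <- contours$v[j]
    out$provenance[i] <- "detected"
  }
  out
}

dist2d <- function(lm, a, b) {
  pa <- lm_point(lm, a); pb <- lm_point(lm, b)
  sqrt(sum((pa - pb)^2))
}

# 2D circle through/refined around three labeled arc landmarks; when
# contours are available, edge points close to the three-point circle and
# within its arc span refine the fit.
circle_2d <- function(lm, p1, apex, p2, contours = NULL, capture = 1.5) {
  P <- rbind(lm_point(lm, p1), lm_point(lm, apex), lm_point(lm, p2))
  fit0 <- fit_circle_sagittal(P)
  if (is.null(contours) || nrow(contours) == 0) return(fit0)
  du <- contours$u - fit0$center[1]; dv <- contours$v - fit0$center[2]
  d <- sqrt(du^2 + dv^2)
  ang <- atan2(dv, du)
  a1 <- atan2(P[1, 2] - fit0$center[2], P[1, 1] - fit0$center[1])
  am <- atan2(P[2, 2] - fit0$center[2], P[2, 1] - fit0$center[1])
  a2 <- atan2(P[3, 2] - fit0$center[2], P[3, 1] - fit0$center[1])
  sw <- function(from, to) (to - from) %% (2 * pi)
  span <- sw(a1, a2); through <- sw(a1, am) <= span
  pos <- sw(a1, ang)
  in_arc <- if (through) pos <= span else pos >= span
  keep <- abs(d - fit0$radius) <= capture & in_arc
  if (sum(keep) >= 10) {
    fit <- try(fit_circle_sagittal(cbind(contours$u[keep], contours$v[keep])),
               silent = TRUE)
    if (!inherits(fit, "try-error") &&
        abs(fit$radius - fit0$radius) <= 0.15 * fit0$radius) {
      fit$source <- "contour"
      return(fit)
    }
  }
  fit0$source <- "landmarks"
  fit0
}

#' Measure the view-specific morphological parameters on a DRR
#'
#' Applies the same geometric definitions as in 3D, but in image coordinates
#' and in detector millimetres, with no magnification correction (the
#' projection bias is the object of study). On the M/L view the image axes
#' stand for (X, Y) and the sagittal parameters are measured; on the A/P
#' view they stand for (Z, Y) and the frontal parameters are measured.
#' Angles are measured against the fixed image axes.
#'
#' @param lm2d Labeled 2D landmark tibble for the view.
#' @param view `"ML"` or `"AP"`.
#' @param contours Optional contour tibble for the radius refinements.
#' @param config [morphometry_config()].
#' @return A [morphometric_profile()] tibble (provenance `"2D-ML"` or
#'   `"2D-AP"`).
#' @export
measure_view_2d <- function(lm2d, view, contours = NULL,
                            config = morphometry_config()) {
  view <- toupper(view)
  p <- function(nm) lm_point(lm2d, nm)
  if (view == "ML") {
    need <- c("A", "B", "V", "C", "D", "F_c", "G_c", "H_c")
  } else {
    need <- c("TiWa_m", "TiWa_l", "TiWp_m", "TiWp_l", "FibLat", "TibMed",
              "FibDist", "TibDist", "H_m", "H_l", "TaVert_m", "TaVert_l")
  }
  missing <- setdiff(need, lm2d$name)
  if (length(missing))
    stop("missing 2D landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (view == "ML") {
    A <- p("A"); B <- p("B"); V <- p("V"); C <- p("C"); D <- p("D")
    va <- config$variant
    mort <- circle_2d(lm2d, "A", "V", "B", contours)
    troch <- circle_2d(lm2d, paste0("F_", va), paste0("H_", va),
                       paste0("G_", va), contours)
    values <- c(
      TiAL = sqrt(sum((A - B)^2)),
      TiSR = mort$radius,
      APG = abs(A[2] - B[2]),
      APA = angle_to_axis(A[1] - B[1], A[2] - B[2]),
      MTiTh = abs(C[1] - D[1]),
      MDA = abs(A[2] - C[2]),
      MDV = abs(V[2] - D[2]),
      TaAL = arc_length_three_points(p(paste0("F_", va)),
                                     p(paste0("H_", va)),
                                     p(paste0("G_", va))),
      TaR = troch$radius)
    morphometric_profile(values, provenance = "2D-ML")
  } else {
    tilt <- p("TibDist") - p("FibDist")
    ta_tilt <- p("TaVert_m") - p("TaVert_l")
    values <- c(
      TiW = (dist2d(lm2d, "TiWa_m", "TiWa_l") +
               dist2d(lm2d, "TiWp_m", "TiWp_l")) / 2,
      MalW = abs(p("FibLat")[1] - p("TibMed")[1]),
      MLATi = angle_to_axis(tilt[1], tilt[2]),
      TaW = dist2d(lm2d, "H_m", "H_l"),
      MLATa = angle_to_axis(ta_tilt[1], ta_tilt[2]))
    morphometric_profile(values, provenance = "2D-AP")
  }
}

#' Measure the full fourteen-parameter 2D profile from both views
#'
#' @param ml_img,ap_img `drr_image` objects (may be NULL to skip the
#'   contour-based radius refinements).
#' @param lm_ml,lm_ap Labeled 2D landmark tibbles per view.
#' @param config [morphometry_config()].
#' @param use_contours Run edge detection on the images for the TiSR/TaR
#'   refinements.
#' @return A [morphometric_profile()] tibble with per-row provenance
#'   (`"2D-ML"` for the sagittal set, `"2D-AP"` for the frontal set).
#' @export
measure_2d <- function(ml_img = NULL, ap_img = NULL, lm_ml, lm_ap,
                       config = morphometry_config(), use_contours = TRUE) {
  cml <- if (use_contours && !is.null(ml_img))
    detect_bone_contours(ml_img) else NULL
  cap <- if (use_contours && !is.null(ap_img))
    detect_bone_contours(ap_img) else NULL
  dplyr::bind_rows(
    measure_view_2d(lm_ml, "ML", cml, config),
    measure_view_2d(lm_ap, "AP", cap, config))
}
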