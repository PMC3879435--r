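#' Least-squares circle fit in a plane
#'
#' Algebraic (Kasa) fit followed by a few Gauss-Newton steps minimising
#' orthogonal distances. Used for the tibial mortise arc (sagittal radius)
#' and the trochlea tali dome (talar radius).
#'
#' @param xy N x 2 matrix (or data frame) of points in a common plane, mm.
#' @param refine Number of Gauss-Newton refinement iterations.
#' @return A list with `center` (length 2), `radius`, `rms` (orthogonal
#'   residual RMS) and `n`.
#' @examples
#' fit_circle_sagittal(rbind(c(0, 1), c(1, 0), c(0, -1)))
#' @export
fit_circle_sagittal <- function(xy, refine = 5) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2)
  if (nrow(xy) < 3) stop("need at least 3 points for a circle fit", call. = FALSE)
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("circle fit failed: points are collinear", call. = FALSE))
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  if (!is.finite(r) || r <= 0)
    stop("circle fit failed: degenerate configuration", call. = FALSE)
  # guard against exact collinearity that sneaks through numerically
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  if (r > 1e7 * max(diff(range(x)), diff(range(y))))
    stop("circle fit failed: points are collinear", call. = FALSE)
  for (it in seq_len(refine)) {
    dx <- x - cx; dy <- y - cy
    d <- sqrt(dx^2 + dy^2)
    J <- cbind(-dx / d, -dy / d, rep(-1, length(d)))
    res <- d - r
    step <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0, 0))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (max(abs(step)) < 1e-12) break
  }
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  list(center = c(cx, cy), radius = r,
       rms = sqrt(mean((d - r)^2)), n = nrow(xy))
}

# Robust circle fit: iteratively re-fit on inliers within `tol` mm of the
# current circle. Seeded either from all points or from a provided subset.
fit_circle_trimmed <- function(xy, tol = 0.5, seed_idx = NULL, max_iter = 20) {
  xy <- as.matrix(xy)
  idx <- if (is.null(seed_idx)) seq_len(nrow(xy)) else seed_idx
  fit <- fit_circle_sagittal(xy[idx, , drop = FALSE])
  for (it in seq_len(max_iter)) {
    d <- sqrt((xy[, 1] - fit$center[1])^2 + (xy[, 2] - fit$center[2])^2)
    new_idx <- which(abs(d - fit$radius) <= tol)
    if (length(new_idx) < 3) break
    if (length(new_idx) == length(idx) && all(new_idx == idx)) break
    idx <- new_idx
    fit <- fit_circle_sagittal(xy[idx, , drop = FALSE])
  }
  fit$inliers <- idx
  fit
}

# Arc length of the circular arc through three points (end, apex, end).
# Angles measured at the fitted/circumscribed centre; the arc is the one
# passing through the apex.
arc_length_three_points <- function(p1, apex, p2) {
  fit <- fit_circle_sagittal(rbind(p1, apex, p2))
  a1 <- atan2(p1[2] - fit$center[2], p1[1] - fit$center[1])
  a2 <- atan2(p2[2] - fit$center[2], p2[1] - fit$center[1])
  am <- atan2(apex[2] - fit$center[2], apex[1] - fit$center[1])
  sweep_angle <- function(from, to) (to - from) %% (2 * pi)
  # choose arc direction that passes through the apex
  s12 <- sweep_angle(a1, a2)
  sm <- sweep_angle(a1, am)
  ang <- if (sm <= s12) s12 else 2 * pi - s12
  fit$radius * ang
}
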