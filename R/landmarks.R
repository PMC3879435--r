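#' Named 3D landmark sets
#'
#' Landmarks are stored as tibbles with columns `name`, `x`, `y`, `z`
#' (anatomical-frame mm), so they flow naturally through dplyr verbs and
#' [apply_pose()].
#'
#' @param name Character vector of landmark names.
#' @param x,y,z Coordinates in mm.
#' @return A tibble with one row per landmark.
#' @export
landmark_set <- function(name, x, y, z) {
  tibble::tibble(name = as.character(name),
                 x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
}

#' Look up one landmark as a length-3 vector
#' @param lm Landmark tibble.
#' @param which Landmark name.
#' @return Numeric length-3 `(x, y, z)` (or `(u, v)` for 2D sets).
#' @export
lm_point <- function(lm, which) {
  i <- match(which, lm$name)
  if (is.na(i)) stop("missing landmark '", which, "'", call. = FALSE)
  if ("z" %in% names(lm)) {
    as.numeric(c(lm$x[i], lm$y[i], lm$z[i]))
  } else {
    as.numeric(c(lm$u[i], lm$v[i]))
  }
}

#' Serialise landmarks or a morphometric profile to JSON
#' @param x A landmark tibble or profile tibble.
#' @param path Output path.
#' @export
write_landmarks_json <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

# deterministic extremal vertex: maximise `coord` (after multiplying by
# `sign`), break ties lexicographically on ascending (x, y, z)
extremal_point <- function(pts, axis, maximize = TRUE, tol = 1e-9) {
  key <- pts[, axis] * if (maximize) 1 else -1
  best <- max(key)
  cand <- which(key >= best - tol)
  if (length(cand) > 1) {
    o <- order(pts[cand, 1], pts[cand, 2], pts[cand, 3])
    cand <- cand[o[1]]
  }
  pts[cand[1], ]
}
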