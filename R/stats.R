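#' Compare paired 2D and 3D cohort measurements
#'
#' Per parameter: Shapiro-Wilk normality (raw values and paired differences,
#' reported, never gating), cohort means/SDs, percent error of the means,
#' two-sided paired t-test, Pearson correlation, and the ordinary
#' least-squares calibration regression `3D = a * 2D + b`.
#'
#' @param profiles3d,profiles2d Long tibbles with columns `specimen`,
#'   `parameter`, `value`, paired by specimen.
#' @return A tibble of class `comparison_table`: one row per parameter with
#'   `mean3d`, `sd3d`, `mean2d`, `sd2d`, `pct_error`, `shapiro_p3d`,
#'   `shapiro_p_diff`, `t_p`, `r`, `a`, `b`, `n`.
#' @export
compare_2d_3d <- function(profiles3d, profiles2d) {
  pars <- intersect(unique(profiles3d$parameter), unique(profiles2d$parameter))
  rows <- lapply(pars, function(pp) {
    x3 <- profiles3d[profiles3d$parameter == pp, ]
    x2 <- profiles2d[profiles2d$parameter == pp, ]
    m <- dplyr::inner_join(x3[, c("specimen", "value")],
                           x2[, c("specimen", "value")],
                           by = "specimen", suffix = c("3", "2"))
    m <- m[is.finite(m$value3) & is.finite(m$value2), ]
    if (nrow(x3) != nrow(x2))
      stop("unpaired 2D/3D profiles for parameter ", pp, call. = FALSE)
    v3 <- m$value3; v2 <- m$value2; n <- nrow(m)
    safe_shapiro <- function(x) {
      if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
      tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
    }
    tp <- tryCatch(stats::t.test(v2, v3, paired = TRUE)$p.value,
                   error = function(e) NA_real_)
    r <- if (n >= 3 && stats::sd(v2) > 0 && stats::sd(v3) > 0)
      stats::cor(v2, v3) else NA_real_
    if (stats::sd(v2) > 0) {
      fit <- stats::lm(v3 ~ v2)
      a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
    } else {
      a <- NA_real_; b <- NA_real_
    }
    tibble::tibble(parameter = pp,
                   mean3d = mean(v3), sd3d = stats::sd(v3),
                   mean2d = mean(v2), sd2d = stats::sd(v2),
                   pct_error = 100 * (mean(v2) - mean(v3)) / mean(v3),
                   shapiro_p3d = safe_shapiro(v3),
                   shapiro_p_diff = safe_shapiro(v2 - v3),
                   t_p = tp, r = r, a = a, b = b, n = n)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("comparison_table", class(out))
  out
}

#' Fit the 2D-to-3D calibration regression for one parameter
#'
#' Ordinary least squares of the 3D gold-standard values on the standard-pose
#' 2D values: `3D = a * 2D + b`.
#'
#' @param value2d,value3d Paired numeric vectors (n >= 3).
#' @return An object of class `regression_2d3d`: `a`, `b`, `r2`, `n`.
#' @export
fit_2d3d_regression <- function(value2d, value3d) {
  keep <- is.finite(value2d) & is.finite(value3d)
  value2d <- value2d[keep]; value3d <- value3d[keep]
  if (length(value2d) < 3)
    stop("regression needs at least 3 paired values", call. = FALSE)
  fit <- stats::lm(value3d ~ value2d)
  # near-exact relations (phantom data) trip lm's perfect-fit warning
  r2 <- suppressWarnings(summary(fit))$r.squared
  structure(list(a = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 r2 = r2, n = length(value2d), fit = fit),
            class = "regression_2d3d")
}

#' @export
print.regression_2d3d <- function(x, ...) {
  cat(sprintf("<regression_2d3d: 3D = %.4f * 2D + %.4f (R2 %.3f, n %d)>\n",
              x$a, x$b, x$r2, x$n))
  invisible(x)
}

#' Correct a 2D measurement with a standard-pose calibration regression
#' @param value2d Numeric vector of 2D measurements.
#' @param model A [fit_2d3d_regression()] model (or a list with `a`, `b`).
#' @return The predicted 3D values `a * value2d + b`.
#' @export
correct_2d <- function(value2d, model) {
  model$a * value2d + model$b
}

#' ICC(3,k): two-way mixed-effects, average-measures, consistency
#'
#' From the two-way ANOVA decomposition of the specimen-by-pose matrix:
#' `ICC(3,k) = (BMS - EMS) / BMS`, with BMS the between-specimen mean square
#' and EMS the residual mean square. Reliability bands: very good above
#' 0.81, good 0.61-0.80, moderate 0.41-0.60, fair 0.21-0.40, poor below 0.2.
#'
#' @param mat Numeric matrix, specimens in rows, poses (raters) in columns;
#'   rows with missing entries are dropped (count reported).
#' @return An object of class `icc_result`: `icc`, `bms`, `jms` (between-pose
#'   mean square), `ems`, `n`, `k`, `n_dropped`, `band`.
#' @export
icc_3k <- function(mat) {
  mat <- as.matrix(mat)
  complete <- stats::complete.cases(mat)
  n_dropped <- sum(!complete)
  mat <- mat[complete, , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2)
    stop("ICC needs at least 2 specimens and 2 poses with complete data",
         call. = FALSE)
  gm <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((mat - gm)^2)
  sse <- sst - ssr - ssc
  bms <- ssr / (n - 1)
  jms <- ssc / (k - 1)
  ems <- sse / ((n - 1) * (k - 1))
  if (bms <= 0)
    stop("ICC undefined: no between-specimen variance (constant matrix)",
         call. = FALSE)
  icc <- (bms - ems) / bms
  structure(list(icc = icc, bms = bms, jms = jms, ems = ems,
                 n = n, k = k, n_dropped = n_dropped,
                 band = icc_band(icc)),
            class = "icc_result")
}

icc_band <- function(icc) {
  if (icc > 0.81) "very good"
  else if (icc > 0.60) "good"
  else if (icc > 0.40) "moderate"
  else if (icc > 0.20) "fair"
  else "poor"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result: ICC(3,k) = %.3f (%s), n = %d, k = %d>\n",
              x$icc, x$band, x$n, x$k))
  invisible(x)
}

#' ICC(3,k) per parameter of a repeatability measurement table
#' @param measurements Long tibble from [repeatability_experiment()].
#' @return Tibble: `parameter`, `icc`, `band`, `n`, `k`, `n_dropped`.
#' @export
icc_by_parameter <- function(measurements) {
  pars <- unique(measurements$parameter)
  dplyr::bind_rows(lapply(pars, function(pp) {
    res <- icc_3k(measurement_matrix(measurements, pp))
    tibble::tibble(parameter = pp, icc = res$icc, band = res$band,
                   n = res$n, k = res$k, n_dropped = res$n_dropped)
  }))
}

#' Residual errors of regression-corrected 2D measurements under pose error
#'
#' For each perturbation bound, measures every specimen's 2D parameters at
#' each random pose, compares the raw and regression-corrected values to the
#' 3D gold standard, and summarises per parameter the mean signed percent
#' error before and after correction (with companion mean-absolute columns,
#' since signed means can hide dispersion).
#'
#' @param cohort List of phantoms with volumes (when `render = TRUE`).
#' @param profiles3d Long tibble `specimen`, `parameter`, `value` of 3D
#'   gold-standard values.
#' @param models Named list (by parameter) of [fit_2d3d_regression()] models
#'   fitted on standard-pose data.
#' @param bounds Perturbation bounds in degrees (default 3 and 6).
#' @param n_poses Poses per specimen per bound.
#' @param seed RNG seed (per-bound seeds are derived from it).
#' @param landmarks3d Optional per-specimen landmark list.
#' @inheritParams measure_pose_2d
#' @param ... Passed to [make_standard_geometry()].
#' @return A tibble: `parameter`, `bound`, `error_pct`, `corrected_error_pct`,
#'   `abs_error_pct`, `abs_corrected_error_pct`, `n_measurements`.
#' @export
residual_error_table <- function(cohort, profiles3d, models,
                                 bounds = c(3, 6), n_poses = 10, seed = 1L,
                                 landmarks3d = NULL,
                                 config = morphometry_config(),
                                 render = TRUE, capture_radius = 0,
                                 step = NULL, ...) {
  out <- list()
  for (bi in seq_along(bounds)) {
    bound <- bounds[bi]
    meas <- list()
    for (i in seq_along(cohort)) {
      ph <- cohort[[i]]
      lm3 <- if (is.null(landmarks3d)) ph$truth_landmarks else landmarks3d[[i]]
      poses <- random_pose_set(bound, n_poses,
                               seed = seed + 1000L * bi + i)
      for (view in c("ML", "AP")) {
        geom <- make_standard_geometry(view, ph$meshes, ph$frame, lm3, ...)
        for (j in seq_along(poses)) {
          prof <- measure_pose_2d(ph, poses[[j]], geom, lm3, config,
                                  render, capture_radius, step)
          meas[[length(meas) + 1L]] <- tibble::tibble(
            specimen = i, pose_id = j, parameter = prof$parameter,
            value = prof$value)
        }
      }
    }
    meas <- dplyr::bind_rows(meas)
    meas <- dplyr::inner_join(
      meas, dplyr::rename(profiles3d[, c("specimen", "parameter", "value")],
                          value3d = "value"),
      by = c("specimen", "parameter"))
    meas$corrected <- NA_real_
    for (pp in names(models)) {
      sel <- meas$parameter == pp
      meas$corrected[sel] <- correct_2d(meas$value[sel], models[[pp]])
    }
    sumtab <- meas |>
      dplyr::filter(is.finite(.data$value)) |>
      dplyr::mutate(
        err = 100 * (.data$value - .data$value3d) / .data$value3d,
        cerr = 100 * (.data$corrected - .data$value3d) / .data$value3d) |>
      dplyr::group_by(.data$parameter) |>
      dplyr::summarise(
        bound = bound,
        error_pct = mean(.data$err),
        corrected_error_pct = mean(.data$cerr),
        abs_error_pct = mean(abs(.data$err)),
        abs_corrected_error_pct = mean(abs(.data$cerr)),
        n_measurements = dplyr::n(), .groups = "drop")
    out[[bi]] <- sumtab
  }
  dplyr::bind_rows(out)
}
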