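#' Default study configuration
#'
#' Settings for the end-to-end simulated study. The full profile mirrors the
#' emulated imaging chain (0.625 mm voxels, 512 x 512 detector at 0.35 mm
#' pitch); the fast profile uses coarse voxels and a smaller detector so the
#' whole pipeline runs in minutes on one CPU.
#'
#' @param n Cohort size.
#' @param seed Master seed; per-stage seeds are derived as documented in
#'   `run_study()`.
#' @param fast Use the fast profile (1.25 mm voxels, 192 px detector at
#'   0.7 mm pitch).
#' @param ... Overrides for any field.
#' @return A named list of class `study_config`.
#' @export
study_config <- function(n = 6, seed = 1L, fast = TRUE, ...) {
  cfg <- list(
    n = n, seed = as.integer(seed),
    voxel_spacing = if (fast) 1.25 else 0.625,
    image_size = if (fast) 192L else 512L,
    pixel_spacing = if (fast) 0.7 else 0.35,
    sid = 1000, heel_offset = 40,
    sweep_max_angle = 6,
    sweep_specimens = if (fast) 1L else NA_integer_,  # NA = all
    repeat_bound = 6, repeat_poses = 10,
    correct_bounds = c(3, 6), correct_poses = 10,
    render = TRUE, capture_radius = 0,
    cohort_table = ankle_cohort_defaults(),
    out_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown study config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "study_config")
}

#' Read a study configuration from YAML
#' @param path YAML file; keys must match [study_config()] fields.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  obj <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare key `n` as boolean FALSE; map it back
  names(obj)[names(obj) %in% c("FALSE", "no")] <- "n"
  do.call(study_config, obj)
}

#' Run the complete simulated morphometry study
#'
#' Orchestrates the full pipeline from one configuration: cohort generation,
#' 3D gold-standard measurement, standard-pose DRR rendering and 2D
#' measurement, the 2D-vs-3D comparison table, the systematic sensitivity
#' sweep, the randomized repeatability experiment with ICC(3,k), and the
#' regression-based correction of perturbed 2D measurements.
#'
#' Per-stage seeds derive deterministically from the master seed
#' (cohort: `seed`; repeatability: `seed + 101`; correction: `seed + 202`),
#' so stages can be re-run independently and the whole study is reproducible.
#'
#' @param config A [study_config()] (or path to a YAML file).
#' @return A list of result tables: `truth`, `profiles3d`, `profiles2d`,
#'   `comparison`, `sensitivity`, `trends`, `icc`, `residuals`, plus the
#'   `config` echo. When `config$out_dir` is set, each table is also written
#'   there as CSV.
#' @export
run_study <- function(config = study_config()) {
  if (is.character(config)) config <- read_study_config(config)
  if (!inherits(config, "study_config")) config <- do.call(study_config, config)
  cfg <- config
  if (cfg$n < 2)
    stop("the repeatability stage needs a cohort of at least 2 specimens; ",
         "got n = ", cfg$n, call. = FALSE)
  geom_args <- list(sid = cfg$sid, pixel_spacing = cfg$pixel_spacing,
                    image_size = cfg$image_size, heel_offset = cfg$heel_offset)

  message("[1/7] generating cohort (n = ", cfg$n, ")")
  cohort <- generate_cohort(cfg$n, cfg$cohort_table, seed = cfg$seed,
                            raster = cfg$render,
                            voxel_spacing = cfg$voxel_spacing)
  truth <- cohort_truth(cohort)

  message("[2/7] 3D gold-standard morphometry")
  m3 <- lapply(cohort, measure_phantom_3d)
  profiles3d <- purrr::imap_dfr(m3, function(p, i)
    dplyr::mutate(p, specimen = i, .before = 1))
  landmarks3d <- lapply(m3, attr, "landmarks")

  message("[3/7] standard-pose DRRs and 2D morphometry")
  profiles2d <- purrr::imap_dfr(cohort, function(ph, i) {
    lm3 <- landmarks3d[[i]]
    prof <- dplyr::bind_rows(lapply(c("ML", "AP"), function(view) {
      geom <- do.call(make_standard_geometry,
                      c(list(view, ph$meshes, ph$frame, lm3), geom_args))
      measure_pose_2d(ph, rigid_pose(), geom, lm3, render = cfg$render,
                      capture_radius = cfg$capture_radius)
    }))
    dplyr::mutate(prof, specimen = i, .before = 1)
  })

  message("[4/7] 2D-vs-3D comparison and calibration regressions")
  comparison <- compare_2d_3d(profiles3d, profiles2d)
  models <- list()
  for (pp in comparison$parameter) {
    x2 <- profiles2d$value[profiles2d$parameter == pp]
    x3 <- profiles3d$value[profiles3d$parameter == pp]
    models[[pp]] <- tryCatch(fit_2d3d_regression(x2, x3),
                             error = function(e) NULL)
  }
  models <- models[!vapply(models, is.null, TRUE)]

  message("[5/7] systematic sensitivity sweep")
  nsw <- if (is.na(cfg$sweep_specimens)) length(cohort)
  else min(cfg$sweep_specimens, length(cohort))
  sens <- dplyr::bind_rows(lapply(seq_len(nsw), function(i) {
    dplyr::bind_rows(lapply(c("ML", "AP"), function(view) {
      tab <- do.call(sensitivity_sweep,
                     c(list(cohort[[i]], view,
                            max_angle = cfg$sweep_max_angle,
                            landmarks3d = landmarks3d[[i]],
                            render = cfg$render,
                            capture_radius = cfg$capture_radius),
                       geom_args))
      dplyr::mutate(tab, specimen = i, view = view, .before = 1)
    }))
  }))
  sens_mean <- sens |>
    dplyr::group_by(.data$parameter, .data$axis, .data$angle) |>
    dplyr::summarise(pct_error = mean(.data$pct_error, na.rm = TRUE),
                     .groups = "drop")
  trends <- sensitivity_trends(sens_mean |>
                                 dplyr::mutate(value = NA_real_))

  message("[6/7] repeatability experiment and ICC(3,k)")
  pose_sets <- lapply(seq_along(cohort), function(i)
    random_pose_set(cfg$repeat_bound, cfg$repeat_poses,
                    seed = cfg$seed + 101L + i))
  icc <- dplyr::bind_rows(lapply(c("ML", "AP"), function(view) {
    meas <- do.call(repeatability_experiment,
                    c(list(cohort, view, pose_sets,
                           landmarks3d = landmarks3d,
                           render = cfg$render,
                           capture_radius = cfg$capture_radius),
                      geom_args))
    dplyr::mutate(icc_by_parameter(meas), view = view, .before = 1)
  }))

  message("[7/7] regression correction under pose error")
  residuals <- do.call(residual_error_table,
                       c(list(cohort, profiles3d, models,
                              bounds = cfg$correct_bounds,
                              n_poses = cfg$correct_poses,
                              seed = cfg$seed + 202L,
                              landmarks3d = landmarks3d,
                              render = cfg$render,
                              capture_radius = cfg$capture_radius),
                         geom_args))

  out <- list(truth = truth, profiles3d = profiles3d,
              profiles2d = profiles2d, comparison = comparison,
              sensitivity = sens, sensitivity_mean = sens_mean,
              trends = trends, icc = icc, residuals = residuals,
              models = models, config = cfg)
  if (!is.null(cfg$out_dir)) write_study_outputs(out, cfg$out_dir)
  out
}

write_study_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("truth", "profiles3d", "profiles2d", "comparison",
            "sensitivity", "sensitivity_mean", "trends", "icc", "residuals")
  for (nm in tabs)
    utils::write.csv(res[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  cfg <- res$config
  cfg$cohort_table <- NULL
  yaml::write_yaml(c(cfg, list(package_version =
                                 as.character(utils::packageVersion("anklemorph")))),
                   file.path(dir, "config_echo.yaml"))
  invisible(dir)
}

#' Wide, publication-style view of the sensitivity table
#'
#' Rearranges a (cohort-mean) sensitivity table into parameter rows with
#' -6/-3/+3/+6 degree columns per axis, the shape in which pose-sensitivity
#' results are conventionally reported.
#'
#' @param sens_mean Tibble with `parameter`, `axis`, `angle`, `pct_error`.
#' @return A wide tibble.
#' @export
sensitivity_wide <- function(sens_mean) {
  sens_mean |>
    dplyr::filter(.data$angle %in% c(-6, -3, 3, 6)) |>
    dplyr::mutate(col = sprintf("%s_%+d", .data$axis, .data$angle)) |>
    dplyr::select("parameter", "col", "pct_error") |>
    tidyr::pivot_wider(names_from = "col", values_from = "pct_error")
}
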