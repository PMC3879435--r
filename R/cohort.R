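#' Default cohort distribution of the morphometric parameters
#'
#' Means and standard deviations of the fourteen parameters used to emulate
#' cohort-level anatomical variation (3D gold-standard column of the emulated
#' study population; APG is excluded because it is geometrically determined
#' by TiAL and APA).
#'
#' @return A tibble with columns `parameter`, `mean`, `sd`.
#' @export
ankle_cohort_defaults <- function() {
  tibble::tribble(
    ~parameter, ~mean, ~sd,
    "TiAL",  28.41, 2.62,
    "TiSR",  29.07, 8.30,
    "APA",    7.86, 5.40,
    "MTiTh", 42.44, 4.83,
    "MDA",   10.21, 2.47,
    "MDV",    3.15, 1.64,
    "TiW",   32.84, 2.72,
    "MalW",  62.60, 3.69,
    "MLATi", 12.59, 3.08,
    "TaAL",  33.55, 4.54,
    "TaR",   20.57, 2.78,
    "TaW",   19.89, 4.45,
    "MLATa",  2.31, 3.67)
}

# one truncated-normal draw per parameter (+/- 3 SD)
rtruncnorm3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- abs(x - mean) <= 3 * sd
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a cohort of ankle phantoms
#'
#' Draws specimen-level parameter values from truncated normal distributions
#' (+/- 3 SD) around the supplied means, rejecting draws that violate the
#' geometric feasibility invariants of [phantom_spec()], and builds one
#' phantom per specimen. Reproducible under `seed`.
#'
#' @param n Number of specimens (>= 2).
#' @param parameter_means_sds Tibble like [ankle_cohort_defaults()].
#' @param seed Integer RNG seed.
#' @param raster Rasterise each phantom's volume (slow); default FALSE, use
#'   [rasterize_phantom()] on demand.
#' @param voxel_spacing Voxel spacing recorded in each spec.
#' @return A list of `ankle_phantom` objects.
#' @export
generate_cohort <- function(n, parameter_means_sds = ankle_cohort_defaults(),
                            seed = 1L, raster = FALSE, voxel_spacing = 0.625) {
  stopifnot(n >= 2)
  tab <- parameter_means_sds
  if (any(tab$sd < 0)) stop("parameter SDs must be >= 0", call. = FALSE)
  sym <- parameter_symbols()
  spec_from_draw <- function(draw) {
    args <- stats::setNames(as.list(draw[sym]), names(sym))
    args <- args[!vapply(args, is.na, TRUE)]
    do.call(phantom_spec, c(args, list(voxel_spacing = voxel_spacing)))
  }
  # check the means themselves are feasible
  mean_spec <- try(spec_from_draw(stats::setNames(tab$mean, tab$parameter)),
                   silent = TRUE)
  if (inherits(mean_spec, "try-error"))
    stop("cohort parameter means are infeasible: ",
         attr(mean_spec, "condition")$message, call. = FALSE)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- NULL
    for (attempt in 1:200) {
      draw <- stats::setNames(
        mapply(function(m, s) rtruncnorm3(1, m, s), tab$mean, tab$sd),
        tab$parameter)
      spec <- try(spec_from_draw(draw), silent = TRUE)
      if (!inherits(spec, "try-error")) break
      spec <- NULL
    }
    if (is.null(spec))
      stop("could not draw a feasible phantom spec for specimen ", i,
           " in 200 attempts", call. = FALSE)
    phantoms[[i]] <- generate_phantom(spec, seed = seed + i, raster = raster)
  }
  phantoms
}

#' Collect the ground-truth profiles of a cohort into one tibble
#' @param cohort A list of phantoms from [generate_cohort()].
#' @return Tibble with columns `specimen`, `parameter`, `value`, `units`.
#' @export
cohort_truth <- function(cohort) {
  purrr::imap_dfr(cohort, function(ph, i)
    dplyr::mutate(ph$truth_profile, specimen = i, .before = 1))
}

# scoped RNG helpers: never clobber the caller's RNG state
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
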