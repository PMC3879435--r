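test_that("phantom ground truth equals the closed-form spec values", {
  spec <- phantom_spec(tar = 20, mlata = 0, mlati = 0)
  ph <- generate_phantom(spec, raster = FALSE)
  tr <- ph$truth_profile
  expect_equal(profile_value(tr, "TaR"), 20)
  expect_equal(profile_value(tr, "MLATa"), 0)
  expect_equal(profile_value(tr, "TaW"), spec$taw)  # no tilt: exact width

  # talar frontal tilt is reproduced exactly in the truth profile
  ph2 <- generate_phantom(phantom_spec(mlata = 2.31), raster = FALSE)
  expect_equal(profile_value(ph2$truth_profile, "MLATa"), 2.31)

  # APG is geometrically determined by TiAL and APA
  expect_equal(profile_value(tr, "APG"),
               spec$tial * sin(spec$apa * pi / 180), tolerance = 1e-12)
})

test_that("truth landmarks lie on the mesh surfaces", {
  ph <- mesh_phantom()
  allv <- do.call(rbind, lapply(ph$meshes, `[[`, "vertices"))
  lm <- as.matrix(ph$truth_landmarks[, c("x", "y", "z")])
  for (i in seq_len(nrow(lm))) {
    d <- sqrt(colSums((t(allv) - lm[i, ])^2))
    expect_lt(min(d), 0.3125)  # half a CT voxel
  }
})

test_that("infeasible specs are rejected with the violated invariant named", {
  expect_error(phantom_spec(crest_height = 25), "crest height")
  expect_error(phantom_spec(taw = 70), "malleolar width")
  expect_error(phantom_spec(tial = 70), "arc")
  expect_error(phantom_spec(mlata = 30), "frontal tilt")
  expect_error(phantom_spec(taw = 25, tiw = 30), "narrower than the mortise")
})

test_that("rasterised volume matches the analytic solid volume within 2%", {
  ph <- fast_phantom()
  vox <- sum(ph$volume$values > 0.5) * prod(ph$volume$spacing)
  solid <- anklemorph:::phantom_solid_volume(ph)
  expect_lt(abs(vox - solid) / solid, 0.02)
})

test_that("cohort sampling is reproducible and honours degenerate SDs", {
  tab <- ankle_cohort_defaults()
  tab$sd <- 0
  co <- generate_cohort(2, tab, seed = 1)
  expect_equal(co[[1]]$truth_profile$value, co[[2]]$truth_profile$value)

  a <- generate_cohort(3, seed = 5, raster = FALSE)
  b <- generate_cohort(3, seed = 5, raster = FALSE)
  d <- generate_cohort(3, seed = 6, raster = FALSE)
  expect_identical(cohort_truth(a)$value, cohort_truth(b)$value)
  expect_false(identical(cohort_truth(a)$value, cohort_truth(d)$value))
  expect_error(generate_cohort(1), "n >= 2")
})

test_that("a study-sized cohort reproduces the target distribution", {
  co <- generate_cohort(58, seed = 3, raster = FALSE)
  tr <- cohort_truth(co)
  tial <- tr$value[tr$parameter == "TiAL"]
  expect_lt(abs(mean(tial) - 28.41), 3 * 2.62 / sqrt(58))
  expect_gt(sd(tial), 1)  # genuine between-specimen variation
})

test_that("increasing the trochlea radius strictly increases measured TaR", {
  radii <- c(18, 20.57, 23)
  tar <- vapply(radii, function(r) {
    ph <- generate_phantom(phantom_spec(tar = r), raster = FALSE)
    profile_value(measure_phantom_3d(ph), "TaR")
  }, 0)
  expect_true(all(diff(tar) > 0))
  expect_equal(tar, radii, tolerance = 1e-6)
})
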