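test_that("automatic landmarks hit the phantom ground truth", {
  ph <- mesh_phantom()
  prof <- measure_phantom_3d(ph)
  got <- attr(prof, "landmarks")
  truth <- ph$truth_landmarks
  m <- merge(as.data.frame(got), as.data.frame(truth), by = "name",
             suffixes = c("_got", "_true"))
  expect_equal(nrow(m), nrow(truth))
  err <- sqrt((m$x_got - m$x_true)^2 + (m$y_got - m$y_true)^2 +
                (m$z_got - m$z_true)^2)
  expect_lt(max(err), 0.35)  # half a voxel equivalent
})

test_that("measure_3d recovers the full truth profile", {
  ph <- mesh_phantom()
  prof <- measure_phantom_3d(ph)
  m <- merge(as.data.frame(prof), as.data.frame(ph$truth_profile),
             by = "parameter", suffixes = c("_got", "_true"))
  ang <- m$units_got == "deg"
  expect_lt(max(abs(m$value_got[ang] - m$value_true[ang])), 0.2)
  expect_lt(max(abs(m$value_got[!ang] / m$value_true[!ang] - 1)), 0.01)
})

test_that("parameter recovery holds across a cohort of phantoms", {
  co <- small_cohort(20)
  for (ph in co) {
    prof <- measure_phantom_3d(ph)
    m <- merge(as.data.frame(prof), as.data.frame(ph$truth_profile),
               by = "parameter", suffixes = c("_got", "_true"))
    ang <- m$units_got == "deg"
    expect_lt(max(abs(m$value_got[ang] - m$value_true[ang])), 0.2)
    expect_lt(max(abs(m$value_got[!ang] / m$value_true[!ang] - 1)), 0.01)
  }
})

test_that("the profile is equivariant to rotating mesh and frame together", {
  ph <- mesh_phantom()
  prof0 <- measure_phantom_3d(ph)
  R <- pose_rotation(rigid_pose(4, -3, 5))
  ph2 <- ph
  for (nm in names(ph2$meshes))
    ph2$meshes[[nm]]$vertices <- ph2$meshes[[nm]]$vertices %*% t(R)
  ph2$frame <- anatomical_frame(origin = as.numeric(R %*% ph$frame$origin),
                                axis_x = R[, 1], axis_y = R[, 2],
                                axis_z = R[, 3])
  prof2 <- measure_phantom_3d(ph2)
  expect_equal(prof2$value, prof0$value, tolerance = 1e-6)
})

test_that("mirroring in Z preserves sagittal landmarks and swaps sides", {
  ph <- mesh_phantom()
  mir <- ph
  for (nm in names(mir$meshes)) {
    mir$meshes[[nm]]$vertices[, 3] <- -mir$meshes[[nm]]$vertices[, 3]
    mir$meshes[[nm]]$faces <- mir$meshes[[nm]]$faces[, c(1, 3, 2)]
  }
  tib0 <- extract_tibial_landmarks(ph$meshes$tibia, ph$meshes$fibula,
                                   ph$frame)$landmarks
  tibm <- extract_tibial_landmarks(mir$meshes$tibia, mir$meshes$fibula,
                                   ph$frame)$landmarks
  for (nm in c("A", "B", "C", "D", "V")) {
    expect_equal(lm_point(tibm, nm)[1:2], lm_point(tib0, nm)[1:2],
                 tolerance = 1e-9)
  }
  # medial/lateral labels swap: the mirrored medial trochlea slab is the
  # original lateral one reflected
  tal0 <- extract_talar_landmarks(ph$meshes$talus, ph$frame)$landmarks
  talm <- extract_talar_landmarks(mir$meshes$talus, ph$frame)$landmarks
  expect_equal(lm_point(talm, "H_m")[2], lm_point(tal0, "H_l")[2],
               tolerance = 1e-9)
  expect_equal(lm_point(talm, "TaVert_m")[3], -lm_point(tal0, "TaVert_l")[3],
               tolerance = 1e-9)
})

test_that("measure_3d evaluates the chord/gap/angle definitions correctly", {
  # hand-computed: A = (10, 3, 0), B = (-17, 0, 0)
  ph <- mesh_phantom()
  prof <- measure_phantom_3d(ph)
  lm <- attr(prof, "landmarks")
  lm$x[lm$name == "A"] <- 10; lm$y[lm$name == "A"] <- 3; lm$z[lm$name == "A"] <- 0
  lm$x[lm$name == "B"] <- -17; lm$y[lm$name == "B"] <- 0; lm$z[lm$name == "B"] <- 0
  tib <- extract_tibial_landmarks(ph$meshes$tibia, ph$meshes$fibula, ph$frame)
  tal <- extract_talar_landmarks(ph$meshes$talus, ph$frame)
  out <- measure_3d(lm, tib$mortise_points, tal$trochlea_points)
  expect_equal(profile_value(out, "TiAL"), sqrt(27^2 + 9), tolerance = 1e-9)
  expect_equal(profile_value(out, "TiAL"), 27.166, tolerance = 1e-3)
  expect_equal(profile_value(out, "APG"), 3)
  expect_equal(profile_value(out, "APA"), atan(3 / 27) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(profile_value(out, "APA"), 6.34, tolerance = 1e-2)

  # degenerate gap: equal heights give zero gap and zero inclination
  lm$y[lm$name == "A"] <- 0
  out2 <- measure_3d(lm, tib$mortise_points, tal$trochlea_points)
  expect_equal(profile_value(out2, "APG"), 0)
  expect_equal(profile_value(out2, "APA"), 0)

  # a missing landmark is reported by name
  expect_error(measure_3d(lm[lm$name != "V", ], tib$mortise_points,
                          tal$trochlea_points), "V")
})

test_that("degenerate meshes raise classification errors", {
  ph <- mesh_phantom()
  flat <- ph$meshes$tibia
  flat$vertices[, 2] <- 0  # squashed: no articular geometry survives
  expect_error(
    suppressWarnings(extract_tibial_landmarks(flat, ph$meshes$fibula,
                                              ph$frame)))
})
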