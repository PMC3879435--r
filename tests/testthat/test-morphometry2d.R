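test_that("detected contours trace the analytic silhouette of a thin slab", {
  # 50 x 30 x 10 mm homogeneous slab; its DRR silhouette is an analytic
  # rectangle whose edges magnify with the slab's depth range
  vol <- voxel_volume(array(1, dim = c(51, 31, 11)), spacing = 1,
                      origin = c(-25, -15, 40))
  geom <- projection_geometry(source = c(0, 0, 1000),
                              det_origin = c(0, 0, 0),
                              u_axis = c(1, 0, 0), v_axis = c(0, 1, 0),
                              pixel_spacing = 0.7, image_size = 160)
  img <- cast_drr(vol, rigid_pose(), geom, step = 0.5)
  ct <- detect_bone_contours(img)
  expect_gt(nrow(ct), 50)
  m_lo <- 1000 / (1000 - 40); m_hi <- 1000 / (1000 - 50)
  # every contour point sits within a pixel of a magnified slab edge band
  near_u <- abs(abs(ct$u) - 25 * m_lo) < (25 * (m_hi - m_lo) + 1.5 * 0.7)
  near_v <- abs(abs(ct$v) - 15 * m_lo) < (15 * (m_hi - m_lo) + 1.5 * 0.7)
  expect_true(all(near_u | near_v))
  # and the contour spans the full silhouette, not a corner
  expect_gt(diff(range(ct$u)), 2 * 25 * m_lo - 3)
})

test_that("edge detection refuses blank images", {
  blank <- structure(list(pixels = matrix(0, 32, 32), pixel_spacing = 1,
                          view = "ML", pose = rigid_pose()),
                     class = "drr_image")
  expect_error(detect_bone_contours(blank), "no edges")
})

test_that("contour coordinates are in mm, independent of pixel pitch", {
  ph <- fast_phantom()
  g1 <- fast_geometry("ML", ph)
  g2 <- make_standard_geometry("ML", ph$meshes, ph$frame, fast_landmarks3d(),
                               image_size = 96, pixel_spacing = 1.4)
  c1 <- detect_bone_contours(cast_drr(ph$volume, rigid_pose(), g1))
  c2 <- detect_bone_contours(cast_drr(ph$volume, rigid_pose(), g2))
  # the coarse contour stays within a coarse pixel of the fine one
  for (i in sample.int(nrow(c2), 40)) {
    d <- sqrt((c1$u - c2$u[i])^2 + (c1$v - c2$v[i])^2)
    expect_lt(min(d), 2 * 1.4)
  }
})

test_that("landmark labeling snaps deterministically and falls back", {
  contours <- tibble::tibble(contour = c(1L, 1L, 2L),
                             u = c(0.4, 5, -0.4), v = c(0, 0, 0),
                             grad = 1)
  proj <- tibble::tibble(name = c("A", "B"), u = c(0, 50), v = c(0, 0),
                         depth = 10, provenance = "projected")
  # radius 0: unchanged, provenance projected
  out0 <- label_landmarks_2d(contours, proj, capture_radius = 0)
  expect_identical(out0$u, proj$u)
  expect_true(all(out0$provenance == "projected"))
  # two equidistant candidates: the lower contour index wins
  out1 <- label_landmarks_2d(contours, proj, capture_radius = 1)
  expect_equal(out1$u[1], 0.4)
  expect_equal(out1$provenance[1], "detected")
  # nothing in range: fall back to the projection
  expect_equal(out1$u[2], 50)
  expect_equal(out1$provenance[2], "projected")
})

test_that("snapped landmarks stay within a pixel on a noiseless phantom", {
  ph <- fast_phantom()
  geom <- fast_geometry("ML", ph)
  img <- cast_drr(ph$volume, rigid_pose(), geom)
  ct <- detect_bone_contours(img)
  proj <- project_landmarks(fast_landmarks3d(), rigid_pose(), geom, ph$frame)
  snapped <- label_landmarks_2d(ct, proj, capture_radius = 1.4)
  moved <- sqrt((snapped$u - proj$u)^2 + (snapped$v - proj$v)^2)
  expect_lt(max(moved), 2 * 0.7 + 1e-9)
})

test_that("equal-depth angles and lengths obey the projection laws", {
  ph <- fast_phantom()
  prof3 <- fast_profile3d()
  lm3 <- fast_landmarks3d()
  geom <- fast_geometry("ML", ph)
  proj <- project_landmarks(lm3, rigid_pose(), geom, ph$frame)
  p2 <- measure_view_2d(proj, "ML")

  # the mortise chord endpoints share mediolateral depth: the inclination
  # angle survives projection exactly
  expect_equal(profile_value(p2, "APA"), profile_value(prof3, "APA"),
               tolerance = 1e-9)
  # and the chord length magnifies by exactly SID/(SID - d)
  dA <- proj$depth[proj$name == "A"]
  expect_equal(profile_value(p2, "TiAL") / profile_value(prof3, "TiAL"),
               1000 / (1000 - dA), tolerance = 2e-3)
  # magnification bound: every 2D length is >= its 3D value
  for (pp in c("TiAL", "MTiTh", "MDA", "MDV", "APG", "TaAL")) {
    expect_gte(profile_value(p2, pp), profile_value(prof3, pp) - 1e-9)
  }
})

test_that("contour-refined 2D radii stay close to the projected-arc radii", {
  ph <- fast_phantom()
  geom <- fast_geometry("ML", ph)
  img <- cast_drr(ph$volume, rigid_pose(), geom)
  proj <- project_landmarks(fast_landmarks3d(), rigid_pose(), geom, ph$frame)
  with_ct <- measure_view_2d(proj, "ML", contours = detect_bone_contours(img))
  without <- measure_view_2d(proj, "ML", contours = NULL)
  expect_equal(profile_value(with_ct, "TiSR"),
               profile_value(without, "TiSR"), tolerance = 0.05)
  expect_equal(profile_value(with_ct, "TaR"),
               profile_value(without, "TaR"), tolerance = 0.05)
})

test_that("a missing 2D landmark is reported by name", {
  ph <- fast_phantom()
  geom <- fast_geometry("ML", ph)
  proj <- project_landmarks(fast_landmarks3d(), rigid_pose(), geom, ph$frame)
  expect_error(measure_view_2d(proj[proj$name != "A", ], "ML"), "A")
})
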