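test_that("central projection follows similar triangles", {
  geom <- projection_geometry(source = c(0, 0, 1000), det_origin = c(0, 0, 0),
                              u_axis = c(1, 0, 0), v_axis = c(0, 1, 0))
  # a point on the detector plane projects to itself
  expect_equal(project_point(c(7, -3, 0), geom), c(u = 7, v = -3))
  # 10 mm off-axis at 100 mm depth: 10 * 1000 / 900
  expect_equal(project_point(c(10, 0, 100), geom)[["u"]],
               10 * 1000 / (1000 - 100), tolerance = 1e-12)
  expect_error(project_point(c(0, 0, 1000.1), geom), "behind")
})

test_that("projected distances obey the magnification law", {
  geom <- projection_geometry(source = c(0, 0, 1000), det_origin = c(0, 0, 0),
                              u_axis = c(1, 0, 0), v_axis = c(0, 1, 0))
  set.seed(4)
  for (d in c(0, 35, 100)) {
    p1 <- c(runif(1, -40, 40), runif(1, -40, 40), d)
    p2 <- c(runif(1, -40, 40), runif(1, -40, 40), d)
    true_len <- sqrt(sum((p1 - p2)^2))
    uv <- project_point(rbind(p1, p2), geom)
    proj_len <- sqrt(sum((uv[1, ] - uv[2, ])^2))
    expect_equal(proj_len / true_len, 1000 / (1000 - d), tolerance = 0.002)
  }
  # a pair 28.41 mm apart at the talus-centre depth of the lateral view
  p1 <- c(0, 0, 35); p2 <- c(28.41, 0, 35)
  uv <- project_point(rbind(p1, p2), geom)
  expect_equal(abs(diff(uv[, 1])), 28.41 * 1000 / 965, tolerance = 1e-9)
})

test_that("projection preserves collinearity", {
  geom <- projection_geometry(source = c(5, 2, 1000), det_origin = c(0, 0, 0),
                              u_axis = c(1, 0, 0), v_axis = c(0, 1, 0))
  a <- c(-20, 10, 40); b <- c(35, -5, 160)
  t <- seq(0, 1, length.out = 7)
  pts <- outer(1 - t, a) + outer(t, b)
  uv <- project_point(pts, geom)
  # area of the triangle formed with the endpoints is ~0 for every point
  for (i in 2:6) {
    cr <- (uv[7, 1] - uv[1, 1]) * (uv[i, 2] - uv[1, 2]) -
      (uv[7, 2] - uv[1, 2]) * (uv[i, 1] - uv[1, 1])
    expect_lt(abs(cr), 1e-9)
  }
})

test_that("the ray caster reproduces exact path lengths through a box", {
  # homogeneous cube, node box spanning exactly 50 mm per side
  vol <- voxel_volume(array(1, dim = c(51, 51, 51)), spacing = 1,
                      origin = c(-25, -25, -25))
  geom <- projection_geometry(source = c(0, 0, 1000),
                              det_origin = c(0, 0, -200),
                              u_axis = c(1, 0, 0), v_axis = c(0, 1, 0),
                              pixel_spacing = 1, image_size = 1)
  img <- cast_drr(vol, rigid_pose(), geom, step = 0.25)
  expect_equal(img$pixels[1, 1], 50, tolerance = 0.01 * 50)

  # 10 degrees oblique (rotating the volume tilts the path):
  # the central ray crosses the parallel faces at 50 / cos(10 deg)
  img2 <- cast_drr(vol, rigid_pose(theta_x = 10), geom,
                   frame = anatomical_frame(), step = 0.25)
  expect_equal(img2$pixels[1, 1], 50 / cos(10 * pi / 180),
               tolerance = 0.01 * 50.77)

  expect_error(cast_drr(vol, rigid_pose(), geom, step = 0), "> 0")
})

test_that("trilinear caster agrees with the fine-step oracle on random rays", {
  ph <- fast_phantom()
  vol <- ph$volume
  geom <- fast_geometry("ML", ph)
  set.seed(21)
  n_checked <- 0
  for (i in 1:100) {
    u <- runif(1, -35, 35); v <- runif(1, -20, 40)
    got <- drr_at_uv(vol, geom, u, v, step = min(vol$spacing) / 2)
    pix <- geom$det_origin + u * geom$u_axis + v * geom$v_axis
    want <- oracle_ray_integral(vol, geom$source, pix,
                                step = min(vol$spacing) / 10)
    if (want > 1) {
      expect_equal(got, want, tolerance = 0.005)
      n_checked <- n_checked + 1
    } else {
      expect_lt(abs(got - want), 0.05)
    }
  }
  expect_gt(n_checked, 20)  # most sampled rays really crossed bone
})

test_that("rays missing the volume give exactly zero", {
  ph <- fast_phantom()
  geom <- fast_geometry("ML", ph)
  expect_identical(drr_at_uv(ph$volume, geom, 500, 500,
                             step = min(ph$volume$spacing) / 2), 0)
})

test_that("standard geometries satisfy the contact and principal-ray rules", {
  ph <- mesh_phantom()
  lm3 <- ph$truth_landmarks
  gml <- make_standard_geometry("ML", ph$meshes, ph$frame, lm3)
  gap <- make_standard_geometry("AP", ph$meshes, ph$frame, lm3)
  allv <- do.call(rbind, lapply(ph$meshes, `[[`, "vertices"))

  # detector touches the lateral-most bone point; source is SID away
  expect_equal(min(projection_depth(allv, gml)), 0, tolerance = 1e-9)
  expect_equal(gml$sid, 1000)
  # the principal ray passes through the medial malleolus point
  tm <- lm_point(lm3, "TibMed")
  expect_lt(sqrt(sum(project_point(tm, gml)^2)), 1e-9)

  # AP: heel stand-in offset, principal ray through the inter-malleolar
  # midpoint
  expect_equal(min(projection_depth(allv, gap)), 40, tolerance = 1e-9)
  mid <- (lm_point(lm3, "TibMed") + lm_point(lm3, "FibLat")) / 2
  expect_lt(sqrt(sum(project_point(mid, gap)^2)), 1e-9)

  expect_error(make_standard_geometry("XX", ph$meshes, ph$frame, lm3),
               "view")
})

test_that("projected landmarks rotate in-plane about the pivot's projection", {
  ph <- mesh_phantom()
  lm3 <- ph$truth_landmarks
  geom <- make_standard_geometry("ML", ph$meshes, ph$frame, lm3)
  th <- 5
  base <- project_landmarks(lm3, rigid_pose(), geom, ph$frame)
  rot <- project_landmarks(lm3, rigid_pose(theta_z = th), geom, ph$frame)
  # each landmark rotates in its own depth plane about the projection of
  # the rotation axis at that depth (closed-form in-plane rotation)
  cs <- cos(th * pi / 180); sn <- sin(th * pi / 180)
  for (i in seq_len(nrow(base))) {
    zi <- lm3$z[i]
    ctr <- unname(project_point(c(0, 0, zi), geom))
    du <- base$u[i] - ctr[1]; dv <- base$v[i] - ctr[2]
    expect_equal(c(rot$u[i], rot$v[i]),
                 c(ctr[1] + cs * du - sn * dv, ctr[2] + sn * du + cs * dv),
                 tolerance = 1e-6)
  }
})
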