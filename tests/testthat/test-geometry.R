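test_that("rigid poses compose and preserve distances", {
  frame <- anatomical_frame()
  set.seed(42)
  pts <- matrix(rnorm(30, sd = 20), ncol = 3)

  # identity leaves coordinates bitwise equal
  expect_identical(apply_pose(pts, rigid_pose(), frame), pts)

  # group property about a single axis: 90 + 90 == 180
  twice <- apply_pose(apply_pose(pts, rigid_pose(theta_z = 90), frame),
                      rigid_pose(theta_z = 90), frame)
  once <- apply_pose(pts, rigid_pose(theta_z = 180), frame)
  expect_lt(max(abs(twice - once)), 1e-9)

  # rigidity: pairwise distances preserved under a combined rotation
  posed <- apply_pose(pts, rigid_pose(6, 6, 6), frame)
  expect_lt(max(abs(dist(posed) - dist(pts)) / dist(pts)), 1e-9)

  # rotation about a shifted frame origin keeps that origin fixed
  f2 <- anatomical_frame(origin = c(5, -2, 3))
  expect_equal(apply_pose(matrix(c(5, -2, 3), 1), rigid_pose(10, 20, 30), f2),
               matrix(c(5, -2, 3), 1), tolerance = 1e-12)
})

test_that("pose rotation matrices stay orthonormal under composition", {
  R <- diag(3)
  set.seed(1)
  for (i in 1:20) {
    R <- pose_rotation(rigid_pose(runif(1, -6, 6), runif(1, -6, 6),
                                  runif(1, -6, 6))) %*% R
  }
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("frame construction rejects bad axes and keeps right-handedness", {
  expect_error(anatomical_frame(axis_x = c(1, 0, 0), axis_y = c(1, 0, 0)),
               "orthonormal")
  expect_error(anatomical_frame(axis_x = c(1, 0, 0), axis_y = c(0, 1, 0),
                                axis_z = c(0, 0, -1)), "right-handed")
  f <- anatomical_frame()
  expect_equal(cross3(f$axis_x, f$axis_y), f$axis_z)
})

test_that("area-weighted centroid of a unit cube surface is its centre", {
  # closed form: each face's centroid is at 0.5 in two coordinates and
  # 0 or 1 in the third; equal areas make the mean (0.5, 0.5, 0.5)
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0 and z = 1 handled via all six faces
    c(5, 6, 8), c(5, 8, 7),
    c(1, 2, 6), c(1, 6, 5),
    c(3, 7, 8), c(3, 8, 4),
    c(1, 5, 7), c(1, 7, 3),
    c(2, 4, 8), c(2, 8, 6))
  cube <- surface_mesh(v, f, label = "talus")
  expect_equal(mesh_centroid(cube), c(0.5, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(abs(mesh_volume(cube)), 1, tolerance = 1e-12)

  # translation equivariance of the frame origin
  shifted <- cube
  shifted$vertices <- sweep(cube$vertices, 2, c(5, -2, 3), `+`)
  expect_equal(compute_anatomical_frame(shifted)$origin,
               c(5.5, -1.5, 3.5), tolerance = 1e-12)
  expect_error(compute_anatomical_frame(
    surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), "talus")), "empty")
})

test_that("phantom talus centroid defines the frame origin", {
  ph <- mesh_phantom()
  expect_lt(max(abs(mesh_centroid(ph$meshes$talus))), 1e-6)
  expect_lt(max(abs(compute_anatomical_frame(ph$meshes$talus)$origin)), 1e-6)
})
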