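test_that("the systematic sweep renders 37 distinct poses per view", {
  ph <- fast_phantom()
  sw <- sensitivity_sweep(ph, "ML", geom = fast_geometry("ML", ph),
                          landmarks3d = fast_landmarks3d(), render = FALSE)
  expect_identical(attr(sw, "n_poses"), 37L)
  # 13 angles per axis per parameter
  counts <- dplyr::count(sw, parameter, axis)
  expect_true(all(counts$n == 13))
  # zero perturbation means exactly zero percent error
  expect_true(all(sw$pct_error[sw$angle == 0] == 0))
})

test_that("in-plane rotations leave equal-depth lengths unchanged", {
  ph <- fast_phantom()
  sw <- sensitivity_sweep(ph, "AP", geom = fast_geometry("AP", ph),
                          landmarks3d = fast_landmarks3d(), render = FALSE)
  # X rotation is in-plane for the frontal view: the mortise width, whose
  # endpoints share anteroposterior depth, must not change at all
  tiw <- sw$pct_error[sw$parameter == "TiW" & sw$axis == "X"]
  expect_lt(max(abs(tiw)), 0.05)
})

test_that("the sweep is deterministic", {
  ph <- fast_phantom()
  a <- sensitivity_sweep(ph, "ML", geom = fast_geometry("ML", ph),
                         landmarks3d = fast_landmarks3d(), render = FALSE)
  b <- sensitivity_sweep(ph, "ML", geom = fast_geometry("ML", ph),
                         landmarks3d = fast_landmarks3d(), render = FALSE)
  expect_identical(a$pct_error, b$pct_error)
})

test_that("trend classification distinguishes linear/quadratic/none", {
  th <- -6:6
  expect_equal(trend_test(th, 0.5 * th)$class, "linear")
  expect_lt(abs(trend_test(th, 0.5 * th)$b2), 1e-9)
  expect_equal(trend_test(th, 0.1 * th^2)$class, "quadratic")
  expect_equal(trend_test(th, rep(0, 13))$class, "none")
  set.seed(2)
  expect_equal(trend_test(th, 2 * th + rnorm(13, sd = 0.1))$class, "linear")
  expect_error(trend_test(1:3, 1:3), "5 angle")
})

test_that("random pose sets honour the bound and the seed contract", {
  ps <- random_pose_set(6, 10, seed = 3)
  ang <- unlist(lapply(ps, function(p) c(p$theta_x, p$theta_y, p$theta_z)))
  expect_length(ang, 30)
  expect_true(all(abs(ang) <= 6))
  expect_identical(random_pose_set(6, 10, seed = 3), ps)
  expect_false(identical(random_pose_set(6, 10, seed = 4), ps))
  # law of large numbers: uniform components are centred
  big <- random_pose_set(3, 10000, seed = 12)
  m <- colMeans(do.call(rbind, lapply(big, function(p)
    c(p$theta_x, p$theta_y, p$theta_z))))
  expect_lt(max(abs(m)), 0.1)
})

test_that("repeatability matrices behave at the degenerate limits", {
  co <- lapply(1:2, function(i) mesh_phantom())
  zero_poses <- lapply(1:2, function(i)
    lapply(1:3, function(j) rigid_pose()))
  meas <- repeatability_experiment(co, "ML", zero_poses, render = FALSE)
  # zero-amplitude poses: all columns identical per specimen
  m <- measurement_matrix(meas, "TiAL")
  expect_true(all(abs(m - m[, 1]) < 1e-12))
  expect_error(repeatability_experiment(co[1], "ML", zero_poses[1]),
               "at least 2")
})

test_that("an insensitive parameter with cohort variation is repeatable", {
  co <- small_cohort(8, seed = 13)
  pose_sets <- lapply(1:8, function(i) random_pose_set(6, 5, seed = 100 + i))
  meas <- repeatability_experiment(co, "ML", pose_sets, render = FALSE)
  res <- icc_3k(measurement_matrix(meas, "TiAL"))
  expect_gte(res$icc, 0.9)
  expect_equal(res$band, "very good")
})
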