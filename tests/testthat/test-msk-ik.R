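test_that("angles are recovered exactly from forward-generated positions", {
  mod <- scaled_leg()
  set.seed(11)
  hips <- cbind(runif(6, -20, 20), runif(6, -20, 20))
  q1 <- runif(6, -pi, pi)
  q2 <- runif(6, -2.5, 2.5)
  traj <- list(hip = data.frame(x_mm = hips[, 1], y_mm = hips[, 2]))
  kn <- an <- matrix(0, 6, 2)
  for (i in 1:6) {
    p <- fetalkick:::fk_pose(mod, hips[i, ],
                             c(q1[i], q2[i], mod$ankle_locked_angle))
    kn[i, ] <- p$knee; an[i, ] <- p$ankle
  }
  traj$knee <- data.frame(x_mm = kn[, 1], y_mm = kn[, 2])
  traj$ankle <- data.frame(x_mm = an[, 1], y_mm = an[, 2])
  ik <- inverse_kinematics(mod, traj)
  expect_lt(max(abs(ik$hip_angle - q1)), 1e-6)
  expect_lt(max(abs(ik$knee_angle - q2)), 1e-6)
  expect_lt(max(ik$residual_mm), 1e-6)
})

test_that("a straight leg recovers zero knee flexion", {
  mod <- scaled_leg()
  Lf <- fetalkick:::seg_row(mod, "femur")$length
  Lt <- fetalkick:::seg_row(mod, "tibia")$length
  d <- c(cos(0.4), sin(0.4))
  traj <- list(hip = data.frame(x_mm = 0, y_mm = 0),
               knee = data.frame(x_mm = Lf * d[1], y_mm = Lf * d[2]),
               ankle = data.frame(x_mm = (Lf + Lt) * d[1],
                                  y_mm = (Lf + Lt) * d[2]))
  ik <- inverse_kinematics(mod, traj)
  expect_equal(ik$knee_angle, 0, tolerance = 1e-9)
  expect_equal(ik$hip_angle, 0.4, tolerance = 1e-9)
})

test_that("coincident joints are rejected", {
  mod <- scaled_leg()
  traj <- list(hip = data.frame(x_mm = 0, y_mm = 0),
               knee = data.frame(x_mm = 0, y_mm = 0),
               ankle = data.frame(x_mm = 10, y_mm = 0))
  expect_error(inverse_kinematics(mod, traj), class = "fk_config_error")
})

test_that("IK residual stays below half a pixel on tracked fixtures", {
  sc <- reference_scenarios()$A
  case <- make_tracked_case(sc)
  trk <- track_sequence(case$seqs, case$seeds)
  lens <- segment_lengths(trk$hip, trk$knee, trk$ankle)
  mod <- scale_model(reference_skeleton(), lens["femur"], lens["tibia"])
  ik <- inverse_kinematics(mod, trk)
  expect_lt(mean(ik$residual_mm), 0.5 * sc$pixel_size)
})
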