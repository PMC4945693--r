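test_that("a static pose with no load carries no joint moments", {
  mod <- scaled_leg()
  traj <- static_trajectories(mod, c(5, -10), c(0.7, -0.9))
  ik <- inverse_kinematics(mod, traj)
  id <- inverse_dynamics(mod, ik, matrix(0, 5, 2))
  expect_lt(max(abs(as.matrix(id[c("hip_moment", "knee_moment",
                                   "ankle_moment")]))), 1e-9)
})

test_that("static moments equal the hand-computed cross products", {
  mod <- scaled_leg()
  hip <- c(5, -10); q <- c(0.7, -0.9)
  traj <- static_trajectories(mod, hip, q)
  ik <- inverse_kinematics(mod, traj)
  F <- c(0.3, -0.2)
  id <- inverse_dynamics(mod, ik, matrix(rep(F, each = 5), ncol = 2))
  pose <- fetalkick:::fk_pose(mod, hip, c(q, mod$ankle_locked_angle))
  calc <- fetalkick:::calcaneus_point(mod, pose)
  cross2 <- function(r, f) r[1] * f[2] - r[2] * f[1]
  ## the net moment the proximal structures must supply balances the
  ## external force's moment about each joint
  expect_equal(id$hip_moment[3], -cross2(calc - pose$hip, F),
               tolerance = 1e-9)
  expect_equal(id$knee_moment[3], -cross2(calc - pose$knee, F),
               tolerance = 1e-9)
  expect_equal(id$ankle_moment[3], -cross2(calc - pose$ankle, F),
               tolerance = 1e-9)
})

test_that("static moments are linear in the external force", {
  mod <- scaled_leg()
  traj <- static_trajectories(mod, c(0, 0), c(1.2, -0.5))
  ik <- inverse_kinematics(mod, traj)
  F <- c(0.25, 0.15)
  id1 <- inverse_dynamics(mod, ik, matrix(rep(F, each = 5), ncol = 2))
  id2 <- inverse_dynamics(mod, ik, matrix(rep(2 * F, each = 5), ncol = 2))
  expect_equal(id2$hip_moment, 2 * id1$hip_moment, tolerance = 1e-9)
  expect_equal(id2$knee_moment, 2 * id1$knee_moment, tolerance = 1e-9)
})

test_that("too-short series cannot be differentiated", {
  mod <- scaled_leg()
  traj <- static_trajectories(mod, c(0, 0), c(1, -1), n = 2)
  ik <- inverse_kinematics(mod, traj)
  expect_error(inverse_dynamics(mod, ik, matrix(0, 2, 2)),
               class = "fk_config_error")
})
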