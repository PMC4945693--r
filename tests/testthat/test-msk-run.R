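test_that("no external force and a static pose produce near-zero forces", {
  mod <- scaled_leg()
  traj <- static_trajectories(mod, c(0, 0), c(0.8, -1.0), n = 6)
  res <- run_kick(mod, traj, matrix(0, 6, 2))
  expect_lt(max(res$maxima$max_force_N), 0.1)
})

test_that("scaling the external force never lowers a group maximum", {
  mod <- scaled_leg()
  traj <- static_trajectories(mod, c(2, 3), c(1.0, -0.8), n = 5)
  F <- c(0.25, -0.3)
  gm <- sapply(c(1, 2, 4), function(k) {
    res <- run_kick(mod, traj, matrix(rep(k * F, each = 5), ncol = 2))
    res$group_maxima
  })
  expect_true(all(diff(gm["hip", ]) >= -1e-9))
  expect_true(all(diff(gm["knee", ]) >= -1e-9))
})

test_that("the calcaneus force series follows the indentation history", {
  defl <- structure(list(window = c(3L, 6L),
                         curve = c(0, 0, 0, 0, 2, 4, 6, 0),
                         max_displacement = 6), class = "deflection_result")
  hist <- data.frame(displacement_mm = c(2, 4, 6), total_N = c(0.1, 0.25, 0.5))
  fs <- calcaneus_force_series(defl, list(history = hist), c(0, 1), 8)
  expect_equal(dim(fs), c(8L, 2L))
  expect_equal(fs[1:3, ], matrix(0, 3, 2))          # before contact
  expect_equal(fs[5, ], c(0, -0.1))                 # 2 mm -> 0.1 N, inward
  expect_equal(fs[7, ], c(0, -0.5))                 # 6 mm -> 0.5 N
  expect_equal(fs[8, ], c(0, 0))                    # after the window
})
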