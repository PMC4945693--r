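test_that("frame count is one more than completed acquisition intervals", {
  sc <- toy_scenario(kick_duration = 3.0, frame_interval = 0.303)
  expect_equal(nrow(generate_kick_kinematics(sc)), 10L)
  sc2 <- toy_scenario(kick_duration = 2.0, frame_interval = 0.303)
  expect_equal(nrow(generate_kick_kinematics(sc2)), 7L)
})

test_that("segment lengths are conserved exactly across random scenarios", {
  set.seed(7)
  for (i in 1:10) {
    sc <- kick_scenario(femur_length = runif(1, 35, 55),
                        tibia_length = runif(1, 40, 60),
                        uterus_major_axis = runif(1, 150, 220),
                        uterus_minor_axis = runif(1, 140, 175),
                        max_deflection = runif(1, 0, 7),
                        kick_duration = runif(1, 1.5, 3.3),
                        rng_seed = i)
    tr <- generate_kick_kinematics(sc)
    fem <- sqrt((tr$knee_x - tr$hip_x)^2 + (tr$knee_y - tr$hip_y)^2)
    tib <- sqrt((tr$ankle_x - tr$knee_x)^2 + (tr$ankle_y - tr$knee_y)^2)
    expect_lt(max(abs(fem - sc$femur_length)), 1e-9)
    expect_lt(max(abs(tib - sc$tibia_length)), 1e-9)
  }
})

test_that("deflection ramps monotonically to the scenario maximum", {
  sc <- toy_scenario()
  tr <- generate_kick_kinematics(sc)
  d <- tr$deflection_mm
  expect_true(all(diff(d) >= -1e-12))
  expect_equal(max(d), sc$max_deflection)
  expect_equal(d[nrow(tr)], sc$max_deflection)
  expect_true(all(d[!tr$contact] == 0))
})

test_that("zero-deflection kicks never touch the wall", {
  tr <- generate_kick_kinematics(toy_scenario(max_deflection = 0))
  expect_false(any(tr$contact))
  expect_true(all(tr$deflection_mm == 0))
})

test_that("unreachable configurations raise a configuration error", {
  expect_error(generate_kick_kinematics(toy_scenario(max_deflection = 12)),
               class = "fk_config_error")
})
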