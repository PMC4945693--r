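test_that("segment lengths from ground truth match the scenario exactly", {
  sc <- reference_scenarios()$A
  tr <- generate_kick_kinematics(sc)
  traj <- fetalkick:::trajectories_from_truth(tr)
  lens <- segment_lengths(traj$hip, traj$knee, traj$ankle)
  expect_equal(unname(lens["femur"]), 51.02, tolerance = 1e-9)
  expect_equal(unname(lens["tibia"]), 54.58, tolerance = 1e-9)
  expect_error(segment_lengths(traj$hip[1:3, ], traj$knee, traj$ankle),
               class = "fk_config_error")
})

test_that("coincident joints give zero length without error", {
  df <- data.frame(x_mm = c(0, 0), y_mm = c(0, 0))
  df2 <- data.frame(x_mm = c(1, 1), y_mm = c(0, 0))
  lens <- segment_lengths(df, df, df2)
  expect_equal(unname(lens["femur"]), 0)
})

test_that("a constructed ramp past first contact measures exactly", {
  ## ankle approaches the cavity surface along the normal, then ramps 5 mm
  major <- 160; minor <- 150; thick <- 6.6
  a <- major / 2; b <- minor / 2
  cpt <- drop(fetalkick:::ellipse_offset_point(a, b, pi / 2, thick))
  nrm <- drop(fetalkick:::ellipse_normal(a, b, pi / 2))
  offsets <- c(-12, -6, 0, 1.5, 3.2, 5.0)
  pts <- t(sapply(offsets, function(d) cpt + d * nrm))
  ankle <- data.frame(x_mm = pts[, 1], y_mm = pts[, 2])
  res <- wall_deflection(ankle, major, minor, thick, contact_band = 1.1)
  expect_equal(res$window, c(2L, 5L))
  expect_equal(res$max_displacement, 5.0, tolerance = 1e-9)
})

test_that("a static ankle far from the wall has zero deflection", {
  ankle <- data.frame(x_mm = rep(5, 6), y_mm = rep(5, 6))
  res <- wall_deflection(ankle, 160, 150)
  expect_null(res$window)
  expect_equal(res$max_displacement, 0)
})

test_that("cohort summaries use the population (divisor-n) spread", {
  s <- summarize(c(6.40, 7.37, 7.07))
  expect_equal(round(s$mean, 2), 6.95)
  expect_equal(round(s$spread, 2), 0.41)
  expect_equal(s$spread, 0.4055, tolerance = 1e-4)
  s2 <- summarize(c(0.72, 0.33, 0.51))
  expect_equal(round(s2$mean, 2), 0.52)
  expect_equal(round(s2$spread, 2), 0.16)
  expect_equal(summarize(3.14), list(mean = 3.14, spread = 0))
  expect_error(summarize(numeric(0)), class = "fk_config_error")
})
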