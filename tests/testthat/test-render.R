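test_that("rendering is bit-identical under a fixed seed", {
  sc <- toy_scenario()
  tr <- generate_kick_kinematics(sc)
  s1 <- render_frames(tr, sc)
  s2 <- render_frames(tr, sc)
  expect_identical(s1$frames, s2$frames)
})

test_that("noiseless frames peak within half a pixel of each joint", {
  sc <- toy_scenario(noise_sd = 0)
  tr <- generate_kick_kinematics(sc)
  seqs <- render_frames(tr, sc)
  for (i in c(1, nrow(tr))) {
    fr <- seqs$frames[[i]]
    for (j in c("hip", "knee", "ankle")) {
      p_px <- fetalkick:::mm_to_px(fetalkick:::joint_xy(tr, j)[i, ], seqs)
      r0 <- round(p_px[2]) + 1L; c0 <- round(p_px[1]) + 1L
      win <- fr[(r0 - 2):(r0 + 2), (c0 - 2):(c0 + 2)]
      pk <- which(win == max(win), arr.ind = TRUE)[1, ]
      peak_px <- c(c0 - 3 + pk[2], r0 - 3 + pk[1]) - 1
      expect_lt(sqrt(sum((peak_px - p_px)^2)), 1.0)
    }
  }
})

test_that("frame extent covers the outer wall ellipse with margin", {
  sc <- kick_scenario(femur_length = 51.02, tibia_length = 54.58,
                      uterus_major_axis = 160.12, uterus_minor_axis = 155.69,
                      max_deflection = 6.40, kick_duration = 3.0)
  tr <- generate_kick_kinematics(sc)
  seqs <- render_frames(tr, sc)
  d <- dim(seqs$frames[[1]])
  expect_gte(d[2] * seqs$pixel_size, 160.12)
  expect_gte(d[1] * seqs$pixel_size, 155.69)
})

test_that("additive noise statistics match the configured level", {
  sc0 <- toy_scenario(noise_sd = 0)
  scn <- toy_scenario(noise_sd = 0.08)
  tr <- generate_kick_kinematics(sc0)
  clean <- render_frames(tr, sc0)
  noisy <- render_frames(tr, scn)
  resid <- unlist(Map(function(a, b) as.vector(a - b),
                      noisy$frames, clean$frames))
  expect_lt(abs(sd(resid) - 0.08) / 0.08, 0.05)
})
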