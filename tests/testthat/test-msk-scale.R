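test_that("unit scale factors reproduce the reference model", {
  ref <- reference_skeleton()
  m <- scale_model(ref, 396, 430)
  expect_equal(m$segments, ref$segments, tolerance = 1e-12)
  expect_equal(unname(m$scale), rep(1, 4))
})

test_that("fetal scaling is per-segment with cubed masses and fixed Fmax", {
  ref <- reference_skeleton()
  m <- scale_model(ref, 51.02, 54.58)
  f_fem <- 51.02 / 396
  f_tib <- 54.58 / 430
  expect_equal(unname(m$scale["femur"]), f_fem)
  expect_equal(unname(m$scale["tibia"]), f_tib)
  expect_equal(unname(m$scale["pelvis"]), (f_fem + f_tib) / 2)
  seg <- m$segments
  expect_equal(seg$length[seg$name == "femur"], 51.02)
  expect_equal(seg$mass[seg$name == "femur"],
               ref$segments$mass[2] * f_fem^3)
  ## maximum isometric forces are unchanged by scaling
  expect_identical(m$muscles$fmax_N, ref$muscles$fmax_N)
  expect_equal(m$muscles$fmax_N[m$muscles$name == "soleus"], 3549)
  expect_error(scale_model(ref, -1, 50), class = "fk_config_error")
})

test_that("the bundled muscle set has 18 muscles in two groups", {
  ref <- reference_skeleton()
  expect_equal(nrow(ref$muscles), 18L)
  expect_setequal(unique(ref$muscles$group), c("hip", "knee"))
  expect_true(all(c("psoas", "iliacus", "soleus", "gastrocnemius_medialis",
                    "vastus_intermedius", "gracilis") %in% ref$muscles$name))
})
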