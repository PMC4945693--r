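test_that("scenario validation enforces geometric and physical constraints", {
  expect_s3_class(toy_scenario(), "kick_scenario")
  expect_error(kick_scenario(femur_length = -1, tibia_length = 45,
                             uterus_major_axis = 130, uterus_minor_axis = 120,
                             max_deflection = 5, kick_duration = 2),
               class = "fk_config_error")
  expect_error(toy_scenario(max_deflection = -0.1), class = "fk_config_error")
  expect_error(kick_scenario(femur_length = 70, tibia_length = 70,
                             uterus_major_axis = 150, uterus_minor_axis = 120,
                             max_deflection = 5, kick_duration = 2),
               class = "fk_config_error")
  expect_error(toy_scenario(contact_fraction = 1.2), class = "fk_config_error")
})

test_that("scenario YAML round trip preserves every field", {
  sc <- toy_scenario(noise_sd = 0.02)
  path <- tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(unclass(sc2), unclass(sc), tolerance = 1e-9)
})

test_that("scenario config parsing reports offending fields", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(femur_length = 40, banana = 1), path)
  expect_error(read_scenario(path), "banana", class = "fk_parse_error")
  yaml::write_yaml(list(femur_length = 40, tibia_length = 45), path)
  expect_error(read_scenario(path), "uterus_major_axis", class = "fk_parse_error")
})

test_that("study scenarios carry the measured per-fetus parameters", {
  scs <- reference_scenarios()
  expect_named(scs, c("A", "B", "C"))
  expect_equal(scs$A$femur_length, 51.02)
  expect_equal(scs$B$uterus_major_axis, 223.34)
  expect_equal(scs$C$max_deflection, 7.07)
  expect_equal(vapply(scs, function(s) s$frame_interval, numeric(1)),
               c(A = 0.303, B = 0.303, C = 0.303))
})
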