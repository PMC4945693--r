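test_that("missing rig geometry is reported explicitly", {
  expect_error(run_validation_scenario(list(span = 120)),
               "sheet_thickness", class = "fk_config_error")
  expect_error(run_validation_scenario(list()), "span",
               class = "fk_config_error")
})

test_that("the bench indentation is elastic, monotone, and path-independent", {
  curve <- run_validation_scenario(list(span = 120, sheet_thickness = 2,
                                        displacement = 5, n_increments = 5))
  load <- curve[curve$phase == "loading", ]
  unload <- curve[curve$phase == "unloading", ]
  expect_equal(load$force_N[load$displacement_mm == 0], 0)
  expect_true(all(diff(load$force_N) > -1e-9))
  expect_equal(load$force_N, rev(unload$force_N), tolerance = 1e-12)
  expect_gt(max(load$force_N), 0)
})
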