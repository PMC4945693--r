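test_that("fixtures round-trip the trajectory losslessly", {
  sc <- toy_scenario()
  tr <- generate_kick_kinematics(sc)
  seqs <- render_frames(tr, sc)
  path <- file.path(tempdir(), "fix1")
  write_fixture(tr, seqs, path)
  back <- read_fixture(path)
  for (col in c("hip_x", "hip_y", "knee_x", "knee_y", "ankle_x", "ankle_y",
                "deflection_mm"))
    expect_lt(max(abs(back$truth[[col]] - tr[[col]])), 1e-12)
  expect_identical(back$truth$contact, tr$contact)
  expect_equal(back$sequence$pixel_size, seqs$pixel_size)
  expect_equal(back$sequence$origin, seqs$origin)
})

test_that("TIFF and NIfTI backends store the same frames", {
  sc <- toy_scenario()
  tr <- generate_kick_kinematics(sc)
  seqs <- render_frames(tr, sc)
  p1 <- file.path(tempdir(), "fix_tiff")
  p2 <- file.path(tempdir(), "fix_nifti")
  write_fixture(tr, seqs, p1, backend = "tiff")
  write_fixture(tr, seqs, p2, backend = "nifti")
  a <- read_fixture(p1)$sequence$frames
  b <- read_fixture(p2)$sequence$frames
  scale <- max(abs(unlist(a)))
  expect_lt(max(abs(unlist(a) - unlist(b))) / scale, 1e-5)
})

test_that("malformed fixtures raise parse errors naming the problem", {
  sc <- toy_scenario()
  tr <- generate_kick_kinematics(sc)
  seqs <- render_frames(tr, sc)
  path <- file.path(tempdir(), "fix_bad")
  write_fixture(tr, seqs, path)
  ## truncate the CSV: drop a column
  tab <- read.csv(file.path(path, "truth.csv"))
  write.csv(tab[-which(names(tab) == "ankle_y")],
            file.path(path, "truth.csv"), row.names = FALSE)
  expect_error(read_fixture(path), "ankle_y", class = "fk_parse_error")
  expect_error(read_fixture(file.path(tempdir(), "nope")),
               class = "fk_parse_error")
})
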