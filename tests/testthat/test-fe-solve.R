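test_that("zero target displacement produces identically zero forces", {
  m <- build_uterus_model(uterus_geometry(160.12, 155.69),
                          resolution = fast_resolution())
  sol <- solve_indentation(m, 0)
  expect_equal(sol$total_contact, 0)
  expect_equal(sol$max_nodal, 0)
  expect_true(all(sol$u == 0))
})

test_that("probe force and wall reaction are equal and opposite", {
  m <- build_uterus_model(uterus_geometry(160.12, 155.69),
                          resolution = fast_resolution())
  sol <- solve_indentation(m, 5)
  ctrl <- m$control$nodes
  probe_res <- c(sum(sol$reactions[2 * ctrl - 1]),
                 sum(sol$reactions[2 * ctrl]))
  ## probe drive resultant balances the contact force on the wall
  expect_lt(sqrt(sum((probe_res - sol$total_contact_vec)^2)) /
            sol$total_contact, 1e-6)
  ## global: reactions at all constrained DOFs balance (no external loads)
  expect_lt(abs(sum(sol$reactions)), 1e-6 * max(abs(sol$reactions)))
})

test_that("forces scale exactly with a global modulus factor", {
  g <- uterus_geometry(160.12, 155.69)
  m1 <- build_uterus_model(g, resolution = fast_resolution())
  mats <- default_materials()
  for (nm in names(mats))
    mats[[nm]] <- material(mats[[nm]]$elastic_modulus * 3,
                           mats[[nm]]$poisson_ratio)
  m3 <- build_uterus_model(g, mats, resolution = fast_resolution())
  s1 <- solve_indentation(m1, 5)
  s3 <- solve_indentation(m3, 5)
  expect_equal(s3$total_contact / s1$total_contact, 3, tolerance = 1e-6)
  expect_equal(s3$max_nodal / s1$max_nodal, 3, tolerance = 1e-6)
})

test_that("apex loading of a symmetric model leaves little net lateral force", {
  ## frictionless contact admits a family of tangentially slid equilibria,
  ## so the discrete solution carries a small contact-patch asymmetry; the
  ## resultant must still be dominated by the wall-normal component
  m <- build_uterus_model(uterus_geometry(160, 160),
                          resolution = fast_resolution())
  sol <- solve_indentation(m, 5)
  expect_lt(abs(sol$total_contact_vec[1]), 0.10 * sol$total_contact)
  expect_gt(sol$total_contact_vec[2], 0.99 * sol$total_contact)
})

test_that("reaction report is consistent and requires convergence", {
  m <- build_uterus_model(uterus_geometry(160.12, 155.69),
                          resolution = fast_resolution())
  sol <- solve_indentation(m, 5)
  rep <- reaction_report(sol)
  expect_lte(rep$max_nodal, rep$total_contact + 1e-9)
  expect_true(all(c("node", "fx", "fy", "magnitude") %in% names(rep$vectors)))
  expect_error(reaction_report(list(converged = FALSE)),
               class = "fk_config_error")
})

test_that("total contact force is mesh-converged within 5 percent", {
  ## three-level wall refinement; the check compares the two finest levels
  g <- uterus_geometry(160.12, 155.69)
  tot <- vapply(c(2, 1.5, 1), function(sn)
    solve_indentation(build_uterus_model(
      g, resolution = fe_resolution(size_near = sn)), 6.40)$total_contact,
    numeric(1))
  expect_lt(abs(tot[3] - tot[2]) / tot[3], 0.05)
  expect_lt(abs(tot[3] - tot[1]) / tot[3], 0.10)
})

test_that("probe modulus changes leave the reaction nearly unchanged", {
  sen <- sensitivity_probe_modulus(uterus_geometry(160.12, 155.69),
                                   resolution = fast_resolution(),
                                   target_displacement = 5,
                                   factors = c(1.0))
  expect_equal(sen$percent_change[2], 0, tolerance = 1e-9)
})

test_that("mesh building rejects inadequate layer resolutions", {
  expect_error(fe_resolution(n_membrane = 1L), class = "fk_config_error")
  expect_error(fe_resolution(n_muscle = 3L), class = "fk_config_error")
  expect_error(uterus_geometry(160, 150, membrane_thickness = 0),
               class = "fk_config_error")
})
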