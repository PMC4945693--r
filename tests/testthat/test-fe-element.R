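test_that("a single element is symmetric with exactly three rigid modes", {
  mesh <- rect_mesh(1, 1, 1, 1)
  K <- as.matrix(fe_assemble(mesh)$K)
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(abs(ev))), 3L)
})

test_that("irregular patches reproduce a linear field exactly (patch test)", {
  nodes <- as.matrix(expand.grid(x = c(0, 0.45, 1), y = c(0, 0.55, 1)))
  nodes[5, ] <- c(0.52, 0.48)  # perturbed interior node
  elems <- fetalkick:::orient_elems(nodes,
           fetalkick:::grid_elems(matrix(1:9, 3, 3)))
  mesh <- structure(list(nodes = nodes, elems = elems, region = rep("m", 4),
                         E = rep(200, 4), nu = rep(0.25, 4),
                         thickness_mm = 2), class = "fe_mesh")
  A <- matrix(c(1e-6, 4e-7, -2e-7, 8e-7), 2, 2)  # tiny: linear regime
  uex <- as.vector(t(nodes %*% t(A)))
  bound <- which(nodes[, 1] %in% c(0, 1) | nodes[, 2] %in% c(0, 1))
  fixed <- sort(c(2 * bound - 1, 2 * bound))
  free <- setdiff(1:18, fixed)
  u <- numeric(18); u[fixed] <- uex[fixed]
  for (it in 1:5) {
    asm <- fe_assemble(mesh, u)
    if (sqrt(sum(asm$fint[free]^2)) < 1e-18) break
    u[free] <- u[free] -
      as.numeric(Matrix::solve(asm$K[free, free], asm$fint[free]))
  }
  expect_lt(max(abs(u[free] - uex[free])), 1e-12)
})

test_that("a slender cantilever matches the Euler-Bernoulli tip deflection", {
  L <- 100; h <- 5
  mesh <- rect_mesh(120, 6, L, h, E = 1000, nu = 0)
  nn <- nrow(mesh$nodes)
  left <- which(mesh$nodes[, 1] == 0)
  tip <- which(mesh$nodes[, 1] == L)
  fixed <- sort(c(2 * left - 1, 2 * left))
  free <- setdiff(seq_len(2 * nn), fixed)
  P <- 0.01
  fext <- numeric(2 * nn); fext[2 * tip] <- P / length(tip)
  u <- numeric(2 * nn)
  for (it in 1:10) {
    asm <- fe_assemble(mesh, u)
    r <- asm$fint - fext
    if (sqrt(sum(r[free]^2)) < 1e-12) break
    u[free] <- u[free] - as.numeric(Matrix::solve(asm$K[free, free], r[free]))
  }
  eb <- P * L^3 / (3 * 1000 * (h^3 / 12))
  expect_lt(abs(mean(u[2 * tip]) - eb) / eb, 0.05)
})

test_that("inverted elements are reported by id", {
  mesh <- rect_mesh(1, 1, 1, 1)
  mesh$elems <- mesh$elems[, 4:1, drop = FALSE]  # reversed orientation
  expect_error(fe_assemble(mesh), "element 1", class = "fk_solver_error")
})
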