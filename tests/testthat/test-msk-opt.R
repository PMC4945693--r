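test_that("one muscle takes exactly M / (r Fmax) below its bound", {
  r <- 12; Fmax <- 800; M <- 3000
  sol <- solve_activation_qp(matrix(r * Fmax, 1, 1), c(M), w = 1e10)
  expect_equal(sol$a, M / (r * Fmax), tolerance = 1e-6)
  expect_lt(abs(sol$reserve[1]) / M, 1e-6)
})

test_that("two muscles split by the closed-form KKT solution", {
  r <- c(10, 4); Fmax <- c(600, 1500); M <- 2500
  A <- matrix(r * Fmax, 1, 2)
  sol <- solve_activation_qp(A, c(M), w = 1e10)
  ## minimise a1^2 + a2^2 subject to sum(r F a) = M:
  ## F_j = r_j Fmax_j^2 M / sum(r_k^2 Fmax_k^2)
  denom <- sum(r^2 * Fmax^2)
  F_expect <- r * Fmax^2 * M / denom
  expect_equal(sol$a * Fmax, F_expect, tolerance = 1e-6)
})

test_that("toy problems match a brute-force activation grid", {
  set.seed(21)
  for (trial in 1:3) {
    r <- runif(3, 2, 15)
    Fmax <- runif(3, 200, 2000)
    M <- runif(1, 0.2, 0.6) * sum(r * Fmax)
    A <- matrix(r * Fmax, 1, 3)
    sol <- solve_activation_qp(A, c(M), w = 1e8)
    ## exhaustive grid over activations (step 1e-3), exact constraint via
    ## solving the third activation from the first two
    grid <- seq(0, 1, by = 1e-3)
    best <- NULL
    for (a1 in grid) {
      ## a2 range where a3 stays in [0, 1]
      a3v <- (M - A[1] * a1 - A[2] * grid) / A[3]
      okk <- which(a3v >= 0 & a3v <= 1)
      if (!length(okk)) next
      cost <- a1^2 + grid[okk]^2 + a3v[okk]^2
      j <- which.min(cost)
      if (is.null(best) || cost[j] < best$cost)
        best <- list(cost = cost[j], a = c(a1, grid[okk][j], a3v[okk][j]))
    }
    expect_lt(max(abs(sol$a * Fmax - best$a * Fmax)), 1e-2 * max(Fmax))
    expect_lte(max(sol$a), 1)
    expect_gte(min(sol$a), 0)
  }
})

test_that("reserves absorb moments no muscle can produce", {
  ## all arms are positive but the demanded moment is negative
  A <- matrix(c(5 * 100, 8 * 200), 1, 2)
  sol <- solve_activation_qp(A, c(-500), w = 1e3)
  expect_equal(sol$a, c(0, 0), tolerance = 1e-9)
  expect_equal(sol$reserve[1], -500, tolerance = 1e-9)
})

test_that("KKT stationarity and moment balance hold at every frame", {
  mod <- scaled_leg()
  traj <- static_trajectories(mod, c(2, -4), c(0.9, -1.1))
  ik <- inverse_kinematics(mod, traj)
  F <- c(0.2, -0.35)
  id <- inverse_dynamics(mod, ik, matrix(rep(F, each = 5), ncol = 2))
  so <- static_optimization(id, mod, ik)
  expect_lt(max(so$kkt_residual), 1e-6)
  expect_true(all(so$activation >= 0 & so$activation <= 1))
  ## moment balance: R^T (Fmax a) + reserve = M
  for (i in seq_len(nrow(id))) {
    M <- c(id$hip_moment[i], id$knee_moment[i], id$ankle_moment[i])
    recon <- as.numeric(t(so$arms[[i]]) %*% so$force[i, ]) + so$reserves[i, ]
    expect_lt(max(abs(recon - M)) / max(abs(M), 1), 1e-6)
  }
})
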