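#' Quadratic static optimization of muscle redundancy
#'
#' Per frame, resolves the muscle redundancy by minimising the sum of
#' squared activations plus a heavily weighted penalty on reserve
#' generalized forces, subject to reproducing the inverse-dynamics joint
#' moments and activation bounds:
#' \deqn{\min \sum_j a_j^2 + w \sum_i (res_i / ref)^2
#'   \quad s.t. \quad \sum_j r_{ij} F_{max,j} a_j + res_i = M_i,
#'   \; 0 \le a_j \le 1.}
#' One reserve acts on each moment-balance row (hip, knee, locked ankle);
#' they stand in for the pelvis reserve actuators of the source gait model
#' and guarantee feasibility.  The reserves are eliminated analytically,
#' leaving a bound-constrained convex quadratic programme solved exactly by
#' an active-set method.
#'
#' @param moments Data frame from [inverse_dynamics()] (`hip_moment`,
#'   `knee_moment`, `ankle_moment`, N mm).
#' @param model A scaled `skeleton_model`.
#' @param angles The `joint_angle_series` used for the moments.
#' @param reserve_weight Penalty weight `w` on squared normalised reserves.
#' @param reserve_ref Reserve normalisation, N mm.
#' @return A `muscle_force_series`: list with `activation` and `force`
#'   (n_frames x n_muscles matrices), `reserves` (n x 3, N mm),
#'   `arms` (list of per-frame moment-arm matrices), `maxima` (per-muscle
#'   peak force with group), and `high_reserve_frames` (frames where any
#'   reserve exceeds 1\% of the corresponding moment magnitude).
#' @export
static_optimization <- function(moments, model, angles,
                                reserve_weight = 1e3, reserve_ref = 1) {
  n <- nrow(moments)
  mus <- model$muscles
  nm <- nrow(mus)
  fmax <- mus$fmax_N
  hip_pos <- attr(angles, "hip_positions")
  if (is.null(hip_pos)) hip_pos <- matrix(0, n, 2)
  q3 <- model$ankle_locked_angle

  act <- matrix(0, n, nm, dimnames = list(NULL, mus$name))
  res <- matrix(0, n, 3, dimnames = list(NULL, c("hip", "knee", "ankle")))
  arms_list <- vector("list", n)
  kkt <- numeric(n)
  for (i in seq_len(n)) {
    R <- moment_arms(model, hip_pos[i, ],
                     c(angles$hip_angle[i], angles$knee_angle[i], q3),
                     pelvis_dir_angle = angles$hip_angle[1])
    arms_list[[i]] <- R
    M <- c(moments$hip_moment[i], moments$knee_moment[i],
           moments$ankle_moment[i])
    sol <- solve_activation_qp(t(R) * rep(fmax, each = 3), M,
                               w = reserve_weight, ref = reserve_ref)
    act[i, ] <- sol$a
    res[i, ] <- sol$reserve
    kkt[i] <- sol$kkt_residual
  }
  force <- sweep(act, 2, fmax, `*`)
  maxima <- data.frame(muscle = mus$name, group = mus$group,
                       max_force_N = apply(force, 2, max))
  hi <- which(apply(abs(res) > 0.01 * pmax(abs(as.matrix(
    moments[c("hip_moment", "knee_moment", "ankle_moment")])), 1e-9),
    1, any))
  structure(list(activation = act, force = force, reserves = res,
                 arms = arms_list, maxima = maxima, kkt_residual = kkt,
                 high_reserve_frames = moments$frame[hi]),
            class = "muscle_force_series")
}

#' Solve one frame's activation QP
#'
#' Minimise `sum(a^2) + w * sum(((M - A a)/ref)^2)` over `0 <= a <= 1`,
#' which is the reserve-eliminated form of the moment-constrained problem
#' (`reserve = M - A a`).  Exact primal active-set solver: at the solution
#' the KKT conditions hold to machine precision.
#'
#' @param A 3 x n matrix of `r_ij * Fmax_j` (N mm per unit activation).
#' @param M Length-3 moment vector, N mm.
#' @param w,ref Reserve penalty weight and normalisation.
#' @return List `a`, `reserve`, `kkt_residual`.
#' @export
solve_activation_qp <- function(A, M, w = 1e3, ref = 1) {
  A <- rbind(A)
  nm <- ncol(A)
  nc <- nrow(A)
  eps <- ref^2 / (2 * w)  # vanishes as the reserve weight grows

  ## Stationarity with multipliers lam = (2 w / ref^2) * reserve:
  ##   2 a_f = A_f' lam,   A a + eps * lam = M
  ## solved through the nc x nc Schur complement in lam; clamped variables
  ## move to the right-hand side.  Well-conditioned for any weight.
  a <- rep(0, nm)
  state <- rep(0L, nm)  # -1 at lower (0), +1 at upper (1), 0 free
  lam <- rep(0, nc)
  for (outer in 1:(5 * nm + 10)) {
    freei <- which(state == 0L)
    a[state == -1L] <- 0; a[state == 1L] <- 1
    Mred <- M - if (any(state == 1L))
      as.numeric(A[, state == 1L, drop = FALSE] %*%
                 rep(1, sum(state == 1L))) else 0
    Af <- A[, freei, drop = FALSE]
    S <- 0.5 * tcrossprod(Af) + diag(eps, nc)
    lam <- as.numeric(solve(S, Mred))
    if (length(freei)) a[freei] <- 0.5 * as.numeric(crossprod(Af, lam))
    ## clamp the worst bound violation, if any
    viol_lo <- which(a < -1e-12 & state == 0L)
    viol_hi <- which(a > 1 + 1e-12 & state == 0L)
    if (length(viol_lo) || length(viol_hi)) {
      cand <- c(viol_lo, viol_hi)
      worst <- cand[which.max(pmax(-a[cand], a[cand] - 1))]
      state[worst] <- if (a[worst] < 0) -1L else 1L
      next
    }
    ## multipliers of clamped variables: g_i = 2 a_i - A_i' lam
    g <- 2 * a - as.numeric(crossprod(A, lam))
    rel_lo <- which(state == -1L & g < -1e-10)
    rel_hi <- which(state == 1L & g > 1e-10)
    if (length(rel_lo) || length(rel_hi)) {
      cand <- c(rel_lo, rel_hi)
      worst <- cand[which.max(abs(g[cand]))]
      state[worst] <- 0L
      next
    }
    break
  }
  a <- pmin(pmax(a, 0), 1)
  g <- 2 * a - as.numeric(crossprod(A, lam))
  kkt <- if (any(state == 0L)) max(abs(g[state == 0L])) else 0
  scale <- max(1, max(abs(g)), max(abs(lam)))
  list(a = a, reserve = as.numeric(M - A %*% a),
       kkt_residual = kkt / scale)
}
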