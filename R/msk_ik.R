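#' Inverse kinematics of the planar leg
#'
#' Per frame, finds the hip (global femur) angle and relative knee angle
#' that minimise the summed squared distance between the model's knee and
#' ankle joint centres and the tracked positions, with the pelvis
#' translated to the tracked hip.  An analytic fit (angles from the tracked
#' segment directions) is polished by a few Gauss-Newton steps so the
#' result is the true least-squares solution for the model's (scaled)
#' segment lengths.  The locked ankle angle is held constant.
#'
#' @param model A scaled `skeleton_model`.
#' @param trajectories Named list of `hip`, `knee`, `ankle` trajectories
#'   (data frames with `x_mm`, `y_mm`), as produced by [track_sequence()]
#'   or built from a ground-truth table.
#' @return A `joint_angle_series` data frame: `frame`, `hip_angle`,
#'   `knee_angle` (radians; knee 0 = straight), `residual_mm` (RMS joint
#'   fit residual), plus attribute `hip_positions`.
#' @export
inverse_kinematics <- function(model, trajectories) {
  hip_t <- cbind(trajectories$hip$x_mm, trajectories$hip$y_mm)
  knee_t <- cbind(trajectories$knee$x_mm, trajectories$knee$y_mm)
  ankle_t <- cbind(trajectories$ankle$x_mm, trajectories$ankle$y_mm)
  n <- nrow(hip_t)
  if (nrow(knee_t) != n || nrow(ankle_t) != n)
    fk_config_error("trajectories must have equal length")
  Lf <- seg_row(model, "femur")$length
  Lt <- seg_row(model, "tibia")$length

  out <- data.frame(frame = seq_len(n) - 1L, hip_angle = NA_real_,
                    knee_angle = NA_real_, residual_mm = NA_real_)
  for (i in seq_len(n)) {
    hp <- hip_t[i, ]
    v1 <- knee_t[i, ] - hp
    v2 <- ankle_t[i, ] - knee_t[i, ]
    if (sqrt(sum(v1^2)) < 1e-9 || sqrt(sum(v2^2)) < 1e-9)
      fk_config_error(sprintf("degenerate configuration at frame %d (coincident joints)", i - 1L))
    th1 <- atan2(v1[2], v1[1])
    th2 <- atan2(v2[2], v2[1]) - th1
    th2 <- atan2(sin(th2), cos(th2))
    q <- c(th1, th2)
    ## Gauss-Newton on the 4-vector of joint residuals
    resid <- function(q) {
      knee_m <- hp + Lf * c(cos(q[1]), sin(q[1]))
      ankle_m <- knee_m + Lt * c(cos(q[1] + q[2]), sin(q[1] + q[2]))
      c(knee_m - knee_t[i, ], ankle_m - ankle_t[i, ])
    }
    for (it in 1:10) {
      r0 <- resid(q)
      J <- matrix(0, 4, 2)
      h <- 1e-6
      for (k in 1:2) {
        qp <- q; qp[k] <- qp[k] + h
        J[, k] <- (resid(qp) - r0) / h
      }
      dq <- tryCatch(solve(crossprod(J), -crossprod(J, r0)),
                     error = function(e) matrix(0, 2, 1))
      q <- q + as.numeric(dq)
      if (sqrt(sum(dq^2)) < 1e-12) break
    }
    r0 <- resid(q)
    out$hip_angle[i] <- q[1]
    out$knee_angle[i] <- atan2(sin(q[2]), cos(q[2]))
    out$residual_mm[i] <- sqrt(mean(c(sum(r0[1:2]^2), sum(r0[3:4]^2))))
  }
  attr(out, "hip_positions") <- hip_t
  class(out) <- c("joint_angle_series", "data.frame")
  out
}

## Build trajectory list in the tracker's layout from a ground-truth table
## (useful for feeding truth instead of tracked positions).
trajectories_from_truth <- function(truth) {
  mk <- function(j) {
    structure(data.frame(frame = truth$frame, time_s = truth$time_s,
                         x_mm = truth[[paste0(j, "_x")]],
                         y_mm = truth[[paste0(j, "_y")]],
                         score = 1, valid = TRUE),
              class = c("joint_trajectory", "data.frame"), joint = j)
  }
  list(hip = mk("hip"), knee = mk("knee"), ankle = mk("ankle"))
}
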