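#' Inverse dynamics of the planar leg (gravity neglected)
#'
#' Newton-Euler recursion from the foot to the femur with gravity set to
#' zero (the fetus and amniotic fluid have nearly equal specific gravity).
#' Segment accelerations come from central finite differences of the
#' joint-angle series (forward/backward one-sided at the ends); the
#' external wall-reaction force acts at the calcaneus of the foot.  Returns
#' the net inter-segment moments at the hip, knee and (locked) ankle --
#' the generalized forces the muscles plus reserves must reproduce.
#'
#' @param model A scaled `skeleton_model`.
#' @param angles A `joint_angle_series` from [inverse_kinematics()].
#' @param external n x 2 matrix of external forces at the calcaneus, N (one
#'   row per frame; zero rows outside the contact window).
#' @param frame_interval Frame spacing, s.
#' @return A data frame `frame`, `hip_moment`, `knee_moment`,
#'   `ankle_moment` (N mm, +z / counterclockwise).
#' @export
inverse_dynamics <- function(model, angles, external, frame_interval = 0.303) {
  n <- nrow(angles)
  if (n < 3)
    fk_stop("need at least 3 frames for finite-difference accelerations",
            "fk_config_error")
  external <- rbind(external)
  if (nrow(external) == 1) external <- external[rep(1, n), , drop = FALSE]
  if (nrow(external) != n)
    fk_config_error("external force series must match the angle series length")
  hip_pos <- attr(angles, "hip_positions")
  if (is.null(hip_pos)) hip_pos <- matrix(0, n, 2)

  q3 <- model$ankle_locked_angle
  poses <- lapply(seq_len(n), function(i)
    fk_pose(model, hip_pos[i, ],
            c(angles$hip_angle[i], angles$knee_angle[i], q3),
            pelvis_dir_angle = angles$hip_angle[1]))

  ## COM positions (m) and segment angles per frame
  segnames <- c("femur", "tibia", "foot")
  com <- array(0, c(n, 3, 2))
  ang <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- poses[[i]]
    for (s in 1:3) {
      sr <- seg_row(model, segnames[s])
      com[i, s, ] <- (p$origins[segnames[s], ] +
                      sr$com_frac * sr$length * p$dirs[segnames[s], ]) / 1000
      ang[i, s] <- atan2(p$dirs[segnames[s], 2], p$dirs[segnames[s], 1])
    }
    ang[i, ] <- c(angles$hip_angle[i],
                  angles$hip_angle[i] + angles$knee_angle[i],
                  angles$hip_angle[i] + angles$knee_angle[i] + q3)
  }

  fd2 <- function(x, dt) {  # second derivative, one-sided at the ends
    n <- length(x)
    a <- numeric(n)
    if (n >= 3) {
      a[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
      a[1] <- a[2]; a[n] <- a[n - 1]
    }
    a
  }
  acc <- array(0, c(n, 3, 2))
  alp <- matrix(0, n, 3)
  for (s in 1:3) {
    acc[, s, 1] <- fd2(com[, s, 1], frame_interval)
    acc[, s, 2] <- fd2(com[, s, 2], frame_interval)
    alp[, s] <- fd2(unwrap_angle(ang[, s]), frame_interval)
  }

  out <- data.frame(frame = angles$frame, hip_moment = 0, knee_moment = 0,
                    ankle_moment = 0)
  cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]
  for (i in seq_len(n)) {
    p <- poses[[i]]
    F_ext <- external[i, ]
    calc <- calcaneus_point(model, p) / 1000          # m
    jts <- list(foot = p$ankle / 1000, tibia = p$knee / 1000,
                femur = p$hip / 1000)
    F_child <- c(0, 0); M_child <- 0; pt_child <- c(0, 0)
    Ms <- c(foot = 0, tibia = 0, femur = 0)
    for (s in c("foot", "tibia", "femur")) {
      sr <- seg_row(model, s)
      si <- match(s, segnames)
      a_com <- acc[i, si, ]
      cm <- com[i, si, ]
      jt <- jts[[s]]
      Fx <- sr$mass * a_com                       # N (SI units)
      Mz <- sr$inertia * alp[i, si]               # N m
      ## proximal joint load on this segment:
      F_prox <- Fx - (if (s == "foot") F_ext else -F_child)
      M_prox <- Mz -
        (if (s == "foot") cross2(calc - cm, F_ext) else
           -M_child - cross2(pt_child - cm, F_child)) -
        cross2(jt - cm, F_prox)
      Ms[s] <- M_prox
      F_child <- F_prox; M_child <- M_prox; pt_child <- jt
    }
    out$ankle_moment[i] <- Ms["foot"] * 1000       # N mm
    out$knee_moment[i] <- Ms["tibia"] * 1000
    out$hip_moment[i] <- Ms["femur"] * 1000
  }
  out
}

unwrap_angle <- function(a) {
  d <- diff(a)
  d <- atan2(sin(d), cos(d))
  cumsum(c(a[1], d))
}
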