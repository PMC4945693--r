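#' Generate ground-truth kick kinematics
#'
#' Constructs the per-frame hip, knee and ankle positions of a simple
#' in-plane extension kick: the hip stays quasi-stationary (a small, smooth
#' drift), the leg extends until the ankle meets the cavity surface of the
#' uterine wall, and the ankle then displaces the wall outward along the
#' local normal, ramping smoothly to the scenario's `max_deflection` at the
#' final frame.  Segment lengths are preserved exactly at every frame by
#' construction (two-link inverse kinematics from the current hip position).
#'
#' @param scenario A [kick_scenario()].
#' @return A `kick_truth` data frame with one row per frame and columns
#'   `frame` (0-based), `time_s`, `hip_x`, `hip_y`, `knee_x`, `knee_y`,
#'   `ankle_x`, `ankle_y`, `contact` (logical) and `deflection_mm`, plus
#'   attributes `scenario`, `contact_point` and `contact_normal`.
#' @export
generate_kick_kinematics <- function(scenario) {
  stopifnot(inherits(scenario, "kick_scenario"))
  sc <- scenario
  n <- n_frames(sc)
  a <- sc$uterus_major_axis / 2
  b <- sc$uterus_minor_axis / 2
  L1 <- sc$femur_length
  L2 <- sc$tibia_length

  ## Contact point on the cavity (inner) surface and its outward normal.
  cpt <- drop(ellipse_offset_point(a, b, sc$contact_angle, sc$wall_thickness))
  nrm <- drop(ellipse_normal(a, b, sc$contact_angle))

  ## Hip placed inside the cavity so the leg is nearly extended at contact.
  standoff <- 0.90
  hip0 <- cpt - standoff * (L1 + L2) * nrm
  if (inner_wall_signed_distance(rbind(hip0), sc$uterus_major_axis,
                                 sc$uterus_minor_axis, sc$wall_thickness) >= 0)
    fk_config_error("hip position falls outside the uterine cavity; limb cannot reach the wall from inside")
  reach_final <- standoff * (L1 + L2) + sc$max_deflection
  if (reach_final >= L1 + L2)
    fk_config_error("limb cannot reach the wall: max_deflection exceeds the leg's remaining reach")

  ## Ankle path: retracted start -> contact point (eased), then outward
  ## along the normal following a smooth ramp to max_deflection.
  u0 <- drop(rot2(20 * pi / 180) %*% nrm)
  ankle0 <- hip0 + 0.75 * (L1 + L2) * u0
  i_contact <- max(1L, min(n - 1L, as.integer(round(sc$contact_fraction * (n - 1)))))
  if (sc$max_deflection == 0) i_contact <- n - 1L

  idx <- 0:(n - 1)
  t_s <- idx * sc$frame_interval
  drift_dir <- drop(rot2(pi / 2) %*% nrm)

  hip <- knee <- ankle <- matrix(NA_real_, n, 2)
  contact <- logical(n)
  defl <- numeric(n)
  for (i in seq_len(n)) {
    k <- idx[i]
    hip_i <- hip0 + sc$hip_drift_mm * sin(pi * k / max(1, n - 1)) * drift_dir
    if (k <= i_contact) {
      u <- smoothstep(k / i_contact)
      ankle_i <- ankle0 + u * (cpt - ankle0)
      contact[i] <- k == i_contact && sc$max_deflection > 0
      defl[i] <- 0
    } else {
      u <- smoothstep((k - i_contact) / (n - 1 - i_contact))
      defl[i] <- sc$max_deflection * u
      ankle_i <- cpt + defl[i] * nrm
      contact[i] <- TRUE
    }
    knee_i <- two_link_ik(hip_i, ankle_i, L1, L2)
    hip[i, ] <- hip_i; knee[i, ] <- knee_i; ankle[i, ] <- ankle_i
  }
  if (sc$max_deflection == 0) contact[] <- FALSE

  out <- data.frame(frame = idx, time_s = t_s,
                    hip_x = hip[, 1], hip_y = hip[, 2],
                    knee_x = knee[, 1], knee_y = knee[, 2],
                    ankle_x = ankle[, 1], ankle_y = ankle[, 2],
                    contact = contact, deflection_mm = defl)
  attr(out, "scenario") <- sc
  attr(out, "contact_point") <- cpt
  attr(out, "contact_normal") <- nrm
  class(out) <- c("kick_truth", "data.frame")
  out
}

## Knee position for a two-link chain from hip to ankle with exact segment
## lengths; the elbow branch is fixed (knee on the +cross side) so the pose
## varies continuously across frames.
two_link_ik <- function(hip, ankle, L1, L2, branch = 1) {
  d <- sqrt(sum((ankle - hip)^2))
  if (d > L1 + L2 + 1e-9 || d < abs(L1 - L2) - 1e-9 || d < 1e-9)
    fk_config_error(sprintf("ankle target at distance %.3f mm unreachable with segments %.2f + %.2f mm", d, L1, L2))
  d <- min(d, L1 + L2)
  u <- (ankle - hip) / d
  x <- (d^2 + L1^2 - L2^2) / (2 * d)
  h2 <- max(L1^2 - x^2, 0)
  perp <- branch * c(-u[2], u[1])
  hip + x * u + sqrt(h2) * perp
}

joint_xy <- function(truth, joint = c("hip", "knee", "ankle")) {
  joint <- match.arg(joint)
  cbind(truth[[paste0(joint, "_x")]], truth[[paste0(joint, "_y")]])
}
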