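#' Reference adult planar leg model
#'
#' A planar reduction of an adult right-leg musculoskeletal model: four
#' segments (pelvis fixed to ground at the hip, femur, tibia, foot with the
#' talus/calcaneus/toes lumped and the ankle locked), a hinge knee, and 18
#' muscles with via-point paths read from the bundled synthetic planar
#' muscle table (see
#' `system.file("extdata", "adult_leg_muscles_planar_synthetic.csv",
#' package = "fetalkick")`).
#'
#' Segment reference lengths (mm) and masses (kg) approximate an adult gait
#' model; planar inertia is taken as a slender rod about the segment COM at
#' midlength.  The calcaneus load point (where wall reaction forces act) is
#' the heel point of the foot segment.
#'
#' @param muscle_file Optional path to an alternative muscle CSV.
#' @return A `skeleton_model` list with `segments`, `muscles`,
#'   `ankle_locked_angle` (radians) and `calcaneus` (foot-frame fraction /
#'   perpendicular offset).
#' @export
reference_skeleton <- function(muscle_file = NULL) {
  segments <- data.frame(
    name = c("pelvis", "femur", "tibia", "foot"),
    length = c(100, 396, 430, 150),
    mass = c(11.78, 9.30, 3.71, 1.50),
    com_frac = c(0.5, 0.5, 0.5, 0.4),
    stringsAsFactors = FALSE
  )
  segments$inertia <- segments$mass * (segments$length / 1000)^2 / 12  # kg m^2
  if (is.null(muscle_file))
    muscle_file <- system.file("extdata", "adult_leg_muscles_planar_synthetic.csv",
                               package = "fetalkick")
  muscles <- utils::read.csv(muscle_file, comment.char = "#",
                             stringsAsFactors = FALSE)
  if (!all(c("name", "group", "fmax_N") %in% names(muscles)))
    fk_parse_error("muscle table must have name, group, fmax_N and path columns")
  structure(list(segments = segments, muscles = muscles,
                 ankle_locked_angle = -pi / 2,  # plantargrade: heel leads into the wall
                 calcaneus = c(frac = -0.33, perp = -10),
                 scale = c(pelvis = 1, femur = 1, tibia = 1, foot = 1)),
            class = "skeleton_model")
}

#' Scale the reference model to a fetus
#'
#' Femur and tibia scale linearly by their measured-to-reference length
#' ratios; the pelvis and foot scale by the mean of those two factors;
#' masses scale with the cube of the segment factor (inertia follows from
#' the scaled mass and length).  Muscle path fractions are preserved and
#' perpendicular offsets scale with their segment; maximum isometric forces
#' are left unchanged.
#'
#' @param reference A [reference_skeleton()].
#' @param femur_mm,tibia_mm Measured segment lengths, mm.
#' @return A scaled `skeleton_model`.
#' @export
scale_model <- function(reference, femur_mm, tibia_mm) {
  stopifnot(inherits(reference, "skeleton_model"))
  femur_mm <- unname(femur_mm); tibia_mm <- unname(tibia_mm)
  if (femur_mm <= 0 || tibia_mm <= 0)
    fk_config_error("segment lengths must be positive")
  seg <- reference$segments
  f_fem <- femur_mm / seg$length[seg$name == "femur"]
  f_tib <- tibia_mm / seg$length[seg$name == "tibia"]
  f_mean <- (f_fem + f_tib) / 2
  fac <- c(pelvis = f_mean, femur = f_fem, tibia = f_tib, foot = f_mean)
  out <- reference
  out$segments$length <- seg$length * fac[seg$name]
  out$segments$mass <- seg$mass * fac[seg$name]^3
  out$segments$inertia <- out$segments$mass * (out$segments$length / 1000)^2 / 12
  out$scale <- fac * reference$scale
  out
}

seg_row <- function(model, name) model$segments[model$segments$name == name, ]

## Forward kinematics for one frame.
## q = c(femur_angle, knee_rel, ankle_rel): global femur direction angle and
## relative (tibia - femur), (foot - tibia) direction angles, radians.
## hip = hip joint position (mm).  Returns joint positions, segment
## direction/perp unit vectors, and COM positions.
fk_pose <- function(model, hip, q, pelvis_dir_angle = NULL) {
  th_f <- q[1]
  th_t <- q[1] + q[2]
  th_ft <- th_t + q[3]
  d_f <- c(cos(th_f), sin(th_f))
  d_t <- c(cos(th_t), sin(th_t))
  d_ft <- c(cos(th_ft), sin(th_ft))
  Lf <- seg_row(model, "femur")$length
  Lt <- seg_row(model, "tibia")$length
  knee <- hip + Lf * d_f
  ankle <- knee + Lt * d_t
  if (is.null(pelvis_dir_angle)) pelvis_dir_angle <- th_f
  d_p <- c(cos(pelvis_dir_angle), sin(pelvis_dir_angle))
  dirs <- rbind(pelvis = d_p, femur = d_f, tibia = d_t, foot = d_ft)
  perps <- cbind(-dirs[, 2], dirs[, 1])
  origins <- rbind(pelvis = hip, femur = hip, tibia = knee, foot = ankle)
  list(q = q, hip = hip, knee = knee, ankle = ankle,
       dirs = dirs, perps = perps, origins = origins)
}

## Global position of a (segment, frac, perp) path point at a pose.
path_point <- function(model, pose, segname, frac, perp) {
  L <- seg_row(model, segname)$length
  pose$origins[segname, ] + frac * L * pose$dirs[segname, ] +
    perp * pose$perps[segname, ]
}

## Calcaneus (heel) load point in global coordinates.
calcaneus_point <- function(model, pose) {
  path_point(model, pose, "foot", model$calcaneus["frac"],
             model$calcaneus["perp"] * model$scale["foot"])
}

## Muscle path length at a pose (polyline through up to 3 via points).
muscle_length <- function(model, pose, mrow) {
  pts <- list()
  for (k in 1:3) {
    sg <- mrow[[paste0("p", k, "_seg")]]
    if (is.na(sg) || sg == "") next
    pts[[length(pts) + 1]] <-
      path_point(model, pose, sg, mrow[[paste0("p", k, "_frac")]],
                 mrow[[paste0("p", k, "_perp")]] * model$scale[[sg]])
  }
  s <- 0
  for (k in seq_len(length(pts) - 1))
    s <- s + sqrt(sum((pts[[k + 1]] - pts[[k]])^2))
  s
}

#' Muscle moment arms at a pose
#'
#' Moment arm of each muscle about each generalized coordinate, computed as
#' minus the partial derivative of the muscle's path length with respect to
#' the coordinate (central differences).  Columns: hip (global femur
#' angle), knee (relative tibia angle), ankle (relative foot angle).
#'
#' @param model A `skeleton_model`.
#' @param hip Hip position, mm.
#' @param q Coordinates `c(femur_angle, knee_rel, ankle_rel)`, radians.
#' @param pelvis_dir_angle Frozen pelvis axis orientation (radians).
#' @return n_muscles x 3 matrix of moment arms in mm.
#' @export
moment_arms <- function(model, hip, q, pelvis_dir_angle = q[1]) {
  h <- 1e-5
  mus <- model$muscles
  out <- matrix(0, nrow(mus), 3,
                dimnames = list(mus$name, c("hip", "knee", "ankle")))
  for (i in 1:3) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    pp <- fk_pose(model, hip, qp, pelvis_dir_angle)
    pm <- fk_pose(model, hip, qm, pelvis_dir_angle)
    for (j in seq_len(nrow(mus))) {
      Lp <- muscle_length(model, pp, mus[j, ])
      Lm <- muscle_length(model, pm, mus[j, ])
      out[j, i] <- -(Lp - Lm) / (2 * h)
    }
  }
  out
}
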