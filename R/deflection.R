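#' Mean femur and tibia lengths from tracked trajectories
#'
#' The hip-knee distance is reported as the femur length and the knee-ankle
#' distance as the tibia length, averaged over frames, in mm.
#'
#' @param hip,knee,ankle `joint_trajectory` data frames (or any data frames
#'   with `x_mm`/`y_mm` columns) of equal length.
#' @return Named numeric vector `c(femur = ..., tibia = ...)` in mm.
#' @export
segment_lengths <- function(hip, knee, ankle) {
  if (nrow(hip) != nrow(knee) || nrow(knee) != nrow(ankle))
    fk_config_error("trajectories must have equal length")
  femur <- sqrt((knee$x_mm - hip$x_mm)^2 + (knee$y_mm - hip$y_mm)^2)
  tibia <- sqrt((ankle$x_mm - knee$x_mm)^2 + (ankle$y_mm - knee$y_mm)^2)
  c(femur = mean(femur), tibia = mean(tibia))
}

#' Uterine wall deflection from a tracked ankle trajectory
#'
#' The deflection is the translational displacement of the ankle joint while
#' in contact with the uterine wall: frames where the ankle lies within a
#' contact band of the cavity surface (or beyond it) form the contact
#' window, and the deflection curve is the Euclidean displacement of the
#' ankle from its position at first contact.
#'
#' @param ankle A `joint_trajectory` (needs `x_mm`, `y_mm`).
#' @param major_axis,minor_axis Outer-wall ellipse axes, mm.
#' @param wall_thickness Total wall thickness, mm (places the cavity
#'   surface).
#' @param contact_band Contact detection half-band, mm; by default half a
#'   pixel (1.1 mm at the 2.2 mm acquisition).
#' @return A `deflection_result`: list with `window` (first/last contact
#'   frame, 0-based; `NULL` when no contact), `curve` (mm per frame, 0
#'   outside the window) and `max_displacement` (mm).
#' @export
wall_deflection <- function(ankle, major_axis, minor_axis,
                            wall_thickness = 6.6, contact_band = 1.1) {
  if (major_axis <= 0 || minor_axis <= 0)
    fk_config_error("wall axes must be positive")
  pts <- cbind(ankle$x_mm, ankle$y_mm)
  sd_ <- inner_wall_signed_distance(pts, major_axis, minor_axis, wall_thickness)
  in_contact <- sd_ >= -contact_band
  n <- nrow(pts)
  curve <- numeric(n)
  if (!any(in_contact)) {
    res <- list(window = NULL, curve = curve, max_displacement = 0)
    class(res) <- "deflection_result"
    return(res)
  }
  first <- which(in_contact)[1]
  last <- max(which(in_contact))
  ref <- pts[first, ]
  idx <- first:last
  curve[idx] <- sqrt((pts[idx, 1] - ref[1])^2 + (pts[idx, 2] - ref[2])^2)
  res <- list(window = c(first, last) - 1L, curve = curve,
              max_displacement = max(curve[idx]))
  class(res) <- "deflection_result"
  res
}

#' @export
print.deflection_result <- function(x, ...) {
  if (is.null(x$window)) cat("<deflection_result> no wall contact\n")
  else cat(sprintf("<deflection_result> contact frames %d-%d, max displacement %.2f mm\n",
                   x$window[1], x$window[2], x$max_displacement))
  invisible(x)
}

#' Mean and population spread of a set of measurements
#'
#' Cohort summaries use the population standard deviation (divisor n), the
#' convention under which the three per-fetus deflections 6.40, 7.37 and
#' 7.07 mm summarise to 6.95 +/- 0.41 mm.
#'
#' @param values Non-empty numeric vector.
#' @return List with `mean` and `spread` (population SD; 0 for a single
#'   value).
#' @export
summarize <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values))
    fk_config_error("summarize() needs a non-empty numeric vector without NA")
  m <- mean(values)
  list(mean = m, spread = sqrt(mean((values - m)^2)))
}
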