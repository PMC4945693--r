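#' Run the musculoskeletal analysis for one kick
#'
#' Chains inverse kinematics, inverse dynamics (gravity neglected) and
#' quadratic static optimization for one tracked kick: the wall reaction
#' force acts at the calcaneus along the inward contact normal, ramped over
#' the contact window following the indentation force-displacement history.
#'
#' @param model A scaled `skeleton_model`.
#' @param trajectories Named list of hip/knee/ankle trajectories (mm).
#' @param force_series n x 2 matrix of external calcaneus force per frame
#'   (N), e.g. from [calcaneus_force_series()].
#' @param frame_interval Frame spacing, s.
#' @param reserve_weight,reserve_ref Passed to [static_optimization()].
#' @return List with `angles`, `moments`, `forces` (a
#'   `muscle_force_series`), `maxima` (per-muscle peak forces with group)
#'   and `group_maxima` (named vector, largest per-muscle maximum within
#'   the hip and knee groups).
#' @export
run_kick <- function(model, trajectories, force_series,
                     frame_interval = 0.303,
                     reserve_weight = 1e3, reserve_ref = 1) {
  angles <- inverse_kinematics(model, trajectories)
  moments <- inverse_dynamics(model, angles, force_series,
                              frame_interval = frame_interval)
  forces <- static_optimization(moments, model, angles,
                                reserve_weight = reserve_weight,
                                reserve_ref = reserve_ref)
  maxima <- forces$maxima
  gm <- tapply(maxima$max_force_N, maxima$group, max)
  list(angles = angles, moments = moments, forces = forces,
       maxima = maxima,
       group_maxima = c(hip = unname(gm["hip"]), knee = unname(gm["knee"])))
}

#' External calcaneus force series from tracking + indentation results
#'
#' Builds the per-frame external force at the calcaneus: zero before wall
#' contact, then directed along the inward wall normal (the wall pushes
#' back on the foot) with magnitude interpolated from the indentation
#' force-displacement history at the tracked deflection of each frame.
#'
#' @param deflection A `deflection_result` from [wall_deflection()].
#' @param fe_solution An `fe_solution` from [solve_indentation()] (its
#'   `history` maps displacement to total contact force).
#' @param contact_normal Outward wall unit normal at the contact site.
#' @param n_frames Number of frames in the kick.
#' @return n x 2 matrix of forces (N).
#' @export
calcaneus_force_series <- function(deflection, fe_solution, contact_normal,
                                   n_frames) {
  out <- matrix(0, n_frames, 2)
  if (is.null(deflection$window)) return(out)
  hist <- rbind(data.frame(displacement_mm = 0, total_N = 0),
                fe_solution$history[c("displacement_mm", "total_N")])
  idx <- (deflection$window[1]:deflection$window[2]) + 1L
  mag <- stats::approx(hist$displacement_mm, hist$total_N,
                       xout = deflection$curve[idx], rule = 2)$y
  dirn <- -contact_normal / sqrt(sum(contact_normal^2))
  out[idx, ] <- outer(mag, dirn)
  out
}

#' Write per-muscle results as CSV tables
#'
#' @param result A [run_kick()] result.
#' @param dir Output directory.
#' @export
write_msk_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- as.data.frame(result$forces$force)
  f <- cbind(frame = result$angles$frame, f)
  utils::write.csv(f, file.path(dir, "muscle_forces.csv"), row.names = FALSE)
  utils::write.csv(result$maxima, file.path(dir, "muscle_maxima.csv"),
                   row.names = FALSE)
  invisible(dir)
}
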