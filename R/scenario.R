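#' Define a fetal kick scenario
#'
#' A `kick_scenario` bundles the per-fetus geometry and kinematic parameters
#' from which a ground-truthed synthetic kick sequence is generated: limb
#' segment lengths, the elliptical uterine wall, the maximal wall deflection
#' achieved by the kick, its duration, and the imaging parameters of the
#' emulated cine acquisition (frame interval 0.303 s, in-plane pixel
#' 2.2 mm by default).
#'
#' @param gestational_age Gestational age in weeks (metadata only).
#' @param femur_length,tibia_length Segment lengths in mm (hip-knee and
#'   knee-ankle distances).
#' @param uterus_major_axis,uterus_minor_axis Outer-wall ellipse axes in mm.
#' @param max_deflection Maximal outward wall deflection of the kick, mm.
#' @param kick_duration Kick duration in seconds.
#' @param frame_interval Acquisition time per frame, seconds.
#' @param pixel_size In-plane pixel size, mm.
#' @param noise_sd Additive Gaussian noise, as a fraction of the rendered
#'   dynamic range.
#' @param blur_sigma Gaussian point-spread blur, mm.
#' @param wall_thickness Total wall thickness (membrane + muscle), mm; used
#'   to place the cavity surface the foot contacts.
#' @param contact_angle Parametric angle on the ellipse where the foot
#'   strikes the wall, radians (default the half-arc midpoint, pi/2).
#' @param contact_fraction Fraction of the kick duration elapsed at first
#'   wall contact.
#' @param hip_drift_mm Amplitude of the slow residual hip drift, mm.
#' @param probe_width Width of the fetal foot contact (controls the
#'   rendered width of the wall bump), mm.
#' @param rng_seed Integer seed making rendering reproducible.
#' @return An object of class `kick_scenario` (a validated list).
#' @seealso [generate_kick_kinematics()], [render_frames()],
#'   [reference_scenarios()]
#' @export
kick_scenario <- function(gestational_age = NA_real_,
                          femur_length,
                          tibia_length,
                          uterus_major_axis,
                          uterus_minor_axis,
                          max_deflection,
                          kick_duration,
                          frame_interval = 0.303,
                          pixel_size = 2.2,
                          noise_sd = 0.05,
                          blur_sigma = 1.5,
                          wall_thickness = 6.6,
                          contact_angle = pi / 2,
                          contact_fraction = 0.6,
                          hip_drift_mm = 0.5,
                          probe_width = 15,
                          rng_seed = 1L) {
  sc <- list(gestational_age = as.numeric(gestational_age),
             femur_length = as.numeric(femur_length),
             tibia_length = as.numeric(tibia_length),
             uterus_major_axis = as.numeric(uterus_major_axis),
             uterus_minor_axis = as.numeric(uterus_minor_axis),
             max_deflection = as.numeric(max_deflection),
             kick_duration = as.numeric(kick_duration),
             frame_interval = as.numeric(frame_interval),
             pixel_size = as.numeric(pixel_size),
             noise_sd = as.numeric(noise_sd),
             blur_sigma = as.numeric(blur_sigma),
             wall_thickness = as.numeric(wall_thickness),
             contact_angle = as.numeric(contact_angle),
             contact_fraction = as.numeric(contact_fraction),
             hip_drift_mm = as.numeric(hip_drift_mm),
             probe_width = as.numeric(probe_width),
             rng_seed = as.integer(rng_seed))
  class(sc) <- "kick_scenario"
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  need_pos <- c("femur_length", "tibia_length", "uterus_major_axis",
                "uterus_minor_axis", "kick_duration", "frame_interval",
                "pixel_size", "wall_thickness", "probe_width")
  for (f in need_pos) {
    v <- sc[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      fk_config_error(sprintf("scenario field '%s' must be a positive number", f))
  }
  if (!is.finite(sc$max_deflection) || sc$max_deflection < 0)
    fk_config_error("max_deflection must be >= 0")
  if (sc$noise_sd < 0) fk_config_error("noise_sd must be >= 0")
  if (sc$blur_sigma < 0) fk_config_error("blur_sigma must be >= 0")
  if (sc$contact_fraction <= 0 || sc$contact_fraction >= 1)
    fk_config_error("contact_fraction must be in (0, 1)")
  if (sc$femur_length + sc$tibia_length >= sc$uterus_minor_axis)
    fk_config_error("limb does not fit: femur + tibia must be < uterus_minor_axis")
  sc
}

#' Study scenarios for the three imaged fetuses
#'
#' Returns the three per-fetus scenarios used throughout: gestational ages
#' 20-22 weeks, measured femur/tibia lengths, uterine ellipse axes, maximal
#' wall deflections, and kick durations of 3.0, 2.0 and 3.3 s, at the cine
#' acquisition's 0.303 s frame interval and 2.2 mm pixels.
#'
#' @param noise_sd,rng_seed Overrides applied to every scenario (the seed is
#'   offset per fetus so sequences differ).
#' @return Named list of three `kick_scenario` objects (`A`, `B`, `C`).
#' @export
reference_scenarios <- function(noise_sd = 0.05, rng_seed = 1L) {
  tab <- data.frame(
    id = c("A", "B", "C"),
    ga = c(20, 21, 22),
    femur = c(51.02, 58.34, 52.41),
    tibia = c(54.58, 60.86, 59.81),
    major = c(160.12, 223.34, 185.09),
    minor = c(155.69, 156.88, 175.43),
    deflection = c(6.40, 7.37, 7.07),
    duration = c(3.0, 2.0, 3.3)
  )
  out <- lapply(seq_len(nrow(tab)), function(i) {
    kick_scenario(gestational_age = tab$ga[i],
                  femur_length = tab$femur[i],
                  tibia_length = tab$tibia[i],
                  uterus_major_axis = tab$major[i],
                  uterus_minor_axis = tab$minor[i],
                  max_deflection = tab$deflection[i],
                  kick_duration = tab$duration[i],
                  noise_sd = noise_sd,
                  rng_seed = as.integer(rng_seed) + (i - 1L) * 1000L)
  })
  names(out) <- tab$id
  out
}

#' Read a kick scenario from a YAML or JSON config file
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A validated `kick_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) fk_parse_error(sprintf("scenario file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else fk_parse_error(sprintf("unsupported scenario format '.%s'", ext))
  known <- names(formals(kick_scenario))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    fk_parse_error(sprintf("unknown scenario field(s): %s", paste(bad, collapse = ", ")))
  req <- c("femur_length", "tibia_length", "uterus_major_axis",
           "uterus_minor_axis", "max_deflection", "kick_duration")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    fk_parse_error(sprintf("missing scenario field(s): %s", paste(miss, collapse = ", ")))
  do.call(kick_scenario, raw)
}

#' Write a kick scenario to YAML
#' @param scenario A `kick_scenario`.
#' @param path Output file path.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "kick_scenario"))
  yaml::write_yaml(unclass(scenario), path, precision = 15L)
  invisible(path)
}

#' @export
print.kick_scenario <- function(x, ...) {
  cat(sprintf("<kick_scenario> GA %s wk | femur %.2f mm, tibia %.2f mm\n",
              format(x$gestational_age), x$femur_length, x$tibia_length))
  cat(sprintf("  uterus %.2f x %.2f mm, deflection %.2f mm, kick %.1f s (%d frames)\n",
              x$uterus_major_axis, x$uterus_minor_axis, x$max_deflection,
              x$kick_duration, n_frames(x)))
  invisible(x)
}

## Frame count: one frame at t = 0 plus one per completed acquisition
## interval within the kick duration.
n_frames <- function(scenario) {
  as.integer(floor(scenario$kick_duration / scenario$frame_interval)) + 1L
}
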