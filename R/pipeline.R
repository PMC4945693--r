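#' Run the full kick-biomechanics pipeline
#'
#' For each scenario: synthesize the ground-truthed kick sequence, track
#' the three joints with the constrained template matcher, measure the
#' wall deflection, solve the wall indentation at the tracked deflection,
#' and run the musculoskeletal analysis with the tracked kinematics and
#' the computed calcaneus force.  A failing scenario is recorded as an
#' error entry and the remaining scenarios still run.  Fully reproducible
#' under a fixed seed (each scenario's rendering seed is derived from
#' `seed` and its index).
#'
#' @param scenarios Named list of [kick_scenario()]s (e.g.
#'   [reference_scenarios()]).
#' @param seed Global integer seed.
#' @param tracking [tracking_config()].
#' @param resolution [fe_resolution()] for the wall models.
#' @param out_dir Optional directory; when given, per-scenario
#'   intermediates (truth CSV, trajectory CSV, FE reaction history, muscle
#'   maxima) are written under it.
#' @param verbose Log stage progress to stderr.
#' @return A `results_bundle`: per-scenario entries (tracked deflection,
#'   FE forces, muscle maxima, group maxima, or an `error` string) and a
#'   `summary` with cohort means and population SDs.
#' @export
run_pipeline <- function(scenarios, seed = 1L,
                         tracking = tracking_config(),
                         resolution = fe_resolution(),
                         out_dir = NULL, verbose = FALSE) {
  if (!length(scenarios)) fk_config_error("need at least one scenario")
  if (is.null(names(scenarios)))
    names(scenarios) <- sprintf("scenario%02d", seq_along(scenarios))
  say <- function(...) if (verbose) message(sprintf(...))

  results <- list()
  for (i in seq_along(scenarios)) {
    id <- names(scenarios)[i]
    sc <- scenarios[[i]]
    sc$rng_seed <- as.integer((seed + i * 9973L) %% .Machine$integer.max)
    t0 <- Sys.time()
    entry <- tryCatch({
      say("[%s] synthesize", id)
      truth <- generate_kick_kinematics(sc)
      seqs <- render_frames(truth, sc)

      say("[%s] track", id)
      seeds_px <- round(rbind(mm_to_px(joint_xy(truth, "hip"), seqs)[1, ],
                              mm_to_px(joint_xy(truth, "knee"), seqs)[1, ],
                              mm_to_px(joint_xy(truth, "ankle"), seqs)[1, ]))
      trk <- track_sequence(seqs, seeds_px, tracking)
      defl <- wall_deflection(trk$ankle, sc$uterus_major_axis,
                              sc$uterus_minor_axis, sc$wall_thickness,
                              contact_band = 0.5 * sc$pixel_size)
      lens <- segment_lengths(trk$hip, trk$knee, trk$ankle)

      say("[%s] indent wall (%.2f mm)", id, defl$max_displacement)
      geom <- uterus_geometry(sc$uterus_major_axis, sc$uterus_minor_axis,
                              probe_width = sc$probe_width,
                              contact_angle = sc$contact_angle)
      fe_model <- build_uterus_model(geom, resolution = resolution)
      fe_sol <- solve_indentation(fe_model, defl$max_displacement)

      say("[%s] musculoskeletal", id)
      skel <- scale_model(reference_skeleton(), lens["femur"], lens["tibia"])
      force_series <- calcaneus_force_series(
        defl, fe_sol, attr(truth, "contact_normal"), nrow(truth))
      msk <- run_kick(skel, trk, force_series,
                      frame_interval = sc$frame_interval)

      if (!is.null(out_dir)) {
        d <- file.path(out_dir, id)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        write_fixture(truth, seqs, file.path(d, "fixture"))
        write_trajectories(trk, file.path(d, "tracked.csv"))
        utils::write.csv(fe_sol$history, file.path(d, "fe_reactions.csv"),
                         row.names = FALSE)
        write_msk_results(msk, file.path(d, "msk"))
      }
      list(id = id,
           tracked_deflection = defl$max_displacement,
           contact_window = defl$window,
           femur_mm = unname(lens["femur"]), tibia_mm = unname(lens["tibia"]),
           fe_total_contact = fe_sol$total_contact,
           fe_max_nodal = fe_sol$max_nodal,
           muscle_maxima = msk$maxima,
           group_maxima = msk$group_maxima,
           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }, error = function(e) {
      say("[%s] FAILED: %s", id, conditionMessage(e))
      list(id = id, error = conditionMessage(e),
           error_class = class(e)[1],
           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    })
    results[[id]] <- entry
  }

  ok <- Filter(function(e) is.null(e$error), results)
  summary <- NULL
  if (length(ok)) {
    pull <- function(f) vapply(ok, `[[`, numeric(1), f)
    summary <- list(
      n = length(ok),
      deflection = summarize(pull("tracked_deflection")),
      femur = summarize(pull("femur_mm")),
      tibia = summarize(pull("tibia_mm")),
      fe_total_contact = summarize(pull("fe_total_contact")),
      fe_max_nodal = summarize(pull("fe_max_nodal")),
      hip_group_max = summarize(vapply(ok, function(e)
        e$group_maxima[["hip"]], numeric(1))),
      knee_group_max = summarize(vapply(ok, function(e)
        e$group_maxima[["knee"]], numeric(1))))
  }
  structure(list(results = results, summary = summary, seed = seed),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle> %d scenario(s), seed %d\n",
              length(x$results), x$seed))
  for (e in x$results) {
    if (!is.null(e$error))
      cat(sprintf("  %s: ERROR %s\n", e$id, e$error))
    else
      cat(sprintf("  %s: deflection %.2f mm | wall force %.3f N | muscle max hip %.2f / knee %.2f N\n",
                  e$id, e$tracked_deflection, e$fe_total_contact,
                  e$group_maxima[["hip"]], e$group_maxima[["knee"]]))
  }
  if (!is.null(x$summary))
    cat(sprintf("  cohort deflection %.2f +/- %.2f mm; wall force %.2f +/- %.2f N\n",
                x$summary$deflection$mean, x$summary$deflection$spread,
                x$summary$fe_total_contact$mean, x$summary$fe_total_contact$spread))
  invisible(x)
}

#' Write pipeline reports
#'
#' Emits a per-fetus measurement table (gestational metadata, segment
#' lengths, deflection, wall reaction forces) with a cohort mean +/-
#' population-SD row, per-muscle maxima tables split by joint group, and a
#' JSON file with all headline numbers.
#'
#' @param bundle A `results_bundle`.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  ok <- Filter(function(e) is.null(e$error), bundle$results)
  if (!length(ok)) fk_config_error("no successful scenarios to report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  per <- do.call(rbind, lapply(ok, function(e)
    data.frame(id = e$id, femur_mm = e$femur_mm, tibia_mm = e$tibia_mm,
               deflection_mm = e$tracked_deflection,
               wall_force_total_N = e$fe_total_contact,
               wall_force_max_nodal_N = e$fe_max_nodal)))
  avg <- data.frame(id = "average",
                    femur_mm = NA, tibia_mm = NA, deflection_mm = NA,
                    wall_force_total_N = NA, wall_force_max_nodal_N = NA)
  fmt <- function(s) sprintf("%.2f +/- %.2f", s$mean, s$spread)
  meas_path <- file.path(dir, "measurements.csv")
  utils::write.csv(per, meas_path, row.names = FALSE)
  cat(sprintf("average: femur %s, tibia %s, deflection %s mm, wall force %s N\n",
              fmt(bundle$summary$femur), fmt(bundle$summary$tibia),
              fmt(bundle$summary$deflection),
              fmt(bundle$summary$fe_total_contact)),
      file = file.path(dir, "measurements_summary.txt"))

  mm <- do.call(rbind, lapply(ok, function(e) {
    d <- e$muscle_maxima; d$id <- e$id; d
  }))
  for (grp in c("hip", "knee")) {
    wide <- stats::reshape(mm[mm$group == grp, c("id", "muscle", "max_force_N")],
                           idvar = "id", timevar = "muscle", direction = "wide")
    names(wide) <- sub("^max_force_N\\.", "", names(wide))
    utils::write.csv(wide, file.path(dir, sprintf("muscle_maxima_%s.csv", grp)),
                     row.names = FALSE)
  }

  headline <- list(
    seed = bundle$seed,
    n_scenarios = length(ok),
    per_fetus = per,
    cohort = lapply(bundle$summary[-1], function(s)
      if (is.list(s)) list(mean = s$mean, spread = s$spread) else s))
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(headline, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(meas_path, json_path))
}
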