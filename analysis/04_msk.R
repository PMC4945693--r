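#!/usr/bin/env Rscript
## Scale the planar leg model to each fetus, run inverse kinematics /
## inverse dynamics / static optimization with the tracked kinematics and
## the computed wall reaction at the calcaneus.  Outputs under results/msk/.

library(fetalkick)

scenarios <- reference_scenarios()
meas <- read.csv("results/tracking/measurements.csv")
dir.create("results/msk", recursive = TRUE, showWarnings = FALSE)

group_rows <- list()
for (i in seq_len(nrow(meas))) {
  id <- meas$id[i]
  sc <- scenarios[[id]]
  fix <- read_fixture(file.path("results/fixtures", id))
  trk_tab <- read.csv(file.path("results/tracking", paste0(id, ".csv")))
  trk <- fetalkick:::trajectories_from_truth(
    structure(trk_tab, class = c("kick_truth", "data.frame")))

  defl <- wall_deflection(trk$ankle, sc$uterus_major_axis, sc$uterus_minor_axis)
  geom <- uterus_geometry(sc$uterus_major_axis, sc$uterus_minor_axis)
  sol <- solve_indentation(build_uterus_model(geom), defl$max_displacement)
  model <- scale_model(reference_skeleton(), meas$femur_mm[i], meas$tibia_mm[i])
  fs <- calcaneus_force_series(defl, sol, attr(generate_kick_kinematics(sc),
                                               "contact_normal"), nrow(trk_tab))
  res <- run_kick(model, trk, fs, frame_interval = sc$frame_interval)
  write_msk_results(res, file.path("results/msk", id))
  group_rows[[id]] <- data.frame(id = id,
                                 hip_group_max_N = res$group_maxima[["hip"]],
                                 knee_group_max_N = res$group_maxima[["knee"]])
  message(sprintf("fetus %s: hip-group max %.2f N, knee-group max %.2f N",
                  id, res$group_maxima[["hip"]], res$group_maxima[["knee"]]))
}
tab <- do.call(rbind, group_rows)
write.csv(tab, "results/msk/group_maxima.csv", row.names = FALSE)
message(sprintf("knee group exceeds hip group in %d/%d fetuses",
                sum(tab$knee_group_max_N > tab$hip_group_max_N), nrow(tab)))
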