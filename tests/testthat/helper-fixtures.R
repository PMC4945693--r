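## Shared fixture builders (everything generated in code at test time).

## A small, fast scenario (not one of the study fetuses) for unit tests.
toy_scenario <- function(...) {
  args <- utils::modifyList(
    list(femur_length = 40, tibia_length = 45,
         uterus_major_axis = 130, uterus_minor_axis = 120,
         max_deflection = 5, kick_duration = 2.0, rng_seed = 42L),
    list(...))
  do.call(kick_scenario, args)
}

## Generate truth + frames + integer seeds + per-joint truth in px.
make_tracked_case <- function(scenario) {
  truth <- generate_kick_kinematics(scenario)
  seqs <- render_frames(truth, scenario)
  tpx <- lapply(c("hip", "knee", "ankle"), function(j)
    fetalkick:::mm_to_px(fetalkick:::joint_xy(truth, j), seqs))
  names(tpx) <- c("hip", "knee", "ankle")
  seeds <- round(rbind(tpx$hip[1, ], tpx$knee[1, ], tpx$ankle[1, ]))
  list(truth = truth, seqs = seqs, tpx = tpx, seeds = seeds)
}

track_errors_px <- function(case, config = tracking_config()) {
  trk <- track_sequence(case$seqs, case$seeds, config)
  sapply(c("hip", "knee", "ankle"), function(j)
    sqrt((trk[[j]]$x_px - case$tpx[[j]][, 1])^2 +
         (trk[[j]]$y_px - case$tpx[[j]][, 2])^2))
}

## Simple rectangular mesh for element-level FE tests.
rect_mesh <- function(nx, ny, Lx, Ly, E = 1000, nu = 0.3, thickness = 1) {
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  nn <- (nx + 1) * (ny + 1)
  nodes <- cbind(rep(xs, each = ny + 1), rep(ys, nx + 1))
  idx <- matrix(seq_len(nn), ny + 1, nx + 1)
  elems <- fetalkick:::orient_elems(nodes, fetalkick:::grid_elems(idx))
  ne <- nrow(elems)
  structure(list(nodes = nodes, elems = elems, region = rep("m", ne),
                 E = rep(E, ne), nu = rep(nu, ne), thickness_mm = thickness),
            class = "fe_mesh")
}

## Coarse-but-valid uterus resolution for fast solves in unit tests.
fast_resolution <- function() fe_resolution(n_membrane = 2L, n_muscle = 4L,
                                            size_near = 3, size_far = 10)

scaled_leg <- function(femur = 51.02, tibia = 54.58)
  scale_model(reference_skeleton(), femur, tibia)

## Trajectory list at a fixed pose (n frames, static).
static_trajectories <- function(model, hip, q, n = 5) {
  p <- fetalkick:::fk_pose(model, hip, c(q, model$ankle_locked_angle))
  mk <- function(pt) data.frame(x_mm = rep(pt[1], n), y_mm = rep(pt[2], n))
  list(hip = mk(hip), knee = mk(p$knee), ankle = mk(p$ankle))
}
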