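#' Tracking configuration
#'
#' Parameters of the constrained template-matching tracker: template size,
#' the maximum plausible inter-frame joint motion, the allowed fractional
#' change of the running femur/tibia lengths (out-of-plane slack), the
#' recency weighting of accumulated templates, and the minimum acceptable
#' match score.
#'
#' @param template_halfwidth Template patch half-width, px (patch is
#'   `2 * halfwidth + 1` square).
#' @param search_radius Maximum inter-frame joint motion, px.
#' @param length_tolerance Allowed fractional deviation of the hip-knee and
#'   knee-ankle distances from their running values (default 0.10).
#' @param recency_decay Geometric weight factor per frame of template age,
#'   in (0, 1]; recent frames weigh more.
#' @param min_match_score Minimum weighted correlation for a match to be
#'   accepted.
#' @param max_templates Templates retained per joint (oldest dropped; the
#'   frame-0 seed template is always kept).
#' @param anchor_weight Guaranteed weight share of the frame-0 (manually
#'   seeded) template, limiting template-update drift; must stay small
#'   enough that the most recent template keeps the largest weight.
#' @param length_ema_alpha Update rate of the running segment lengths.
#' @return A `tracking_config` list.
#' @export
tracking_config <- function(template_halfwidth = 3L,
                            search_radius = 8L,
                            length_tolerance = 0.10,
                            recency_decay = 0.8,
                            min_match_score = 0.4,
                            max_templates = 16L,
                            anchor_weight = 0.1,
                            length_ema_alpha = 0.3) {
  if (length_tolerance <= 0 || length_tolerance >= 1)
    fk_config_error("length_tolerance must be in (0, 1)")
  if (template_halfwidth < 1) fk_config_error("template_halfwidth must be >= 1")
  if (search_radius < 1) fk_config_error("search_radius must be >= 1")
  if (recency_decay <= 0 || recency_decay > 1)
    fk_config_error("recency_decay must be in (0, 1]")
  if (anchor_weight < 0 || anchor_weight >= 0.5)
    fk_config_error("anchor_weight must be in [0, 0.5)")
  structure(list(template_halfwidth = as.integer(template_halfwidth),
                 search_radius = as.integer(search_radius),
                 length_tolerance = length_tolerance,
                 recency_decay = recency_decay,
                 min_match_score = min_match_score,
                 max_templates = as.integer(max_templates),
                 anchor_weight = anchor_weight,
                 length_ema_alpha = length_ema_alpha),
            class = "tracking_config")
}

## --- template ensembles ----------------------------------------------------

new_ensemble <- function(patch) {
  v <- stats::var(as.vector(patch))
  if (!is.finite(v) || v <= 0)
    fk_degenerate_match("initial template has zero intensity variance")
  structure(list(patches = list(patch)), class = "template_ensemble")
}

ensemble_add <- function(ensemble, patch, max_templates) {
  if (stats::var(as.vector(patch)) > 0)
    ensemble$patches <- c(ensemble$patches, list(patch))
  n <- length(ensemble$patches)
  if (n > max_templates)  # drop oldest but keep the frame-0 seed template
    ensemble$patches <- ensemble$patches[c(1, (n - max_templates + 2):n)]
  ensemble
}

## Normalised recency weights, most recent template last and largest.  The
## first (seed) template keeps a guaranteed `anchor` share so accumulated
## updates cannot drift arbitrarily far from the operator's selection.
ensemble_weights <- function(ensemble, decay, anchor = 0) {
  n <- length(ensemble$patches)
  w <- decay^((n - 1):0)
  w <- w / sum(w)
  if (anchor > 0 && n > 1) {
    w <- (1 - anchor) * w
    w[1] <- w[1] + anchor
  }
  w
}

## Extract the (2h+1)^2 patch centred at 0-based pixel (x, y); NULL if it
## leaves the frame.
extract_patch <- function(frame, x, y, h) {
  rows <- (y - h):(y + h) + 1L
  cols <- (x - h):(x + h) + 1L
  if (rows[1] < 1 || cols[1] < 1 || rows[length(rows)] > nrow(frame) ||
      cols[length(cols)] > ncol(frame)) return(NULL)
  frame[rows, cols, drop = FALSE]
}

#' Match a template ensemble within a frame region
#'
#' Scores every candidate centre by the weight-averaged zero-normalised
#' cross-correlation between the accumulated templates and the image patch
#' at that centre, and returns the best-scoring position.  Ties are broken
#' by smallest row-major candidate index for reproducibility.
#'
#' @param frame 2D intensity matrix (row = y).
#' @param ensemble A template ensemble (internal) or a single patch matrix.
#' @param region Either an integer rectangle `list(xmin, xmax, ymin, ymax)`
#'   in 0-based pixel coordinates, or an n x 2 matrix of candidate centres.
#' @param decay Recency weight factor per frame of template age.
#' @param subpixel If `TRUE`, refine the best match to subpixel precision by
#'   a separable quadratic fit of the correlation surface over the
#'   neighbouring candidates.
#' @param anchor_weight Guaranteed weight share of the first template.
#' @return List with `position` (0-based px), `score` in `[-1, 1]`, and the
#'   per-candidate score vector.
#' @export
ncc_match <- function(frame, ensemble, region, decay = 0.8, subpixel = FALSE,
                      anchor_weight = 0) {
  if (is.matrix(ensemble)) ensemble <- new_ensemble(ensemble)
  patches <- ensemble$patches
  w <- ensemble_weights(ensemble, decay, anchor_weight)
  h <- (nrow(patches[[1]]) - 1L) %/% 2L
  tvecs <- lapply(patches, function(p) {
    v <- as.vector(p) - mean(p)
    s <- sqrt(sum(v^2))
    if (s <= 0) fk_degenerate_match("template has zero intensity variance")
    v / s
  })

  if (is.list(region) && !is.null(region$xmin)) {
    cand <- as.matrix(expand.grid(x = region$xmin:region$xmax,
                                  y = region$ymin:region$ymax))
  } else {
    cand <- rbind(region)
    colnames(cand) <- c("x", "y")
  }
  ## Row-major candidate order (y major, then x) for deterministic ties.
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]

  scores <- rep(NA_real_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- extract_patch(frame, cand[i, 1], cand[i, 2], h)
    if (is.null(p)) next
    pv <- as.vector(p) - mean(p)
    s <- sqrt(sum(pv^2))
    if (s <= 0) next
    pv <- pv / s
    scores[i] <- sum(w * vapply(tvecs, function(tv) sum(tv * pv), numeric(1)))
  }
  if (all(is.na(scores)))
    fk_degenerate_match("no valid candidate: search region flat or outside the frame")
  best <- which.max(scores)  # first max = smallest row-major index
  pos <- as.numeric(cand[best, ])
  if (subpixel) {
    sc_at <- function(dx, dy) {
      i <- which(cand[, 1] == pos[1] + dx & cand[, 2] == pos[2] + dy)
      if (length(i) == 1 && is.finite(scores[i])) scores[i] else NA_real_
    }
    s0 <- scores[best]
    para <- function(sm, sp) {
      if (is.na(sm) || is.na(sp)) return(0)
      den <- sm - 2 * s0 + sp
      if (den >= -1e-12) return(0)  # not a local peak
      max(min(0.5 * (sm - sp) / den, 0.5), -0.5)
    }
    pos <- pos + c(para(sc_at(-1, 0), sc_at(1, 0)),
                   para(sc_at(0, -1), sc_at(0, 1)))
  }
  list(position = pos, score = scores[best], scores = scores)
}

## --- per-frame tracking ----------------------------------------------------

## Candidate centres inside a disc around a 0-based pixel position.
disc_candidates <- function(center, radius, dim_yx) {
  cx <- round(center[1]); cy <- round(center[2])
  xs <- (cx - radius):(cx + radius)
  ys <- (cy - radius):(cy + radius)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  g <- g[(g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 <= radius^2 + 1e-9, ,
         drop = FALSE]
  g[g[, 1] >= 0 & g[, 2] >= 0 & g[, 1] < dim_yx[2] & g[, 2] < dim_yx[1], ,
    drop = FALSE]
}

## Refine a seed to the local intensity peak by a separable quadratic fit
## over the 3x3 neighbourhood (the operator clicks near, not exactly on,
## the joint centre).  Returns a continuous 0-based pixel position.
refine_seed <- function(frame, seed) {
  r0 <- round(seed)
  x <- r0[1]; y <- r0[2]
  if (x < 1 || y < 1 || x > ncol(frame) - 2 || y > nrow(frame) - 2) return(r0)
  s <- function(dx, dy) frame[y + dy + 1L, x + dx + 1L]
  para <- function(sm, s0, sp) {
    den <- sm - 2 * s0 + sp
    if (den >= -1e-12) return(0)
    max(min(0.5 * (sm - sp) / den, 0.5), -0.5)
  }
  r0 + c(para(s(-1, 0), s(0, 0), s(1, 0)), para(s(0, -1), s(0, 0), s(0, 1)))
}

init_track_state <- function(frame0, seeds_px, config, pixel_size, origin) {
  d <- dim(frame0)
  seeds_px <- rbind(seeds_px)
  if (nrow(seeds_px) != 3) fk_config_error("need three seed points (hip, knee, ankle)")
  for (i in 1:3) {
    s <- seeds_px[i, ]
    if (any(s < 0) || s[1] >= d[2] || s[2] >= d[1])
      fk_config_error(sprintf("seed %d at (%.1f, %.1f) lies outside the frame", i, s[1], s[2]))
  }
  ## Snap each seed to the local intensity peak; templates live on the
  ## integer grid, and the residual fractional offset is carried through to
  ## every reported position.
  refined <- t(vapply(1:3, function(i) refine_seed(frame0, seeds_px[i, ]),
                      numeric(2)))
  anchors <- round(refined)
  offsets <- refined - anchors
  h <- config$template_halfwidth
  ens <- lapply(1:3, function(i) {
    p <- extract_patch(frame0, anchors[i, 1], anchors[i, 2], h)
    if (is.null(p))
      fk_config_error(sprintf("seed %d too close to the frame border for the template size", i))
    new_ensemble(p)
  })
  names(ens) <- c("hip", "knee", "ankle")
  femur_px <- sqrt(sum((refined[2, ] - refined[1, ])^2))
  tibia_px <- sqrt(sum((refined[3, ] - refined[2, ])^2))
  list(frame_idx = 0L,
       positions = anchors,
       offsets = offsets,
       scores = c(hip = 1, knee = 1, ankle = 1),
       ensembles = ens,
       femur_px = femur_px, tibia_px = tibia_px,
       config = config, pixel_size = pixel_size, origin = origin,
       history = list(positions = list(refined),
                      scores = list(c(hip = 1, knee = 1, ankle = 1))))
}

#' Advance the tracker by one frame
#'
#' Matches the hip within a disc of `search_radius` around its previous
#' position; knee candidates are restricted to positions both within
#' `search_radius` of the previous knee and whose distance to the new hip
#' lies within `length_tolerance` of the running femur length; the ankle is
#' found likewise against the running tibia length.  Running lengths are
#' updated by an exponential moving average and template ensembles are
#' extended with the newly matched patches.
#'
#' @param state Tracker state from `init_track_state` or a previous call.
#' @param frame Next 2D intensity frame.
#' @return Updated state.
#' @export
track_frame <- function(state, frame) {
  cfg <- state$config
  d <- dim(frame)
  r <- cfg$search_radius

  match_joint <- function(joint, prev, extra_filter = NULL) {
    cand <- disc_candidates(prev, r, d)
    if (!is.null(extra_filter)) cand <- extra_filter(cand)
    if (nrow(cand) == 0)
      fk_track_lost(sprintf("track lost: no admissible %s candidate at frame %d",
                            joint, state$frame_idx + 1L))
    m <- tryCatch(ncc_match(frame, state$ensembles[[joint]], cand,
                            decay = cfg$recency_decay, subpixel = TRUE,
                            anchor_weight = cfg$anchor_weight),
                  fk_degenerate_match = function(e)
                    fk_track_lost(sprintf("track lost: degenerate match for %s at frame %d",
                                          joint, state$frame_idx + 1L)))
    if (m$score < cfg$min_match_score)
      fk_track_lost(sprintf("track lost: best %s score %.3f below threshold at frame %d",
                            joint, m$score, state$frame_idx + 1L))
    m
  }

  prev <- state$positions
  hip_m <- match_joint("hip", prev[1, ])
  hip_new <- hip_m$position

  annulus <- function(ref, length_px) {
    lo <- (1 - cfg$length_tolerance) * length_px
    hi <- (1 + cfg$length_tolerance) * length_px
    function(cand) {
      dd <- sqrt((cand[, 1] - ref[1])^2 + (cand[, 2] - ref[2])^2)
      cand[dd >= lo & dd <= hi, , drop = FALSE]
    }
  }
  knee_m <- match_joint("knee", prev[2, ], annulus(hip_new, state$femur_px))
  knee_new <- knee_m$position
  ankle_m <- match_joint("ankle", prev[3, ], annulus(knee_new, state$tibia_px))
  ankle_new <- ankle_m$position

  h <- cfg$template_halfwidth
  pos <- rbind(hip_new, knee_new, ankle_new)
  for (i in 1:3) {
    joint <- c("hip", "knee", "ankle")[i]
    p <- extract_patch(frame, round(pos[i, 1]), round(pos[i, 2]), h)
    if (!is.null(p))
      state$ensembles[[joint]] <- ensemble_add(state$ensembles[[joint]], p,
                                               cfg$max_templates)
  }
  a <- cfg$length_ema_alpha
  state$femur_px <- (1 - a) * state$femur_px +
    a * sqrt(sum((knee_new - hip_new)^2))
  state$tibia_px <- (1 - a) * state$tibia_px +
    a * sqrt(sum((ankle_new - knee_new)^2))
  state$positions <- pos
  state$scores <- c(hip = hip_m$score, knee = knee_m$score, ankle = ankle_m$score)
  state$frame_idx <- state$frame_idx + 1L
  state$history$positions <- c(state$history$positions,
                               list(pos + state$offsets))
  state$history$scores <- c(state$history$scores, list(state$scores))
  state
}

#' Track hip, knee and ankle through an image sequence
#'
#' Runs the accumulated-template tracker over all frames, starting from
#' manually supplied seed points on frame 0 (which also provide the initial
#' femur and tibia lengths).  Deterministic: identical inputs yield
#' identical trajectories.
#'
#' @param sequence An `image_sequence`.
#' @param seeds 3 x 2 matrix of 0-based pixel seed positions (hip, knee,
#'   ankle rows) on frame 0.
#' @param config A [tracking_config()].
#' @return Named list of three `joint_trajectory` data frames (`hip`,
#'   `knee`, `ankle`), each with per-frame pixel and mm positions, match
#'   score and validity flag.
#' @export
track_sequence <- function(sequence, seeds, config = tracking_config()) {
  stopifnot(inherits(sequence, "image_sequence"))
  state <- init_track_state(sequence$frames[[1]], seeds, config,
                            sequence$pixel_size, sequence$origin)
  n <- length(sequence$frames)
  if (n > 1)
    for (i in 2:n) state <- track_frame(state, sequence$frames[[i]])

  joints <- c("hip", "knee", "ankle")
  out <- lapply(seq_along(joints), function(j) {
    px <- t(vapply(state$history$positions, function(p) p[j, ], numeric(2)))
    mm <- px_to_mm(px, sequence)
    sc <- vapply(state$history$scores, function(s) s[[j]], numeric(1))
    structure(data.frame(frame = 0:(n - 1),
                         time_s = (0:(n - 1)) * sequence$frame_interval,
                         x_px = px[, 1], y_px = px[, 2],
                         x_mm = mm[, 1], y_mm = mm[, 2],
                         score = sc, valid = TRUE),
              class = c("joint_trajectory", "data.frame"), joint = joints[j])
  })
  names(out) <- joints
  out
}

#' Write tracked trajectories in the ground-truth CSV layout
#'
#' @param trajectories Result of [track_sequence()].
#' @param path Output CSV path.
#' @export
write_trajectories <- function(trajectories, path) {
  df <- data.frame(frame = trajectories$hip$frame,
                   time_s = trajectories$hip$time_s,
                   hip_x = trajectories$hip$x_mm, hip_y = trajectories$hip$y_mm,
                   knee_x = trajectories$knee$x_mm, knee_y = trajectories$knee$y_mm,
                   ankle_x = trajectories$ankle$x_mm, ankle_y = trajectories$ankle$y_mm,
                   contact = NA, deflection_mm = NA)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
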