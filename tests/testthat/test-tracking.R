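test_that("an exact sub-patch template scores 1 at its true location", {
  set.seed(1)
  frame <- matrix(runif(40 * 40), 40, 40)
  patch <- fetalkick:::extract_patch(frame, 20L, 15L, 3L)
  cand <- fetalkick:::disc_candidates(c(20, 15), 4L, dim(frame))
  m <- ncc_match(frame, patch, cand)
  expect_equal(m$position, c(20, 15))
  expect_equal(m$score, 1.0, tolerance = 1e-12)
})

test_that("flat search regions are rejected as degenerate", {
  frame <- matrix(0.5, 40, 40)
  frame[1:5, 1:5] <- matrix(runif(25), 5)  # template area has texture
  patch <- fetalkick:::extract_patch(frame, 2L, 2L, 1L)
  cand <- fetalkick:::disc_candidates(c(25, 25), 3L, dim(frame))
  expect_error(ncc_match(frame, patch, cand), class = "fk_degenerate_match")
})

test_that("ensemble scores are the recency-weighted mean of per-template ZNCC", {
  set.seed(2)
  frame <- matrix(runif(30 * 30), 30, 30)
  t1 <- matrix(runif(49), 7, 7)
  t2 <- matrix(runif(49), 7, 7)
  ens <- fetalkick:::new_ensemble(t1)
  ens <- fetalkick:::ensemble_add(ens, t2, 10L)
  decay <- 0.25 / 0.75  # weights 0.25 (older t1), 0.75 (recent t2)
  w <- fetalkick:::ensemble_weights(ens, decay)
  expect_equal(w, c(0.25, 0.75))
  pos <- c(12, 14)
  patch <- fetalkick:::extract_patch(frame, pos[1], pos[2], 3L)
  manual <- 0.25 * cor(as.vector(t1), as.vector(patch)) +
            0.75 * cor(as.vector(t2), as.vector(patch))
  m <- ncc_match(frame, ens, rbind(pos), decay = decay)
  expect_equal(m$score, manual, tolerance = 1e-12)
})

test_that("noiseless synthetic sequences are recovered within one pixel", {
  for (sc in list(toy_scenario(noise_sd = 0),
                  reference_scenarios(noise_sd = 0)$A)) {
    case <- make_tracked_case(sc)
    errs <- track_errors_px(case)
    expect_lt(max(errs), 1.0)
  }
})

test_that("a high-scoring decoy outside the length annulus is rejected", {
  sc <- toy_scenario(noise_sd = 0)
  case <- make_tracked_case(sc)
  seqs <- case$seqs
  ## paste an exact copy of the frame-1 knee appearance far from the knee,
  ## well outside the +/-10% femur-length annulus but inside the search disc
  fr <- seqs$frames[[2]]
  knee1 <- round(case$tpx$knee[2, ])
  hip1 <- case$tpx$hip[2, ]
  ## place the decoy 6 px from the previous knee, radially toward the hip so
  ## it breaks the femur-length annulus while staying inside the search disc
  prev <- case$tpx$knee[1, ]
  u <- (hip1 - prev) / sqrt(sum((hip1 - prev)^2))
  decoy <- round(prev + 6 * u)
  stopifnot(sqrt(sum((decoy - prev)^2)) <= 8)
  patch <- fetalkick:::extract_patch(fr, knee1[1], knee1[2], 3L)
  rows <- decoy[2] + (-3:3) + 1L; cols <- decoy[1] + (-3:3) + 1L
  fr[rows, cols] <- patch * 1.05  # slightly brighter copy
  seqs$frames[[2]] <- fr
  femur_px <- sqrt(sum((case$tpx$knee[1, ] - case$tpx$hip[1, ])^2))
  ## the decoy must violate the annulus around the running femur length
  stopifnot(abs(sqrt(sum((decoy - hip1)^2)) - femur_px) > 0.12 * femur_px)
  trk <- track_sequence(seqs, case$seeds, tracking_config())
  err_knee <- sqrt(sum((c(trk$knee$x_px[2], trk$knee$y_px[2]) -
                        case$tpx$knee[2, ])^2))
  expect_lt(err_knee, 1.5)  # stayed on the true knee, not the decoy
})

test_that("pure-noise frames lose the track with a classed error", {
  sc <- toy_scenario(noise_sd = 0)
  case <- make_tracked_case(sc)
  seqs <- case$seqs
  set.seed(3)
  seqs$frames[[3]] <- matrix(rnorm(prod(dim(seqs$frames[[1]]))),
                             nrow(seqs$frames[[1]]))
  expect_error(track_sequence(seqs, case$seeds), class = "fk_track_lost")
})

test_that("single-frame sequences return the (refined) seeds", {
  sc <- toy_scenario()
  case <- make_tracked_case(sc)
  seqs <- case$seqs
  seqs$frames <- seqs$frames[1]
  trk <- track_sequence(seqs, case$seeds)
  expect_equal(nrow(trk$hip), 1L)
  for (j in 1:3)
    expect_lt(sqrt(sum((c(trk[[j]]$x_px, trk[[j]]$y_px) -
                        case$seeds[j, ])^2)), 1.0)
})

test_that("seeds outside the frame raise a precondition error", {
  sc <- toy_scenario()
  case <- make_tracked_case(sc)
  bad <- case$seeds; bad[1, ] <- c(-3, 10)
  expect_error(track_sequence(case$seqs, bad), class = "fk_config_error")
})

test_that("tracking is deterministic and respects the length constraint", {
  case <- make_tracked_case(toy_scenario())
  t1 <- track_sequence(case$seqs, case$seeds)
  t2 <- track_sequence(case$seqs, case$seeds)
  expect_identical(t1, t2)
  fem <- sqrt((t1$knee$x_px - t1$hip$x_px)^2 + (t1$knee$y_px - t1$hip$y_px)^2)
  tib <- sqrt((t1$ankle$x_px - t1$knee$x_px)^2 + (t1$ankle$y_px - t1$knee$y_px)^2)
  expect_true(all(abs(fem - mean(fem)) / mean(fem) < 0.10))
  expect_true(all(abs(tib - mean(tib)) / mean(tib) < 0.10))
})
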