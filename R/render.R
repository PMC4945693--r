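#' Render a synthetic cine-MRI-like image sequence
#'
#' Rasterises a ground-truth kick trajectory into grayscale frames that
#' emulate the appearance of a thick-slice cine acquisition: the uterine
#' wall as a bright elliptical band (locally bulged outward under the ankle
#' by the current deflection), femur and tibia as bright capsules, joints as
#' Gaussian blobs, followed by Gaussian blur and additive Gaussian noise.
#' Rendering is seeded by the scenario and fully reproducible.
#'
#' @param truth A `kick_truth` trajectory from [generate_kick_kinematics()].
#' @param scenario The matching [kick_scenario()].
#' @param margin_mm Margin added around the outer wall ellipse, mm.
#' @return An `image_sequence`: list with `frames` (list of matrices, row =
#'   y, column = x, intensities in arbitrary units), `pixel_size` (mm),
#'   `frame_interval` (s) and `origin` (mm position of the corner of pixel
#'   (0, 0); pixel centres sit at `origin + (index + 0.5) * pixel_size`).
#' @export
render_frames <- function(truth, scenario, margin_mm = 16) {
  stopifnot(inherits(truth, "kick_truth"), inherits(scenario, "kick_scenario"))
  sc <- scenario
  if (sc$pixel_size <= 0) fk_config_error("pixel_size must be > 0")
  p <- sc$pixel_size
  a <- sc$uterus_major_axis / 2
  b <- sc$uterus_minor_axis / 2

  nx <- as.integer(ceiling((sc$uterus_major_axis + 2 * margin_mm) / p))
  ny <- as.integer(ceiling((sc$uterus_minor_axis + 2 * margin_mm) / p))
  origin <- c(-(nx * p) / 2, -(ny * p) / 2)
  xs <- origin[1] + (seq_len(nx) - 0.5) * p
  ys <- origin[2] + (seq_len(ny) - 0.5) * p
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)

  ## Per-pixel ellipse parameter and normalised outer radius.
  theta_px <- atan2(Y / b, X / a)
  rho <- sqrt((X / a)^2 + (Y / b)^2)
  ## Normalised radius of the (undeformed) cavity surface at each pixel's
  ## parameter: the outer point offset inward by the wall thickness.
  n_px_x <- cos(theta_px) / a
  n_px_y <- sin(theta_px) / b
  n_len <- sqrt(n_px_x^2 + n_px_y^2)
  in_x <- a * cos(theta_px) - sc$wall_thickness * n_px_x / n_len
  in_y <- b * sin(theta_px) - sc$wall_thickness * n_px_y / n_len
  rho_in0 <- sqrt((in_x / a)^2 + (in_y / b)^2)

  cpt_theta <- sc$contact_angle
  arc_all <- ellipse_arclength(a, b, seq(0, 2 * pi, length.out = 721),
                               depth = sc$wall_thickness)
  arc_of <- function(th) stats::approx(seq(0, 2 * pi, length.out = 721),
                                       arc_all, xout = th %% (2 * pi), rule = 2)$y
  s_contact <- arc_of(cpt_theta)
  bump_sd <- sc$probe_width / 2

  n <- nrow(truth)
  frames <- vector("list", n)
  with_seed(sc$rng_seed, {
    for (i in seq_len(n)) {
      img <- matrix(0, ny, nx)
      ## Wall band with local outward bump under the ankle.
      d_i <- truth$deflection_mm[i]
      rho_in <- rho_in0
      if (d_i > 0) {
        s_px <- arc_of(theta_px)
        ds <- abs(s_px - s_contact)
        total <- max(arc_all)
        ds <- pmin(ds, total - ds)
        bump <- d_i * exp(-0.5 * (ds / bump_sd)^2)
        ## Displace the cavity boundary outward along the local normal and
        ## re-express it as a normalised radius.
        bx <- in_x + bump * n_px_x / n_len
        by <- in_y + bump * n_px_y / n_len
        rho_in <- sqrt((bx / a)^2 + (by / b)^2)
      }
      img[rho >= rho_in & rho <= 1] <- 0.5

      hip <- c(truth$hip_x[i], truth$hip_y[i])
      knee <- c(truth$knee_x[i], truth$knee_y[i])
      ankle <- c(truth$ankle_x[i], truth$ankle_y[i])
      img <- img + 0.25 * capsule_mask(X, Y, hip, knee, 3) +
                   0.25 * capsule_mask(X, Y, knee, ankle, 3)
      for (jp in list(hip, knee, ankle)) {
        r2 <- (X - jp[1])^2 + (Y - jp[2])^2
        img <- img + 1.2 * exp(-0.5 * r2 / 2.4^2)
      }
      if (sc$blur_sigma > 0) img <- gaussian_blur(img, sc$blur_sigma / p)
      if (sc$noise_sd > 0)
        img <- img + matrix(stats::rnorm(ny * nx, sd = sc$noise_sd), ny, nx)
      frames[[i]] <- img
    }
  })
  structure(list(frames = frames, pixel_size = p,
                 frame_interval = sc$frame_interval, origin = origin),
            class = "image_sequence")
}

capsule_mask <- function(X, Y, p1, p2, radius) {
  v <- p2 - p1
  L2 <- sum(v^2)
  t <- ((X - p1[1]) * v[1] + (Y - p1[2]) * v[2]) / max(L2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  d2 <- (X - (p1[1] + t * v[1]))^2 + (Y - (p1[2] + t * v[2]))^2
  (d2 < radius^2) * 1
}

## Separable Gaussian blur with a truncated discrete kernel (reflected
## edges); sigma in pixels.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  h <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- stats::dnorm(-h:h, sd = sigma_px)
  k <- k / sum(k)
  img <- apply_kernel_rows(img, k)
  t(apply_kernel_rows(t(img), k))
}

apply_kernel_rows <- function(img, k) {
  h <- (length(k) - 1L) / 2L
  n <- ncol(img)
  idx <- outer(seq_len(n), -h:h, "+")
  idx <- pmin(pmax(idx, 1L), n)  # replicate edges
  out <- matrix(0, nrow(img), n)
  for (j in seq_along(k)) out <- out + img[, idx[, j]] * k[j]
  out
}

## Convert between mm coordinates and continuous pixel coordinates
## (0-based; pixel centre c(i, j) is at origin + (c(i, j) + 0.5) * pixel).
mm_to_px <- function(pts, sequence) {
  sweep(rbind(pts), 2, sequence$origin) / sequence$pixel_size - 0.5
}

px_to_mm <- function(px, sequence) {
  sweep((rbind(px) + 0.5) * sequence$pixel_size, 2, sequence$origin, "+")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_sequence> %d frames of %d x %d px (%.1f mm/px, %.3f s/frame)\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}
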