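## Elliptical uterine-wall geometry helpers.
##
## The outer wall is the ellipse (x/a)^2 + (y/b)^2 = 1 with a = major_axis/2,
## b = minor_axis/2, centred at the origin with x along the major axis.  The
## cavity (inner) surface is the outer ellipse offset inward along its local
## normal by the total wall thickness.  All lengths in mm.

ellipse_point <- function(a, b, theta) {
  cbind(a * cos(theta), b * sin(theta))
}

## Unit outward normal of the outer ellipse at parameter theta.
ellipse_normal <- function(a, b, theta) {
  n <- cbind(cos(theta) / a, sin(theta) / b)
  n / sqrt(rowSums(n^2))
}

## Point on the surface offset inward by `depth` from the outer ellipse.
ellipse_offset_point <- function(a, b, theta, depth) {
  ellipse_point(a, b, theta) - depth * ellipse_normal(a, b, theta)
}

## Nearest-parameter projection of point p onto the inward-offset surface.
## Newton iteration on d/dtheta |p - q(theta)|^2 with a coarse grid start.
## Returns list(theta, point, normal, signed) where signed > 0 means p lies
## beyond the surface in the outward-normal direction (inside the wall or
## past it), signed < 0 means p is in the cavity.
ellipse_project <- function(p, a, b, depth = 0) {
  stopifnot(length(p) == 2)
  grid <- seq(0, 2 * pi, length.out = 181)
  q <- ellipse_offset_point(a, b, grid, depth)
  d2 <- (q[, 1] - p[1])^2 + (q[, 2] - p[2])^2
  th <- grid[which.min(d2)]
  for (i in 1:30) {
    h <- 1e-5
    f0 <- sum((drop(ellipse_offset_point(a, b, th, depth)) - p)^2)
    fp <- sum((drop(ellipse_offset_point(a, b, th + h, depth)) - p)^2)
    fm <- sum((drop(ellipse_offset_point(a, b, th - h, depth)) - p)^2)
    g <- (fp - fm) / (2 * h)
    H <- (fp - 2 * f0 + fm) / h^2
    step <- if (abs(H) > 1e-12) -g / H else -sign(g) * 1e-3
    step <- max(min(step, 0.2), -0.2)
    th <- th + step
    if (abs(step) < 1e-12) break
  }
  q0 <- drop(ellipse_offset_point(a, b, th, depth))
  n0 <- drop(ellipse_normal(a, b, th))
  list(theta = th, point = q0, normal = n0,
       signed = sum((p - q0) * n0))
}

## Signed distances of an n x 2 matrix of points to the inner cavity surface
## (positive = beyond the surface, into/past the wall).
inner_wall_signed_distance <- function(pts, major_axis, minor_axis,
                                       wall_thickness) {
  a <- major_axis / 2
  b <- minor_axis / 2
  pts <- rbind(pts)
  vapply(seq_len(nrow(pts)), function(i) {
    ellipse_project(pts[i, ], a, b, depth = wall_thickness)$signed
  }, numeric(1))
}

## Arc length along the inward-offset surface from theta = 0, by fine
## trapezoidal quadrature; vectorised over theta.
ellipse_arclength <- function(a, b, theta, depth = 0, n_sub = 2000) {
  tt <- seq(0, max(theta), length.out = n_sub)
  q <- ellipse_offset_point(a, b, tt, depth)
  seg <- sqrt(diff(q[, 1])^2 + diff(q[, 2])^2)
  cum <- c(0, cumsum(seg))
  stats::approx(tt, cum, xout = theta, rule = 2)$y
}

rot2 <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
}
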