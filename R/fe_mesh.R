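#' Materials and geometry for the uterine-wall indentation model
#'
#' Linear elastic isotropic material. Units: `elastic_modulus` in MPa
#' (N/mm^2), dimensionless Poisson ratio.
#'
#' @param elastic_modulus Young's modulus, MPa.
#' @param poisson_ratio Poisson's ratio in `[0, 0.5)`.
#' @return A `material` list.
#' @export
material <- function(elastic_modulus, poisson_ratio) {
  if (!is.finite(elastic_modulus) || elastic_modulus <= 0)
    fk_config_error("elastic_modulus must be > 0")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    fk_config_error("poisson_ratio must be in [0, 0.5)")
  structure(list(elastic_modulus = elastic_modulus,
                 poisson_ratio = poisson_ratio), class = "material")
}

#' Default wall and probe materials
#'
#' Fetal membrane 7.53 MPa, uterine muscle 0.586 MPa (both Poisson 0.4) and
#' a fetal-cartilage probe of 1.1 MPa (Poisson 0.49).
#' @return Named list of three [material()] objects.
#' @export
default_materials <- function() {
  list(membrane = material(7.53, 0.4),
       muscle = material(0.586, 0.4),
       probe = material(1.1, 0.49))
}

#' Uterine wall geometry
#'
#' Elliptical bilayer wall: a thin fetal membrane lining the cavity backed
#' by a thicker layer of uterine muscle, indented by a round-ended probe of
#' the fetal foot's width.
#'
#' @param major_axis,minor_axis Outer-wall ellipse axes, mm.
#' @param membrane_thickness Fetal membrane thickness, mm (default 0.6).
#' @param muscle_thickness Uterine muscle thickness, mm (default 6.0).
#' @param probe_width Probe (foot) width, mm (default 15).
#' @param contact_angle Parametric angle of the contact site on the
#'   half-ellipse; default the arc midpoint (the apex, pi/2), maximally far
#'   from both symmetry edges.
#' @return A `uterus_geometry` list.
#' @export
uterus_geometry <- function(major_axis, minor_axis,
                            membrane_thickness = 0.6,
                            muscle_thickness = 6.0,
                            probe_width = 15,
                            contact_angle = pi / 2) {
  if (membrane_thickness <= 0 || muscle_thickness <= 0)
    fk_config_error("layer thicknesses must be > 0")
  if (probe_width <= 0) fk_config_error("probe_width must be > 0")
  total <- membrane_thickness + muscle_thickness
  if (major_axis <= 2 * total || minor_axis <= 2 * total)
    fk_config_error("ellipse axes must exceed twice the wall thickness")
  structure(list(major_axis = major_axis, minor_axis = minor_axis,
                 membrane_thickness = membrane_thickness,
                 muscle_thickness = muscle_thickness,
                 probe_width = probe_width, contact_angle = contact_angle),
            class = "uterus_geometry")
}

#' Mesh resolution settings
#'
#' @param n_membrane,n_muscle Element layers through the membrane (>= 2)
#'   and muscle (>= 4).
#' @param size_near,size_far Circumferential element size near/away from
#'   the contact site, mm.
#' @param refine_span Arc half-width of the fine region around contact, mm.
#' @param probe_nw Node columns across the probe width.
#' @param probe_ns Element rows along the probe.
#' @return A `fe_resolution` list.
#' @export
fe_resolution <- function(n_membrane = 2L, n_muscle = 6L,
                          size_near = 2, size_far = 8, refine_span = 30,
                          probe_nw = 9L, probe_ns = 6L) {
  if (n_membrane < 2 || n_muscle < 4)
    fk_config_error("resolution too coarse for layer thicknesses: need >= 2 membrane and >= 4 muscle layers")
  if (size_near <= 0 || size_far < size_near)
    fk_config_error("need 0 < size_near <= size_far")
  structure(list(n_membrane = as.integer(n_membrane),
                 n_muscle = as.integer(n_muscle),
                 size_near = size_near, size_far = size_far,
                 refine_span = refine_span,
                 probe_nw = as.integer(probe_nw),
                 probe_ns = as.integer(probe_ns)),
            class = "fe_resolution")
}

## Structured quad grid helper: nodes is a (nr x nc) index matrix into a
## coordinate list; returns m x 4 element table with CCW orientation.
grid_elems <- function(idx) {
  nr <- nrow(idx); nc <- ncol(idx)
  el <- matrix(0L, (nr - 1) * (nc - 1), 4)
  k <- 1L
  for (j in seq_len(nc - 1)) for (i in seq_len(nr - 1)) {
    el[k, ] <- c(idx[i, j], idx[i + 1, j], idx[i + 1, j + 1], idx[i, j + 1])
    k <- k + 1L
  }
  el
}

## Ensure CCW node ordering (positive area) for every element.
orient_elems <- function(nodes, elems) {
  for (k in seq_len(nrow(elems))) {
    p <- nodes[elems[k, ], ]
    area2 <- sum(p[, 1] * p[c(2, 3, 4, 1), 2] - p[c(2, 3, 4, 1), 1] * p[, 2])
    if (area2 < 0) elems[k, ] <- elems[k, 4:1]
  }
  elems
}

#' Build the half-ellipse bilayer wall + probe FE model
#'
#' Meshes half of the uterine environment (the upper half-ellipse, cut
#' along the major axis) with bilinear quadrilaterals graded fine near the
#' contact site, and places a round-ended cartilage probe just inside the
#' cavity surface at the contact angle.  Symmetry boundary conditions
#' constrain the normal displacement on the two cut edges; the outer node
#' of each cut edge additionally pins the tangential rigid-body mode
#' (physically, the restraint of surrounding tissue).  The probe's shank
#' carries the ramped displacement along the outward wall normal.
#'
#' @param geom A [uterus_geometry()].
#' @param materials Named list of membrane/muscle/probe [material()]s.
#' @param resolution A [fe_resolution()].
#' @param out_of_plane_thickness Plane-stress out-of-plane depth, m.  The
#'   default 0.035 (35 mm) is the midpoint of the 30-40 mm section
#'   thickness of the emulated thick-slice acquisition: the 2D model
#'   represents the tissue slab actually imaged.
#' @param initial_gap Initial probe-wall clearance, mm.
#' @return An `fe_model` list with the mesh, node sets, contact pair,
#'   control (driven) nodes and direction, boundary conditions and penalty
#'   stiffness.
#' @export
build_uterus_model <- function(geom, materials = default_materials(),
                               resolution = fe_resolution(),
                               out_of_plane_thickness = 0.035,
                               initial_gap = 0.05) {
  stopifnot(inherits(geom, "uterus_geometry"))
  a <- geom$major_axis / 2
  b <- geom$minor_axis / 2
  Tw <- geom$membrane_thickness + geom$muscle_thickness
  res <- resolution
  thick_mm <- out_of_plane_thickness * 1000

  ## --- circumferential node placement (graded by arc distance to contact)
  th_fine <- seq(0, pi, length.out = 4001)
  arc <- ellipse_arclength(a, b, th_fine, depth = Tw)
  s_total <- max(arc)
  s_c <- stats::approx(th_fine, arc, xout = geom$contact_angle)$y
  hsize <- function(s) {
    d <- pmax(abs(s - s_c) - res$refine_span, 0)
    pmin(res$size_near + d * 0.15, res$size_far)
  }
  ## march node positions outward from the contact arc position in both
  ## directions with the local size function, so the mesh is symmetric
  ## about the contact point; the final step each side is stretched to
  ## land exactly on the cut edges
  march <- function(from, to) {
    s <- from; out <- c()
    dir <- sign(to - from)
    while (dir * (to - s) > 1e-9) {
      step <- hsize(s)
      if (dir * (to - s) < 1.5 * step) {
        ## distribute the remainder evenly over the final stretch
        k <- max(1L, round(abs(to - s) / step))
        out <- c(out, s + dir * seq_len(k) * abs(to - s) / k)
        break
      }
      s <- s + dir * step
      out <- c(out, s)
    }
    out
  }
  s_nodes <- sort(unique(c(march(s_c, 0), s_c, march(s_c, s_total))))
  th_nodes <- stats::approx(arc, th_fine, xout = s_nodes)$y
  th_nodes[1] <- 0; th_nodes[length(th_nodes)] <- pi

  ## --- radial layers: d = 0 at cavity surface, Tw at outer surface
  d_mem <- seq(0, geom$membrane_thickness, length.out = res$n_membrane + 1)
  d_mus <- seq(geom$membrane_thickness, Tw, length.out = res$n_muscle + 1)
  d_all <- c(d_mem, d_mus[-1])
  n_rad <- length(d_all)

  nt <- length(th_nodes)
  nodes <- matrix(0, nt * n_rad, 2)
  idx <- matrix(0L, n_rad, nt)
  k <- 1L
  for (i in seq_len(nt)) {
    p_out <- drop(ellipse_point(a, b, th_nodes[i]))
    nrm <- drop(ellipse_normal(a, b, th_nodes[i]))
    for (j in seq_len(n_rad)) {
      nodes[k, ] <- p_out - (Tw - d_all[j]) * nrm
      idx[j, i] <- k
      k <- k + 1L
    }
  }
  elems <- grid_elems(idx)
  ## region by radial interval: first n_membrane intervals are membrane
  rad_int <- rep(rep(seq_len(n_rad - 1)), times = nt - 1)
  region <- ifelse(rad_int <= res$n_membrane, "membrane", "muscle")

  inner_chain <- idx[1, ]              # cavity-surface nodes, ordered by theta
  sym_nodes <- c(idx[, 1], idx[, nt])  # both cut edges lie on y = 0
  ## pin the tangential rigid-body mode at the far cut edge's outer node
  ## (the restraint of surrounding tissue); a single pin leaves the
  ## full-model symmetry free to widen along the cut plane
  far_col <- if (geom$contact_angle <= pi / 2) nt else 1L
  pin_node <- idx[n_rad, far_col]

  ## --- probe mesh (round-ended, width probe_width, behind an initial gap)
  cpt <- drop(ellipse_offset_point(a, b, geom$contact_angle, Tw))
  nrm_c <- drop(ellipse_normal(a, b, geom$contact_angle))
  tng_c <- c(-nrm_c[2], nrm_c[1])
  R <- geom$probe_width / 2
  shank <- geom$probe_width / 2
  nw <- res$probe_nw; ns <- res$probe_ns
  wv <- seq(-R, R, length.out = nw)
  front_l <- -R + sqrt(pmax(R^2 - wv^2, 0))
  back_l <- -R - shank
  pr_nodes <- matrix(0, nw * (ns + 1), 2)
  pr_idx <- matrix(0L, ns + 1, nw)
  apex <- cpt - initial_gap * nrm_c
  k <- 1L
  for (i in seq_len(nw)) {
    for (j in seq_len(ns + 1)) {
      l <- back_l + (j - 1) / ns * (front_l[i] - back_l)
      pr_nodes[k, ] <- apex + l * nrm_c + wv[i] * tng_c
      pr_idx[j, i] <- k
      k <- k + 1L
    }
  }
  off <- nrow(nodes)
  pr_elems <- grid_elems(pr_idx) + off
  probe_back <- pr_idx[1, ] + off
  probe_front <- pr_idx[ns + 1, ] + off
  ## the driven (control) set is the whole shank (local l <= -R): the foot
  ## is pushed as a blunt body, and only the round cap stays elastic
  lvals <- (pr_nodes[, 1] - apex[1]) * nrm_c[1] +
           (pr_nodes[, 2] - apex[2]) * nrm_c[2]
  probe_ctrl <- which(lvals <= -R + 1e-6) + off

  nodes <- rbind(nodes, pr_nodes)
  elems <- rbind(elems, pr_elems)
  region <- c(region, rep("probe", nrow(pr_elems)))
  elems <- orient_elems(nodes, elems)

  Evec <- vapply(region, function(r) materials[[r]]$elastic_modulus, numeric(1))
  nuvec <- vapply(region, function(r) materials[[r]]$poisson_ratio, numeric(1))

  mesh <- structure(list(nodes = nodes, elems = elems, region = region,
                         E = unname(Evec), nu = unname(nuvec),
                         thickness_mm = thick_mm), class = "fe_mesh")

  penalty <- 100 * min(Evec) * thick_mm  # N/mm per mm penetration
  structure(list(
    mesh = mesh,
    sets = list(inner_chain = inner_chain, sym_nodes = unique(sym_nodes),
                pin_node = pin_node, probe_back = probe_back,
                probe_front = probe_front),
    contact = list(
      pairs = list(
        ## probe cap nodes against the wall cavity surface
        list(slave = probe_front, master_chain = inner_chain,
             ref_interior = c(0, 0)),
        ## wall cavity nodes against the probe cap (two-pass: distributes
        ## the load as the wall wraps the foot)
        list(slave = inner_chain[abs(s_nodes - s_c) < 2.5 * geom$probe_width],
             master_chain = probe_front,
             ref_interior = cpt + 20 * nrm_c)),
      wall_nodes = inner_chain),
    control = list(nodes = probe_ctrl, dir = nrm_c),
    bc = list(sym_uy = unique(sym_nodes), pin_ux = pin_node),
    penalty = penalty,
    contact_reg = 0.05,
    materials = materials, geom = geom, resolution = res,
    initial_gap = initial_gap
  ), class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model> %d nodes, %d elements (%s)\n",
              nrow(x$mesh$nodes), nrow(x$mesh$elems),
              paste(names(table(x$mesh$region)), table(x$mesh$region),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

## Rectangular sheet + probe model for the bench validation scenario.
build_sheet_model <- function(span, sheet_thickness,
                              probe_diameter = 10,
                              sheet_material = material(10.3, 0.49),
                              probe_material = material(2600, 0.3),
                              out_of_plane_thickness = 0.035,
                              nx = 61L, ny = 4L,
                              probe_nw = 9L, probe_ns = 6L,
                              initial_gap = 0.05) {
  thick_mm <- out_of_plane_thickness * 1000
  ## sheet occupies y in [-t, 0]; grade x spacing toward the centre
  u <- seq(-1, 1, length.out = nx)
  xv <- span / 2 * sign(u) * (abs(u)^1.4)
  yv <- seq(-sheet_thickness, 0, length.out = ny + 1)
  idx <- matrix(0L, ny + 1, nx)
  nodes <- matrix(0, nx * (ny + 1), 2)
  k <- 1L
  for (i in seq_len(nx)) for (j in seq_len(ny + 1)) {
    nodes[k, ] <- c(xv[i], yv[j])
    idx[j, i] <- k; k <- k + 1L
  }
  elems <- grid_elems(idx)
  region <- rep("sheet", nrow(elems))
  top_chain <- idx[ny + 1, ]
  end_nodes <- c(idx[, 1], idx[, nx])

  R <- probe_diameter / 2
  wv <- seq(-R, R, length.out = probe_nw)
  front_l <- -R + sqrt(pmax(R^2 - wv^2, 0))
  back_l <- -R - R
  pr_idx <- matrix(0L, probe_ns + 1, probe_nw)
  pr_nodes <- matrix(0, probe_nw * (probe_ns + 1), 2)
  apex <- c(0, initial_gap)
  dirn <- c(0, -1)  # probe presses downward
  tng <- c(1, 0)
  k <- 1L
  for (i in seq_len(probe_nw)) for (j in seq_len(probe_ns + 1)) {
    ## l <= 0 runs from the back edge to the cap front, along the pressing
    ## direction (so the shank sits behind the apex, away from the sheet)
    l <- back_l + (j - 1) / probe_ns * (front_l[i] - back_l)
    pr_nodes[k, ] <- apex + l * dirn + wv[i] * tng
    pr_idx[j, i] <- k; k <- k + 1L
  }
  off <- nrow(nodes)
  lvals <- (pr_nodes[, 1] - apex[1]) * dirn[1] +
           (pr_nodes[, 2] - apex[2]) * dirn[2]
  probe_ctrl <- which(lvals <= -R + 1e-6) + off
  nodes <- rbind(nodes, pr_nodes)
  pr_elems <- grid_elems(pr_idx) + off
  elems <- rbind(elems, pr_elems)
  region <- c(region, rep("probe", nrow(pr_elems)))
  elems <- orient_elems(nodes, elems)
  mats <- list(sheet = sheet_material, probe = probe_material)
  Evec <- vapply(region, function(r) mats[[r]]$elastic_modulus, numeric(1))
  nuvec <- vapply(region, function(r) mats[[r]]$poisson_ratio, numeric(1))
  mesh <- structure(list(nodes = nodes, elems = elems, region = region,
                         E = unname(Evec), nu = unname(nuvec),
                         thickness_mm = thick_mm), class = "fe_mesh")
  structure(list(
    mesh = mesh,
    sets = list(inner_chain = top_chain, sym_nodes = integer(0),
                pin_node = NA_integer_,
                probe_back = pr_idx[1, ] + off,
                probe_front = pr_idx[probe_ns + 1, ] + off),
    contact = list(
      pairs = list(
        list(slave = pr_idx[probe_ns + 1, ] + off, master_chain = top_chain,
             ref_interior = c(0, 50)),
        list(slave = top_chain[abs(xv) < 2.5 * probe_diameter],
             master_chain = pr_idx[probe_ns + 1, ] + off,
             ref_interior = c(0, -50))),
      wall_nodes = top_chain),
    control = list(nodes = probe_ctrl, dir = dirn),
    bc = list(fixed_xy = unique(end_nodes), sym_uy = integer(0),
              pin_ux = NA_integer_),
    penalty = 100 * min(Evec) * thick_mm,
    contact_reg = 0.05,
    materials = mats, geom = list(span = span,
                                  sheet_thickness = sheet_thickness,
                                  probe_diameter = probe_diameter),
    initial_gap = initial_gap
  ), class = "fe_model")
}
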