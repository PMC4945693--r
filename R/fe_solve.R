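#' Assemble tangent stiffness and internal forces
#'
#' Total-Lagrangian assembly of 4-node bilinear plane-stress quadrilaterals
#' (Green-Lagrange strain, St. Venant-Kirchhoff material, 2 x 2 Gauss
#' quadrature).  At zero displacement the tangent is the linear plane-stress
#' stiffness: symmetric, with exactly three rigid-body zero-energy modes on
#' an unconstrained patch.
#'
#' @param mesh An `fe_mesh` (nodes, elems, per-element E and nu, thickness).
#' @param u Displacement vector, length `2 * n_nodes` (x, y interleaved).
#' @return List with sparse `K` (dgCMatrix), `fint`, and `detj_min`.
#' @export
fe_assemble <- function(mesh, u = NULL, nlgeom = TRUE) {
  n <- nrow(mesh$nodes)
  if (is.null(u)) u <- numeric(2 * n)
  out <- .tl_q4_assemble(mesh$nodes, mesh$elems, u, mesh$E, mesh$nu,
                         mesh$thickness_mm, nlgeom)
  if (out$detj_min <= 0)
    fk_solver_error(sprintf("inverted element %d (det J = %.3g)",
                            out$detj_min_elem, out$detj_min))
  K <- Matrix::sparseMatrix(i = out$i, j = out$j, x = out$x,
                            dims = c(2 * n, 2 * n))
  list(K = K, fint = out$fint, detj_min = out$detj_min)
}

## --- frictionless node-to-segment penalty contact --------------------------

## For each slave node, find the closest point on the master chain and the
## penetration beyond the surface (positive = penetrated), with the surface
## normal oriented away from `ref` (the side the slave approaches from).
## Returns per-contact gradient rows for the penalty energy 0.5 * k * p^2.
contact_eval <- function(model, u) {
  nodes <- model$mesh$nodes
  x <- nodes + matrix(u, ncol = 2, byrow = TRUE)
  k_pen <- model$penalty
  pairs <- model$contact$pairs %||%
    list(list(slave = model$contact$slave,
              master_chain = model$contact$master_chain,
              ref_interior = model$contact$ref_interior))

  grad <- numeric(length(u))
  trips_i <- integer(0); trips_j <- integer(0); trips_x <- numeric(0)
  any_active <- FALSE
  max_pen <- 0

  for (pair in pairs) {
  chain <- pair$master_chain
  slaves <- pair$slave
  ref <- pair$ref_interior

  ## averaged nodal normals on the deformed master chain, oriented away
  ## from the reference interior point; interpolating them within segments
  ## gives a C0-continuous normal field (prevents active-set cycling)
  nseg <- length(chain) - 1
  seg_n <- matrix(0, nseg, 2)
  for (ci in seq_len(nseg)) {
    v <- x[chain[ci + 1], ] - x[chain[ci], ]
    nrm <- c(v[2], -v[1])
    nrm <- nrm / max(sqrt(sum(nrm^2)), 1e-12)
    mid <- (x[chain[ci], ] + x[chain[ci + 1], ]) / 2
    if (sum(nrm * (mid - ref)) < 0) nrm <- -nrm
    seg_n[ci, ] <- nrm
  }
  nod_n <- matrix(0, length(chain), 2)
  nod_n[1, ] <- seg_n[1, ]
  nod_n[length(chain), ] <- seg_n[nseg, ]
  if (nseg > 1)
    for (ci in 2:nseg) {
      v <- seg_n[ci - 1, ] + seg_n[ci, ]
      nod_n[ci, ] <- v / max(sqrt(sum(v^2)), 1e-12)
    }

  for (s in slaves) {
    xs <- x[s, ]
    best <- NULL
    for (ci in seq_len(nseg)) {
      p1 <- x[chain[ci], ]; p2 <- x[chain[ci + 1], ]
      v <- p2 - p1
      L2 <- sum(v^2)
      t <- sum((xs - p1) * v) / max(L2, 1e-12)
      t <- min(max(t, 0), 1)
      xm <- p1 + t * v
      d2 <- sum((xs - xm)^2)
      if (is.null(best) || d2 < best$d2)
        best <- list(d2 = d2, ci = ci, t = t, xm = xm, p1 = p1, p2 = p2)
    }
    nrm <- (1 - best$t) * nod_n[best$ci, ] + best$t * nod_n[best$ci + 1, ]
    nrm <- nrm / max(sqrt(sum(nrm^2)), 1e-12)
    p <- sum((xs - best$xm) * nrm)
    if (p <= 0) next
    any_active <- TRUE
    max_pen <- max(max_pen, p)

    ## C1-regularised penalty: quadratic force up to p0, linear beyond, so
    ## the contact stiffness is continuous at activation
    p0 <- model$contact_reg %||% 0.05
    if (p <= p0) {
      fmag <- k_pen * p^2 / (2 * p0)
      kt <- k_pen * p / p0
    } else {
      fmag <- k_pen * (p - p0 / 2)
      kt <- k_pen
    }

    na <- chain[best$ci]; nb <- chain[best$ci + 1]
    t <- best$t
    dofs <- c(2 * s - 1, 2 * s, 2 * na - 1, 2 * na, 2 * nb - 1, 2 * nb)
    g <- c(nrm, -(1 - t) * nrm, -t * nrm)  # d p / d dofs
    grad[dofs] <- grad[dofs] + fmag * g
    ## tangent: kt * g g^T (gap-gradient outer product; slip/curvature terms
    ## omitted -- convergence is robust at these penetrations)
    Kc <- kt * tcrossprod(g)
    trips_i <- c(trips_i, rep(dofs, each = 6))
    trips_j <- c(trips_j, rep(dofs, times = 6))
    trips_x <- c(trips_x, as.vector(t(Kc)))
  }
  }
  ## resultant contact force exerted on the wall: minus the contact-energy
  ## gradient summed over the wall-side nodes
  wn <- model$contact$wall_nodes %||% model$contact$master_chain
  wall_force <- -c(sum(grad[2 * wn - 1]), sum(grad[2 * wn]))
  list(grad = grad, i = trips_i, j = trips_j, x = trips_x,
       active = any_active, max_penetration = max_pen,
       wall_force = wall_force)
}

## --- Newton solve with ramped prescribed displacement ----------------------

model_bc_dofs <- function(model) {
  fixed <- integer(0)
  if (length(model$bc$sym_uy))
    fixed <- c(fixed, 2 * model$bc$sym_uy)           # uy = 0 on cut planes
  pins <- model$bc$pin_ux
  pins <- pins[!is.na(pins)]
  if (length(pins))
    fixed <- c(fixed, 2 * pins - 1)                  # tangential pins
  if (!is.null(model$bc$fixed_xy) && length(model$bc$fixed_xy))
    fixed <- c(fixed, 2 * model$bc$fixed_xy - 1, 2 * model$bc$fixed_xy)
  ctrl <- model$control$nodes
  fixed <- c(fixed, 2 * ctrl - 1, 2 * ctrl)          # driven probe edge
  sort(unique(fixed))
}

#' Solve the ramped indentation problem
#'
#' Applies the target displacement to the probe control nodes along the
#' contact normal in equal increments, resolving frictionless penalty
#' contact between the probe tip and the wall surface with full Newton
#' iterations (geometrically nonlinear total-Lagrangian elements).
#'
#' @param model An `fe_model` from [build_uterus_model()].
#' @param target_displacement Final probe displacement, mm (>= 0).
#' @param n_increments Number of equal displacement increments.
#' @param tol Relative residual tolerance per increment.
#' @param max_iter Newton iteration cap per increment.
#' @param u_init Optional displacement field to continue from (e.g. a
#'   nearby converged solution in a parameter study); the solver then
#'   converges directly at the target displacement instead of ramping,
#'   falling back to the ramp if that fails.
#' @param continuation_stab Grounding-spring factor applied during a
#'   continuation solve (relative to the median diagonal stiffness).  A
#'   small value anchors the nearly neutral frictionless sliding mode at
#'   the `u_init` state so parameter perturbations are compared on one
#'   contact configuration.
#' @return An `fe_solution`: final displacement field `u`, nodal reaction
#'   vector `reactions` (at constrained DOFs), `total_contact` force (N),
#'   `max_nodal` reaction among probe control nodes (N), per-increment
#'   `history` (displacement, total and max-nodal force), and a
#'   convergence log.
#' @export
solve_indentation <- function(model, target_displacement, n_increments = 10,
                              tol = 1e-8, max_iter = 50, u_init = NULL,
                              continuation_stab = 0) {
  if (target_displacement < 0)
    fk_config_error("target_displacement must be >= 0")
  mesh <- model$mesh
  ndof <- 2 * nrow(mesh$nodes)
  u <- numeric(ndof)
  fixed <- model_bc_dofs(model)
  free <- setdiff(seq_len(ndof), fixed)
  ctrl <- model$control$nodes
  dirn <- model$control$dir
  log_lines <- character(0)
  hist <- data.frame(increment = integer(0), displacement_mm = numeric(0),
                     total_N = numeric(0), max_nodal_N = numeric(0))

  ## reference diagonal stiffness for adaptive stabilisation springs
  k_diag_ref <- stats::median(abs(Matrix::diag(fe_assemble(mesh)$K)[free]))

  nlg <- model$nlgeom %||% TRUE
  res_norm <- function(uv, u_ref, k_stab) {
    a <- fe_assemble(mesh, uv, nlgeom = nlg)
    cc <- contact_eval(model, uv)
    r <- a$fint + cc$grad
    if (k_stab > 0) r[free] <- r[free] + k_stab * (uv[free] - u_ref[free])
    list(asm = a, con = cc, r = r, norm = sqrt(sum(r[free]^2)))
  }

  ## Newton solve at prescribed probe displacement d, from warm start u.
  ## Returns NULL on non-convergence (the caller then bisects the step or
  ## engages stabilisation).  stab > 0 adds grounding springs of stiffness
  ## stab * k_diag_ref anchored at the warm start, regularising limit
  ## points (frictionless sliding modes); the artificial force vanishes as
  ## the substep size shrinks.
  newton_at <- function(u, d, label, stab = 0) {
    u_ref <- u
    k_stab <- stab * k_diag_ref
    u[2 * ctrl - 1] <- d * dirn[1]
    u[2 * ctrl] <- d * dirn[2]
    st <- res_norm(u, u_ref, k_stab)
    rel <- Inf
    for (it in seq_len(max_iter)) {
      asm <- st$asm; con <- st$con; r <- st$r
      K <- asm$K
      if (length(con$i))
        K <- K + Matrix::sparseMatrix(i = con$i, j = con$j, x = con$x,
                                      dims = dim(K))
      ref_force <- max(sum(abs(r[fixed])), sum(abs(asm$fint)), 1e-8)
      rel <- st$norm / ref_force
      log_lines <<- c(log_lines,
                      sprintf("%s it %d rel %.3e pen %.3e stab %g", label, it,
                              rel, con$max_penetration, stab))
      if (rel < tol) return(list(u = u, r = r, rel = rel))
      Kff <- K[free, free]
      if (k_stab > 0)
        Kff <- Kff + Matrix::Diagonal(length(free), k_stab)
      du <- as.numeric(Matrix::solve(Kff, -r[free]))
      ## backtracking on the residual norm damps contact active-set flips
      step <- 1
      for (ls in 1:6) {
        u_try <- u
        u_try[free] <- u[free] + step * du
        st_try <- res_norm(u_try, u_ref, k_stab)
        if (st_try$norm < st$norm || step < 0.05) break
        step <- step / 2
      }
      u <- u_try
      st <- st_try
    }
    NULL
  }

  reactions <- numeric(ndof)
  tot <- c(0, 0)
  mn <- 0
  if (target_displacement > 0 && !is.null(u_init)) {
    ## continuation from a nearby converged state: one direct solve
    ok <- newton_at(u_init, target_displacement, "continuation",
                    stab = continuation_stab)
    if (!is.null(ok)) {
      u <- ok$u
      reactions <- ok$r
      tot <- contact_eval(model, u)$wall_force
      mn <- max_nodal_reaction(model, reactions)
      hist <- data.frame(increment = seq_len(n_increments),
                         displacement_mm = target_displacement,
                         total_N = sqrt(sum(tot^2)), max_nodal_N = mn)
      return(structure(list(u = u, reactions = reactions, fixed_dofs = fixed,
                            total_contact = sqrt(sum(tot^2)),
                            total_contact_vec = tot, max_nodal = mn,
                            history = hist, converged = TRUE,
                            log = log_lines, model = model,
                            target_displacement = target_displacement),
                       class = "fe_solution"))
    }
  }
  if (target_displacement > 0) {
    d_cur <- 0
    milestones <- target_displacement * seq_len(n_increments) / n_increments
    d_nom <- target_displacement / n_increments
    min_step <- d_nom / 16
    last_rel <- NA_real_
    for (inc in seq_len(n_increments)) {
      target_inc <- milestones[inc]
      while (d_cur < target_inc - 1e-12) {
        step_d <- min(d_nom, target_inc - d_cur)
        ok <- NULL
        while (is.null(ok)) {
          ok <- newton_at(u, d_cur + step_d,
                          sprintf("inc %d d %.4f", inc, d_cur + step_d))
          if (is.null(ok)) {
            if (step_d / 2 >= min_step) {
              step_d <- step_d / 2
            } else {
              ## smallest step still stalls: pass the limit point with
              ## grounding springs of increasing stiffness
              for (stab in c(1e-5, 1e-4, 1e-3)) {
                ok <- newton_at(u, d_cur + step_d,
                                sprintf("inc %d d %.4f (stab)", inc,
                                        d_cur + step_d), stab = stab)
                if (!is.null(ok)) break
              }
              if (is.null(ok))
                fk_solver_error(sprintf(
                  "Newton failed to converge at increment %d even with substepping and stabilisation (displacement %.4f mm)",
                  inc, d_cur + step_d))
            }
          }
        }
        u <- ok$u
        reactions <- ok$r
        last_rel <- ok$rel
        d_cur <- d_cur + step_d
      }
      tot <- contact_eval(model, u)$wall_force
      mn <- max_nodal_reaction(model, reactions)
      hist <- rbind(hist, data.frame(increment = inc,
                                     displacement_mm = d_cur,
                                     total_N = sqrt(sum(tot^2)),
                                     max_nodal_N = mn))
    }
  }
  structure(list(u = u, reactions = reactions,
                 fixed_dofs = fixed,
                 total_contact = sqrt(sum(tot^2)),
                 total_contact_vec = tot,
                 max_nodal = mn,
                 history = hist,
                 converged = TRUE,
                 log = log_lines,
                 model = model,
                 target_displacement = target_displacement),
            class = "fe_solution")
}

## Largest nodal reaction magnitude among the driven probe nodes (the
## location of the applied boundary condition).
max_nodal_reaction <- function(model, r) {
  ctrl <- model$control$nodes
  fx <- r[2 * ctrl - 1]; fy <- r[2 * ctrl]
  max(sqrt(fx^2 + fy^2))
}

#' Reaction report from a converged solution
#'
#' @param solution An `fe_solution`.
#' @return List with `max_nodal` (N), `total_contact` (N) and `vectors`
#'   (data frame of per-node reaction vectors at constrained nodes).
#' @export
reaction_report <- function(solution) {
  if (!inherits(solution, "fe_solution") || !isTRUE(solution$converged))
    fk_config_error("reaction_report() needs a converged fe_solution")
  r <- solution$reactions
  fixed_nodes <- sort(unique(ceiling(solution$fixed_dofs / 2)))
  vec <- data.frame(node = fixed_nodes,
                    fx = r[2 * fixed_nodes - 1],
                    fy = r[2 * fixed_nodes])
  vec$magnitude <- sqrt(vec$fx^2 + vec$fy^2)
  list(max_nodal = solution$max_nodal,
       total_contact = solution$total_contact,
       vectors = vec)
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("<fe_solution> indentation %.2f mm: total contact %.4f N, max nodal %.4f N\n",
              x$target_displacement, x$total_contact, x$max_nodal))
  invisible(x)
}

#' Sensitivity of the reaction force to the probe modulus
#'
#' Re-solves the indentation with the probe modulus scaled by each factor
#' and reports the signed percent change of the reaction force (the total
#' contact force on the foot, the scalar handed downstream) relative to
#' the unscaled solve; the per-node maximum is reported alongside.
#'
#' @param geom,materials,resolution,target_displacement Model inputs as for
#'   [build_uterus_model()] / [solve_indentation()].
#' @param factors Probe-modulus scale factors.
#' @param ... Passed on to [solve_indentation()].
#' @return A `sensitivity_result` data frame with columns `factor`,
#'   `probe_modulus_MPa`, `max_nodal_N` and `percent_change`.
#' @export
sensitivity_probe_modulus <- function(geom, materials = default_materials(),
                                      resolution = fe_resolution(),
                                      target_displacement = 6.4,
                                      factors = c(0.5, 2.0), ...) {
  ## Frictionless contact admits a nearly neutral family of tangentially
  ## slid equilibria, so independent ramped solves carry a few percent of
  ## branch noise.  All evaluations are therefore relaxed onto a common
  ## branch: ramp the baseline, continue to the first perturbed modulus,
  ## continue back to the baseline (now on the relaxed branch), and
  ## evaluate every factor by continuation from that state.
  model_for <- function(fac) {
    mats <- materials
    mats$probe <- material(materials$probe$elastic_modulus * fac,
                           materials$probe$poisson_ratio)
    build_uterus_model(geom, mats, resolution)
  }
  s_ramp <- solve_indentation(model_for(1), target_displacement, ...)
  s_tmp <- solve_indentation(model_for(factors[1]), target_displacement,
                             u_init = s_ramp$u, ...)
  base_sol <- solve_indentation(model_for(1), target_displacement,
                                u_init = s_tmp$u, ...)
  run1 <- function(fac) {
    s <- solve_indentation(model_for(fac), target_displacement,
                           u_init = base_sol$u, ...)
    c(s$total_contact, s$max_nodal)
  }
  pert <- vapply(factors, run1, numeric(2))
  out <- data.frame(factor = c(1, factors),
                    probe_modulus_MPa = materials$probe$elastic_modulus * c(1, factors))
  out$reaction_N <- c(base_sol$total_contact, pert[1, ])
  out$max_nodal_N <- c(base_sol$max_nodal, pert[2, ])
  out$percent_change <- 100 * (out$reaction_N - base_sol$total_contact) /
    base_sol$total_contact
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' Bench validation: round-ended probe pressed into a clamped sheet
#'
#' Simulates the desk-scale rig: an elastic sheet held between circular
#' clamps, indented 5 mm by a round-ended rigid-plastic probe under
#' displacement control, then unloaded.  The sheet span between the clamps
#' and the sheet thickness are not part of the published rig description
#' and must be supplied.
#'
#' @param config List with `span` and `sheet_thickness` (mm); optional
#'   `probe_diameter` (default 10), `displacement` (default 5),
#'   `n_increments`, and material overrides `sheet_material`,
#'   `probe_material`.
#' @return Data frame `phase` (loading/unloading), `displacement_mm`,
#'   `force_N`.
#' @export
run_validation_scenario <- function(config) {
  req <- c("span", "sheet_thickness")
  miss <- req[!vapply(req, function(f) !is.null(config[[f]]), logical(1))]
  if (length(miss))
    fk_config_error(sprintf("missing validation geometry field(s): %s",
                            paste(miss, collapse = ", ")))
  disp <- config$displacement %||% 5
  n_inc <- config$n_increments %||% 10
  model <- build_sheet_model(
    span = config$span, sheet_thickness = config$sheet_thickness,
    probe_diameter = config$probe_diameter %||% 10,
    sheet_material = config$sheet_material %||% material(10.3, 0.49),
    probe_material = config$probe_material %||% material(2600, 0.3))
  sol <- solve_indentation(model, disp, n_increments = n_inc)
  load_curve <- rbind(data.frame(displacement_mm = 0, total_N = 0),
                      sol$history[c("displacement_mm", "total_N")])
  ## elastic + frictionless: unloading retraces the loading curve
  out <- rbind(
    data.frame(phase = "loading", load_curve),
    data.frame(phase = "unloading",
               load_curve[rev(seq_len(nrow(load_curve))), ]))
  names(out) <- c("phase", "displacement_mm", "force_N")
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a mesh and solution to legacy VTK (ASCII)
#'
#' @param mesh An `fe_mesh`.
#' @param path Output `.vtk` path.
#' @param u Optional displacement vector (point data).
#' @param reactions Optional nodal force vector (point data).
#' @export
write_vtk <- function(mesh, path, u = NULL, reactions = NULL) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fe mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elems[, 1] - 1, mesh$elems[, 2] - 1,
                     mesh$elems[, 3] - 1, mesh$elems[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("9", m), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$region))), con)
  if (!is.null(u) || !is.null(reactions)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    if (!is.null(u)) {
      writeLines("VECTORS displacement float", con)
      writeLines(sprintf("%.9g %.9g 0", u[seq(1, 2 * n, 2)], u[seq(2, 2 * n, 2)]), con)
    }
    if (!is.null(reactions)) {
      writeLines("VECTORS reaction float", con)
      writeLines(sprintf("%.9g %.9g 0", reactions[seq(1, 2 * n, 2)],
                         reactions[seq(2, 2 * n, 2)]), con)
    }
  }
  invisible(path)
}
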