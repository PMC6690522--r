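#' Configuration of an end-to-end growth scenario
#'
#' Two reference scenarios are provided. `"root"`: a tissue slab (default
#' 76 x 32 um, `Yx = 40`, `Yy = 80` MPa·m, `nu = 0.2`, `pt = 0.2` MPa·m)
#' elongating only along x with a growth rate that increases linearly from
#' the bottom to the top border — the growth asymmetry bends the tissue with
#' the slower side on the inner arc. `"leaf"`: a 76 x 67 um sheet growing in
#' both directions with an asymmetric field, building up residual strain
#' (stretch at the borders, compression in the center).
#'
#' @param scenario `"root"`, `"leaf"` or `"custom"`.
#' @param width,height mesh dimensions (um).
#' @param params a `pm_material`.
#' @param field a `pm_growth_field`; defaults to the scenario's gradient
#'   field at the maximal elemental growth rate.
#' @param duration total simulated time (min).
#' @param ht growth integration step (min).
#' @param snapshots times (min) at which to record strain-field snapshots.
#' @param solver a `pm_solver`.
#' @param L0 initial spring length (um).
#' @return object of class `pm_scenario`.
#' @export
scenario_config <- function(scenario = c("root", "leaf", "custom"),
                            width = NULL, height = NULL, params = NULL,
                            field = NULL, duration = 141, ht = 1,
                            snapshots = c(42, 85, 107, 129, 141),
                            solver = solver_params(), L0 = 1) {
  scenario <- match.arg(scenario)
  if (scenario == "root") {
    if (is.null(width)) width <- 76
    if (is.null(height)) height <- 32
    if (is.null(params)) params <- material_params(40, 80, nu = 0.2, pt = 0.2)
    if (is.null(field))
      field <- growth_field("linear-gradient-y", kx = k_max_rate(), ky = 0)
  } else if (scenario == "leaf") {
    if (is.null(width)) width <- 76
    if (is.null(height)) height <- 67
    if (is.null(params)) params <- material_params(40, 80, nu = 0.2, pt = 0.2)
    if (is.null(field))
      field <- growth_field("linear-gradient-xy",
                            kx = k_max_rate(), ky = k_max_rate() / 2)
  } else {
    if (is.null(width) || is.null(height) || is.null(params) || is.null(field))
      stop("custom scenarios need width, height, params and field")
  }
  structure(list(scenario = scenario, width = width, height = height,
                 params = params, field = field, duration = duration,
                 ht = ht, snapshots = snapshots, solver = solver, L0 = L0),
            class = "pm_scenario")
}

#' Run a growth scenario
#'
#' The elastostatic growth loop: per time step `ht` the resting lengths
#' grow, springs at the remeshing threshold are split, the mesh is relaxed
#' under turgor with free-floating boundaries, and rigid-body motion is
#' removed against the previous frame. Strain-field snapshots are collected
#' at the configured times.
#'
#' @param cfg a `pm_scenario`.
#' @param quiet suppress the per-step log line.
#' @return list of class `pm_scenario_result`: the final mesh, a list of
#'   snapshots (each with time, positions, per-spring strains, per-point
#'   shear and the remesh insertions so far) and the per-step log as a data
#'   frame.
#' @export
run_scenario <- function(cfg, quiet = TRUE) {
  mesh <- build_rectangular_mesh(cfg$width, cfg$height, cfg$L0)
  mesh <- relax(mesh, cfg$params, loads = NULL, solver = cfg$solver)
  ref <- mesh
  snaps <- list()
  log <- list()
  nstep <- ceiling(cfg$duration / cfg$ht)
  total_inserted <- 0L
  for (k in seq_len(nstep)) {
    mesh <- growth_step(mesh, cfg$field, cfg$ht)
    mesh <- remesh(mesh)
    ins <- attr(mesh, "inserted")
    total_inserted <- total_inserted + ins
    mesh <- relax(mesh, cfg$params, loads = NULL, solver = cfg$solver)
    mesh <- remove_rigid_motion(mesh, ref)
    log[[k]] <- data.frame(step = k, time = mesh$time,
                           points = npoints(mesh), springs = nsprings(mesh),
                           inserted = ins,
                           relax_steps = attr(mesh, "steps"),
                           residual = attr(mesh, "residual"))
    if (!quiet)
      message(sprintf("t = %5.1f min: %d points, +%d inserted, %d relax steps",
                      mesh$time, npoints(mesh), ins, log[[k]]$relax_steps))
    if (any(abs(cfg$snapshots - mesh$time) < cfg$ht / 2))
      snaps[[length(snaps) + 1L]] <- strain_snapshot(mesh, total_inserted)
  }
  structure(list(mesh = mesh, snapshots = snaps,
                 log = do.call(rbind, log)),
            class = "pm_scenario_result")
}

#' Strain-field snapshot of a mesh
#'
#' @param mesh a `pm_mesh`.
#' @param inserted cumulative remesh insertions (bookkeeping).
#' @return list with `time`, point positions, per-spring strains by
#'   orientation and the per-point absolute shear field.
#' @export
strain_snapshot <- function(mesh, inserted = NA_integer_) {
  e <- spring_strains(mesh)
  list(time = mesh$time, pos = mesh$pos, grid = mesh$grid,
       sa = mesh$sa, sb = mesh$sb, sor = mesh$sor,
       exx = e[mesh$sor == 1L], eyy = e[mesh$sor == 2L],
       strain = e, tau = point_shear(mesh), inserted = inserted,
       mesh = mesh)
}

#' Signed curvature of the tissue mid-line
#'
#' Fits a circle (algebraic least squares) through the mesh points nearest
#' the horizontal mid-line and returns the signed curvature: positive when
#' the tissue bends upward (center of the arc above the tissue), negative
#' downward. Near-straight configurations return 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param mesh a `pm_mesh` (or a snapshot with `pos`/`grid`).
#' @return curvature in 1/um.
#' @export
curvature <- function(mesh) {
  g <- mesh$grid; p <- mesh$pos
  midrow <- (min(g[, 1]) + max(g[, 1])) / 2
  rows <- sort(unique(g[, 1]))
  midrow <- rows[which.min(abs(rows - midrow))]
  sel <- g[, 1] == midrow
  pts <- p[sel, , drop = FALSE]
  pts <- pts[order(g[sel, 2]), , drop = FALSE]
  if (nrow(pts) < 3) stop("not enough mid-line points for a curvature fit")
  x <- pts[, 1]; y <- pts[, 2]
  # Kasa circle fit: minimize ||x^2+y^2 + D x + E y + F||
  M <- cbind(x, y, 1)
  z <- -(x^2 + y^2)
  co <- tryCatch(qr.solve(M, z), error = function(e) NULL)
  if (is.null(co)) return(structure(0, degenerate = TRUE))
  cx <- -co[1] / 2; cy <- -co[2] / 2
  r2 <- cx^2 + cy^2 - co[3]
  if (r2 <= 0) return(structure(0, degenerate = TRUE))
  r <- sqrt(r2)
  span <- max(x) - min(x)
  if (r > 50 * span) return(structure(0, degenerate = TRUE))
  sign_up <- if (cy > mean(y)) 1 else -1
  sign_up / r
}
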