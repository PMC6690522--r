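#' Mean strain over interior springs
#'
#' Strain readout used by the virtual experiments: the mean direct strain of
#' springs of one orientation whose endpoints are both interior (boundary
#' springs are excluded to suppress clamp artifacts).
#'
#' @param mesh a `pm_mesh`.
#' @param orientation `"x"` or `"y"`.
#' @return mean dimensionless strain.
#' @export
interior_strain <- function(mesh, orientation = c("x", "y")) {
  orientation <- match.arg(orientation)
  o <- if (orientation == "x") 1L else 2L
  bdry <- rep(FALSE, npoints(mesh)); bdry[mesh$cycle] <- TRUE
  keep <- mesh$sor == o & !bdry[mesh$sa] & !bdry[mesh$sb]
  if (!any(keep)) keep <- mesh$sor == o
  mean(spring_strain(mesh, which(keep)))
}

#' Mean shear strain over interior points
#'
#' @param mesh a `pm_mesh`.
#' @return mean signed point shear (mean of the adjacent hinge shears) over
#'   non-boundary points.
#' @export
interior_shear <- function(mesh) {
  tau <- point_shear(mesh)
  bdry <- rep(FALSE, npoints(mesh)); bdry[mesh$cycle] <- TRUE
  keep <- !bdry & !is.na(tau)
  if (!any(keep)) keep <- !is.na(tau)
  mean(tau[keep])
}

# build the standard square specimen and relax its turgid prestate
.specimen <- function(params, size = 100, L0 = 1, solver = solver_params(),
                      constrain_fn = NULL, mesh = NULL) {
  if (is.null(mesh)) mesh <- build_rectangular_mesh(size, size, L0)
  if (!is.null(constrain_fn)) mesh <- constrain_fn(mesh)
  relax(mesh, params, loads = NULL, solver = solver)
}

# bottom border restrained to its horizontal line (points slide sideways);
# the sliding rigid mode is force-free and symmetric, so no point is pinned
.direct_bc <- function(axis) {
  force(axis)
  function(mesh) {
    edge <- if (axis == "y") "bottom" else "left"
    ids <- edge_points(mesh, edge)
    constrain(mesh, ids, if (axis == "y") "horizontal" else "vertical")
  }
}

# per-load-level convergence threshold: the per-point force criterion gets
# weaker with specimen size, so aim the residual strain error at rel_acc of
# the strain the load level produces (empirical err_e ~ thr * N / (2 S))
.level_thr <- function(solver, sigma, size, L0, rel_acc = 0.005) {
  min(solver$thr, max(2 * rel_acc * abs(sigma) * L0 / size, 2e-7))
}

.with_thr <- function(solver, thr) { solver$thr <- thr; solver }

#' Direct (uniaxial) stress experiment
#'
#' The virtual tensile test: a square tissue is restrained along one border
#' (points slide along the border line), relaxed to its turgid prestate,
#' and a uniform normal stress is applied to the opposite border in
#' increasing levels. After each relaxation the mean interior strains are
#' recorded and the secant effective moduli are measured from the turgid
#' prestate:
#' `Y_eff = d sigma / d e_axis`, `nu_eff = -d e_perp / d e_axis`.
#'
#' @param params a `pm_material`.
#' @param axis `"y"` (stress on the top border; default) or `"x"`.
#' @param stress_levels increasing applied stress values (MPa·m).
#' @param size,L0 specimen geometry (um); the reference specimen is a
#'   100 um square with 1 um spacing.
#' @param solver a `pm_solver`; the convergence threshold is additionally
#'   scaled per load level so that the residual strain error stays around
#'   `rel_acc` of the strain that level produces.
#' @param rel_acc target relative strain accuracy per load level.
#' @return data frame of class `pm_sweep`: one row per level with applied
#'   stress, mean strains `exx`, `eyy`, shear `tau`, secant `Yeff`, `nueff`,
#'   and the prestrains as attributes.
#' @export
direct_stress_experiment <- function(params, axis = c("y", "x"),
                                     stress_levels,
                                     size = 100, L0 = 1,
                                     solver = solver_params(),
                                     rel_acc = 0.005) {
  axis <- match.arg(axis)
  pre_solver <- if (params$pt > 0)
    .with_thr(solver, .level_thr(solver, params$pt, size, L0, rel_acc)) else solver
  pre <- .specimen(params, size, L0, pre_solver, .direct_bc(axis))
  e0 <- c(x = interior_strain(pre, "x"), y = interior_strain(pre, "y"))
  edge <- if (axis == "y") "top" else "right"
  rows <- vector("list", length(stress_levels))
  m <- pre
  for (k in seq_along(stress_levels)) {
    sg <- stress_levels[k]
    loads <- load_protocol(edges = list(
      list(edge = edge, sigma = sg, direction = "normal")))
    m <- relax(m, params, loads,
               .with_thr(solver, .level_thr(solver, sg, size, L0, rel_acc)),
               from_rest = (k == 1))
    ex <- interior_strain(m, "x"); ey <- interior_strain(m, "y")
    ea <- if (axis == "y") ey else ex
    ep <- if (axis == "y") ex else ey
    ea0 <- e0[[if (axis == "y") "y" else "x"]]
    ep0 <- e0[[if (axis == "y") "x" else "y"]]
    rows[[k]] <- data.frame(
      stress = sg, exx = ex, eyy = ey, tau = interior_shear(m),
      Yeff = sg / (ea - ea0),
      nueff = -(ep - ep0) / (ea - ea0),
      steps = attr(m, "steps"))
  }
  out <- do.call(rbind, rows)
  attr(out, "prestrain") <- e0
  attr(out, "axis") <- axis
  class(out) <- c("pm_sweep", class(out))
  out
}

#' Pure-shear stress experiment
#'
#' Equal tangential tractions on all four walls; the effective shear modulus
#' is the secant `mu_eff = d(S_xy + S_yx) / d tau` from the turgid prestate,
#' with `tau` the mean interior point shear.
#'
#' @param params a `pm_material`.
#' @param stress_levels total applied shear stress `S_xy + S_yx` levels.
#' @inheritParams direct_stress_experiment
#' @return a `pm_sweep` data frame with `stress`, `tau`, `mueff`.
#' @export
shear_stress_experiment <- function(params, stress_levels,
                                    size = 100, L0 = 1,
                                    solver = solver_params(),
                                    rel_acc = 0.005) {
  pre_solver <- if (params$pt > 0)
    .with_thr(solver, .level_thr(solver, params$pt, size, L0, rel_acc)) else solver
  pre <- .specimen(params, size, L0, pre_solver)
  tau0 <- interior_shear(pre)
  rows <- vector("list", length(stress_levels))
  m <- pre
  for (k in seq_along(stress_levels)) {
    tot <- stress_levels[k]
    m <- relax(m, params, shear_protocol(tot),
               .with_thr(solver, .level_thr(solver, tot, size, L0, rel_acc)),
               from_rest = (k == 1))
    tau <- interior_shear(m)
    rows[[k]] <- data.frame(stress = tot, tau = tau,
                            exx = interior_strain(m, "x"),
                            eyy = interior_strain(m, "y"),
                            mueff = tot / (tau - tau0),
                            steps = attr(m, "steps"))
  }
  out <- do.call(rbind, rows)
  attr(out, "pretau") <- tau0
  class(out) <- c("pm_sweep", class(out))
  out
}

#' Rotating point-force isotropy experiment
#'
#' The tissue is inflated to its turgid prestate (free floating), all
#' boundary points are then fixed, and a point force of constant magnitude
#' is applied at the center point over a sweep of directions. Each direction
#' is relaxed independently from the prestate (at equilibrium the protocol
#' is path independent). The displacement profile of the center point probes
#' the isotropy of the lattice: for an isotropic material it is a circle,
#' for an anisotropic one an ellipse.
#'
#' @param params a `pm_material`.
#' @param force force magnitude (uN).
#' @param angles force directions (radians).
#' @inheritParams direct_stress_experiment
#' @param reference optional displacement magnitude to compare against
#'   (e.g. the undeformed-lattice response); default is the angular mean.
#' @return data frame of class `pm_isotropy`: `alpha`, `dx`, `dy`,
#'   `displacement`, `rel_dev` (relative deviation from the reference),
#'   with the maximum relative deviation as attribute `max_rel_dev`.
#' @export
rotating_force_experiment <- function(params, force,
                                      angles = seq(0, 2 * pi, length.out = 17)[-17],
                                      size = 100, L0 = 1,
                                      solver = solver_params(),
                                      reference = NULL) {
  pre <- .specimen(params, size, L0, solver)
  pre <- constrain(pre, pre$cycle, "fixed")
  center <- which.min(rowSums(sweep(pre$pos, 2, colMeans(pre$pos))^2))
  p0 <- pre$pos[center, ]
  rows <- vector("list", length(angles))
  for (k in seq_along(angles)) {
    al <- angles[k]
    loads <- load_protocol(point_forces = data.frame(
      id = center, fx = force * cos(al), fy = force * sin(al)))
    m <- relax(pre, params, loads, solver)
    d <- m$pos[center, ] - p0
    rows[[k]] <- data.frame(alpha = al, dx = d[1], dy = d[2],
                            displacement = sqrt(sum(d^2)),
                            steps = attr(m, "steps"))
  }
  out <- do.call(rbind, rows)
  ref <- if (is.null(reference)) mean(out$displacement) else reference
  out$rel_dev <- (out$displacement - ref) / ref
  attr(out, "reference") <- ref
  attr(out, "max_rel_dev") <- max(abs(out$rel_dev))
  class(out) <- c("pm_isotropy", class(out))
  out
}

#' Mean trajectory deviation
#'
#' `MD = (1/T) sum_t ||p_t - p_t^ref||` between two matched position
#' sequences; the convergence metric for integration-parameter validation.
#'
#' @param traj,ref T x 2 matrices of positions at matched time points.
#' @return mean deviation (um).
#' @export
mean_deviation <- function(traj, ref) {
  traj <- as.matrix(traj); ref <- as.matrix(ref)
  if (!all(dim(traj) == dim(ref)))
    stop("trajectory and reference must have matching dimensions")
  mean(sqrt(rowSums((traj - ref)^2)))
}

#' Uniform growth applied without remeshing
#'
#' Scales the resting lengths of all springs of one orientation by `factor`
#' (must stay below the remeshing threshold), then relaxes. Used to probe
#' how the changed unit-cell metric drifts the effective material
#' properties.
#'
#' @param mesh a `pm_mesh`.
#' @param params a `pm_material`.
#' @param factor resting-length scale (1 <= factor < 2).
#' @param orientation `"x"` or `"y"`.
#' @param solver a `pm_solver`.
#' @return the grown, relaxed mesh.
#' @export
grow_uniform <- function(mesh, params, factor, orientation = c("x", "y"),
                         solver = solver_params()) {
  orientation <- match.arg(orientation)
  if (factor < 1 || factor >= 2)
    stop("growth factor must lie in [1, 2): larger values trigger remeshing")
  o <- if (orientation == "x") 1L else 2L
  mesh$srest[mesh$sor == o] <- mesh$srest[mesh$sor == o] * factor
  relax(mesh, params, loads = NULL, solver = solver)
}

#' Modulus drift under anisotropic growth
#'
#' Grows the specimen uniformly in one direction to each target cell-metric
#' (aspect `h` / metric `s`) without triggering remeshing, reruns the
#' direct- and pure-shear experiments at a small probe stress, and reports
#' the relative drift of the effective moduli against the ungrown baseline.
#'
#' @param params a `pm_material` (typically `pt = 0`).
#' @param targets metric values in `[1, 2)`.
#' @param probe_direct,probe_shear probe stress levels (MPa·m).
#' @inheritParams direct_stress_experiment
#' @return data frame: target metric, effective moduli and their relative
#'   drifts (fractions) vs the baseline.
#' @export
growth_drift_experiment <- function(params, targets,
                                    probe_direct = 0.05, probe_shear = 0.04,
                                    size = 100, L0 = 1,
                                    solver = solver_params()) {
  if (any(targets < 1 | targets >= 2))
    stop("growth targets must lie in [1, 2): the remeshing threshold is 2")
  run_once <- function(factor) {
    base_mesh <- function() {
      m <- build_rectangular_mesh(size, size, L0)
      if (factor > 1) m$srest[m$sor == 1L] <- m$srest[m$sor == 1L] * factor
      m
    }
    dm <- .direct_bc("y")(base_mesh())
    dsw <- direct_stress_experiment_on(dm, params, "y", probe_direct, solver)
    ssw <- shear_stress_experiment_on(base_mesh(), params, probe_shear, solver)
    c(Yeff = dsw$Yeff, nueff = dsw$nueff, mueff = ssw$mueff)
  }
  base <- run_once(1)
  rows <- lapply(targets, function(tg) {
    v <- if (tg == 1) base else run_once(tg)
    data.frame(target = tg,
               Yeff = v[["Yeff"]], nueff = v[["nueff"]], mueff = v[["mueff"]],
               dY = v[["Yeff"]] / base[["Yeff"]] - 1,
               dnu = v[["nueff"]] / base[["nueff"]] - 1,
               dmu = v[["mueff"]] / base[["mueff"]] - 1)
  })
  do.call(rbind, rows)
}

# single-level direct experiment on a prepared (possibly grown) mesh
direct_stress_experiment_on <- function(mesh, params, axis, sigma, solver) {
  size <- diff(range(mesh$pos[, 1]))
  solver <- .with_thr(solver, .level_thr(solver, sigma, size, mesh$L0))
  pre <- relax(mesh, params, loads = NULL, solver = solver)
  e0 <- c(x = interior_strain(pre, "x"), y = interior_strain(pre, "y"))
  edge <- if (axis == "y") "top" else "right"
  loads <- load_protocol(edges = list(list(edge = edge, sigma = sigma,
                                           direction = "normal")))
  m <- relax(pre, params, loads, solver)
  ea <- interior_strain(m, if (axis == "y") "y" else "x") -
    e0[[if (axis == "y") "y" else "x"]]
  ep <- interior_strain(m, if (axis == "y") "x" else "y") -
    e0[[if (axis == "y") "x" else "y"]]
  data.frame(Yeff = sigma / ea, nueff = -ep / ea)
}

# single-level shear experiment on a prepared mesh
shear_stress_experiment_on <- function(mesh, params, total, solver) {
  size <- diff(range(mesh$pos[, 1]))
  solver <- .with_thr(solver, .level_thr(solver, total, size, mesh$L0))
  pre <- relax(mesh, params, loads = NULL, solver = solver)
  tau0 <- interior_shear(pre)
  m <- relax(pre, params, shear_protocol(total), solver)
  data.frame(mueff = total / (interior_shear(m) - tau0))
}
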