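#' Solver parameters for the damped Verlet relaxation
#'
#' Defaults are the scheme's reference setting: dimensionless Verlet step
#' `hgamma = 0.01`, point mass `m = 1` ug, damping `eta = 1` (in units of
#' N·hgamma/um, so the viscous force is `-eta (pos - prev)/hgamma`) and the
#' convergence threshold `thr = 0.05` uN on the per-point resultant force.
#' Mass and damping have no physical meaning: they set the convergence path,
#' not the equilibrium.
#'
#' @param hgamma dimensionless Verlet integration step.
#' @param mass point mass (ug).
#' @param eta damping constant.
#' @param thr convergence threshold (uN): relaxation stops when the largest
#'   per-point static force norm (viscous force excluded, constrained
#'   components projected out) drops below `thr`.
#' @param max_steps guard on the number of Verlet steps.
#' @return object of class `pm_solver`.
#' @export
solver_params <- function(hgamma = 0.01, mass = 1, eta = 1, thr = 0.05,
                          max_steps = 2e6) {
  stopifnot(hgamma > 0, mass > 0, eta > 0, thr > 0, max_steps >= 1)
  structure(list(hgamma = hgamma, mass = mass, eta = eta, thr = thr,
                 max_steps = max_steps), class = "pm_solver")
}

#' Solver tuned to the specimen's slowest elastic mode
#'
#' Mass and damping do not affect the equilibrium, only the convergence
#' path; the reference damping is strongly over-damped for the slowest
#' breathing mode of large specimens and makes relaxation needlessly slow.
#' This helper picks a damping constant near critical for the slowest mode
#' (`eta ~ 2 m omega_min`, with `omega_min ~ pi sqrt(S/m) / N` for a
#' specimen of `N` spacings and dominant stiffness `S = max(lambda + 2 mu)`)
#' and a Verlet step safely below the stability limit of the fastest mode.
#'
#' @param params a `pm_material`.
#' @param size specimen extent (um).
#' @param L0 spring length (um).
#' @param thr convergence threshold (uN); `NULL` picks a threshold tight
#'   enough that the residual strain error of the softest long-wavelength
#'   mode stays around 2e-4 (the per-point force criterion gets weaker for
#'   softer and larger specimens, so the threshold scales with
#'   `S_soft / N`).
#' @param mass point mass (ug).
#' @param max_steps step guard.
#' @return a `pm_solver`.
#' @export
tuned_solver <- function(params, size = 100, L0 = 1, thr = NULL, mass = 1,
                         max_steps = 2e6) {
  S_stiff <- max(params$lamx + 2 * params$mux,
                 params$lamy + 2 * params$muy) + 2 * params$pt
  # softest long-wavelength mode: direct stiffness or the (possibly
  # turgor-only) shear stiffness, whichever is weaker
  S_soft <- min(params$lamx + 2 * params$mux, params$lamy + 2 * params$muy)
  S_shear <- (if (params$hinges) params$mux + params$muy else 0) + 2 * params$pt
  if (S_shear > 0) S_soft <- min(S_soft, S_shear)
  N <- max(size / L0, 2)
  omega_min <- pi * sqrt(S_soft / mass) / N
  eta <- 2 * mass * omega_min
  hgamma <- min(0.35 / sqrt(8 * S_stiff / mass), 0.05)
  if (is.null(thr)) thr <- max(4e-4 * S_soft / N, 1e-6)
  solver_params(hgamma = hgamma, mass = mass, eta = max(eta, 1e-3), thr = thr,
                max_steps = max_steps)
}

#' Advance the mesh by one Verlet step
#'
#' Two-step Verlet rule `x(g+h) = 2 x(g) - x(g-h) + a h^2`; from rest the
#' half-acceleration form `x(h) = x(0) + a h^2 / 2` is used. The
#' acceleration includes the supplied static forces plus the viscous force.
#' Constrained coordinates are re-projected after the update.
#'
#' @param mesh a `pm_mesh`.
#' @param forces n x 2 matrix of static forces (elastic + turgor + applied).
#' @param solver a `pm_solver`.
#' @param first logical: use the initial half-acceleration form.
#' @return the advanced mesh.
#' @export
verlet_step <- function(mesh, forces, solver = solver_params(), first = FALSE) {
  h <- solver$hgamma
  fd <- -solver$eta * (mesh$pos - mesh$prev) / h
  acc <- (forces + fd) / solver$mass
  new <- if (first) mesh$pos + 0.5 * acc * h^2
         else 2 * mesh$pos - mesh$prev + acc * h^2
  if (any(!is.finite(new)))
    stop("verlet step produced non-finite positions")
  cs <- mesh$constraint
  new[cs == 1L, ] <- mesh$fixpos[cs == 1L, ]
  new[cs == 2L, 2] <- mesh$fixpos[cs == 2L, 2]
  new[cs == 3L, 1] <- mesh$fixpos[cs == 3L, 1]
  mesh$prev <- mesh$pos
  mesh$pos <- new
  mesh
}

#' Relax the mesh to elastostatic equilibrium
#'
#' Damped Verlet integration under constant loads until the resultant static
#' force on every point (viscous term excluded — it vanishes at equilibrium)
#' is below the solver threshold. The equilibrium does not depend on mass or
#' damping; those only set the number of steps needed.
#'
#' @param mesh a `pm_mesh`.
#' @param params a `pm_material` (its `pt` drives the turgor load).
#' @param loads a `pm_loads` or `NULL`.
#' @param solver a `pm_solver`.
#' @param from_rest logical: start with the half-acceleration first step and
#'   a cleared velocity history (default takes the mesh's stored history).
#' @return the relaxed mesh, with attributes `steps` and `residual`.
#' @export
relax <- function(mesh, params, loads = NULL, solver = solver_params(),
                  from_rest = TRUE) {
  if (from_rest) mesh$prev <- mesh$pos
  el <- .edge_load_list(mesh, loads)
  pf <- .point_force_matrix(mesh, loads)
  out <- core_relax(mesh, .mat_list(params), el, pf,
                    solver$hgamma, solver$mass, solver$eta, solver$thr,
                    solver$max_steps, first = from_rest)
  if (!out$converged)
    stop(sprintf(
      "relaxation did not converge in %d steps (residual %.4g uN > thr %.4g)",
      as.integer(out$steps), out$residual, solver$thr))
  mesh$pos <- out$pos
  mesh$prev <- out$prev
  attr(mesh, "steps") <- out$steps
  attr(mesh, "residual") <- out$residual
  mesh
}

#' Remove rigid-body motion relative to a reference configuration
#'
#' Least-squares optimal 2D rigid transform (rotation + translation over all
#' points) from the current onto the reference configuration, applied to
#' positions and Verlet history alike. Lengths and angles — hence the
#' elastic energy — are unchanged; this is a reporting frame for
#' free-floating media.
#'
#' @param mesh a `pm_mesh`.
#' @param reference a `pm_mesh` with the same point ids (extra points in
#'   `mesh` after remeshing are allowed; the transform is estimated on the
#'   common leading ids).
#' @return the re-framed mesh.
#' @export
remove_rigid_motion <- function(mesh, reference) {
  n <- min(npoints(mesh), npoints(reference))
  p <- mesh$pos[seq_len(n), , drop = FALSE]
  q <- reference$pos[seq_len(n), , drop = FALSE]
  pc <- colMeans(p); qc <- colMeans(q)
  H <- crossprod(sweep(p, 2, pc), sweep(q, 2, qc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  shift <- function(m) sweep(sweep(m, 2, pc) %*% t(R), 2, qc, "+")
  mesh$pos <- shift(mesh$pos)
  mesh$prev <- shift(mesh$prev)
  mesh$fixpos <- shift(mesh$fixpos)
  mesh
}
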