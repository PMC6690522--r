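#' Shoelace area of the tissue polygon
#'
#' Signed polygon area of the ordered boundary positions; positive for
#' counterclockwise input. The hydrostatic potential of the turgid tissue is
#' `-A_t * p_t`.
#'
#' @param boundary m x 2 matrix of boundary point positions in cyclic order.
#' @param check if `TRUE`, run a quadratic segment-intersection test and
#'   raise an error for self-intersecting polygons (debug aid).
#' @return signed area (um^2).
#' @export
tissue_area <- function(boundary, check = FALSE) {
  if (nrow(boundary) < 3) stop("polygon needs at least 3 vertices")
  if (check && .self_intersects(boundary))
    stop("boundary polygon is self-intersecting")
  x <- boundary[, 1]; y <- boundary[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# brute-force proper-crossing test between non-adjacent polygon edges
.self_intersects <- function(p) {
  m <- nrow(p)
  nxt <- c(2:m, 1)
  ccw <- function(a, b, cc)
    (p[b, 1] - p[a, 1]) * (p[cc, 2] - p[a, 2]) -
    (p[b, 2] - p[a, 2]) * (p[cc, 1] - p[a, 1])
  for (i in seq_len(m - 2)) {
    for (j in (i + 1):m) {
      i2 <- nxt[i]; j2 <- nxt[j]
      if (j == i2 || j2 == i) next
      d1 <- ccw(i, i2, j); d2 <- ccw(i, i2, j2)
      d3 <- ccw(j, j2, i); d4 <- ccw(j, j2, i2)
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Turgor nodal forces
#'
#' The negative gradient of the hydrostatic potential `-A_t p_t` with respect
#' to each border point: for border point `i` with cyclic neighbours
#' `i-1`, `i+1` (counterclockwise),
#' \deqn{f_i = \frac{p_t}{2}\,(y_{i+1}-y_{i-1},\; x_{i-1}-x_{i+1}).}
#' Interior points carry no turgor force; the net force and torque on a
#' closed boundary vanish identically.
#'
#' @param mesh a `pm_mesh`.
#' @param pt turgor pressure (MPa·m).
#' @return n x 2 matrix of nodal forces (uN), zero rows for interior points.
#' @export
turgor_forces <- function(mesh, pt) {
  n <- npoints(mesh)
  f <- matrix(0, n, 2)
  cyc <- mesh$cycle
  if (pt == 0 || length(cyc) < 3) return(f)
  nxt <- c(cyc[-1], cyc[1])
  prv <- c(cyc[length(cyc)], cyc[-length(cyc)])
  f[cyc, 1] <- 0.5 * pt * (mesh$pos[nxt, 2] - mesh$pos[prv, 2])
  f[cyc, 2] <- 0.5 * pt * (mesh$pos[prv, 1] - mesh$pos[nxt, 1])
  f
}

#' Viscous damping force
#'
#' `-eta` times the backward-difference velocity of a point over one Verlet
#' step. Purely numerical: it does not affect the equilibrium configuration,
#' only the convergence path.
#'
#' @param pos,prev current and previous position (length-2).
#' @param eta damping constant.
#' @param hgamma dimensionless Verlet step.
#' @return length-2 force vector.
#' @export
viscous_force <- function(pos, prev, eta = 1, hgamma = 0.01) {
  -eta * (pos - prev) / hgamma
}

#' Nodal forces realizing a prescribed boundary stress
#'
#' Converts a uniform stress on one mesh edge into lumped nodal forces: each
#' point takes `sigma` times the half-lengths of its incident boundary
#' springs, with the edge end points taking their single incident segment at
#' full weight (the lattice transmits boundary stress through all N+1
#' parallel spring lines, and the uniform per-point load is the exact
#' natural load of an affinely strained lattice). The load is a follower
#' load: it tracks the current, deformed edge length. Direction is normal
#' or tangential to the undeformed edge axis.
#'
#' @param mesh a `pm_mesh`.
#' @param edge `"top"`, `"bottom"`, `"left"` or `"right"`.
#' @param sigma stress (MPa·m); for `direction = "normal"` positive is
#'   outward tension, for `"tangential"` positive follows the pure-shear
#'   sign convention (+x on top, -x on bottom, +y on right, -y on left).
#' @param direction `"normal"` or `"tangential"`.
#' @return data frame `id`, `fx`, `fy` of nodal forces at the current
#'   configuration (the solver re-evaluates them every step).
#' @export
boundary_stress_forces <- function(mesh, edge, sigma,
                                   direction = c("normal", "tangential")) {
  direction <- match.arg(direction)
  ids <- edge_points(mesh, edge)
  dir <- .edge_dir(edge, direction)
  f <- matrix(0, length(ids), 2)
  if (sigma != 0 && length(ids) >= 2) {
    p <- mesh$pos[ids, , drop = FALSE]
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    w <- c(seg, 0) / 2 + c(0, seg) / 2
    # edge end points take their incident segment at full weight: the
    # lattice carries boundary stress through all N+1 parallel spring
    # lines, and the uniform per-point load is the exact natural load of
    # an affinely strained lattice
    w[1] <- w[1] + seg[1] / 2
    w[length(w)] <- w[length(w)] + seg[length(seg)] / 2
    f <- outer(sigma * w, dir)
  }
  out <- data.frame(id = ids, fx = f[, 1], fy = f[, 2])
  if (sigma == 0) out[0, ] else out
}

.edge_dir <- function(edge, direction) {
  if (direction == "normal")
    switch(edge, top = c(0, 1), bottom = c(0, -1), left = c(-1, 0), right = c(1, 0))
  else
    switch(edge, top = c(1, 0), bottom = c(-1, 0), left = c(0, -1), right = c(0, 1))
}

#' Declarative load protocol for one virtual experiment
#'
#' @param edges list of edge loads, each `list(edge =, sigma =, direction =)`.
#' @param point_forces data frame `id`, `fx`, `fy` of constant point forces,
#'   or `NULL`.
#' @return object of class `pm_loads`.
#' @export
load_protocol <- function(edges = list(), point_forces = NULL) {
  structure(list(edges = edges, point_forces = point_forces),
            class = "pm_loads")
}

#' Pure-shear load protocol
#'
#' Equal tangential tractions on all four walls (`S_xy` on top/bottom,
#' `S_yx` on left/right, identical magnitudes) generating a positive pure
#' shear with zero net force and torque.
#'
#' @param total total applied shear stress `S_xy + S_yx` (MPa·m).
#' @return a `pm_loads`.
#' @export
shear_protocol <- function(total) {
  s <- total / 2
  load_protocol(edges = list(
    list(edge = "top", sigma = s, direction = "tangential"),
    list(edge = "bottom", sigma = s, direction = "tangential"),
    list(edge = "left", sigma = s, direction = "tangential"),
    list(edge = "right", sigma = s, direction = "tangential")))
}

# internal: edge loads in the form the compiled solver consumes
.edge_load_list <- function(mesh, loads) {
  if (is.null(loads) || length(loads$edges) == 0) return(list())
  lapply(loads$edges, function(el) {
    direction <- if (is.null(el$direction)) "normal" else el$direction
    list(ids = edge_points(mesh, el$edge),
         dir = .edge_dir(el$edge, direction),
         sigma = el$sigma)
  })
}

.point_force_matrix <- function(mesh, loads) {
  if (is.null(loads) || is.null(loads$point_forces)) return(NULL)
  pf <- matrix(0, npoints(mesh), 2)
  pf[loads$point_forces$id, 1] <- loads$point_forces$fx
  pf[loads$point_forces$id, 2] <- loads$point_forces$fy
  pf
}
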