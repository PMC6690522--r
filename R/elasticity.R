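#' Direct strain of a single spring
#'
#' `(current length - resting length) / resting length`; extension positive.
#'
#' @param mesh a `pm_mesh`.
#' @param s spring id(s); all springs if missing.
#' @return dimensionless strain(s).
#' @export
spring_strain <- function(mesh, s) {
  if (missing(s)) s <- seq_along(mesh$sa)
  a <- mesh$sa[s]; b <- mesh$sb[s]
  len <- sqrt(rowSums((mesh$pos[b, , drop = FALSE] - mesh$pos[a, , drop = FALSE])^2))
  (len - mesh$srest[s]) / mesh$srest[s]
}

#' @rdname spring_strain
#' @export
spring_strains <- function(mesh) spring_strain(mesh)

#' Hinge shear measures from two spring vectors
#'
#' For a hinge with arm vectors `xn` (x-spring) and `yn` (y-spring) the shear
#' state is described by the cosine of the angle deviation
#' `a_n = xn.yn/(|xn||yn|)`, the hinge shear strain
#' `tau_n = tan(arcsin(a_n)) = a_n/sqrt(1-a_n^2)` and the parallelogram area
#' `A_n = |xn x yn|`.
#'
#' @param xn,yn numeric length-2 arm vectors.
#' @return named vector `c(a =, tau =, A =)`.
#' @export
hinge_shear <- function(xn, yn) {
  nx <- sqrt(sum(xn^2)); ny <- sqrt(sum(yn^2))
  if (nx == 0 || ny == 0) stop("degenerate hinge: zero-length arm")
  a <- sum(xn * yn) / (nx * ny)
  if (abs(a) >= 1 - 1e-12) stop("degenerate (collapsed) hinge configuration")
  c(a = a, tau = a / sqrt(1 - a^2), A = abs(xn[1] * yn[2] - xn[2] * yn[1]))
}

#' Per-point shear strain field
#'
#' The total shear strain at each mass point: the mean over its adjacent
#' hinges of the hinge shear strains `tau_n`, signed per hinge quadrant so
#' that a positive simple shear gives a positive value at every point. Loose
#' points use the auxiliary-point construction for their missing arm.
#'
#' @param mesh a `pm_mesh`.
#' @return numeric vector, one value per point (`NA` for points with no
#'   hinge).
#' @export
point_shear <- function(mesh) core_point_shear(mesh)

#' Elastic energy of the mesh
#'
#' Sum over springs of the direct and Poisson (cross) contributions and over
#' hinges of the shear contribution, using the same stiffness components,
#' mean-of-adjacent conventions and current mean cell areas as the force
#' assembly. The nodal elastic force approximates the negative gradient of
#' this energy: exactly for the hinge term with frozen areas, and up to terms
#' of order strain (the neglected area derivatives) otherwise. Used by the
#' gradient-oracle tests, not by the force loop.
#'
#' @param mesh a `pm_mesh`.
#' @param params a `pm_material`.
#' @return energy in MPa·m·um^2.
#' @export
elastic_energy <- function(mesh, params) {
  n <- npoints(mesh)
  A <- mean_cell_area(mesh)
  e <- spring_strains(mesh)
  # per-point mean strain / mean rest by orientation
  mstat <- .orient_means(mesh, e)

  E <- 0
  for (s in seq_along(mesh$sa)) {
    o <- mesh$sor[s]
    lam <- if (o == 1L) params$lamx else params$lamy
    mu <- if (o == 1L) params$mux else params$muy
    x0 <- mesh$srest[s]
    base <- 0; ebar <- 0
    for (p in c(mesh$sa[s], mesh$sb[s])) {
      p0m <- mstat$mrest[p, 3 - o]; if (is.na(p0m)) p0m <- x0
      eb <- mstat$mstrain[p, 3 - o]; if (is.na(eb)) eb <- 0
      base <- base + 0.5 * A[p]^2 / (x0 * p0m)
      ebar <- ebar + 0.5 * eb
    }
    # direct term plus the cross (Poisson) term, the latter split half/half
    # between the two orientations so each pairing is counted once in total
    E <- E + 0.5 * (lam + 2 * mu) * base * e[s]^2 +
      0.5 * lam * base * e[s] * ebar
  }
  if (params$hinges) {
    hs <- .point_hinge_table(mesh)
    if (nrow(hs)) {
      mu2 <- params$mux + params$muy
      st <- hs$s / (1 + hs$s^2)
      E <- E + sum((mu2 / (4 * hs$N)) * hs$An^2 /
                     ((hs$x0^2 + hs$y0^2) * 4 * st^2) * hs$tau^2)
    }
  }
  E
}

# per-point mean strain and mean rest length of incident springs by
# orientation (col 1 = x springs, col 2 = y springs)
.orient_means <- function(mesh, e = spring_strains(mesh)) {
  n <- npoints(mesh)
  msum <- matrix(0, n, 2); rsum <- matrix(0, n, 2); cnt <- matrix(0L, n, 2)
  for (s in seq_along(mesh$sa)) {
    o <- mesh$sor[s]
    for (p in c(mesh$sa[s], mesh$sb[s])) {
      msum[p, o] <- msum[p, o] + e[s]
      rsum[p, o] <- rsum[p, o] + mesh$srest[s]
      cnt[p, o] <- cnt[p, o] + 1L
    }
  }
  list(mstrain = ifelse(cnt > 0, msum / cnt, NA_real_),
       mrest = ifelse(cnt > 0, rsum / cnt, NA_real_))
}

# enumerate the hinges cornered at every point: one row per hinge with arm
# geometry, rest lengths, parallelogram area and the point's hinge count N
.point_hinge_table <- function(mesh) {
  rows <- list(); k <- 0L
  for (i in seq_len(npoints(mesh))) {
    hs <- .hinges_at(mesh, i)
    for (h in hs) {
      k <- k + 1L
      rows[[k]] <- data.frame(i = i, N = length(hs), an = h$an, tau = h$tau,
                              An = h$An, x0 = h$x0, y0 = h$y0,
                              s = max(h$x0, h$y0) / min(h$x0, h$y0),
                              sgn = h$sgn)
    }
  }
  if (k == 0L) return(data.frame())
  do.call(rbind, rows)
}

# hinges cornered at point i, auxiliary arms synthesized for loose points
.hinges_at <- function(mesh, i) {
  out <- list()
  arm <- function(d) {
    j <- mesh$nbr[i, d]
    if (j > 0)
      return(list(v = mesh$pos[j, ] - mesh$pos[i, ],
                  rest = mesh$srest[mesh$pspr[i, d]], aux = FALSE))
    ax <- .aux_arm(mesh, i, d)
    if (is.null(ax)) NULL else c(ax, list(aux = TRUE))
  }
  for (dx in c(.DIR_R, .DIR_L)) {
    axm <- arm(dx)
    if (is.null(axm)) next
    for (dy in c(.DIR_U, .DIR_D)) {
      aym <- arm(dy)
      if (is.null(aym) || (axm$aux && aym$aux)) next
      hsv <- hinge_shear(axm$v, aym$v)
      sgn <- if ((dx == .DIR_R) == (dy == .DIR_U)) 1 else -1
      out[[length(out) + 1L]] <- list(
        dx = dx, dy = dy, xv = axm$v, yv = aym$v,
        x0 = axm$rest, y0 = aym$rest,
        an = hsv[["a"]], tau = hsv[["tau"]], An = hsv[["A"]], sgn = sgn,
        aux = axm$aux || aym$aux)
    }
  }
  out
}

# auxiliary arm for a loose point: vector to the midpoint of the spring
# between next-next neighbours; rest length copied from the left (missing y)
# or upper (missing x) neighbour
.aux_arm <- function(mesh, i, d) {
  perp <- if (d <= 2) c(.DIR_U, .DIR_D) else c(.DIR_L, .DIR_R)
  p1 <- mesh$nbr[i, perp[1]]; p2 <- mesh$nbr[i, perp[2]]
  if (p1 == 0 || p2 == 0) return(NULL)
  q1 <- mesh$nbr[p1, d]; q2 <- mesh$nbr[p2, d]
  if (q1 == 0 || q2 == 0) return(NULL)
  rest <- if (mesh$pspr[p1, d] > 0) mesh$srest[mesh$pspr[p1, d]]
          else if (mesh$pspr[p2, d] > 0) mesh$srest[mesh$pspr[p2, d]]
          else return(NULL)
  list(v = (mesh$pos[q1, ] + mesh$pos[q2, ]) / 2 - mesh$pos[i, ], rest = rest)
}

#' Hinge shear strains of a loose point via the auxiliary construction
#'
#' A loose point (three neighbours after remeshing) still carries four hinge
#' strains: the missing arm is synthesized from an auxiliary point at the
#' midpoint of the spring between next-next neighbours, with the resting
#' length of the left (missing y-arm) or upper (missing x-arm) neighbour.
#' No force acts on the auxiliary point.
#'
#' @param mesh a `pm_mesh`.
#' @param i a loose point id.
#' @return data frame with one row per hinge: `an`, `tau` and whether the
#'   hinge uses an auxiliary arm.
#' @export
loose_point_hinge_strain <- function(mesh, i) {
  if (!(i %in% loose_points(mesh)))
    stop("point ", i, " is not a loose point")
  hs <- .hinges_at(mesh, i)
  data.frame(an = vapply(hs, `[[`, 0, "an"),
             tau = vapply(hs, `[[`, 0, "tau"),
             aux = vapply(hs, `[[`, TRUE, "aux"))
}

#' Elastic nodal forces
#'
#' The elastic force on every mass point: per incident spring the direct and
#' Poisson (cross-strain) terms with the stiffness components evaluated at
#' the point's current mean cell area, plus the hinge shear force summed
#' over the point's adjacent hinges.
#'
#' @param mesh a `pm_mesh`.
#' @param params a `pm_material`. The turgor pressure in `params` is ignored
#'   here; see [static_forces()] for the full load assembly.
#' @return n x 2 matrix of forces (uN).
#' @export
elastic_forces <- function(mesh, params) {
  mat <- .mat_list(params, pt = 0)
  core_forces(mesh, mat, list(), NULL)$force
}

#' @rdname elastic_forces
#' @param i single point id.
#' @export
elastic_force <- function(mesh, params, i) elastic_forces(mesh, params)[i, ]

.mat_list <- function(params, pt = params$pt) {
  list(lamx = params$lamx, mux = params$mux, lamy = params$lamy,
       muy = params$muy, pt = pt, hinges = params$hinges)
}

#' Full static force assembly (elastic + turgor + applied loads)
#'
#' @param mesh a `pm_mesh`.
#' @param params a `pm_material` (its `pt` drives the turgor term).
#' @param loads a `pm_loads` object from [load_protocol()], or `NULL`.
#' @return list with the n x 2 force matrix and the convergence residual
#'   (max point-force norm with constrained components projected out).
#' @export
static_forces <- function(mesh, params, loads = NULL) {
  el <- .edge_load_list(mesh, loads)
  pf <- .point_force_matrix(mesh, loads)
  core_forces(mesh, .mat_list(params), el, pf)
}
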