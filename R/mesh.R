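#' @useDynLib phytomech, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames
NULL

# Direction slots used in nbr/pspr matrices: 1=R(+x), 2=L(-x), 3=U(+y), 4=D(-y)
.DIR_R <- 1L; .DIR_L <- 2L; .DIR_U <- 3L; .DIR_D <- 4L

#' Build a rectangular mass-point/spring/hinge lattice
#'
#' Constructs the square lattice on which the tissue mechanics is solved:
#' `(width/L0 + 1) x (height/L0 + 1)` mass points on a regular grid, springs
#' of resting length `L0` between direct neighbours in the x- and y-direction,
#' and a hinge in every unit-cell corner. The mesh starts at rest
#' (`prev_pos == pos`, all strains zero).
#'
#' @param width,height mesh dimensions in micrometres; must be positive
#'   multiples of `L0`.
#' @param L0 initial spring resting length in micrometres (default 1).
#' @return An object of class `pm_mesh`: a list with point positions (`pos`,
#'   an n x 2 matrix in micrometres), Verlet history (`prev`), logical grid
#'   coordinates (`grid`, fractional after remeshing), the spring table
#'   (`sa`, `sb`, `sor` with 1 = x / 2 = y orientation, `srest`, `sborder`),
#'   per-point constraint codes, the counterclockwise boundary cycle and
#'   derived topology (`nbr`, `pspr`).
#' @examples
#' m <- build_rectangular_mesh(2, 1)
#' npoints(m)   # 6
#' nsprings(m)  # 7
#' @export
build_rectangular_mesh <- function(width, height, L0 = 1) {
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("mesh dimensions must be positive")
  nx <- width / L0
  ny <- height / L0
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("mesh dimensions must be integer multiples of the spring length L0")
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))

  cols <- nx + 1L; rows <- ny + 1L
  grid <- cbind(row = rep(seq_len(rows) - 1, each = cols),
                col = rep(seq_len(cols) - 1, times = rows))
  pos <- cbind(x = grid[, "col"] * L0, y = grid[, "row"] * L0)
  n <- nrow(pos)
  id_at <- function(r, c) r * cols + c + 1L

  # x-springs: (r, c)-(r, c+1); y-springs: (r, c)-(r+1, c)
  rx <- rep(0:(rows - 1L), each = nx); cx <- rep(0:(nx - 1L), times = rows)
  ry <- rep(0:(ny - 1L), each = cols); cy <- rep(0:(cols - 1L), times = ny)
  sa <- c(id_at(rx, cx), id_at(ry, cy))
  sb <- c(id_at(rx, cx + 1L), id_at(ry + 1L, cy))
  sor <- rep(c(1L, 2L), c(length(rx), length(ry)))
  sborder <- c(rx == 0L | rx == rows - 1L, cy == 0L | cy == cols - 1L)

  mesh <- structure(list(
    pos = unname(pos), prev = unname(pos), grid = unname(grid),
    sa = as.integer(sa), sb = as.integer(sb), sor = sor,
    srest = rep(as.numeric(L0), length(sa)), sborder = sborder,
    L0 = as.numeric(L0), time = 0,
    constraint = integer(n), fixpos = unname(pos)
  ), class = "pm_mesh")
  rebuild_topology(mesh)
}

#' Rebuild derived topology (neighbour tables and boundary cycle)
#'
#' Recomputes, from the spring table and grid coordinates, the per-point
#' neighbour matrix `nbr`, the per-point spring matrix `pspr` (direction
#' slots R/L/U/D) and the counterclockwise boundary cycle. Called internally
#' after construction and after every remeshing pass.
#'
#' @param mesh a `pm_mesh`.
#' @return the mesh with `nbr`, `pspr` and `cycle` refreshed.
#' @export
rebuild_topology <- function(mesh) {
  n <- nrow(mesh$pos)
  nbr <- matrix(0L, n, 4)
  pspr <- matrix(0L, n, 4)
  a <- mesh$sa; b <- mesh$sb
  dx <- mesh$grid[b, 2] - mesh$grid[a, 2]
  dy <- mesh$grid[b, 1] - mesh$grid[a, 1]
  da <- ifelse(mesh$sor == 1L,
               ifelse(dx > 0, .DIR_R, .DIR_L),
               ifelse(dy > 0, .DIR_U, .DIR_D))
  db <- c(.DIR_L, .DIR_R, .DIR_D, .DIR_U)[da]
  slots <- rbind(cbind(a, da), cbind(b, db))
  if (anyDuplicated(slots))
    stop("inconsistent topology: duplicate neighbour slot")
  nbr[slots] <- c(b, a)
  pspr[slots] <- c(seq_along(a), seq_along(a))
  mesh$nbr <- nbr
  mesh$pspr <- pspr
  mesh$cycle <- .build_cycle(mesh)
  mesh
}

# walk the border springs into a simple CCW cycle
.build_cycle <- function(mesh) {
  bs <- which(mesh$sborder)
  if (length(bs) < 3) return(integer(0))
  pts <- sort(unique(c(mesh$sa[bs], mesh$sb[bs])))
  adj <- vector("list", nrow(mesh$pos))
  for (s in bs) {
    adj[[mesh$sa[s]]] <- c(adj[[mesh$sa[s]]], mesh$sb[s])
    adj[[mesh$sb[s]]] <- c(adj[[mesh$sb[s]]], mesh$sa[s])
  }
  deg <- lengths(adj[pts])
  if (any(deg != 2))
    stop("broken boundary topology: border point without two border springs")
  start <- min(pts)
  cyc <- integer(length(pts))
  cyc[1] <- start
  cyc[2] <- min(adj[[start]])
  for (k in 3:length(pts)) {
    nxt <- adj[[cyc[k - 1]]]
    cyc[k] <- nxt[nxt != cyc[k - 2]][1]
  }
  if (anyNA(cyc) || length(unique(cyc)) != length(pts))
    stop("broken boundary topology: border walk did not close")
  x <- mesh$pos[cyc, 1]; y <- mesh$pos[cyc, 2]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (area2 < 0) cyc <- c(cyc[1], rev(cyc[-1]))
  cyc
}

#' @export
npoints <- function(mesh) nrow(mesh$pos)

#' @export
nsprings <- function(mesh) length(mesh$sa)

#' Number of hinges in the mesh
#'
#' Counts the hinges cornered at every point: one per (x-spring, y-spring)
#' pair incident on the point, i.e. 4 for interior points, 2 for border edge
#' points, 1 for corners.
#' @param mesh a `pm_mesh`.
#' @export
nhinges <- function(mesh) {
  hx <- (mesh$nbr[, .DIR_R] > 0) + (mesh$nbr[, .DIR_L] > 0)
  hy <- (mesh$nbr[, .DIR_U] > 0) + (mesh$nbr[, .DIR_D] > 0)
  sum(hx * hy)
}

#' Loose points (three neighbours, created by remeshing)
#' @param mesh a `pm_mesh`.
#' @return integer ids of points whose missing neighbour direction points
#'   into the tissue (remeshing-created loose ends), as opposed to regular
#'   border points.
#' @export
loose_points <- function(mesh) {
  deg <- rowSums(mesh$nbr > 0)
  cand <- which(deg < 4)
  out <- integer(0)
  for (i in cand) {
    for (d in 1:4) {
      if (mesh$nbr[i, d] != 0L) next
      perp <- if (d <= 2) c(.DIR_U, .DIR_D) else c(.DIR_R, .DIR_L)
      p1 <- mesh$nbr[i, perp[1]]; p2 <- mesh$nbr[i, perp[2]]
      if (p1 > 0 && p2 > 0 && mesh$nbr[p1, d] > 0 && mesh$nbr[p2, d] > 0) {
        out <- c(out, i)
        break
      }
    }
  }
  out
}

#' Mean unit-cell area around a mass point
#'
#' Arithmetic mean of the current (deformed) areas of the unit cells incident
#' on point `i` (4 for interior points, 2 for border points, 1 for corners).
#' Each cell area is the shoelace area of its four corner points; cells whose
#' fourth corner is unavailable fall back to the parallelogram spanned by the
#' two hinge arms. This quantity is the area variable of the nodal force
#' terms.
#'
#' @param mesh a `pm_mesh`.
#' @param i point id (optional; all points if missing).
#' @return area(s) in square micrometres.
#' @export
mean_cell_area <- function(mesh, i = NULL) {
  A <- core_point_area(mesh)
  if (is.null(i)) A else A[i]
}

#' Ordered boundary cycle of the tissue
#'
#' @param mesh a `pm_mesh`.
#' @return integer vector of border point ids in counterclockwise order
#'   (positive shoelace area), stable across calls for a fixed topology.
#' @export
boundary_cycle <- function(mesh) mesh$cycle

#' Fix or release boundary conditions on mesh points
#'
#' @param mesh a `pm_mesh`.
#' @param ids point ids to constrain.
#' @param type one of `"free"`, `"fixed"` (both coordinates frozen),
#'   `"horizontal"` (point may only move horizontally; y frozen) or
#'   `"vertical"` (x frozen). Frozen coordinates are pinned at the current
#'   position.
#' @return the modified mesh.
#' @export
constrain <- function(mesh, ids, type = c("fixed", "horizontal", "vertical", "free")) {
  type <- match.arg(type)
  code <- c(free = 0L, fixed = 1L, horizontal = 2L, vertical = 3L)[[type]]
  mesh$constraint[ids] <- code
  mesh$fixpos[ids, ] <- mesh$pos[ids, , drop = FALSE]
  mesh
}

#' Points on a named border of the mesh
#'
#' @param mesh a `pm_mesh`.
#' @param edge `"top"`, `"bottom"`, `"left"` or `"right"`.
#' @return point ids ordered along the edge (by grid coordinate), including
#'   any remeshing-inserted points at fractional grid positions.
#' @export
edge_points <- function(mesh, edge = c("top", "bottom", "left", "right")) {
  edge <- match.arg(edge)
  r <- mesh$grid[, 1]; cc <- mesh$grid[, 2]
  ids <- switch(edge,
    top    = which(r == max(r)),
    bottom = which(r == min(r)),
    left   = which(cc == min(cc)),
    right  = which(cc == max(cc)))
  key <- if (edge %in% c("top", "bottom")) cc[ids] else r[ids]
  ids[order(key)]
}

#' @export
print.pm_mesh <- function(x, ...) {
  cat(sprintf(
    "pm_mesh: %d points, %d springs, %d hinges (L0 = %g um, t = %g min)\n",
    npoints(x), nsprings(x), nhinges(x), x$L0, x$time))
  lp <- loose_points(x)
  if (length(lp)) cat(sprintf("  %d loose points\n", length(lp)))
  invisible(x)
}

#' @export
summary.pm_mesh <- function(object, ...) {
  e <- spring_strains(object)
  cat(sprintf("pm_mesh %d x %d-ish points, time %g min\n",
              length(unique(object$grid[, 1])),
              length(unique(object$grid[, 2])), object$time))
  cat(sprintf("  springs: %d (x: %d, y: %d), rest length range [%.3g, %.3g]\n",
              nsprings(object), sum(object$sor == 1L), sum(object$sor == 2L),
              min(object$srest), max(object$srest)))
  cat(sprintf("  strain range [%.3g, %.3g], boundary cycle length %d\n",
              min(e), max(e), length(object$cycle)))
  invisible(object)
}

#' @export
#' @importFrom graphics segments points
plot.pm_mesh <- function(x, strain = FALSE, ...) {
  a <- x$sa; b <- x$sb
  col <- "grey40"
  if (strain) {
    e <- spring_strains(x)
    pal <- grDevices::colorRampPalette(c("blue", "grey80", "red"))(101)
    sc <- pmax(pmin(e / max(abs(e), 1e-12), 1), -1)
    col <- pal[round(50 * (sc + 1)) + 1]
  }
  plot(x$pos, asp = 1, pch = 16, cex = 0.3, xlab = "x [um]", ylab = "y [um]", ...)
  segments(x$pos[a, 1], x$pos[a, 2], x$pos[b, 1], x$pos[b, 2], col = col)
  invisible(x)
}
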