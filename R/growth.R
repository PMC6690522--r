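#' Maximal relative elemental growth rate
#'
#' `ln(4/3)/60` per minute (one third per hour), the upper bound used for
#' growth-rate fields.
#' @export
k_max_rate <- function() log(4 / 3) / 60

#' Growth-rate fields
#'
#' A growth field maps simulation time and position to the pair of relative
#' growth rates `(kx, ky)` (per minute) applied to spring resting lengths.
#' Supported kinds:
#' \describe{
#'   \item{uniform}{constant `kx`, `ky`.}
#'   \item{linear-gradient-y}{rates scale linearly across the y-extent
#'     between `frac_min` and 1 times the base rates (slow bottom, fast top
#'     for positive gradients); models one-sided elongation.}
#'   \item{linear-gradient-xy}{the same linear profile applied across both
#'     axes multiplicatively.}
#'   \item{custom}{`rate_fn(t, xy)` returning a 2-column matrix of rates.}
#' }
#'
#' @param kind field kind.
#' @param kx,ky base rates (min^-1); bounded by [k_max_rate()].
#' @param frac_min gradient fields: fraction of the base rate at the slow
#'   side (0 gives a one-sided ramp).
#' @param ymin,ymax,xmin,xmax extent over which gradient fields ramp
#'   (defaults are taken from the mesh at evaluation time).
#' @param rate_fn custom rate function.
#' @return object of class `pm_growth_field`, callable via
#'   [growth_rates()].
#' @export
growth_field <- function(kind = c("uniform", "linear-gradient-y",
                                  "linear-gradient-xy", "custom"),
                         kx = 0, ky = 0, frac_min = 0.25,
                         ymin = NULL, ymax = NULL, xmin = NULL, xmax = NULL,
                         rate_fn = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom" && !is.function(rate_fn))
    stop("custom fields need a rate_fn(t, xy)")
  structure(list(kind = kind, kx = kx, ky = ky, frac_min = frac_min,
                 ymin = ymin, ymax = ymax, xmin = xmin, xmax = xmax,
                 rate_fn = rate_fn),
            class = "pm_growth_field")
}

#' Evaluate a growth field
#'
#' @param field a `pm_growth_field`.
#' @param t simulation time (min).
#' @param xy m x 2 matrix of evaluation positions (spring midpoints).
#' @return m x 2 matrix of rates `(kx, ky)` in min^-1.
#' @export
growth_rates <- function(field, t, xy) {
  m <- nrow(xy)
  ramp <- function(v, lo, hi) {
    if (hi <= lo) return(rep(1, length(v)))
    f <- pmin(pmax((v - lo) / (hi - lo), 0), 1)
    field$frac_min + (1 - field$frac_min) * f
  }
  switch(field$kind,
    "uniform" = cbind(rep(field$kx, m), rep(field$ky, m)),
    "linear-gradient-y" = {
      lo <- if (is.null(field$ymin)) min(xy[, 2]) else field$ymin
      hi <- if (is.null(field$ymax)) max(xy[, 2]) else field$ymax
      g <- ramp(xy[, 2], lo, hi)
      cbind(field$kx * g, field$ky * g)
    },
    "linear-gradient-xy" = {
      loy <- if (is.null(field$ymin)) min(xy[, 2]) else field$ymin
      hiy <- if (is.null(field$ymax)) max(xy[, 2]) else field$ymax
      lox <- if (is.null(field$xmin)) min(xy[, 1]) else field$xmin
      hix <- if (is.null(field$xmax)) max(xy[, 1]) else field$xmax
      g <- ramp(xy[, 2], loy, hiy) * ramp(xy[, 1], lox, hix)
      cbind(field$kx * g, field$ky * g)
    },
    "custom" = {
      r <- field$rate_fn(t, xy)
      if (!is.matrix(r) || ncol(r) != 2) stop("rate_fn must return an m x 2 matrix")
      r
    })
}

#' One explicit Euler growth step
#'
#' Multiplies every spring's resting length by `1 + ht * k`, with the rate
#' of the spring's orientation evaluated at its current midpoint. Positions
#' are untouched; elastic relaxation follows separately (elastostatics).
#'
#' @param mesh a `pm_mesh`.
#' @param field a `pm_growth_field`.
#' @param ht growth integration step (min), default 1.
#' @param rate_guard `"warn"` (default), `"error"` or `"none"`: reaction to
#'   rates exceeding [k_max_rate()].
#' @return the grown mesh with `time` advanced by `ht`.
#' @export
growth_step <- function(mesh, field, ht = 1,
                        rate_guard = c("warn", "error", "none")) {
  rate_guard <- match.arg(rate_guard)
  if (ht <= 0) stop("growth step ht must be positive")
  mid <- (mesh$pos[mesh$sa, , drop = FALSE] + mesh$pos[mesh$sb, , drop = FALSE]) / 2
  k <- growth_rates(field, mesh$time, mid)
  if (rate_guard != "none" && any(k > k_max_rate() + 1e-12)) {
    msg <- sprintf("growth rate exceeds k_max = ln(4/3)/60 ~ %.4g min^-1",
                   k_max_rate())
    if (rate_guard == "error") stop(msg) else warning(msg)
  }
  ko <- ifelse(mesh$sor == 1L, k[, 1], k[, 2])
  mesh$srest <- mesh$srest * (1 + ht * ko)
  mesh$time <- mesh$time + ht
  mesh
}

#' Threshold-triggered remeshing
#'
#' Every spring whose resting length has reached twice the initial spring
#' length is split: a new mass point is inserted at the geometric midpoint
#' (with zero velocity), the spring is replaced by two springs of half its
#' resting and current length, and — when the facing parallel spring of an
#' adjacent cell has also split — transverse springs reconnect the grid.
#' New points that cannot yet be reconnected remain loose points (three
#' neighbours). Iterates until no spring is at or above threshold, so
#' afterwards every resting length is strictly below `2 L0`.
#'
#' @param mesh a `pm_mesh`.
#' @param trigger `"rest"` (default; deposition of new wall material tracks
#'   the plastically grown resting length) or `"current"` for
#'   current-length triggering in sensitivity tests.
#' @return the remeshed mesh with attribute `inserted` (number of new
#'   points).
#' @export
remesh <- function(mesh, trigger = c("rest", "current")) {
  trigger <- match.arg(trigger)
  inserted <- 0L
  repeat {
    len <- if (trigger == "rest") mesh$srest else {
      sqrt(rowSums((mesh$pos[mesh$sb, , drop = FALSE] -
                    mesh$pos[mesh$sa, , drop = FALSE])^2))
    }
    hot <- which(len >= 2 * mesh$L0 - 1e-12)
    if (!length(hot)) break
    mesh <- .split_springs(mesh, hot)
    inserted <- inserted + length(hot)
  }
  attr(mesh, "inserted") <- inserted
  mesh
}

# split the given springs at their midpoints (one batch), then reconnect
# transversely wherever the facing parallel spring of an adjacent cell is
# also split
.split_springs <- function(mesh, hot) {
  n0 <- npoints(mesh)
  a <- mesh$sa[hot]; b <- mesh$sb[hot]
  newids <- n0 + seq_along(hot)
  midpos <- (mesh$pos[a, , drop = FALSE] + mesh$pos[b, , drop = FALSE]) / 2
  midgrid <- (mesh$grid[a, , drop = FALSE] + mesh$grid[b, , drop = FALSE]) / 2
  mesh$pos <- rbind(mesh$pos, midpos)
  mesh$prev <- rbind(mesh$prev, midpos)   # zero velocity at insertion
  mesh$fixpos <- rbind(mesh$fixpos, midpos)
  mesh$grid <- rbind(mesh$grid, midgrid)
  mesh$constraint <- c(mesh$constraint, integer(length(hot)))
  half <- mesh$srest[hot] / 2
  # first half replaces the parent in place, second half is appended
  mesh$sb[hot] <- newids
  mesh$srest[hot] <- half
  mesh$sa <- c(mesh$sa, newids); mesh$sb <- c(mesh$sb, b)
  mesh$sor <- c(mesh$sor, mesh$sor[hot])
  mesh$srest <- c(mesh$srest, half)
  mesh$sborder <- c(mesh$sborder, mesh$sborder[hot])
  mesh <- rebuild_topology(mesh)

  # transverse reconnection of facing split points
  key <- paste(format(mesh$grid[, 1], digits = 12),
               format(mesh$grid[, 2], digits = 12))
  idx <- stats::setNames(seq_len(npoints(mesh)), key)
  add_a <- integer(0); add_b <- integer(0); add_o <- integer(0)
  add_r <- numeric(0)
  for (k in seq_along(hot)) {
    nid <- newids[k]; o <- mesh$sor[hot[k]]
    perp_dirs <- if (o == 1L) c(.DIR_U, .DIR_D) else c(.DIR_R, .DIR_L)
    for (d in perp_dirs) {
      q1 <- mesh$nbr[a[k], d]; q2 <- mesh$nbr[b[k], d]
      if (q1 == 0 || q2 == 0) next
      fr <- if (o == 1L) (mesh$grid[q1, 1] + mesh$grid[q2, 1]) / 2 else midgrid[k, 1]
      fc <- if (o == 1L) midgrid[k, 2] else (mesh$grid[q1, 2] + mesh$grid[q2, 2]) / 2
      hit <- idx[paste(format(fr, digits = 12), format(fc, digits = 12))]
      if (is.na(hit)) next
      # resting length: mean of the flanking perpendicular springs
      rest <- mean(c(mesh$srest[mesh$pspr[a[k], d]],
                     mesh$srest[mesh$pspr[b[k], d]]))
      add_a <- c(add_a, nid); add_b <- c(add_b, unname(hit))
      add_o <- c(add_o, if (o == 1L) 2L else 1L)
      add_r <- c(add_r, rest)
    }
  }
  if (length(add_a)) {
    dup <- duplicated(cbind(pmin(add_a, add_b), pmax(add_a, add_b)))
    mesh$sa <- c(mesh$sa, add_a[!dup]); mesh$sb <- c(mesh$sb, add_b[!dup])
    mesh$sor <- c(mesh$sor, add_o[!dup])
    mesh$srest <- c(mesh$srest, add_r[!dup])
    mesh$sborder <- c(mesh$sborder, rep(FALSE, sum(!dup)))
    mesh <- rebuild_topology(mesh)
  }
  mesh
}
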