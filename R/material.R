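#' Plane-stress Lame coefficients from a Young's modulus and Poisson ratio
#'
#' For a thin plate loaded in its plane (plane stress) the Lame pair of the
#' equivalent isotropic material is
#' \deqn{\lambda = \frac{Y\nu}{1-\nu^2}, \qquad \mu = \frac{Y}{2(1+\nu)}.}
#'
#' @param Y Young's modulus (thickness-integrated, MPa·m).
#' @param nu Poisson ratio; the cell wall is partially compressible, so
#'   `0 < nu < 0.5` is required (`nu = 0` is accepted as a limit).
#' @return named numeric vector `c(lambda =, mu =)` in MPa·m.
#' @examples
#' lame_coefficients(20, 0.2)  # lambda 4.1667, mu 8.3333
#' @export
lame_coefficients <- function(Y, nu) {
  if (!is.finite(Y) || Y <= 0) stop("Young's modulus must be positive")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("Poisson ratio must satisfy 0 <= nu < 0.5 (partially compressible)")
  c(lambda = Y * nu / (1 - nu^2), mu = Y / (2 * (1 + nu)))
}

#' Material parameters of the orthotropic tissue model
#'
#' Bundles the two directional Young's moduli, the Poisson ratio and the
#' turgor pressure, and derives the Lame coefficients used by the force
#' assembly. The shear modulus convention is the mean of the two isotropic
#' shear moduli: `2 mu = mu_x + mu_y`.
#'
#' @param Yx,Yy Young's moduli for the x- and y-fibre directions (MPa·m);
#'   `Yy` defaults to `Yx` (isotropic).
#' @param nu Poisson ratio (shared between directions).
#' @param pt turgor pressure (MPa·m), a constant hydrostatic load applied
#'   through the tissue boundary polygon; `>= 0`.
#' @param hinges logical; set `FALSE` to disable the hinge (shear) force term
#'   entirely, e.g. for the turgor-only shear oracle where the effective
#'   shear modulus must equal `2 * pt`.
#' @return object of class `pm_material`.
#' @export
material_params <- function(Yx, Yy = Yx, nu = 0.2, pt = 0, hinges = TRUE) {
  if (pt < 0) stop("turgor pressure must be non-negative")
  lx <- lame_coefficients(Yx, nu)
  ly <- lame_coefficients(Yy, nu)
  structure(list(
    Yx = Yx, Yy = Yy, nu = nu, pt = pt,
    lamx = lx[["lambda"]], mux = lx[["mu"]],
    lamy = ly[["lambda"]], muy = ly[["mu"]],
    mu = (lx[["mu"]] + ly[["mu"]]) / 2,
    hinges = isTRUE(hinges)
  ), class = "pm_material")
}

#' @export
print.pm_material <- function(x, ...) {
  cat(sprintf("pm_material: Yx = %g, Yy = %g MPa·m, nu = %g, pt = %g MPa·m\n",
              x$Yx, x$Yy, x$nu, x$pt))
  cat(sprintf("  lambda_x = %.4g, mu_x = %.4g, lambda_y = %.4g, mu_y = %.4g, mu = %.4g\n",
              x$lamx, x$mux, x$lamy, x$muy, x$mu))
  if (!x$hinges) cat("  hinge (shear) forces disabled\n")
  invisible(x)
}

#' Unit-cell geometry factors
#'
#' The per-cell geometric quantities entering the stiffness components:
#' aspect `h = y0/x0`, metric `s = max(x0,y0)/min(x0,y0)` and the shear
#' geometry factor `stilde = s/(1+s^2)` (equal to 1/2 exactly for square
#' cells), together with the current cell area.
#'
#' @param x0,y0 resting lengths of the cell's x- and y-springs (um).
#' @param A current cell area (um^2); defaults to the resting area `x0*y0`.
#' @return object of class `pm_cellgeom`.
#' @export
cell_geometry <- function(x0, y0, A = x0 * y0) {
  if (x0 <= 0 || y0 <= 0) stop("degenerate cell geometry: rest lengths must be positive")
  s <- max(x0, y0) / min(x0, y0)
  structure(list(x0 = x0, y0 = y0, A = A, h = y0 / x0,
                 s = s, stilde = s / (1 + s^2)), class = "pm_cellgeom")
}

#' Stiffness components of a unit cell
#'
#' The five non-zero components of the discrete stiffness tensor for one
#' unit cell, written in terms of the Lame coefficients and the cell
#' geometry:
#' \deqn{\tilde C_{xxxx} = (\lambda_x + 2\mu_x)\,h^{-1}A/x_0^2,\quad
#'       \tilde C_{yyyy} = (\lambda_y + 2\mu_y)\,h\,A/y_0^2,}
#' \deqn{\tilde C_{xxyy} = \lambda_x A/(x_0 y_0),\quad
#'       \tilde C_{yyxx} = \lambda_y A/(x_0 y_0),\quad
#'       \tilde C_{xyxy} = (\mu_x + \mu_y) A /((x_0^2+y_0^2)\,4\tilde s^2).}
#' All other components vanish.
#'
#' @param params a `pm_material`.
#' @param geom a `pm_cellgeom`.
#' @return named numeric vector of the five components (MPa·m).
#' @export
stiffness_components <- function(params, geom) {
  stopifnot(inherits(params, "pm_material"), inherits(geom, "pm_cellgeom"))
  with(geom, c(
    Cxxxx = (params$lamx + 2 * params$mux) * A / (x0 * y0),
    Cyyyy = (params$lamy + 2 * params$muy) * A / (x0 * y0),
    Cxxyy = params$lamx * A / (x0 * y0),
    Cyyxx = params$lamy * A / (x0 * y0),
    Cxyxy = (params$mux + params$muy) * A / ((x0^2 + y0^2) * 4 * stilde^2)
  ))
}
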