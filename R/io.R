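#' Parse a run configuration file
#'
#' Reads a YAML configuration with blocks `mesh`, `material`, `solver`,
#' `growth`, `loads` and `output`, validates every entry against the model
#' invariants, and fills the reference defaults for omitted keys
#' (`hgamma = 0.01`, `ht = 1` min, `thr = 0.05` uN, `m = 1` ug, `eta = 1`,
#' `L0 = 1` um). Validation problems are aggregated into a single error.
#'
#' @param path path to a YAML file; an empty file yields the all-defaults
#'   configuration.
#' @return object of class `pm_config`: list with `mesh`, `material`
#'   (a `pm_material`), `solver` (a `pm_solver`), `growth`, `loads`,
#'   `output`.
#' @export
parse_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  known <- c("mesh", "material", "solver", "growth", "loads", "output", "seed")
  for (k in setdiff(names(raw), known)) note(sprintf("unknown block '%s'", k))

  num <- function(block, key, default) {
    v <- raw[[block]][[key]]
    if (is.null(v)) return(default)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      note(sprintf("%s/%s must be a single finite number", block, key))
      return(default)
    }
    v
  }

  mesh <- list(width = num("mesh", "width", 100),
               height = num("mesh", "height", 100),
               L0 = num("mesh", "L0", 1))
  if (mesh$width <= 0 || mesh$height <= 0) note("mesh dimensions must be positive")
  else {
    r <- c(mesh$width, mesh$height) / mesh$L0
    if (any(abs(r - round(r)) > 1e-9))
      note("mesh dimensions must be multiples of L0")
  }

  Yx <- num("material", "Yx", 20); Yy <- num("material", "Yy", Yx)
  nu <- num("material", "nu", 0.2); pt <- num("material", "pt", 0)
  if (Yx <= 0 || Yy <= 0) note("Young's moduli must be positive")
  if (nu < 0 || nu >= 0.5)
    note("Poisson ratio must satisfy 0 <= nu < 0.5 (partially compressible wall)")
  if (pt < 0) note("turgor pressure must be non-negative")

  sol <- list(hgamma = num("solver", "hgamma", 0.01),
              mass = num("solver", "mass", 1),
              eta = num("solver", "eta", 1),
              thr = num("solver", "thr", 0.05),
              max_steps = num("solver", "max_steps", 2e6))
  if (any(unlist(sol) <= 0)) note("solver parameters must be positive")

  gr <- raw$growth
  growth <- list(kind = if (is.null(gr$kind)) "uniform" else gr$kind,
                 kx = num("growth", "kx", 0), ky = num("growth", "ky", 0),
                 frac_min = num("growth", "frac_min", 0.25),
                 ht = num("growth", "ht", 1),
                 duration = num("growth", "duration", 0))
  if (!growth$kind %in% c("uniform", "linear-gradient-y", "linear-gradient-xy"))
    note(sprintf("unknown growth field kind '%s'", growth$kind))
  if (growth$kx > k_max_rate() + 1e-12 || growth$ky > k_max_rate() + 1e-12)
    note(sprintf("growth rates are bounded by k_max = ln(4/3)/60 ~ %.4g min^-1",
                 k_max_rate()))
  if (growth$kx < 0 || growth$ky < 0) note("growth rates must be non-negative")

  output <- raw$output
  if (is.null(output)) output <- list()
  if (is.null(output$format)) output$format <- "csv"
  if (!output$format %in% c("csv", "vtk")) note("output format must be csv or vtk")

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))

  structure(list(
    mesh = mesh,
    material = material_params(Yx, Yy, nu = nu, pt = pt),
    solver = solver_params(sol$hgamma, sol$mass, sol$eta, sol$thr, sol$max_steps),
    growth = do.call(growth_field,
                     growth[c("kind", "kx", "ky", "frac_min")]),
    growth_ht = growth$ht, growth_duration = growth$duration,
    loads = raw$loads, output = output,
    seed = raw$seed
  ), class = "pm_config")
}

#' Write a mesh snapshot
#'
#' CSV output: a points file (`id`, `row`, `col`, `x`, `y`, `is_boundary`,
#' `is_loose`, optional per-point fields) and a springs file (`id_a`,
#' `id_b`, `orientation`, `rest_len`, optional per-spring fields), ordered
#' by id for bit-stable output. Alternatively a legacy-VTK polydata file for
#' visualization. All quantities are in model units (um, min, MPa·m).
#'
#' @param mesh a `pm_mesh`.
#' @param path output path; for CSV, `<path>_points.csv` and
#'   `<path>_springs.csv` are written.
#' @param fields optional named list of per-point (`length == npoints`) or
#'   per-spring vectors to include as extra columns.
#' @param format `"csv"` or `"vtk"`.
#' @return invisibly, the written file path(s).
#' @export
write_snapshot <- function(mesh, path, fields = list(), format = c("csv", "vtk")) {
  format <- match.arg(format)
  if (format == "vtk") return(write_vtk(mesh, path, fields))
  n <- npoints(mesh)
  bdry <- rep(FALSE, n); bdry[mesh$cycle] <- TRUE
  loose <- rep(FALSE, n); loose[loose_points(mesh)] <- TRUE
  pts <- data.frame(id = seq_len(n), row = mesh$grid[, 1], col = mesh$grid[, 2],
                    x = mesh$pos[, 1], y = mesh$pos[, 2],
                    is_boundary = bdry, is_loose = loose)
  spr <- data.frame(id_a = mesh$sa, id_b = mesh$sb,
                    orientation = c("x", "y")[mesh$sor],
                    rest_len = mesh$srest)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (length(v) == n) pts[[nm]] <- v
    else if (length(v) == nsprings(mesh)) spr[[nm]] <- v
    else stop("field '", nm, "' matches neither points nor springs")
  }
  pfile <- paste0(path, "_points.csv"); sfile <- paste0(path, "_springs.csv")
  utils::write.csv(pts, pfile, row.names = FALSE)
  utils::write.csv(spr, sfile, row.names = FALSE)
  invisible(c(pfile, sfile))
}

#' Read back a mesh snapshot written by [write_snapshot()]
#'
#' Reconstructs a `pm_mesh` (topology rebuilt from the spring table).
#'
#' @param path the base path used when writing.
#' @param L0 initial spring length of the run (um).
#' @param time simulation time stamp (min).
#' @return a `pm_mesh`.
#' @export
read_snapshot <- function(path, L0 = 1, time = 0) {
  pts <- utils::read.csv(paste0(path, "_points.csv"))
  spr <- utils::read.csv(paste0(path, "_springs.csv"))
  pos <- cbind(pts$x, pts$y)
  mesh <- structure(list(
    pos = pos, prev = pos, grid = cbind(pts$row, pts$col),
    sa = as.integer(spr$id_a), sb = as.integer(spr$id_b),
    sor = ifelse(spr$orientation == "x", 1L, 2L),
    srest = spr$rest_len,
    sborder = logical(nrow(spr)),
    L0 = L0, time = time,
    constraint = integer(nrow(pts)), fixpos = pos
  ), class = "pm_mesh")
  # border springs: both endpoints flagged as boundary in the points file
  mesh$sborder <- pts$is_boundary[mesh$sa] & pts$is_boundary[mesh$sb]
  rebuild_topology(mesh)
}

#' Legacy-VTK polydata export
#'
#' @inheritParams write_snapshot
#' @export
write_vtk <- function(mesh, path, fields = list()) {
  if (!grepl("\\.vtk$", path)) path <- paste0(path, ".vtk")
  n <- npoints(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("phytomech mesh t=%g min (um)", mesh$time),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$pos[, 1], mesh$pos[, 2]), con)
  m <- nsprings(mesh)
  writeLines(sprintf("LINES %d %d", m, 3 * m), con)
  writeLines(sprintf("2 %d %d", mesh$sa - 1L, mesh$sb - 1L), con)
  pf <- fields[lengths(fields) == n]
  if (length(pf)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(pf)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", pf[[nm]]), con)
    }
  }
  invisible(path)
}
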