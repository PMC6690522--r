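test_that("curvature fits recover synthetic arcs", {
  m <- build_rectangular_mesh(10, 2, 1)
  expect_equal(as.numeric(curvature(m)), 0)
  expect_true(isTRUE(attr(curvature(m), "degenerate")))

  # bend the mid-line onto a circle of radius 100
  R <- 100
  m2 <- m
  th <- m$pos[, 1] / R
  m2$pos <- cbind(R * sin(th) - 0 * m$pos[, 2],
                  R * (1 - cos(th)) + m$pos[, 2])
  expect_equal(as.numeric(curvature(m2)), 1 / R, tolerance = 1e-3)

  # downward arc flips the sign
  m3 <- m2; m3$pos[, 2] <- -m3$pos[, 2]
  expect_equal(as.numeric(curvature(m3)), -1 / R, tolerance = 1e-3)
})

test_that("zero growth rates give a static turgid tissue", {
  cfg <- scenario_config("root", width = 10, height = 4,
                         field = growth_field("uniform", kx = 0, ky = 0),
                         duration = 3, snapshots = c(1, 3),
                         solver = tuned_solver(
                           material_params(40, 80, nu = 0.2, pt = 0.2), 10))
  out <- run_scenario(cfg)
  expect_length(out$snapshots, 2)
  expect_equal(out$snapshots[[1]]$pos, out$snapshots[[2]]$pos,
               tolerance = 1e-4)
  expect_equal(sum(out$log$inserted), 0)
})

test_that("asymmetric elongation bends the tissue away from the slow side", {
  p <- material_params(40, 80, nu = 0.2, pt = 0.2)
  s <- tuned_solver(p, 24, thr = 5e-4)
  mk <- function(frac_min) scenario_config(
    "custom", width = 24, height = 8, params = p,
    field = growth_field("linear-gradient-y", kx = k_max_rate(), ky = 0,
                         frac_min = frac_min),
    duration = 50, ht = 1, snapshots = 50, solver = s)
  out <- run_scenario(mk(0.25))
  k1 <- as.numeric(curvature(out$mesh))
  # top grows faster: arc bends downward, slow side inside
  expect_lt(k1, 0)

  # mirrored gradient flips the curvature
  cfgm <- mk(0.25)
  cfgm$field <- growth_field("custom", rate_fn = function(t, xy) {
    g <- 0.25 + 0.75 * (max(xy[, 2]) - xy[, 2]) / max(max(xy[, 2]) - min(xy[, 2]), 1e-9)
    cbind(k_max_rate() * g, 0)
  })
  outm <- run_scenario(cfgm)
  k2 <- as.numeric(curvature(outm$mesh))
  expect_gt(k2, 0)
  expect_equal(abs(k2), abs(k1), tolerance = 0.05)

  # a symmetric field builds no curvature
  cfg0 <- mk(1)
  out0 <- run_scenario(cfg0)
  expect_lt(abs(as.numeric(curvature(out0$mesh))), abs(k1) / 10)

  # growth asymmetry builds a residual strain field of both signs
  snap <- out$snapshots[[length(out$snapshots)]]
  xs <- snap$sor == 1L
  expect_lt(min(snap$strain[xs]), -1e-3)
  expect_gt(max(snap$strain[xs]), 1e-3)

  # the shear field of the bent slab is antisymmetric about the vertical
  # mid-line: the two "eyes" at the ends carry opposite sign
  tau <- snap$tau
  xmid_p <- snap$pos[, 1] - mean(range(snap$pos[, 1]))
  ql <- mean(tau[xmid_p < -2], na.rm = TRUE)
  qr <- mean(tau[xmid_p > 2], na.rm = TRUE)
  expect_lt(ql * qr, 0)
  expect_equal(abs(ql), abs(qr), tolerance = 0.25)
})

test_that("uniform growth keeps residual strain near zero in a scenario", {
  p <- material_params(40, 80, nu = 0.2, pt = 0)
  cfg <- scenario_config("custom", width = 12, height = 6, params = p,
                         field = growth_field("uniform", kx = k_max_rate(),
                                              ky = k_max_rate()),
                         duration = 25, snapshots = 25,
                         solver = tuned_solver(p, 12, thr = 1e-4))
  out <- run_scenario(cfg)
  expect_lt(max(abs(out$snapshots[[1]]$strain)), 1e-3)
})
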