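test_that("verlet step follows the two-step rule and constraints", {
  m <- build_rectangular_mesh(2, 2, 1)
  s <- solver_params()
  # zero forces, resting history: nothing moves
  m2 <- verlet_step(m, matrix(0, npoints(m), 2), s)
  expect_equal(m2$pos, m$pos)

  # single constant force from rest, first step: f/m (hg)^2 / 2
  f <- matrix(0, npoints(m), 2); f[5, 1] <- 2
  m3 <- verlet_step(m, f, s, first = TRUE)
  expect_equal(m3$pos[5, 1] - m$pos[5, 1], 0.5 * 2 * s$hgamma^2)

  # pure inertia: 2x(g) - x(g-h) (modulo damping)
  m4 <- m; m4$prev[5, 1] <- m4$prev[5, 1] - 0.01
  m5 <- verlet_step(m4, matrix(0, npoints(m), 2), solver_params(eta = 1e-12))
  expect_equal(m5$pos[5, 1] - m4$pos[5, 1], 0.01, tolerance = 1e-6)

  # frozen coordinates stay put
  mc <- constrain(m, 1, "fixed")
  mc <- verlet_step(mc, matrix(5, npoints(m), 2), solver_params(), first = TRUE)
  expect_equal(mc$pos[1, ], m$pos[1, ])
})

test_that("damped spring relaxes to its rest length", {
  p <- material_params(20, nu = 0.1)
  m <- build_rectangular_mesh(1, 1, 1)
  m$pos[c(2, 4), 1] <- 1.05   # 5% stretch, then release
  m$prev <- m$pos
  s <- solver_params(thr = 1e-6)
  r <- relax(m, p, solver = s)
  e <- spring_strains(r)
  expect_lt(max(abs(e)), 1e-5)
  expect_gt(attr(r, "steps"), 0)
})

test_that("an equilibrated mesh converges immediately", {
  p <- material_params(20, nu = 0.1)
  m <- build_rectangular_mesh(3, 3, 1)
  r <- relax(m, p)
  expect_equal(attr(r, "steps"), 0)
  expect_equal(r$pos, m$pos)
})

test_that("equilibria are independent of mass and damping", {
  p <- material_params(20, nu = 0.2, pt = 0.5)
  m <- build_rectangular_mesh(8, 8, 1)
  base <- tuned_solver(p, 8, thr = 1e-5)
  r1 <- relax(m, p, solver = base)
  vary <- list(
    solver_params(hgamma = base$hgamma, eta = base$eta / 2, thr = 1e-5),
    solver_params(hgamma = base$hgamma, eta = base$eta / 4, thr = 1e-5),
    solver_params(hgamma = base$hgamma, mass = 0.5, eta = base$eta, thr = 1e-5),
    solver_params(hgamma = base$hgamma, mass = 1.5, eta = base$eta, thr = 1e-5))
  for (s in vary) {
    r2 <- relax(m, p, solver = s)
    expect_lt(max(abs(r2$pos - r1$pos)), 1e-3)
  }
})

test_that("non-convergence raises an informative error", {
  p <- material_params(20, nu = 0.1, pt = 1)
  m <- build_rectangular_mesh(6, 6, 1)
  s <- solver_params(thr = 1e-8, max_steps = 5)
  expect_error(relax(m, p, solver = s), "did not converge")
})

test_that("instability triggers the divergence diagnostic", {
  p <- material_params(20, nu = 0.1, pt = 1)
  m <- build_rectangular_mesh(4, 4, 1)
  s <- solver_params(hgamma = 0.9, eta = 1e-6, thr = 1e-10, max_steps = 1e5)
  expect_error(relax(m, p, solver = s), "diverged")
})

test_that("rigid motion removal undoes translations and rotations exactly", {
  m <- build_rectangular_mesh(3, 2, 1)
  ref <- m
  mt <- m
  mt$pos <- sweep(mt$pos, 2, c(5, -3), "+"); mt$prev <- mt$pos
  expect_equal(remove_rigid_motion(mt, ref)$pos, ref$pos, tolerance = 1e-12)

  mr <- rotate_mesh(m, 17 * pi / 180)
  ctr <- colMeans(m$pos)
  mr$pos <- sweep(sweep(mr$pos, 2, colMeans(mr$pos)), 2, ctr, "+")
  expect_equal(remove_rigid_motion(mr, ref)$pos, ref$pos, tolerance = 1e-12)

  # deformation + rotation: residual deformation preserved, idempotent
  set.seed(2)
  md <- jitter_mesh(m, 0.02)
  e0 <- spring_strains(md)
  mdr <- rotate_mesh(md, 0.6, shift = c(1, 2))
  out <- remove_rigid_motion(mdr, ref)
  expect_equal(spring_strains(out), e0, tolerance = 1e-10)
  out2 <- remove_rigid_motion(out, ref)
  expect_equal(out2$pos, out$pos, tolerance = 1e-10)
})
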