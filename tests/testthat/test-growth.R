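test_that("growth multiplies resting lengths by 1 + ht k at spring midpoints", {
  m <- build_rectangular_mesh(3, 3, 1)
  f0 <- growth_field("uniform", kx = 0, ky = 0)
  expect_equal(growth_step(m, f0)$srest, m$srest)

  # Euler compounding of the maximal rate over one hour
  k <- k_max_rate()
  f <- growth_field("uniform", kx = k, ky = k)
  g <- m
  for (i in 1:60) g <- growth_step(g, f, ht = 1)
  expect_equal(unique(round(g$srest, 6)), round((1 + k)^60, 6))
  expect_equal((1 + k)^60, 1.33242, tolerance = 1e-4)  # Euler-compounded 4/3
  expect_equal(g$time, 60)

  # halving ht halves the per-step factor; results stay consistent
  g2 <- m
  for (i in 1:120) g2 <- growth_step(g2, f, ht = 0.5)
  expect_lt(max(abs(g2$srest - g$srest)), 1e-3)

  # gradient field grows the top faster than the bottom
  fg <- growth_field("linear-gradient-y", kx = k, frac_min = 0.25)
  g3 <- growth_step(m, fg)
  xs <- which(g3$sor == 1L)
  ymid <- (m$pos[g3$sa[xs], 2] + m$pos[g3$sb[xs], 2]) / 2
  expect_gt(mean(g3$srest[xs][ymid == 3]), mean(g3$srest[xs][ymid == 0]))

  expect_warning(growth_step(m, growth_field("uniform", kx = 2 * k)), "k_max")
  expect_error(growth_step(m, growth_field("uniform", kx = 2 * k),
                           rate_guard = "error"), "k_max")
})

test_that("remeshing splits threshold springs and keeps the rest-length bound", {
  m <- build_rectangular_mesh(4, 3, 1)
  r0 <- remesh(m)
  expect_equal(attr(r0, "inserted"), 0L)
  expect_identical(r0$srest, m$srest)

  # single interior x-spring at threshold: one loose point, spring count +1
  m1 <- m
  s <- which(!m1$sborder & m1$sor == 1L)[1]
  m1$srest[s] <- 2
  r1 <- remesh(m1)
  expect_equal(attr(r1, "inserted"), 1L)
  expect_equal(nsprings(r1), nsprings(m1) + 1L)
  expect_equal(npoints(r1), npoints(m1) + 1L)
  expect_length(loose_points(r1), 1L)
  expect_true(all(r1$srest < 2 * r1$L0))
  # split halves rest and current length: children inherit the parent strain
  parent_strain <- (1 - 2) / 2
  kids <- c(s, nsprings(r1))   # in-place child + appended child
  expect_equal(unname(spring_strain(r1, kids)), rep(parent_strain, 2),
               tolerance = 1e-12)

  # uniform x-growth to threshold: every x-spring splits, transverse
  # reconnection leaves no loose points and doubles the columns
  m2 <- build_rectangular_mesh(4, 3, 1)
  nx <- sum(m2$sor == 1L)
  m2$srest[m2$sor == 1L] <- 2
  m2$pos[, 1] <- m2$pos[, 1] * 2; m2$prev <- m2$pos
  r2 <- remesh(m2)
  expect_equal(attr(r2, "inserted"), nx)
  expect_length(loose_points(r2), 0L)
  expect_equal(length(unique(r2$grid[, 2])), 9L)  # 5 -> 9 columns
  expect_equal(max(abs(spring_strains(r2))), 0, tolerance = 1e-12)
})

test_that("neighbour symmetry survives randomized growth and remeshing", {
  set.seed(19)
  m <- build_rectangular_mesh(5, 4, 1)
  for (rep in 1:6) {
    k <- runif(nsprings(m), 0, 0.4)
    m$srest <- m$srest * (1 + k)
    m <- remesh(m)
    for (i in seq_len(npoints(m))) for (d in 1:4) {
      j <- m$nbr[i, d]
      if (j > 0) expect_identical(m$nbr[j, c(2L, 1L, 4L, 3L)[d]], i)
    }
    expect_true(all(m$srest < 2 * m$L0))
  }
  # boundary cycle still a simple CCW polygon
  cyc <- boundary_cycle(m)
  expect_equal(length(cyc), length(unique(cyc)))
  expect_gt(tissue_area(m$pos[cyc, ]), 0)
})

test_that("uniform growth with relaxation leaves no residual strain", {
  p <- material_params(20, nu = 0.2, pt = 0)
  s <- tuned_solver(p, 6, thr = 1e-6)
  m <- build_rectangular_mesh(6, 6, 1)
  f <- growth_field("uniform", kx = k_max_rate(), ky = k_max_rate())
  for (step in 1:30) {
    m <- growth_step(m, f, ht = 1)
    m <- remesh(m)
    m <- relax(m, p, solver = s)
  }
  expect_lt(max(abs(spring_strains(m))), 1e-3)   # < 0.1 % residual strain
})

test_that("remeshing is geometric bookkeeping: relaxed area is continuous", {
  p <- material_params(20, nu = 0.2, pt = 0.2)
  s <- tuned_solver(p, 8, thr = 1e-5)
  m <- build_rectangular_mesh(8, 6, 1)
  m$srest[m$sor == 1L] <- 1.999   # just below threshold
  m <- relax(m, p, solver = s)
  a_before <- tissue_area(m$pos[boundary_cycle(m), ])
  m$srest[m$sor == 1L] <- 2.0
  m <- remesh(m)
  expect_gt(attr(m, "inserted"), 0L)
  m <- relax(m, p, solver = s, from_rest = TRUE)
  a_after <- tissue_area(m$pos[boundary_cycle(m), ])
  expect_lt(abs(a_after / a_before - 1), 0.005)
})
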