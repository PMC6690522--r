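# Pure-R reference implementations used as independent cross-checks of the
# compiled force assembly, plus small fixture builders.

# mean cell area in R (quad shoelace per hinge cell, parallelogram fallback)
ref_mean_area <- function(mesh, i) {
  hs <- phytomech:::.hinges_at(mesh, i)
  if (!length(hs)) {
    acc <- 0; cnt <- 0
    for (d in 1:4) {
      sid <- mesh$pspr[i, d]
      if (sid == 0) next
      po <- if (d <= 2) 3:4 else 1:2
      pr <- mesh$pspr[i, po]; pr <- pr[pr > 0]
      perp <- if (length(pr)) mean(mesh$srest[pr]) else mesh$srest[sid]
      acc <- acc + mesh$srest[sid] * perp; cnt <- cnt + 1
    }
    return(if (cnt) acc / cnt else 0)
  }
  areas <- vapply(hs, function(h) {
    jx <- mesh$nbr[i, h$dx]
    j4 <- if (jx > 0) mesh$nbr[jx, h$dy] else 0L
    jy <- mesh$nbr[i, h$dy]
    if (j4 > 0 && jy > 0) {
      q <- rbind(mesh$pos[i, ], mesh$pos[jx, ], mesh$pos[j4, ], mesh$pos[jy, ])
      abs(phytomech::tissue_area(q))
    } else {
      h$An
    }
  }, 0)
  mean(areas)
}

# full elastic force in R, mirroring the published force expressions
ref_elastic_forces <- function(mesh, params) {
  n <- npoints(mesh)
  f <- matrix(0, n, 2)
  e <- spring_strains(mesh)
  ms <- phytomech:::.orient_means(mesh, e)
  A <- vapply(seq_len(n), function(i) ref_mean_area(mesh, i), 0)
  for (i in seq_len(n)) {
    for (d in 1:4) {
      sid <- mesh$pspr[i, d]
      if (sid == 0) next
      j <- mesh$nbr[i, d]
      dv <- mesh$pos[j, ] - mesh$pos[i, ]
      len <- sqrt(sum(dv^2))
      x0 <- mesh$srest[sid]
      o <- if (d <= 2) 1L else 2L
      lam <- if (o == 1L) params$lamx else params$lamy
      mu <- if (o == 1L) params$mux else params$muy
      ebar <- ms$mstrain[i, 3 - o]; if (is.na(ebar)) ebar <- 0
      p0m <- ms$mrest[i, 3 - o]; if (is.na(p0m)) p0m <- x0
      base <- A[i] / (x0 * p0m)
      coef <- ((lam + 2 * mu) * base * e[sid] + lam * base * ebar) *
        A[i] / (x0 * len)
      f[i, ] <- f[i, ] + coef * dv
    }
    if (params$hinges) {
      hs <- phytomech:::.hinges_at(mesh, i)
      N <- length(hs)
      mu2 <- params$mux + params$muy
      for (h in hs) {
        nx <- sqrt(sum(h$xv^2)); ny <- sqrt(sum(h$yv^2))
        st <- h$s_til <- {
          s <- max(h$x0, h$y0) / min(h$x0, h$y0)
          s / (1 + s^2)
        }
        denom <- (h$x0^2 + h$y0^2) * 4 * st^2
        u <- sqrt(1 - h$an^2)
        pref <- -(mu2 / (2 * N)) * (h$An^2 / denom) * h$tau * (1 + h$tau^2) / u
        vec <- h$an * (h$yv / ny^2 + h$xv / nx^2) - (h$xv + h$yv) / (nx * ny)
        f[i, ] <- f[i, ] + pref * vec
      }
    }
  }
  f
}

# random small deformation of a mesh (fixed seed supplied by caller)
jitter_mesh <- function(mesh, amp) {
  mesh$pos <- mesh$pos + matrix(runif(2 * npoints(mesh), -amp, amp),
                                ncol = 2)
  mesh$prev <- mesh$pos
  mesh
}

# central-difference gradient of a scalar function of the mesh positions
num_gradient <- function(fn, mesh, i, h = 1e-6) {
  g <- numeric(2)
  for (k in 1:2) {
    mp <- mesh; mp$pos[i, k] <- mp$pos[i, k] + h
    mm <- mesh; mm$pos[i, k] <- mm$pos[i, k] - h
    g[k] <- (fn(mp) - fn(mm)) / (2 * h)
  }
  g
}

rotate_mesh <- function(mesh, theta, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  mesh$pos <- sweep(mesh$pos %*% t(R), 2, shift, "+")
  mesh$prev <- mesh$pos
  mesh
}

# one expectation per characterization criterion: every sub-check keeps its
# own tolerance, the block records a single pass/fail with a value table
expect_criterion <- function(measured, target, tol) {
  ok <- abs(measured - target) <= tol + 1e-12
  tab <- paste(sprintf("  %-28s measured %9.4g  expected %g +/- %g  [%s]",
                       names(measured), measured, target, tol,
                       ifelse(ok, "ok", "FAIL")), collapse = "\n")
  expect(all(ok), sprintf("criterion sub-checks out of tolerance:\n%s", tab))
  invisible(ok)
}
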