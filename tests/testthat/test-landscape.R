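test_that("anchored landscape reproduces anchor energies exactly", {
  fl <- buildLandscape(data.frame(z = c(4, 10), deltaG = c(-22.81, -10.05)))
  z <- landscapeGrid(fl); g <- landscapeEnergy(fl)
  expect_true(all(diff(z) > 0))
  expect_true(all(is.finite(g)))
  # well-depth difference in kcal/mol (kT -> kcal/mol at 25 C)
  expect_equal((g[z == 4] - g[z == 10]) / 1.688, -12.76, tolerance = 1e-9)
  # the barrier bump sits between the wells with the requested amplitude
  # above the well-to-well base curve
  fl0 <- buildLandscape(data.frame(z = c(4, 10), deltaG = c(-22.81, -10.05)),
                        barrier_height = 0)
  bump <- g - landscapeEnergy(fl0)
  expect_equal(max(bump), 3, tolerance = 1e-6)
  expect_true(all(bump[z <= 4 | z >= 10] == 0))
  expect_error(
    buildLandscape(data.frame(z = c(1, 10), deltaG = c(0, 0))), "inside")
})

test_that("equal anchors give zero force outside the barrier region", {
  fl <- buildLandscape(data.frame(z = c(4, 10), deltaG = c(-5, -5)),
                       barrier_height = 3)
  z <- landscapeGrid(fl); f <- landscapeForce(fl)
  outside <- z < 4 | z > 10
  expect_true(all(abs(f[outside]) < 1e-9))
  expect_gt(max(abs(f[!outside])), 0.1)
})

test_that("BD integrator is diffusive on a flat landscape (MSD = 2Dt)", {
  flat <- FreeEnergyLandscape(seq(-50, 50, 1), rep(0, 101))
  par <- BDParams(diffusion = 10, dt = 1e-4, z_min = -50, z_max = 50,
                  z_max_boundary = "reflecting")
  set.seed(101)
  nw <- 400; nst <- 200                      # t = 0.02 us -> MSD = 0.4 nm^2
  disp2 <- replicate(nw, {
    p <- simulateBD(flat, par, nst, z0 = 0)
    (p$z[length(p$z)] - 0)^2
  })
  expected <- 2 * 10 * nst * 1e-4
  se <- stats::sd(disp2) / sqrt(nw)
  expect_lt(abs(mean(disp2) - expected), 3 * se)
})

test_that("BD sampling is Boltzmann: well occupancies and harmonic variance", {
  # double well, Delta(dG) = 1 kT between flat wells joined by a small
  # smooth barrier; quadrature (Boltzmann-weight) oracle
  z <- seq(0, 12, 0.01)
  s <- pmin(pmax((z - 5) / 2, 0), 1)          # 0 left of 5, 1 right of 7
  g <- s + 1.5 * sin(pi * s)^2
  dw <- FreeEnergyLandscape(z, g)
  ratio_oracle <- sum(exp(-g[z < 6])) / sum(exp(-g[z > 6]))
  par <- BDParams(diffusion = 10, dt = 1e-4, z_min = 0, z_max = 12,
                  z_max_boundary = "reflecting")
  set.seed(202)
  nw <- 160
  finals <- vapply(seq_len(nw), function(i) {
    p <- simulateBD(dw, par, 3e5, z0 = if (i %% 2) 2 else 10, thin = 1000)
    p$z[length(p$z)]
  }, 0)
  p_left <- mean(finals < 6)
  se <- sqrt(p_left * (1 - p_left) / nw)
  p_oracle <- ratio_oracle / (1 + ratio_oracle)
  expect_lt(abs(p_left - p_oracle), 3 * se + 0.01)

  # harmonic well: stationary variance = kT/kappa
  kappa <- 2
  zh <- seq(-6, 6, 0.01)
  hw <- FreeEnergyLandscape(zh, 0.5 * kappa * zh^2)
  parh <- BDParams(diffusion = 10, dt = 1e-4, z_min = -6, z_max = 6,
                   z_max_boundary = "reflecting")
  set.seed(303)
  p <- simulateBD(hw, parh, 400000, z0 = 0, thin = 10)
  zs <- p$z[-(1:100)]
  v <- mean(zs^2)
  # effective sample size from the relaxation time kappa*D per us
  tau_rel <- 1 / (kappa * 10)                # us
  neff <- length(zs) * (10 * 1e-4) / (2 * tau_rel)
  se_v <- sqrt(2 / neff) * (1 / kappa)
  expect_lt(abs(v - 1 / kappa), 3 * se_v)
})

test_that("BD boundaries and degenerate modes behave", {
  flat <- FreeEnergyLandscape(seq(2, 13, 0.1), rep(0, 111))
  # absorbing top boundary terminates the trajectory
  set.seed(9)
  p <- simulateBD(flat, BDParams(), 5e5, z0 = 12.5)
  expect_true(p$escaped)
  expect_lt(p$steps, 5e5)
  # (near) zero diffusion with zero force: position is frozen
  p0 <- simulateBD(flat, BDParams(diffusion = 1e-12,
                                  z_max_boundary = "reflecting"),
                   1000, z0 = 7)
  expect_lt(max(abs(p0$z - 7)), 1e-3)
  # drift per step exceeding the grid span is a stability error
  steep <- FreeEnergyLandscape(c(2, 13), c(0, -1e9))
  expect_error(simulateBD(steep, BDParams(), 100, z0 = 5), "step too large")
  expect_error(simulateBD(flat, BDParams(), 100, z0 = 1), "outside")
})

test_that("BD paths are reproducible under a fixed seed", {
  flat <- FreeEnergyLandscape(seq(2, 13, 0.1), rep(0, 111))
  set.seed(42); a <- simulateBD(flat, BDParams(), 2000, z0 = 7)
  set.seed(42); b <- simulateBD(flat, BDParams(), 2000, z0 = 7)
  expect_identical(a$z, b$z)
})
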