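test_that("zero forces, zero temperature, zero velocity is a fixed point", {
  st <- particle_gas(8, spacing = 3)
  p0 <- forcefield_params(ks = 0, kal = 0, kh = 0, eps = 0)
  cfg <- integrator_config(kT = 0)
  res <- run_dynamics(st, 100, p0, cfg, seed = 1)
  expect_equal(res$state$particles$pos, st$particles$pos, tolerance = 1e-14)
  expect_equal(res$state$particles$vel, st$particles$vel, tolerance = 1e-14)
})

test_that("constant force at T=0 reaches the Stokes terminal drift F/zeta", {
  # pull one particle with the harmonic trap far from its centre: the force
  # over a short window is nearly constant F = k * d
  st <- particle_gas(1, spacing = 1)
  st$particles$pos[1, ] <- c(0, 0, 0)
  k <- 1e-4; d <- 1e4               # F = 1 along +x, nearly constant
  p <- forcefield_params(ks = 0, kal = 0, kh = 0, eps = 0,
                         k_trap = k, trap_center = c(d, 0, 0))
  cfg <- integrator_config(kT = 0, zeta_t = 2)
  res <- run_dynamics(st, 4000, p, cfg, seed = 1)   # t = 20 >> m/zeta
  expect_equal(res$state$particles$vel[1, 1], k * d / 2, tolerance = 0.01)
})

test_that("identical seeds give bitwise-identical trajectories; streams concatenate", {
  st <- tiny_system()
  p <- forcefield_params(ks = 2, kal = 1, kh = 1, eps = 1, lambda = 2)
  cfg <- integrator_config()
  a <- run_dynamics(st, 60, p, cfg, seed = 42)
  b <- run_dynamics(st, 60, p, cfg, seed = 42)
  expect_identical(a$state$particles$pos, b$state$particles$pos)
  expect_identical(a$state$pair$outer$positions, b$state$pair$outer$positions)
  # run(a)+run(b) == run(a+b) on the same stream
  c1 <- run_dynamics(st, 25, p, cfg, seed = 7)
  c2 <- run_dynamics(c1$state, 35, p, cfg)
  d1 <- run_dynamics(st, 60, p, cfg, seed = 7)
  expect_identical(c2$state$particles$pos, d1$state$particles$pos)
  # n_steps = 0 is the identity
  z <- run_dynamics(st, 0, p, cfg)
  expect_identical(z$state$particles$pos, st$particles$pos)
})

test_that("kinetic temperature is a quadratic velocity functional", {
  st <- particle_gas(20, spacing = 3)
  expect_equal(kinetic_temperature(st), 0)
  set.seed(1)
  st$particles$vel <- matrix(rnorm(60), 20, 3)
  t1 <- kinetic_temperature(st)
  st$particles$vel <- 2 * st$particles$vel
  expect_equal(kinetic_temperature(st), 4 * t1, tolerance = 1e-12)
  expect_error(kinetic_temperature(mps_state()), "empty")
})

test_that("orientations stay unit length along a driven trajectory", {
  st <- particle_gas(30, spacing = 3)
  st$field$xi <- 5
  p <- forcefield_params(ks = 0, kal = 0, kh = 0, eps = 1, lambda = 2, xi = 5)
  res <- run_dynamics(st, 2000, p, integrator_config(), sample_every = 100,
                      seed = 3)
  nrm <- sqrt(apply(res$samples$mnp_orient^2, c(1, 2), sum))
  expect_lt(max(abs(nrm - 1)), 1e-9)
})

test_that("free rotational diffusion decays at 2 kT / zeta_r (overdamped)", {
  set.seed(5)
  st <- particle_gas(150, spacing = 5)
  p0 <- forcefield_params(ks = 0, kal = 0, kh = 0, eps = 0, lambda = 0)
  cfg <- integrator_config(dt = 0.002, zeta_r = 3, inertia = 0.1)
  res <- run_dynamics(st, 25000, p0, cfg, sample_every = 50)
  e <- res$samples$mnp_orient
  nf <- dim(e)[1]
  lags <- seq(0, 80, by = 4)
  corr <- vapply(lags, function(tau) {
    idx <- seq_len(nf - tau)
    mean(vapply(idx, function(t)
      sum(e[t, , ] * e[t + tau, , ]) / dim(e)[2], numeric(1)))
  }, numeric(1))
  tt <- lags * 50 * cfg$dt
  keep <- corr > 0.15 & tt > 0.2      # skip the short inertial transient
  rate <- -unname(coef(lm(log(corr[keep]) ~ tt[keep]))[2])
  expect_equal(rate, 2 * cfg$kT / 3, tolerance = 0.1)
})
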