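test_that("MSD: immobile and ballistic closed forms", {
  nf <- 12; M <- 4
  still <- array(rep(matrix(rnorm(M * 3), M, 3), each = nf), c(nf, M, 3))
  m0 <- msd(still)
  expect_equal(m0$msd, rep(0, nf - 1), tolerance = 1e-14)
  # ballistic: r(t) = v t per particle -> MSD = |v|^2 tau^2
  set.seed(2)
  v <- matrix(rnorm(M * 3), M, 3)
  traj <- array(0, c(nf, M, 3))
  for (t in seq_len(nf)) traj[t, , ] <- v * (t - 1)
  mb <- msd(traj, dt = 1)
  expect_equal(mb$msd, mean(rowSums(v^2)) * mb$lag^2, tolerance = 1e-12)
  expect_error(msd(traj[1, , , drop = FALSE]), "2 frames")
})

test_that("MSD of a free Langevin gas matches the Einstein slope 6 kT/zeta", {
  set.seed(4)
  st <- particle_gas(150, spacing = 4)
  p0 <- forcefield_params(ks = 0, kal = 0, kh = 0, eps = 0)
  cfg <- integrator_config()
  res <- run_dynamics(st, 20000, p0, cfg, sample_every = 100)
  m <- msd(res$samples$mnp_pos, dt = 100 * cfg$dt)
  slope <- unname(coef(lm(msd ~ lag, data = m[m$lag <= 25, ]))[2])
  expect_equal(slope, 6, tolerance = 0.05)
  # two half-trajectories agree within sampling error
  h1 <- msd(res$samples$mnp_pos[1:100, , ], dt = 0.5)
  h2 <- msd(res$samples$mnp_pos[101:200, , ], dt = 0.5)
  expect_equal(mean(h1$msd[1:20] / h2$msd[1:20]), 1, tolerance = 0.2)
})

test_that("log-log exponent: exact linear and quadratic inputs", {
  lag <- 1:50
  expect_equal(msd_linearity_ratio(data.frame(lag = lag, msd = 3 * lag)), 1,
               tolerance = 1e-12)
  expect_equal(msd_linearity_ratio(data.frame(lag = lag, msd = 0.2 * lag^2)),
               2, tolerance = 1e-12)
  expect_error(msd_linearity_ratio(data.frame(lag = 1, msd = 1)), "enough")
})

test_that("aspect ratio: sphere sampling, exact affine stretch, axis swap", {
  set.seed(6)
  u <- matrix(rnorm(3000), 1000, 3)
  u <- u / sqrt(rowSums(u^2))
  ar0 <- aspect_ratio(u, h = c(0, 0, 1))
  expect_equal(ar0, 1, tolerance = 0.05)
  stretched <- u %*% diag(c(1, 1, 1.17))
  expect_equal(aspect_ratio(stretched) / ar0, 1.17, tolerance = 1e-10)
  squeezed <- u %*% diag(c(1.17, 1.17, 1))
  expect_equal(aspect_ratio(squeezed), ar0 / 1.17, tolerance = 1e-10)
  # invariance under joint rotation and uniform rescaling
  Rm <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(aspect_ratio(3.7 * stretched %*% t(Rm),
                            h = as.vector(Rm %*% c(0, 0, 1))),
               aspect_ratio(stretched), tolerance = 1e-9)
  expect_error(aspect_ratio(matrix(rnorm(9), 3)), "at least 4")
})

test_that("slab estimator agrees with the covariance estimator on large clouds", {
  set.seed(8)
  u <- matrix(rnorm(9000), 3000, 3)
  u <- 12 * u / sqrt(rowSums(u^2))
  stretched <- u %*% diag(c(1, 1, 1.15))
  expect_equal(aspect_ratio_slab(stretched, delta = 2),
               aspect_ratio(stretched), tolerance = 0.05)
})

test_that("cluster statistics: singletons, a built chain, permutation invariance", {
  # all far apart
  far <- matrix(seq(0, 45, by = 5), 10, 3)
  cs <- cluster_stats(far, a_red = 1.2)
  expect_identical(cs$n_clusters, 10L)
  expect_equal(cs$bonded_fraction, 0)
  # hand-built trimer at contact spacing + 2 singletons
  pos <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(2.4, 0, 0),
               c(10, 0, 0), c(0, 10, 0))
  cs2 <- cluster_stats(pos, a_red = 1.2)
  expect_identical(cs2$largest, 3L)
  expect_identical(cs2$n_clusters, 3L)
  expect_equal(cs2$bonded_fraction, 3 / 5)
  expect_equal(sum(cs2$sizes), nrow(pos))
  # ordering must not matter
  perm <- c(3, 5, 1, 4, 2)
  cs3 <- cluster_stats(pos[perm, ], a_red = 1.2)
  expect_identical(sort(cs3$sizes), sort(cs2$sizes))
})

test_that("magnetization: aligned, isotropic, and thermal-equilibrium (Langevin function)", {
  M <- 400
  expect_equal(magnetization(matrix(rep(c(0, 0, 1), each = M), M, 3)), 1)
  set.seed(10)
  iso <- matrix(rnorm(M * 3), M, 3)
  iso <- iso / sqrt(rowSums(iso^2))
  expect_lt(abs(magnetization(iso)), 3 / sqrt(M))
  # free dipoles at xi = 5 time-average to L(5) = coth(5) - 1/5
  st <- particle_gas(60, spacing = 5)
  st$field$xi <- 5
  p <- forcefield_params(ks = 0, kal = 0, kh = 0, eps = 0, lambda = 0, xi = 5)
  res <- run_dynamics(st, 30000, p, integrator_config(), sample_every = 100,
                      seed = 11)
  mg <- mean(apply(res$samples$mnp_orient, 1, magnetization))
  expect_equal(mg, 1 / tanh(5) - 1 / 5, tolerance = 0.03)
  expect_error(magnetization(matrix(0, 0, 3)), "empty")
})

test_that("sigmoid fit: exact recovery, noisy recovery, degenerate flat data", {
  xi <- c(0, 0.5, 1, 2, 3, 5, 7, 10)
  truth <- list(ar0 = 1.01, ar_inf = 1.17, xi_half = 3, width = 1.2)
  model <- function(x) truth$ar0 +
    (truth$ar_inf - truth$ar0) / (1 + exp(-(x - truth$xi_half) / truth$width))
  fit <- fit_sigmoid(xi, model(xi))
  for (nm in names(truth))
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-8)
  set.seed(12)
  noisy <- model(xi) * (1 + 0.01 * rnorm(length(xi)))
  fit2 <- fit_sigmoid(xi, noisy)
  expect_true(fit2$converged)
  expect_equal(fit2$ar_inf, truth$ar_inf, tolerance = 0.05)
  flat <- fit_sigmoid(xi, rep(1.05, 8))
  expect_true(flat$degenerate)
  expect_equal(flat$ar0, flat$ar_inf)
  expect_error(fit_sigmoid(1:3, 1:3), "at least 5")
})
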