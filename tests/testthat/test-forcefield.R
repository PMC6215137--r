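test_that("neo-Hookean edge force: equilibrium, printed magnitude, third law", {
  st <- tiny_system()
  p <- forcefield_params(ks = 1, kal = 0, kh = 0, eps = 0)
  # as-built state is the stress-free reference
  f0 <- stretch_forces(st, p)
  expect_lt(max(abs(f0)), 1e-10)
  # scalar law at 10% extension: ks * g(1.1) * 0.1 = 0.0992
  x <- 1.1
  g <- (sqrt(x) + x^-2.5) / (x + x^-3)
  expect_equal(g * 0.1, 0.0992, tolerance = 2e-4)
  # perturbed mesh: forces sum to zero (action-reaction over edges)
  st$pair$outer$positions <- st$pair$outer$positions * 1.07
  f <- stretch_forces(st, p)
  expect_lt(max(abs(colSums(f))), 1e-9)
  expect_gt(max(abs(f)), 1e-3)
})

test_that("local-area force: zero at equilibrium, contracts an inflated shell", {
  st <- tiny_system()
  p <- forcefield_params(ks = 0, kal = 1, kh = 0, eps = 0)
  expect_lt(max(abs(local_area_forces(st, p))), 1e-10)
  st$pair$outer$positions <- st$pair$outer$positions * 1.1
  f <- local_area_forces(st, p)
  n_out <- nrow(st$pair$outer$positions)
  # every outer node pushed inward (negative radial component)
  radial <- rowSums(f[seq_len(n_out), ] * st$pair$outer$positions)
  expect_true(all(radial < 0))
  # an equilateral triangle's three forces cancel: centroid symmetry
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  tri <- matrix(1:3, 1)
  S <- triangle_areas(pos, tri)
  g <- colMeans(pos)
  w <- t(apply(pos, 1, function(v) (v - g) / sqrt(sum((v - g)^2))))
  expect_lt(max(abs(colSums(w))), 1e-12)
})

test_that("tether force is harmonic with Hooke magnitude and exact reaction", {
  st <- tiny_system()
  p <- forcefield_params(ks = 0, kal = 0, kh = 1, eps = 0)
  expect_lt(max(abs(tether_forces(st, p))), 1e-10)
  # stretch all tethers by moving the inner shell inward 0.5
  st$pair$inner$positions <- st$pair$inner$positions *
    (1 - 0.5 / mean(sqrt(rowSums(st$pair$inner$positions^2))))
  f <- tether_forces(st, p)
  n_out <- nrow(st$pair$outer$positions)
  fo <- f[seq_len(n_out), ]
  fi <- f[n_out + order(st$pair$correspondence), ][st$pair$correspondence, ]
  # per-pair action-reaction
  fi2 <- f[n_out + st$pair$correspondence, ]
  expect_equal(fo, -fi2, tolerance = 1e-9)
  # magnitude ~ kh * extension
  r <- sqrt(rowSums((st$pair$outer$positions -
                     st$pair$inner$positions[st$pair$correspondence, ])^2))
  expect_equal(sqrt(rowSums(fo^2)), abs(r - st$pair$r0_tether),
               tolerance = 1e-6)
})

test_that("WCA potential: cutoff, shift, monotone repulsion", {
  rc <- (3.1 + 1.2) / 2
  w <- wca_energy_force(rc, 3.1, 1.2, eps = 1.5)
  expect_equal(w$energy, 0)
  expect_equal(w$force, 0)
  sig <- rc / 2^(1 / 6)
  expect_equal(wca_energy_force(sig, 3.1, 1.2, eps = 1.5)$energy, 1.5)
  r <- seq(0.6 * rc, rc, length.out = 50)
  u <- wca_energy_force(r, 3.1, 1.2, eps = 1.5)$energy
  expect_true(all(diff(u) < 1e-12))
  expect_true(all(wca_energy_force(r[-50], 3.1, 1.2)$force > 0))
  expect_error(wca_energy_force(0, 1, 1), "singular")
})

test_that("dipolar pair energies match the contact values and symmetry cases", {
  # head-to-tail at contact: -2 lambda kT
  ht <- nanoparticle_ensemble(pos = rbind(c(0, 0, 0), c(1.2, 0, 0)),
                              orient = rbind(c(1, 0, 0), c(1, 0, 0)))
  expect_equal(magnetic_energy_forces_torques(ht, lambda = 3)$energy, -6,
               tolerance = 1e-12)
  # side-by-side parallel: +lambda kT
  ss <- nanoparticle_ensemble(pos = rbind(c(0, 0, 0), c(1.2, 0, 0)),
                              orient = rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(magnetic_energy_forces_torques(ss, lambda = 3)$energy, 3,
               tolerance = 1e-12)
  # orthogonal: both scalar products vanish
  orth <- nanoparticle_ensemble(pos = rbind(c(0, 0, 0), c(1.2, 0, 0)),
                                orient = rbind(c(0, 0, 1), c(1, 0, 0)))
  expect_equal(magnetic_energy_forces_torques(orth, lambda = 3)$energy, 0,
               tolerance = 1e-12)
  # lone aligned dipole: Zeeman energy -xi, zero torque
  one <- nanoparticle_ensemble(pos = matrix(0, 1, 3),
                               orient = matrix(c(0, 0, 1), 1))
  r <- magnetic_energy_forces_torques(one, lambda = 0, xi = 10)
  expect_equal(r$energy, -10, tolerance = 1e-12)
  expect_lt(max(abs(r$torques)), 1e-12)
  expect_error(magnetic_energy_forces_torques(
    nanoparticle_ensemble(pos = matrix(0, 2, 3)), 1), "singular")
})

test_that("analytic forces match finite-difference energy gradients", {
  # dipolar + Zeeman on a random ensemble
  ens <- random_ensemble(M = 6, seed = 11)
  ref <- magnetic_energy_forces_torques(ens, lambda = 2, xi = 1.5)
  for (i in c(1, 4)) for (d in 1:3) {
    fd <- -fd_gradient(function(x) {
      e2 <- ens; e2$pos[i, d] <- x
      magnetic_energy_forces_torques(e2, lambda = 2, xi = 1.5)$energy
    }, ens$pos[i, d])
    expect_equal(ref$forces[i, d], fd, tolerance = 1e-6)
  }
  # stretch + tether on a perturbed paired shell, against quadrature energies
  st <- tiny_system()
  set.seed(3)
  st$pair$outer$positions <- st$pair$outer$positions *
    (1 + 0.04 * matrix(rnorm(length(st$pair$outer$positions)),
                       ncol = 3))
  p <- forcefield_params(ks = 1.3, kal = 0, kh = 0.9, eps = 0)
  f_str <- stretch_forces(st, p)
  f_tet <- tether_forces(st, p)
  term_energy <- function(s, term)
    unname(energy_breakdown(s, p, magnetics = FALSE)[term])
  for (i in c(2, 9)) for (d in 1:3) {
    fd_s <- -fd_gradient(function(x) {
      s2 <- st; s2$pair$outer$positions[i, d] <- x
      term_energy(s2, "stretch")
    }, st$pair$outer$positions[i, d])
    fd_t <- -fd_gradient(function(x) {
      s2 <- st; s2$pair$outer$positions[i, d] <- x
      term_energy(s2, "tether")
    }, st$pair$outer$positions[i, d])
    expect_equal(f_str[i, d], fd_s, tolerance = 1e-6)
    expect_equal(f_tet[i, d], fd_t, tolerance = 1e-6)
  }
  # WCA pair force from its own energy
  for (r in c(1.0, 1.1, 1.9)) {
    fd <- -fd_gradient(function(x) wca_energy_force(x, 3.1, 1.2, 2)$energy, r)
    expect_equal(wca_energy_force(r, 3.1, 1.2, 2)$force, fd, tolerance = 1e-6)
  }
})

test_that("torques equal the angular derivative of the magnetic energy", {
  ens <- random_ensemble(M = 5, seed = 13)
  ref <- magnetic_energy_forces_torques(ens, lambda = 2, xi = 1.5)
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    dU <- fd_gradient(function(th) {
      e2 <- ens; e2$orient[2, ] <- rotate_about(ens$orient[2, ], th, ax)
      magnetic_energy_forces_torques(e2, lambda = 2, xi = 1.5)$energy
    }, 0)
    expect_equal(sum(ref$torques[2, ] * ax), -dU, tolerance = 1e-6)
  }
})

test_that("forces are translation-invariant and rotation-covariant", {
  ens <- random_ensemble(M = 5, seed = 17)
  ref <- magnetic_energy_forces_torques(ens, lambda = 2, xi = 1.5)
  shifted <- ens; shifted$pos <- ens$pos + rep(c(3, -2, 5), each = 5)
  sh <- magnetic_energy_forces_torques(shifted, lambda = 2, xi = 1.5)
  expect_equal(sh$forces, ref$forces, tolerance = 1e-10)
  # rigid rotation of system and field rotates forces/torques
  th <- 0.7; ax <- c(1, 2, 2) / 3
  Rm <- t(sapply(list(c(1,0,0), c(0,1,0), c(0,0,1)),
                 function(v) rotate_about(v, th, ax)))
  Rm <- t(Rm)
  rot <- ens
  rot$pos <- ens$pos %*% t(Rm)
  rot$orient <- ens$orient %*% t(Rm)
  rr <- magnetic_energy_forces_torques(rot, lambda = 2, xi = 1.5,
                                       h = as.vector(Rm %*% c(0, 0, 1)))
  expect_equal(rr$energy, ref$energy, tolerance = 1e-9)
  expect_equal(rr$forces, ref$forces %*% t(Rm), tolerance = 1e-8)
  expect_equal(rr$torques, ref$torques %*% t(Rm), tolerance = 1e-8)
})

test_that("total forces: zero couplings give zero, pairwise terms conserve momentum", {
  st <- tiny_system()
  p0 <- forcefield_params(ks = 0, kal = 0, kh = 0, eps = 0, lambda = 0)
  f <- total_forces(st, p0)
  expect_lt(max(abs(f$forces)), 1e-14)
  # thermalise a little, then check net force of all pairwise terms
  # (uniform-field Zeeman exerts torque, not force)
  p <- forcefield_params(ks = 2, kal = 0, kh = 1, eps = 1, lambda = 3, xi = 5)
  st$field$xi <- 5
  st2 <- run_dynamics(st, 200, p, integrator_config(), seed = 5)$state
  f2 <- total_forces(st2, p)
  expect_lt(max(abs(colSums(f2$forces))), 1e-9)
  # removing all particles reproduces the pure-shell forces
  p_sh <- forcefield_params(ks = 2, kal = 1, kh = 1, eps = 1)
  bare <- st2
  bare$particles <- nanoparticle_ensemble(0, a_red = 1.2)
  f_bare <- total_forces(bare, p_sh)$forces
  f_full <- total_forces(st2, p_sh)$forces
  nb <- nrow(f_bare)
  # blob-blob contributions agree where no particle is within reach
  d_pb <- as.matrix(stats::dist(rbind(mpsdyn:::.state_positions(bare),
                                      st2$particles$pos)))
  reach <- (1.2 + 3.1) / 2
  far <- which(apply(d_pb[seq_len(nb), -seq_len(nb), drop = FALSE], 1,
                     min) > reach)
  expect_equal(f_full[far, ], f_bare[far, ], tolerance = 1e-10)
})
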