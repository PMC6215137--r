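test_that("particle counts follow the layer-volume definition of phi", {
  # independent arithmetic oracle for the layer volume and particle volume
  v_layer <- 4 * pi / 3 * ((24 / 2 - 3.1 / 2)^3 - (16 / 2 + 2 / 2)^3)
  v_p <- pi / 6 * 1.2^3
  expect_equal(round(0.055 * v_layer / v_p), 105)
  expect_equal(round(0.11 * v_layer / v_p), 210)
  expect_identical(n_particles_from_phi(system_spec(phi = 0.055)), 105L)
  expect_identical(n_particles_from_phi(system_spec(phi = 0.11)), 210L)
  expect_identical(n_particles_from_phi(system_spec(phi = 0)), 0L)
})

test_that("the capacity cap of 393 particles is enforced", {
  expect_error(n_particles_from_phi(system_spec(phi = 0.25)), "cap of 393")
  expect_silent(n_particles_from_phi(system_spec(phi = 0.2)))
})

test_that("geometry validation rejects a layer thinner than one particle", {
  expect_error(system_spec(Dout = 21.5), "monolayer")
  expect_equal(layer_thickness(24, 3.1, 16, 2), 1.45)
  expect_gte(layer_thickness(24, 3.1, 16, 2), 1.2)
})

test_that("placement respects the admissible band, contacts, and the seed", {
  spec <- system_spec(phi = 0.055, n_nodes = 162)
  pair <- pair_shells(make_sphere_mesh(162, 24, 3.1),
                      make_sphere_mesh(162, 16, 2))
  ens <- place_nanoparticles(spec, pair, seed = 5)
  r <- sqrt(rowSums(ens$pos^2))
  expect_true(all(r >= 16 / 2 + 2 / 2 + 1.2 / 2 - 1e-12))
  expect_true(all(r <= 24 / 2 - 3.1 / 2 - 1.2 / 2 + 1e-12))
  expect_gte(min(stats::dist(ens$pos)), 1.2)
  # no blob overlaps
  d_pb <- sqrt(outer(rowSums(ens$pos^2), rowSums(pair$outer$positions^2),
                     "+") - 2 * ens$pos %*% t(pair$outer$positions))
  expect_gte(min(d_pb), (1.2 + 3.1) / 2)
  # determinism and seed sensitivity
  expect_identical(place_nanoparticles(spec, pair, seed = 5)$pos, ens$pos)
  expect_false(identical(place_nanoparticles(spec, pair, seed = 6)$pos,
                         ens$pos))
})

test_that("assembled default system has 2 x 393 blobs, 105 particles, finite energy", {
  st <- fixture("default_system", function()
    assemble_system(system_spec(phi = 0.055), seed = 9))
  expect_identical(nrow(st$pair$outer$positions), 393L)
  expect_identical(nrow(st$pair$inner$positions), 393L)
  expect_identical(nrow(st$particles$pos), 105L)
  en <- energy_breakdown(st, forcefield_params(lambda = 1))
  expect_true(all(is.finite(en)))
  expect_lt(en["wca"], 1e-6)   # as-built state has no steric frustration
  expect_lt(abs(en["stretch"]), 1e-9)
})

test_that("equilibration converges for a small system and flags the result", {
  spec <- system_spec(phi = 0.02, n_nodes = 60)
  st <- assemble_system(spec, seed = 31)
  p <- forcefield_params(ks = 5, kal = 5, kh = 5, eps = 2, lambda = 1)
  gs <- equilibrate(st, p, integrator_config(), n_pre = 1500, window = 1500,
                    max_windows = 12, tol = 0.02, seed = 1)
  expect_true(attr(gs, "converged"))
  expect_gt(length(attr(gs, "energy_trace")), 1)
})

test_that("field protocol demands a quasi-static (non-decreasing) schedule", {
  expect_error(field_protocol(c(0, 2, 1)), "non-decreasing")
  pr <- field_protocol(c(0, 1), equil_steps = 10, measure_steps = 10)
  expect_equal(pr$h, c(0, 0, 1))
})

test_that("magnetise records one row per field level with sane observables", {
  spec <- system_spec(phi = 0.02, n_nodes = 60)
  st <- assemble_system(spec, seed = 31)
  p <- forcefield_params(ks = 5, kal = 5, kh = 5, eps = 2, lambda = 1)
  pr <- field_protocol(c(0, 5), equil_steps = 400, measure_steps = 600)
  out <- magnetise(st, pr, p, integrator_config(), sample_every = 100,
                   seed = 2)
  expect_identical(nrow(out$series), 2L)
  expect_true(all(out$series$aspect_ratio > 0))
  expect_true(all(abs(out$series$magnetization) <= 1))
  # field alignment grows along the quasi-static schedule
  expect_gt(out$series$magnetization[2], out$series$magnetization[1])
})
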