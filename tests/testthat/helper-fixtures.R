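# shared fixtures: built in code, cached across test files within a run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env))
    assign(name, make(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a small paired-shell system with a few particles, for force/dynamics tests
tiny_system <- function() fixture("tiny_system", function() {
  spec <- system_spec(phi = 0.02, n_nodes = 60)
  assemble_system(spec, seed = 101)
})

small_shell <- function() fixture("small_shell", function() {
  make_sphere_mesh(42, diameter = 8, blob_diameter = 1.5)
})

# random dipolar ensemble away from contact, reproducible
random_ensemble <- function(M = 6, seed = 7) {
  set.seed(seed)
  pos <- matrix(rnorm(M * 3, sd = 2), M, 3) + 6
  orient <- matrix(rnorm(M * 3), M, 3)
  nanoparticle_ensemble(pos = pos, orient = orient, a_red = 1.2)
}

# finite-difference gradient of a scalar energy function of one coordinate
fd_gradient <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# --- shared study-condition runs (computed once, reused across tests) -----
# Full-mesh (393-node) shells as in the reference geometry; the particle
# loading and coupling vary per condition. Each ground-state preparation is
# pre-thermalisation (2e4 steps) + windowed magnetic equilibration (up to
# 9e4 steps), followed by a 2e4-step sampled production segment for MSD and
# structure observables.

ground_run <- function(lambda, phi, seed = 100 + round(100 * phi) + lambda) {
  key <- sprintf("ground_l%g_p%g", lambda, phi)
  fixture(key, function() {
    spec <- system_spec(phi = phi, n_nodes = 393)
    p <- forcefield_params(lambda = lambda)
    cfg <- integrator_config()
    st <- assemble_system(spec, seed = seed)
    st <- suppressWarnings(
      equilibrate(st, p, cfg, n_pre = 20000, window = 15000, tol = 5e-3,
                  max_windows = 6, seed = seed))
    prod <- run_dynamics(st, 20000, p, cfg, sample_every = 200)
    list(state = prod$state, samples = prod$samples,
         p = p, cfg = cfg, spec = spec)
  })
}

ramp_run <- function(lambda, phi) {
  key <- sprintf("ramp_l%g_p%g", lambda, phi)
  fixture(key, function() {
    g <- ground_run(lambda, phi)
    pr <- field_protocol(c(0, 1, 3, 5, 10), equil_steps = 8000,
                         measure_steps = 6000)
    magnetise(g$state, pr, g$p, g$cfg, sample_every = 500)
  })
}

rotate_about <- function(e, th, ax) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  as.vector(Rm %*% e)
}
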