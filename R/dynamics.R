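#' Langevin integrator configuration
#'
#' Parameters of the stochastic velocity-Verlet (BAOAB) discretisation of
#' the inertial Langevin equations
#' `m d2r/dt2 = F - zeta dr/dt + f(t)`, `<f f'> = 2 zeta kT delta`,
#' plus the rotational analogue on the unit sphere of orientations. The
#' translational friction follows the Stokes law, so each element's friction
#' scales with its soft-sphere diameter relative to the nanoparticle; the
#' rotational friction default uses the Stokes ratio for a sphere,
#' `zeta_r = zeta_t a^2 / 3`.
#'
#' @param dt reduced time step.
#' @param mass reduced mass per element.
#' @param zeta_t translational friction coefficient of a nanoparticle.
#' @param zeta_r rotational friction; `NULL` for the Stokes default.
#' @param inertia reduced moment of inertia.
#' @param kT reduced temperature (energy unit; 1 by convention).
#' @return An `integrator_config` object.
#' @export
integrator_config <- function(dt = 0.005, mass = 1, zeta_t = 1,
                              zeta_r = NULL, inertia = 1, kT = 1) {
  stopifnot(dt > 0, mass > 0, zeta_t > 0, inertia > 0, kT >= 0)
  if (!is.null(zeta_r)) stopifnot(zeta_r > 0)
  structure(list(dt = dt, mass = mass, zeta_t = zeta_t, zeta_r = zeta_r,
                 inertia = inertia, kT = kT),
            class = "integrator_config")
}

.cfg_resolved <- function(cfg, a_red) {
  zr <- if (is.null(cfg$zeta_r)) cfg$zeta_t * a_red^2 / 3 else cfg$zeta_r
  list(dt = cfg$dt, mass = cfg$mass, zeta_t = cfg$zeta_t, zeta_r = zr,
       inertia = cfg$inertia, kT = cfg$kT)
}

#' Advance a state by Langevin dynamics
#'
#' Integrates `n_steps` BAOAB steps. Noise is drawn from R's RNG: a given
#' `set.seed()` makes trajectories reproducible, and consecutive calls
#' continue the same noise stream, so `run(a)` followed by `run(b)` equals
#' `run(a + b)`.
#'
#' @param state an [mps_state()].
#' @param n_steps number of integration steps (>= 0).
#' @param p a [forcefield_params()].
#' @param cfg an [integrator_config()].
#' @param sample_every sampling stride in steps; 0 disables sampling.
#' @param magnetics logical; dipolar + Zeeman terms on/off.
#' @param seed optional RNG seed set before integration.
#' @return List with the advanced `state` and `samples` (see
#'   [simulation_samples]).
#' @export
run_dynamics <- function(state, n_steps, p, cfg = integrator_config(),
                         sample_every = 0, magnetics = TRUE, seed = NULL) {
  stopifnot(inherits(state, "mps_state"), n_steps >= 0)
  if (!is.null(seed)) {
    set.seed(seed)
    state$noise <- NULL   # derive a fresh noise stream from the seed
  }
  if (n_steps == 0)
    return(list(state = state, samples = NULL))
  res <- .sim_run(.state_positions(state), .state_velocities(state),
                  state$particles$orient, state$particles$angvel,
                  .state_topology(state),
                  .cpp_params(state, p, magnetics),
                  .cfg_resolved(cfg, state$particles$a_red),
                  as.integer(n_steps), as.integer(sample_every),
                  state$noise %||% integer(0))
  new_state <- .state_update(state, res$pos, res$vel, res$orient, res$angvel)
  new_state$noise <- res$rng_state
  new_state$time <- state$time + n_steps * cfg$dt
  samples <- if (sample_every > 0) .shape_samples(res$samples, state) else NULL
  list(state = new_state, samples = samples)
}

#' Simulation samples
#'
#' `run_dynamics()` with `sample_every > 0` returns a `simulation_samples`
#' list: `time` (absolute reduced time), `mnp_pos` and `mnp_orient`
#' (`n_frames x M x 3` arrays), `outer_pos` (`n_frames x V x 3`), and
#' `energy` (data frame of per-term potential energies plus kinetic energy
#' per frame).
#'
#' @name simulation_samples
NULL

.shape_samples <- function(s, state) {
  n <- .state_counts(state)
  nf <- length(s$time)
  shape <- function(m, k) {
    if (k == 0 || nf == 0) return(array(0, c(nf, k, 3)))
    a <- array(0, c(nf, k, 3))
    for (d in 1:3) a[, , d] <- m[, 3 * (seq_len(k) - 1) + d, drop = FALSE]
    a
  }
  en <- as.data.frame(s$energy)
  names(en) <- c("stretch", "area", "tether", "wca", "dipole", "zeeman",
                 "trap", "kinetic")
  en$potential <- rowSums(en[, c("stretch", "area", "tether", "wca",
                                 "dipole", "zeeman", "trap")])
  structure(list(time = s$time + state$time,
                 mnp_pos = shape(s$mnp_pos, n$n_mnp),
                 mnp_orient = shape(s$mnp_orient, n$n_mnp),
                 outer_pos = shape(s$outer_pos, n$n_out),
                 energy = en),
            class = "simulation_samples")
}

#' Single Langevin step
#'
#' One BAOAB step; thin wrapper over [run_dynamics()].
#' @inheritParams run_dynamics
#' @return The advanced `mps_state`.
#' @export
langevin_step <- function(state, p, cfg = integrator_config(),
                          magnetics = TRUE) {
  run_dynamics(state, 1, p, cfg, magnetics = magnetics)$state
}

#' Instantaneous kinetic temperature
#'
#' Twice the mean kinetic energy per translational degree of freedom, in kT
#' units: `sum(m v^2) / (3 N)`.
#'
#' @param state an [mps_state()].
#' @param mass reduced element mass.
#' @export
kinetic_temperature <- function(state, mass = 1) {
  v <- .state_velocities(state)
  if (nrow(v) == 0) stop("empty state: no mobile elements")
  mass * sum(v^2) / (3 * nrow(v))
}
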