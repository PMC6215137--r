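#' System specification of a magnetic polymersome
#'
#' Reduced-unit geometry and loading of the vesicle: outer/inner shell
#' diameters `Dout`, `Din`, blob diameters `dout`, `din`, nanoparticle
#' diameter `a_red`, volume fraction `phi` of magnetic phase in the
#' intra-membrane layer, and node count per shell. Defaults are the
#' reference geometry (Dout = 24, Din = 16, dout = 3.1, din = 2, a = 1.2;
#' layer thickness 1.45) with 393 nodes per shell and a hard cap of 393
#' nanoparticles.
#'
#' @param Dout,Din shell diameters, reduced units.
#' @param dout,din blob diameters of the outer and inner shell.
#' @param a_red reduced nanoparticle diameter.
#' @param phi volume fraction of magnetic phase in the layer (0--0.11 is the
#'   studied range).
#' @param n_nodes nodes per shell (both shells equal).
#' @param max_particles nanoparticle capacity cap.
#' @return A `system_spec` object.
#' @export
system_spec <- function(Dout = 24, Din = 16, dout = 3.1, din = 2,
                        a_red = 1.2, phi = 0.055, n_nodes = 393,
                        max_particles = 393) {
  stopifnot(Dout > Din, Din > 0, dout > 0, din > 0, a_red > 0,
            phi >= 0, n_nodes >= 12, max_particles >= 0)
  l <- layer_thickness(Dout, dout, Din, din)
  if (l < a_red)
    stop(sprintf(paste0("layer thickness %.3f cannot accommodate the ",
                        "nanoparticle monolayer (a = %.3f)"), l, a_red))
  structure(list(Dout = Dout, Din = Din, dout = dout, din = din,
                 a_red = a_red, phi = phi, n_nodes = as.integer(n_nodes),
                 max_particles = as.integer(max_particles)),
            class = "system_spec")
}

#' Nanoparticle count for a target volume fraction
#'
#' The magnetic-phase volume fraction is defined with respect to the volume
#' of the intra-membrane layer between the blob surfaces:
#' `V_layer = (4 pi / 3) [ (Dout/2 - dout/2)^3 - (Din/2 + din/2)^3 ]`,
#' each particle occupying `v_p = (pi/6) a^3`. Counts above the capacity
#' cap raise an error (the mesh template holds at most `max_particles`,
#' 393 by default).
#'
#' @param spec a [system_spec()].
#' @return Integer particle count.
#' @examples
#' n_particles_from_phi(system_spec(phi = 0.055))  # 105
#' n_particles_from_phi(system_spec(phi = 0.11))   # 210
#' @export
n_particles_from_phi <- function(spec) {
  stopifnot(inherits(spec, "system_spec"))
  r_out <- spec$Dout / 2 - spec$dout / 2
  r_in <- spec$Din / 2 + spec$din / 2
  v_layer <- 4 * pi / 3 * (r_out^3 - r_in^3)
  v_p <- pi / 6 * spec$a_red^3
  n <- as.integer(round(spec$phi * v_layer / v_p))
  if (n > spec$max_particles)
    stop(sprintf("requested phi needs %d particles, above the capacity cap of %d",
                 n, spec$max_particles))
  n
}

# admissible radial band for particle centres (between the blob surfaces,
# leaving half a particle diameter on each side)
.radial_band <- function(spec) {
  c(spec$Din / 2 + spec$din / 2 + spec$a_red / 2,
    spec$Dout / 2 - spec$dout / 2 - spec$a_red / 2)
}

#' Uniform random placement of nanoparticles in the layer
#'
#' Random sequential insertion: uniform direction on the sphere, uniform
#' radius within the admissible band, rejecting candidates closer than
#' `a_red` to an already-placed particle or closer than the blob-particle
#' contact distance `(a_red + d_blob)/2` to any blob. Orientations are
#' uniform on the unit sphere. Deterministic for a given seed.
#'
#' @param spec a [system_spec()].
#' @param pair optional `shell_pair` whose blob positions are respected; if
#'   `NULL` only the radial band and mutual distances constrain placement.
#' @param seed optional RNG seed.
#' @param max_attempts insertion attempts per particle before failing.
#' @return A [nanoparticle_ensemble()].
#' @export
place_nanoparticles <- function(spec, pair = NULL, seed = NULL,
                                max_attempts = 20000) {
  if (!is.null(seed)) set.seed(seed)
  M <- n_particles_from_phi(spec)
  band <- .radial_band(spec)
  pos <- matrix(0, M, 3)
  blobs <- if (is.null(pair)) NULL else
    rbind(pair$outer$positions, pair$inner$positions)
  bd <- if (is.null(pair)) NULL else
    c(rep(pair$outer$blob_diameter, nrow(pair$outer$positions)),
      rep(pair$inner$blob_diameter, nrow(pair$inner$positions)))
  placed <- 0L
  while (placed < M) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      r <- runif(1, band[1], band[2])
      cand <- u * r
      if (placed > 0) {
        d2 <- colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2)
        if (min(d2) < spec$a_red^2) next
      }
      if (!is.null(blobs)) {
        db2 <- colSums((t(blobs) - cand)^2)
        if (any(db2 < ((spec$a_red + bd) / 2)^2)) next
      }
      placed <- placed + 1L
      pos[placed, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("packing failure: could not insert particle %d of %d",
                   placed + 1L, M))
  }
  orient <- matrix(rnorm(3 * M), M, 3)
  if (M > 0) orient <- orient / sqrt(rowSums(orient^2))
  nanoparticle_ensemble(pos = pos, orient = orient, a_red = spec$a_red)
}

#' Assemble the full polymersome
#'
#' Builds both Fibonacci-mesh shells, pairs them node-by-node with radial
#' tethers, and loads the nanoparticle monolayer at the requested volume
#' fraction. The returned state carries zero applied field.
#'
#' @param spec a [system_spec()].
#' @param seed optional RNG seed for particle placement/orientation.
#' @return An [mps_state()] with the spec attached as attribute `spec`.
#' @export
assemble_system <- function(spec = system_spec(), seed = NULL) {
  outer <- make_sphere_mesh(spec$n_nodes, spec$Dout, spec$dout)
  inner <- make_sphere_mesh(spec$n_nodes, spec$Din, spec$din)
  pair <- pair_shells(outer, inner)
  ens <- place_nanoparticles(spec, pair, seed = seed)
  st <- mps_state(pair = pair, particles = ens, xi = 0)
  attr(st, "spec") <- spec
  st
}

#' Two-stage preparation of the zero-field ground state
#'
#' Stage A thermalises the assembled system with all couplings except the
#' magnetic ones (dipole-dipole and Zeeman off). Stage B switches the
#' magnetics on at zero field and continues in windows until the
#' trailing-window mean total energy changes by less than `tol` (relative)
#' between consecutive windows, or the window budget is exhausted (then the
#' returned state carries `converged = FALSE`, with a warning).
#'
#' @param state an assembled [mps_state()].
#' @param p a [forcefield_params()].
#' @param cfg an [integrator_config()].
#' @param n_pre stage-A steps.
#' @param window stage-B window length in steps.
#' @param tol relative energy-plateau tolerance between windows.
#' @param max_windows stage-B window budget.
#' @param seed optional RNG seed.
#' @return The ground-state `mps_state` with attributes `converged` and
#'   `energy_trace` (mean total energy per stage-B window).
#' @export
equilibrate <- function(state, p, cfg = integrator_config(),
                        n_pre = 20000, window = 10000, tol = 1e-3,
                        max_windows = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- run_dynamics(state, n_pre, p, cfg, magnetics = FALSE)$state
  e_prev <- NA_real_
  trace <- numeric(0)
  converged <- FALSE
  for (wnd in seq_len(max_windows)) {
    res <- run_dynamics(state, window, p, cfg,
                        sample_every = max(1L, as.integer(window / 20)),
                        magnetics = TRUE)
    state <- res$state
    e_now <- mean(res$samples$energy$potential + res$samples$energy$kinetic)
    trace <- c(trace, e_now)
    if (!is.na(e_prev) &&
        abs(e_now - e_prev) < tol * max(abs(e_prev), 1)) {
      converged <- TRUE
      break
    }
    e_prev <- e_now
  }
  if (!converged)
    warning("energy plateau not reached within the window budget")
  attr(state, "converged") <- converged
  attr(state, "energy_trace") <- trace
  state
}

#' Quasi-static field protocol
#'
#' Schedule of Zeeman coupling levels with per-level equilibration and
#' measurement lengths. `xi_values` must be non-decreasing (quasi-static
#' magnetisation from the ground state).
#'
#' @param xi_values non-decreasing vector of field levels.
#' @param equil_steps steps run at each level before measuring.
#' @param measure_steps steps sampled at each level.
#' @param h field direction (default +z).
#' @export
field_protocol <- function(xi_values = c(0, 0.5, 1, 2, 3, 5, 7, 10),
                           equil_steps = 10000, measure_steps = 10000,
                           h = c(0, 0, 1)) {
  if (is.unsorted(xi_values))
    stop("xi schedule must be non-decreasing (quasi-static protocol)")
  structure(list(xi_values = xi_values, equil_steps = equil_steps,
                 measure_steps = measure_steps, h = h / sqrt(sum(h^2))),
            class = "field_protocol")
}

#' Magnetise a ground state along a field schedule
#'
#' Steps through the protocol levels; at each level equilibrates, then
#' samples and records the aspect ratio of the outer shell, the reduced
#' magnetization, and cluster statistics of the particle ensemble.
#'
#' @param state ground-state [mps_state()].
#' @param protocol a [field_protocol()].
#' @param p a [forcefield_params()].
#' @param cfg an [integrator_config()].
#' @param sample_every sampling stride during the measurement phase.
#' @param seed optional RNG seed.
#' @return List with `series` (one row per field level: `xi`,
#'   `aspect_ratio`, `aspect_ratio_sd`, `magnetization`, `bonded_fraction`,
#'   `largest_cluster`) and the final `state`.
#' @export
magnetise <- function(state, protocol, p, cfg = integrator_config(),
                      sample_every = 200, seed = NULL) {
  stopifnot(inherits(protocol, "field_protocol"))
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(protocol$xi_values))
  for (k in seq_along(protocol$xi_values)) {
    state$field$xi <- protocol$xi_values[k]
    state$field$h <- protocol$h
    state <- run_dynamics(state, protocol$equil_steps, p, cfg)$state
    res <- run_dynamics(state, protocol$measure_steps, p, cfg,
                        sample_every = sample_every)
    state <- res$state
    ar <- apply(res$samples$outer_pos, 1, function(fr)
      aspect_ratio(fr, protocol$h))
    mg <- apply(res$samples$mnp_orient, 1, function(fr)
      magnetization(fr, protocol$h))
    cl <- cluster_stats(state$particles$pos, a_red = state$particles$a_red)
    rows[[k]] <- data.frame(xi = protocol$xi_values[k],
                            aspect_ratio = mean(ar),
                            aspect_ratio_sd = stats::sd(ar),
                            magnetization = mean(mg),
                            bonded_fraction = cl$bonded_fraction,
                            largest_cluster = cl$largest)
  }
  list(series = do.call(rbind, rows), state = state)
}

#' Full magnetisation curve averaged over realisations
#'
#' Builds, equilibrates and magnetises `n_real` independent realisations
#' (seeds `seed`, `seed + 1`, ...) and averages the per-level series, the
#' way field-sweep curves are usually reported (ten realisations at full
#' scale).
#'
#' @param spec a [system_spec()].
#' @param p a [forcefield_params()].
#' @param cfg an [integrator_config()].
#' @param protocol a [field_protocol()].
#' @param n_real number of realisations.
#' @param seed base RNG seed.
#' @param ... passed to [equilibrate()].
#' @return Data frame of per-level means across realisations (columns as in
#'   [magnetise()], plus `n_real`).
#' @export
magnetisation_curve <- function(spec, p, cfg = integrator_config(),
                                protocol = field_protocol(), n_real = 10,
                                seed = 1, ...) {
  all <- lapply(seq_len(n_real) - 1L, function(k) {
    st <- assemble_system(spec, seed = seed + k)
    st <- equilibrate(st, p, cfg, ...)
    magnetise(st, protocol, p, cfg)$series
  })
  out <- all[[1]]
  num <- setdiff(names(out), "xi")
  for (cn in num)
    out[[cn]] <- rowMeans(sapply(all, function(s) s[[cn]]))
  out$n_real <- n_real
  out
}
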