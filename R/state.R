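#' Assembled simulation state
#'
#' The object the integrator advances: an optional shell pair (outer + inner
#' triangulated shells with tethers) plus the nanoparticle ensemble and the
#' applied-field descriptor. Element ordering in all force and integrator
#' calls is outer blobs, inner blobs, nanoparticles.
#'
#' @param pair a `shell_pair` from [pair_shells()], or `NULL` for a
#'   membrane-free particle system.
#' @param particles a `nanoparticle_ensemble` (may have zero particles).
#' @param xi Zeeman coupling of the applied field.
#' @param h field direction (normalised internally).
#' @return An `mps_state`.
#' @export
mps_state <- function(pair = NULL, particles = nanoparticle_ensemble(0),
                      xi = 0, h = c(0, 0, 1)) {
  stopifnot(is.null(pair) || inherits(pair, "shell_pair"),
            inherits(particles, "nanoparticle_ensemble"))
  h <- h / sqrt(sum(h^2))
  structure(list(pair = pair, particles = particles,
                 field = list(xi = xi, h = h), time = 0),
            class = "mps_state")
}

#' Nanoparticle ensemble
#'
#' Positions, velocities, unit dipole orientations and angular velocities of
#' the mobile magnetic nanoparticles, plus their common reduced diameter.
#'
#' @param M number of particles (arrays are zero-initialised), or pass the
#'   arrays explicitly.
#' @param pos,vel,orient,angvel M x 3 matrices.
#' @param a_red reduced particle diameter.
#' @export
nanoparticle_ensemble <- function(M = NULL, pos = NULL, vel = NULL,
                                  orient = NULL, angvel = NULL, a_red = 1.2) {
  if (is.null(pos)) {
    M <- if (is.null(M)) 0L else as.integer(M)
    pos <- matrix(0, M, 3)
  }
  M <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, M, 3)
  if (is.null(orient)) {
    orient <- matrix(rep(c(0, 0, 1), each = M), M, 3)
  }
  if (is.null(angvel)) angvel <- matrix(0, M, 3)
  stopifnot(nrow(vel) == M, nrow(orient) == M, nrow(angvel) == M, a_red > 0)
  if (M > 0) {
    nrm <- sqrt(rowSums(orient^2))
    if (any(abs(nrm - 1) > 1e-9)) orient <- orient / nrm
  }
  structure(list(pos = pos, vel = vel, orient = orient, angvel = angvel,
                 a_red = a_red),
            class = "nanoparticle_ensemble")
}

#' Membrane-free particle system
#'
#' Convenience builder for thermostat and diffusion studies: M particles on
#' a cubic lattice (spacing `spacing`), no shells.
#'
#' @param M particle count.
#' @param spacing lattice spacing in reduced units.
#' @param a_red reduced particle diameter.
#' @inheritParams mps_state
#' @export
particle_gas <- function(M, spacing = 4, a_red = 1.2, xi = 0, h = c(0, 0, 1)) {
  n_side <- ceiling(M^(1 / 3))
  g <- seq_len(n_side) * spacing
  lat <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(M), , drop = FALSE]
  dimnames(lat) <- NULL
  mps_state(pair = NULL,
            particles = nanoparticle_ensemble(pos = lat, a_red = a_red),
            xi = xi, h = h)
}

# ---- internal marshalling to the C++ core --------------------------------

.state_counts <- function(state) {
  n_out <- if (is.null(state$pair)) 0L else nrow(state$pair$outer$positions)
  n_in <- if (is.null(state$pair)) 0L else nrow(state$pair$inner$positions)
  list(n_out = n_out, n_in = n_in, n_mnp = nrow(state$particles$pos))
}

.state_topology <- function(state) {
  n <- .state_counts(state)
  if (is.null(state$pair)) {
    edges <- matrix(integer(), 0, 2)
    tris <- matrix(integer(), 0, 3)
    teth <- matrix(integer(), 0, 2)
    r0e <- numeric(0); S0 <- numeric(0); r0t <- numeric(0)
    excl <- matrix(integer(), 0, 2)
  } else {
    po <- state$pair$outer; pi_ <- state$pair$inner
    edges <- rbind(po$edges, pi_$edges + n$n_out)
    tris <- rbind(po$triangles, pi_$triangles + n$n_out)
    r0e <- c(po$r0_edge, pi_$r0_edge)
    S0 <- c(po$S0_tri, pi_$S0_tri)
    teth <- cbind(seq_len(n$n_out), state$pair$correspondence + n$n_out)
    r0t <- state$pair$r0_tether
    excl <- state$pair$wca_excl %||% matrix(integer(), 0, 2)
  }
  list(edges = edges - 1L, r0_edge = r0e,
       triangles = tris - 1L, S0 = S0,
       tethers = teth - 1L, r0_tether = r0t,
       extra_excl = excl - 1L,
       n_out = n$n_out, n_in = n$n_in, n_mnp = n$n_mnp)
}

.state_positions <- function(state) {
  if (is.null(state$pair)) return(state$particles$pos)
  rbind(state$pair$outer$positions, state$pair$inner$positions,
        state$particles$pos)
}

.state_velocities <- function(state) {
  if (is.null(state$pair)) return(state$particles$vel)
  rbind(state$pair$outer$velocities, state$pair$inner$velocities,
        state$particles$vel)
}

.state_diam <- function(state) {
  n <- .state_counts(state)
  c(rep(if (n$n_out) state$pair$outer$blob_diameter else numeric(0), n$n_out),
    rep(if (n$n_in) state$pair$inner$blob_diameter else numeric(0), n$n_in),
    rep(state$particles$a_red, n$n_mnp))
}

.state_update <- function(state, pos, vel, orient, angvel) {
  n <- .state_counts(state)
  if (!is.null(state$pair)) {
    state$pair$outer$positions <- pos[seq_len(n$n_out), , drop = FALSE]
    state$pair$outer$velocities <- vel[seq_len(n$n_out), , drop = FALSE]
    idx <- n$n_out + seq_len(n$n_in)
    state$pair$inner$positions <- pos[idx, , drop = FALSE]
    state$pair$inner$velocities <- vel[idx, , drop = FALSE]
  }
  if (n$n_mnp > 0) {
    idx <- n$n_out + n$n_in + seq_len(n$n_mnp)
    state$particles$pos <- pos[idx, , drop = FALSE]
    state$particles$vel <- vel[idx, , drop = FALSE]
    state$particles$orient <- orient
    state$particles$angvel <- angvel
  }
  state
}
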