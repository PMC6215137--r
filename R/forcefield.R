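#' Force-field coupling constants
#'
#' All interaction constants of the model in reduced units (kT = 1):
#' neo-Hookean edge constant `ks`, local-area constraint `kal`, inter-shell
#' tether constant `kh`, WCA energy `eps` (the shift `cshift` equals `eps`
#' so the potential vanishes continuously at its cutoff), dipolar coupling
#' `lambda` and Zeeman coupling `xi`. An optional harmonic trap (`k_trap`
#' about `trap_center`) acting on the nanoparticles is available for
#' calibration studies.
#'
#' The elastic defaults are a deliberate calibration: they are the smallest
#' round values (in kT-based reduced units) at which the tensionless
#' spring-network membrane stays impermeable to the nanoparticles over long
#' strong-coupling runs while remaining soft enough to deform measurably
#' under field-aligned particle chains (see the methods vignette).
#'
#' @param ks neo-Hookean elastic constant (reduced force).
#' @param kal local-area constraint coefficient (reduced force).
#' @param kh tether elastic constant (reduced force/length).
#' @param eps WCA energy parameter, kT units.
#' @param lambda dipolar coupling parameter.
#' @param xi Zeeman coupling of the applied field.
#' @param k_trap harmonic trap stiffness (0 disables).
#' @param trap_center trap centre, length-3.
#' @return A `forcefield_params` object (with `cshift = eps`).
#' @export
forcefield_params <- function(ks = 10, kal = 10, kh = 5, eps = 2,
                              lambda = 0, xi = 0,
                              k_trap = 0, trap_center = c(0, 0, 0)) {
  vals <- c(ks = ks, kal = kal, kh = kh, eps = eps, lambda = lambda, xi = xi,
            k_trap = k_trap)
  if (any(vals < 0)) stop("force-field constants must be non-negative")
  structure(list(ks = ks, kal = kal, kh = kh, eps = eps, cshift = eps,
                 lambda = lambda, xi = xi, k_trap = k_trap,
                 trap_center = trap_center),
            class = "forcefield_params")
}

.cpp_params <- function(state, p, magnetics = TRUE) {
  list(ks = p$ks, kal = p$kal, kh = p$kh, eps = p$eps,
       lambda = p$lambda, a_red = state$particles$a_red,
       xi = if (is.null(state$field)) p$xi else state$field$xi,
       h = if (is.null(state$field)) c(0, 0, 1) else state$field$h,
       k_trap = p$k_trap, trap_center = p$trap_center,
       diam = .state_diam(state), magnetics = magnetics)
}

.forces_raw <- function(state, p, magnetics = TRUE) {
  .ff_forces(.state_positions(state), state$particles$orient,
             .state_topology(state), .cpp_params(state, p, magnetics))
}

#' Total forces and torques on all elements
#'
#' Blobs receive mesh-spring, local-area, tether and excluded-volume forces;
#' nanoparticles receive excluded-volume, dipole-dipole and Zeeman forces
#' plus the rigid-dipole torques. Action--reaction holds pairwise, so in a
#' uniform field the net force on the closed system vanishes.
#'
#' @param state an [mps_state()].
#' @param p a [forcefield_params()].
#' @param magnetics logical; disable to drop dipolar + Zeeman terms (as in
#'   the pre-thermalisation stage).
#' @return List with `forces` (N x 3, element order outer/inner/particles)
#'   and `torques` (M x 3).
#' @export
total_forces <- function(state, p, magnetics = TRUE) {
  .forces_raw(state, p, magnetics)
}

#' Per-term potential energies of a state
#'
#' Returns the named energy breakdown (stretch, area, tether, wca, dipole,
#' zeeman, trap) in kT units. The stretch entry integrates the neo-Hookean
#' force law numerically (Gauss-Legendre) from the rest length; the area
#' entry is the quadratic bookkeeping proxy for the (non-potential)
#' local-area constraint force.
#'
#' @inheritParams total_forces
#' @export
energy_breakdown <- function(state, p, magnetics = TRUE) {
  .ff_energies(.state_positions(state), state$particles$orient,
               .state_topology(state), .cpp_params(state, p, magnetics))
}

.only <- function(p, keep) {
  q <- p
  for (nm in setdiff(c("ks", "kal", "kh", "eps", "lambda", "xi", "k_trap"), keep))
    q[[nm]] <- 0
  q
}

#' Individual force terms
#'
#' Single-term evaluations on a full state, mainly for inspection and
#' testing: `stretch_forces()` (neo-Hookean mesh edges),
#' `local_area_forces()` (per-triangle area constraint), `tether_forces()`
#' (harmonic inter-shell springs). Each returns the N x 3 per-node force
#' matrix with every other coupling switched off.
#'
#' @inheritParams total_forces
#' @export
stretch_forces <- function(state, p) {
  .forces_raw(state, .only(p, "ks"), magnetics = FALSE)$forces
}

#' @rdname stretch_forces
#' @export
local_area_forces <- function(state, p) {
  .forces_raw(state, .only(p, "kal"), magnetics = FALSE)$forces
}

#' @rdname stretch_forces
#' @export
tether_forces <- function(state, p) {
  .forces_raw(state, .only(p, "kh"), magnetics = FALSE)$forces
}

#' Weeks-Chandler-Andersen pair potential
#'
#' Purely repulsive truncated-shifted Lennard-Jones interaction between two
#' soft spheres. The cutoff is half the sum of the diameters,
#' `Rcut = (d_i + d_j)/2`, the length parameter is `sigma = Rcut / 2^(1/6)`,
#' and the shift equals `eps` so that the energy falls continuously to zero
#' at the cutoff.
#'
#' @param r centre-centre distance(s), > 0.
#' @param d_i,d_j soft-sphere diameters.
#' @param eps energy parameter, kT units.
#' @return List with `energy` and `force` (magnitude of the repulsive radial
#'   force, `-dU/dr`), both vectorised over `r`.
#' @examples
#' wca_energy_force(1.2, 1.2, 1.2, eps = 1)  # at cutoff: zero energy/force
#' @export
wca_energy_force <- function(r, d_i, d_j, eps = 1) {
  if (any(r <= 0)) stop("singular configuration: non-positive distance")
  rc <- (d_i + d_j) / 2
  sig6 <- rc^6 / 2
  sr6 <- sig6 / r^6
  inside <- r < rc
  u <- ifelse(inside, 4 * eps * (sr6^2 - sr6) + eps, 0)
  f <- ifelse(inside, 24 * eps * (2 * sr6^2 - sr6) / r, 0)
  list(energy = u, force = f)
}

#' Neo-Hookean edge energy
#'
#' Potential energy of one mesh spring, obtained by Gauss-Legendre
#' integration of the neo-Hookean force law from the rest length `r0` to
#' the current length `r`. Zero and minimal at the rest length.
#'
#' @param r current edge length(s).
#' @param r0 equilibrium length.
#' @param ks elastic constant.
#' @export
neo_hookean_energy <- function(r, r0, ks = 1) {
  if (any(r <= 0)) stop("singular configuration: non-positive edge length")
  .neo_hookean_energy(as.numeric(r), r0, ks)
}

#' Magnetic energy, forces and torques of a dipolar ensemble
#'
#' Direct all-pairs summation (single box, no cutoff, no periodic images) of
#' the reduced dipole-dipole energy
#' `U_dd/kT = lambda a^3 [ (e_i.e_j) - 3 (e_i.rhat)(e_j.rhat) ] / r^3`
#' plus the Zeeman energy `-xi (e_i.h)` per particle. Forces are the
#' analytic gradients; torques follow the rigid-dipole law `e x h_local`
#' with `h_local` the applied plus dipolar field conjugate to `e`.
#'
#' @param ens a [nanoparticle_ensemble()] (or any list with `pos`, `orient`,
#'   `a_red`).
#' @param lambda dipolar coupling.
#' @param xi Zeeman coupling.
#' @param h field direction.
#' @return List with `energy` (dipolar + Zeeman, kT), `forces` (M x 3) and
#'   `torques` (M x 3).
#' @export
magnetic_energy_forces_torques <- function(ens, lambda, xi = 0,
                                           h = c(0, 0, 1)) {
  M <- nrow(ens$pos)
  if (M > 0) {
    d2 <- as.matrix(stats::dist(ens$pos))^2
    if (any(d2[upper.tri(d2)] < 1e-24))
      stop("singular configuration: overlapping particle centres")
  }
  st <- mps_state(pair = NULL,
                  particles = nanoparticle_ensemble(
                    pos = ens$pos, orient = ens$orient, a_red = ens$a_red),
                  xi = xi, h = h)
  p <- forcefield_params(ks = 0, kal = 0, kh = 0, eps = 0,
                         lambda = lambda, xi = xi)
  fr <- .forces_raw(st, p, magnetics = TRUE)
  en <- energy_breakdown(st, p, magnetics = TRUE)
  list(energy = unname(en["dipole"] + en["zeeman"]),
       forces = fr$forces, torques = fr$torques)
}
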