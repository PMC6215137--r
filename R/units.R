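#' Material parameters of the magnetic phase and membrane
#'
#' Bundles the physical quantities needed to map a real particle/membrane
#' system onto the reduced simulation units: saturation magnetisation of the
#' particle material, particle diameter, temperature, carrier viscosity and
#' membrane surface tension. Defaults describe 10 nm maghemite particles in
#' a polymersome membrane at room temperature.
#'
#' @param Ms saturation magnetisation of the particle material, A/m.
#' @param a_phys particle diameter, m.
#' @param T absolute temperature, K.
#' @param eta viscosity of the intra-membrane fluid, Pa s.
#' @param sigma_s membrane surface tension, N/m.
#' @return An object of class `material_params`.
#' @examples
#' m <- material_params()          # maghemite defaults
#' lambda_from_material(m)         # ~ 1
#' @export
material_params <- function(Ms = 4e5, a_phys = 1e-8, T = 300,
                            eta = 1e-3, sigma_s = 2e-2) {
  vals <- c(Ms = Ms, a_phys = a_phys, T = T, eta = eta, sigma_s = sigma_s)
  if (any(!is.finite(vals)) || any(vals <= 0 & names(vals) != "Ms") || Ms < 0)
    stop("material parameters must be positive (Ms may be zero)")
  structure(as.list(vals), class = "material_params")
}

#' Magnetic moment of a single-domain nanoparticle
#'
#' The particle is treated as a uniformly magnetised sphere, so its moment is
#' the saturation magnetisation times the particle volume:
#' mu = Ms * (pi/6) * a^3.
#'
#' @param Ms saturation magnetisation, A/m.
#' @param a_phys particle diameter, m.
#' @return Magnetic moment in A m^2.
#' @examples
#' dipole_moment(4e5, 1e-8)   # ~2e-19 for 10 nm maghemite
#' @export
dipole_moment <- function(Ms, a_phys) {
  if (a_phys <= 0) stop("particle diameter must be positive")
  if (Ms < 0) stop("saturation magnetisation must be non-negative")
  Ms * (pi / 6) * a_phys^3
}

#' Dipolar coupling parameter lambda
#'
#' Ratio of the contact dipole-dipole energy of two particles to the thermal
#' energy, using the SI point-dipole contact energy mu0 mu^2 / (4 pi a^3):
#' lambda = mu0 mu^2 / (4 pi a^3 kB T). Values near or above 1 signal a
#' tendency to chain formation.
#'
#' @param p a [material_params()] object.
#' @return Dimensionless coupling lambda >= 0.
#' @examples
#' lambda_from_material(material_params())  # maghemite, 10 nm: ~1.06
#' @export
lambda_from_material <- function(p) {
  stopifnot(inherits(p, "material_params"))
  if (p$T <= 0) stop("temperature must be positive")
  mu <- dipole_moment(p$Ms, p$a_phys)
  .mu0 * mu^2 / (4 * pi * p$a_phys^3 * .kB * p$T)
}

#' Zeeman coupling (Langevin argument) for an applied field
#'
#' xi = mu0 mu H / (kB T), the ratio of the Zeeman energy of one particle
#' moment to the thermal energy. [xi_coefficient()] returns the
#' proportionality factor mu0 mu / (kB T) in m/A, so that xi = coef * H.
#'
#' @param H applied field strength, A/m.
#' @param moment particle magnetic moment, A m^2.
#' @param T absolute temperature, K.
#' @return Dimensionless xi (or the m/A coefficient).
#' @examples
#' mu <- dipole_moment(4e5, 1e-8)
#' xi_from_field(8e4, mu, 300)   # ~5 at the 80 kA/m reference field
#' @export
xi_from_field <- function(H, moment, T = 300) {
  if (H < 0) stop("field strength must be non-negative")
  xi_coefficient(moment, T) * H
}

#' @rdname xi_from_field
#' @export
xi_coefficient <- function(moment, T = 300) {
  if (T <= 0) stop("temperature must be positive")
  .mu0 * moment / (.kB * T)
}

#' Unit of length of the reduced description
#'
#' All simulation lengths are expressed in a unit chosen so that the
#' nanoparticle diameter takes the reduced value `a_red` (default 1.2); for
#' a 10 nm particle the unit is then 8.3 nm. `to_physical()`/`to_reduced()`
#' convert between the two descriptions.
#'
#' @param a_phys physical particle diameter, m.
#' @param a_red reduced particle diameter (dimensionless).
#' @return Metres per reduced length unit.
#' @examples
#' u <- unit_of_length(1e-8, 1.2)
#' to_physical(24, u) * 1e9      # outer diameter 24 -> ~200 nm
#' @export
unit_of_length <- function(a_phys, a_red = 1.2) {
  if (a_red <= 0) stop("reduced diameter must be positive")
  if (a_phys <= 0) stop("particle diameter must be positive")
  a_phys / a_red
}

#' @rdname unit_of_length
#' @param x length (reduced for `to_physical`, physical for `to_reduced`).
#' @param unit metres per reduced unit, from [unit_of_length()].
#' @export
to_physical <- function(x, unit) x * unit

#' @rdname unit_of_length
#' @export
to_reduced <- function(x, unit) x / unit

#' Surface-tension consistency ratios
#'
#' Order-of-magnitude checks that the membrane interfaces are effectively
#' inextensible on both the thermal and the magnetic energy scales:
#' `thermal` = sigma_s a^2 / (kB T), the cost of opening a particle-sized
#' hole against thermal energy, and `magnetic` = sigma_s a^5 / (mu0 mu^2),
#' the same cost against the contact dipolar energy. Both are returned
#' together with their nearest power of ten.
#'
#' @param p a [material_params()] object.
#' @return List with `thermal`, `magnetic` and the corresponding
#'   `thermal_pow10`, `magnetic_pow10`.
#' @export
surface_tension_ratios <- function(p) {
  stopifnot(inherits(p, "material_params"))
  mu <- dipole_moment(p$Ms, p$a_phys)
  thermal <- p$sigma_s * p$a_phys^2 / (.kB * p$T)
  magnetic <- if (mu > 0) p$sigma_s * p$a_phys^5 / (.mu0 * mu^2) else 0
  list(thermal = thermal, magnetic = magnetic,
       thermal_pow10 = nearest_power_of_ten(thermal),
       magnetic_pow10 = nearest_power_of_ten(magnetic))
}

#' Rounding helpers for order-of-magnitude reporting
#'
#' `nearest_power_of_ten(x)` returns 10^round(log10(x));
#' `round_signif(x, digits)` is [base::signif()] under an explicit name.
#'
#' @param x positive number (zero returns zero).
#' @param digits significant digits.
#' @export
nearest_power_of_ten <- function(x) {
  if (x == 0) return(0)
  10^round(log10(abs(x))) * sign(x)
}

#' @rdname nearest_power_of_ten
#' @export
round_signif <- function(x, digits = 1) signif(x, digits)

#' Reduced simulation parameters
#'
#' Collects the dimensionless couplings of the reduced description: dipolar
#' coupling `lambda`, Zeeman coupling `xi`, reduced particle diameter
#' `a_red`, and the length unit. Built either directly or from material
#' parameters via [reduced_from_material()].
#'
#' @param lambda dipolar coupling, >= 0.
#' @param xi Zeeman coupling, >= 0.
#' @param a_red reduced particle diameter.
#' @param length_unit metres per reduced length.
#' @export
reduced_params <- function(lambda = 1, xi = 0, a_red = 1.2,
                           length_unit = 1e-8 / 1.2) {
  if (lambda < 0 || xi < 0) stop("lambda and xi must be non-negative")
  if (a_red <= 0 || length_unit <= 0) stop("a_red and length_unit must be positive")
  structure(list(lambda = lambda, xi = xi, a_red = a_red,
                 length_unit = length_unit, kT = 1),
            class = "reduced_params")
}

#' @rdname reduced_params
#' @param p a [material_params()] object.
#' @param H applied field, A/m (sets `xi`).
#' @export
reduced_from_material <- function(p, H = 0, a_red = 1.2) {
  mu <- dipole_moment(p$Ms, p$a_phys)
  reduced_params(lambda = lambda_from_material(p),
                 xi = xi_from_field(H, mu, p$T),
                 a_red = a_red,
                 length_unit = unit_of_length(p$a_phys, a_red))
}
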