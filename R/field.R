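# site matrix and SI couplings k_i = (mu_i . mu_agent) D^2 / (4 pi eps0)
.site_matrix <- function(membrane)
  as.matrix(membrane$sites[, c("x", "y", "z")])

.site_couplings <- function(membrane, agent_dipole) {
  mu <- as.matrix(membrane$sites[, c("mux", "muy", "muz")])
  drop(mu %*% agent_dipole) * .const$debye_to_si^2 /
    (4 * pi * .const$eps0)
}

#' Dipole-dipole interaction energy of one pair
#'
#' The engine's pair potential: `E = (mu_a . mu_b) / (4 pi eps0 eps_r r^3)`.
#' Only the scalar product of the two moments enters; the orientational
#' factor of the full dipole tensor is deliberately omitted (the agent is
#' treated as a point mass, not a rotor).
#'
#' @param mu_a,mu_b dipole moments, length-3, Debye.
#' @param separation length-3 separation vector (Angstrom); must be
#'   non-zero.
#' @param eps_r relative dielectric permittivity.
#' @return Energy in joules (per molecule).
#' @examples
#' # two 1-D dipoles aligned, 5 A apart, in water
#' dipole_pair_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 5), eps_r = 88)
#' @export
dipole_pair_energy <- function(mu_a, mu_b, separation, eps_r) {
  stopifnot(length(mu_a) == 3, length(mu_b) == 3, length(separation) == 3)
  r <- sqrt(sum(separation^2))
  if (r == 0)
    stop("zero separation: the 1/r^3 pair energy is singular; ",
         "apply the minimum-distance guard before calling")
  sum(mu_a * mu_b) * .const$debye_to_si^2 /
    (4 * pi * .const$eps0 * eps_r * (r * .const$angstrom)^3)
}

#' Total potential energy of the agent in the membrane field
#'
#' Sum of [dipole_pair_energy()] over all membrane sites, with the
#' permittivity resolved from the agent's z coordinate (see
#' [dielectric_at()]). Site-agent distances below `r_min` are clamped to
#' `r_min` (with a warning) to guard the 1/r^3 singularity when the agent
#' passes a lattice site.
#'
#' @param agent_position length-3 position (Angstrom).
#' @param agent_dipole length-3 dipole (Debye).
#' @param membrane a `membrane` object.
#' @param env an [environment_params()].
#' @param r_min minimum-distance clamp (Angstrom, default 1).
#' @return Energy in joules (per molecule).
#' @export
potential_energy <- function(agent_position, agent_dipole, membrane,
                             env = environment_params(), r_min = 1) {
  ev <- .field_eval(agent_position, agent_dipole, membrane, env, r_min)
  ev$energy
}

#' Force on the agent from the membrane dipole field
#'
#' Analytic gradient of the summed pair potential: each site contributes
#' `3 (mu_i . mu) / (4 pi eps0 eps_r r^4)` along the unit vector from the
#' site to the agent (`F = -dEp/dr`).
#'
#' @inheritParams potential_energy
#' @return Length-3 force vector in newtons.
#' @export
field_force <- function(agent_position, agent_dipole, membrane,
                        env = environment_params(), r_min = 1) {
  ev <- .field_eval(agent_position, agent_dipole, membrane, env, r_min)
  ev$force
}

.field_eval <- function(agent_position, agent_dipole, membrane, env,
                        r_min) {
  stopifnot(inherits(membrane, "membrane"))
  if (nrow(membrane$sites) == 0) stop("membrane has no sites")
  eps_r <- dielectric_at(agent_position[3], membrane, env)
  out <- cpp_field_eval(as.numeric(agent_position),
                        .site_matrix(membrane),
                        .site_couplings(membrane, as.numeric(agent_dipole)),
                        eps_r, r_min)
  if (out$n_clamped > 0)
    warning(out$n_clamped, " site distance(s) below the ", r_min,
            " A minimum were clamped")
  out
}

#' Relative permittivity at a height z
#'
#' Sharp two-region model: the membrane value inside
#' `|z| < half_thickness`, the water value outside; the boundary itself
#' belongs to water. A smooth variant switches between the two values with
#' a logistic ramp about 2 Angstrom wide, available for sensitivity checks
#' but off by default (the propagation engine always uses the sharp rule).
#'
#' @param z height above the bilayer center (Angstrom); vectorised.
#' @param membrane a `membrane` object (supplies `half_thickness`).
#' @param env an [environment_params()].
#' @param boundary `"sharp"` (default) or `"smooth"`.
#' @return Relative permittivity (dimensionless), same length as `z`.
#' @examples
#' m <- make_toy_membrane(rbind(c(0, 0, 20)), c(0, 0, 1))
#' dielectric_at(c(0, 19.9, 20, 45), m, environment_params())
#' @export
dielectric_at <- function(z, membrane, env = environment_params(),
                          boundary = c("sharp", "smooth")) {
  boundary <- match.arg(boundary)
  .region_value(z, membrane$geometry$half_thickness,
                env$eps_r_membrane, env$eps_r_water, boundary)
}

#' Viscosity at a height z
#'
#' Mirrors [dielectric_at()] with the viscosity values; the same
#' `|z| = half_thickness` threshold separates the regions.
#'
#' @inheritParams dielectric_at
#' @return Viscosity in Pa s, same length as `z`.
#' @export
viscosity_at <- function(z, membrane, env = environment_params(),
                         boundary = c("sharp", "smooth")) {
  boundary <- match.arg(boundary)
  .region_value(z, membrane$geometry$half_thickness,
                env$eta_membrane, env$eta_water, boundary)
}

.region_value <- function(z, h, inside, outside, boundary) {
  if (boundary == "sharp") {
    ifelse(abs(z) < h, inside, outside)
  } else {
    # logistic ramp centred on the sharp boundary; 10-90% span ~ 2 A
    w <- 2 / log(81)
    s <- 1 / (1 + exp(-(abs(z) - h) / w))
    inside + (outside - inside) * s
  }
}
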