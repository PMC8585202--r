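#' Lipid specification
#'
#' Per-axis dipole-moment statistics and area per lipid for one lipid type.
#' The membrane generator draws each site's dipole vector from independent
#' normal laws with these per-axis means and standard deviations, estimated
#' for each lipid species from long molecular-dynamics trajectories.
#'
#' @param name text label, e.g. `"PC"`.
#' @param mean_dipole numeric length-3, per-axis mean dipole moment (Debye).
#' @param sd_dipole numeric length-3, per-axis standard deviation (Debye),
#'   all components >= 0.
#' @param apl area per lipid (Angstrom^2), > 0; sets the lateral dipole
#'   density of the generated membrane.
#' @return An object of class `lipid_spec`.
#' @seealso [preset_lipid()] for the built-in PC/PG parameter sets.
#' @examples
#' lipid_spec("PC", c(0.34, -0.37, 1.65), c(11.29, 11.39, 8.44), apl = 64)
#' @export
lipid_spec <- function(name, mean_dipole, sd_dipole, apl = 64) {
  stopifnot(is.character(name), length(name) == 1)
  mean_dipole <- as.numeric(mean_dipole)
  sd_dipole <- as.numeric(sd_dipole)
  if (length(mean_dipole) != 3 || length(sd_dipole) != 3)
    stop("mean_dipole and sd_dipole must be length-3 numeric vectors")
  if (anyNA(mean_dipole) || anyNA(sd_dipole) || anyNA(apl))
    stop("lipid_spec: NA/NaN values are not allowed")
  if (any(sd_dipole < 0)) stop("sd_dipole components must be >= 0")
  if (!is.numeric(apl) || length(apl) != 1 || apl <= 0)
    stop("apl (area per lipid) must be a single positive number")
  structure(list(name = name, mean_dipole = mean_dipole,
                 sd_dipole = sd_dipole, apl = apl),
            class = "lipid_spec")
}

#' Agent (surfactant) specification
#'
#' The screened molecule reduced to a point dipole on a sphere: mass, dipole
#' vector, octanol-water partition coefficient (log10 P, converted to a
#' transfer enthalpy at the water/membrane boundary) and the Stokes drag
#' radius.
#'
#' @param name text label, e.g. `"OCT"`.
#' @param mass molar mass, g/mol (> 0).
#' @param dipole numeric length-3 dipole moment (Debye).
#' @param logp octanol-water partition coefficient (log10, dimensionless).
#' @param drag_radius Stokes radius in metres (> 0). The default 1e-14 m is
#'   far below molecular size; it is kept as the engine's reference value
#'   and only scales the drag coefficient b = 6 pi eta R.
#' @return An object of class `agent_spec`.
#' @seealso [preset_agent()] for the built-in OCT/CHX parameter sets.
#' @export
agent_spec <- function(name, mass, dipole, logp, drag_radius = 1e-14) {
  stopifnot(is.character(name), length(name) == 1)
  dipole <- as.numeric(dipole)
  if (length(dipole) != 3 || anyNA(dipole))
    stop("dipole must be a length-3 numeric vector without NA")
  if (!is.numeric(mass) || mass <= 0) stop("mass must be > 0")
  if (!is.numeric(drag_radius) || drag_radius <= 0)
    stop("drag_radius must be > 0")
  if (!is.numeric(logp) || length(logp) != 1 || is.na(logp))
    stop("logp must be a single number")
  structure(list(name = name, mass = mass, dipole = dipole, logp = logp,
                 drag_radius = drag_radius),
            class = "agent_spec")
}

# Built-in parameter sets: per-axis dipole means/SDs (Debye) from
# MD-derived statistics; masses in g/mol; logP dimensionless.
.lipid_presets <- list(
  PC = list(mean = c(0.34, -0.37, 1.65), sd = c(11.29, 11.39, 8.44)),
  PG = list(mean = c(0.14, 0.29, -35.08), sd = c(10.17, 10.09, 8.29))
)
.agent_presets <- list(
  OCT = list(mass = 623.84, dipole = c(0.69, 2.12, -0.51), logp = 9.25),
  CHX = list(mass = 505.452, dipole = c(2.74, 2.21, -0.55), logp = 5.48)
)

#' Built-in lipid presets
#'
#' `"PC"` (phosphatidylcholine, zwitterionic, eukaryote-mimicking) and
#' `"PG"` (phosphatidylglycerol, anionic, bacteria-mimicking). PG's large
#' negative z dipole component (-35.08 D) is what differentiates agent
#' behaviour in charged membranes.
#'
#' @param name `"PC"` or `"PG"` (case-insensitive).
#' @param apl area per lipid (Angstrom^2), default 64.
#' @return A [lipid_spec()].
#' @examples
#' preset_lipid("PG")$mean_dipole
#' @export
preset_lipid <- function(name, apl = 64) {
  key <- toupper(name)
  p <- .lipid_presets[[key]]
  if (is.null(p))
    stop("unknown lipid preset '", name, "'; available: ",
         paste(names(.lipid_presets), collapse = ", "))
  lipid_spec(key, p$mean, p$sd, apl = apl)
}

#' Built-in agent presets
#'
#' `"OCT"` (octenidine, logP = 9.25, mass 623.84 g/mol) and `"CHX"`
#' (chlorhexidine, logP = 5.48, mass 505.452 g/mol), the two reference
#' antiseptics used to validate the engine.
#'
#' @param name `"OCT"` or `"CHX"` (case-insensitive).
#' @param drag_radius Stokes radius in metres, default 1e-14.
#' @return An [agent_spec()].
#' @examples
#' preset_agent("CHX")$mass
#' @export
preset_agent <- function(name, drag_radius = 1e-14) {
  key <- toupper(name)
  p <- .agent_presets[[key]]
  if (is.null(p))
    stop("unknown agent preset '", name, "'; available: ",
         paste(names(.agent_presets), collapse = ", "))
  agent_spec(key, p$mass, p$dipole, p$logp, drag_radius = drag_radius)
}

#' @export
print.lipid_spec <- function(x, ...) {
  cat("Lipid spec:", x$name, "\n")
  cat(sprintf("  mean dipole (D): %7.2f %7.2f %7.2f\n", x$mean_dipole[1],
              x$mean_dipole[2], x$mean_dipole[3]))
  cat(sprintf("  sd dipole   (D): %7.2f %7.2f %7.2f\n", x$sd_dipole[1],
              x$sd_dipole[2], x$sd_dipole[3]))
  cat(sprintf("  area per lipid : %.2f A^2\n", x$apl))
  invisible(x)
}

#' @export
print.agent_spec <- function(x, ...) {
  cat("Agent spec:", x$name, "\n")
  cat(sprintf("  mass: %.3f g/mol  logP: %.2f  drag radius: %g m\n",
              x$mass, x$logp, x$drag_radius))
  cat(sprintf("  dipole (D): %.2f %.2f %.2f\n", x$dipole[1], x$dipole[2],
              x$dipole[3]))
  invisible(x)
}

#' Environment parameters
#'
#' Dielectric permittivity and viscosity of the two regions (bulk water and
#' membrane interior) plus temperature. The region is decided by the agent's
#' z coordinate against the membrane half-thickness; see [dielectric_at()].
#'
#' @param eps_r_water relative permittivity of water (default 88.0).
#' @param eps_r_membrane relative permittivity of the membrane interior
#'   (default 4.0).
#' @param eta_water water viscosity, Pa s (default 0.89e-3).
#' @param eta_membrane membrane viscosity, Pa s (default 934e-3).
#' @param temperature K (default 300).
#' @return An object of class `environment_params`.
#' @export
environment_params <- function(eps_r_water = 88.0, eps_r_membrane = 4.0,
                               eta_water = 0.89e-3, eta_membrane = 934e-3,
                               temperature = 300) {
  vals <- c(eps_r_water, eps_r_membrane, eta_water, eta_membrane,
            temperature)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all environment parameters must be strictly positive")
  structure(list(eps_r_water = eps_r_water, eps_r_membrane = eps_r_membrane,
                 eta_water = eta_water, eta_membrane = eta_membrane,
                 temperature = temperature),
            class = "environment_params")
}

#' Simulation run controls
#'
#' @param dt integration time step in seconds (default 1e-15 s = 1 fs).
#' @param n_steps number of integration steps (>= 2; default 5e5).
#' @param seed integer seed controlling membrane generation.
#' @param z_start agent starting height above the bilayer center (Angstrom,
#'   default 45).
#' @param temperature K (default 300); sets the kinetic-energy cap k_b T.
#' @param bin_width profile bin width along z (Angstrom, default 0.2).
#' @param ke_cap logical, limit kinetic energy to k_b T (default TRUE).
#' @param transfer_sign +1 or -1: sign with which the logP transfer enthalpy
#'   is added to the free energy on a water-to-membrane crossing (default
#'   +1, i.e. the agent "must overcome additional potential" on entry; -1
#'   gives the lipophilic reading where membrane entry is favourable).
#' @param stop_at_core logical, halt the run once the agent reaches the
#'   bilayer center z <= 0 (default TRUE).
#' @param v_start `"thermal"` (default) starts the agent moving toward the
#'   membrane at the cap speed sqrt(2 k_b T / m) so its kinetic energy
#'   equals the thermal limit k_b T; `"rest"` starts it from zero velocity.
#' @param r_min minimum site-agent distance (Angstrom) used to clamp the
#'   1/r^3 singularity (default 1).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(dt = 1e-15, n_steps = 5e5, seed = 1,
                              z_start = 45, temperature = 300,
                              bin_width = 0.2, ke_cap = TRUE,
                              transfer_sign = 1, stop_at_core = TRUE,
                              v_start = c("thermal", "rest"), r_min = 1) {
  v_start <- match.arg(v_start)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 2) stop("n_steps must be >= 2")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0")
  if (!transfer_sign %in% c(-1, 1))
    stop("transfer_sign must be +1 or -1")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(dt = dt, n_steps = n_steps, seed = as.integer(seed),
                 z_start = z_start, temperature = temperature,
                 bin_width = bin_width, ke_cap = isTRUE(ke_cap),
                 transfer_sign = transfer_sign,
                 stop_at_core = isTRUE(stop_at_core), v_start = v_start,
                 r_min = r_min),
            class = "simulation_params")
}
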