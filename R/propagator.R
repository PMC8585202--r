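#' Stokes drag coefficient
#'
#' `b = 6 pi eta R` for a sphere of radius R in a medium of viscosity eta;
#' the resistance force on the agent is `-b v`.
#'
#' @param eta viscosity, Pa s (> 0).
#' @param radius sphere radius, metres (> 0).
#' @return Drag coefficient in kg/s.
#' @examples
#' drag_coefficient(0.89e-3, 1e-14) # water, reference agent radius
#' @export
drag_coefficient <- function(eta, radius) {
  if (any(eta <= 0) || any(radius <= 0))
    stop("eta and radius must be > 0")
  6 * pi * eta * radius
}

#' One update of the damped two-step Verlet recurrence
#'
#' Implements the engine's propagation rule literally:
#' position two time levels ahead from the position two levels back and the
#' intervening velocity, velocity from the velocity two levels back, the
#' force at the current position, and the Stokes drag term:
#' \deqn{r_{n+1} = r_{n-1} + 2\Delta t\, v_n}
#' \deqn{v_{n+1} = v_{n-1}\,(1 - 2\Delta t\, b/m) + 2\Delta t\, F(r_n)/m}
#'
#' @param position current position r_n (Angstrom, length 3).
#' @param position_prev previous position r_{n-1} (Angstrom).
#' @param v_curr velocity v_n (m/s).
#' @param v_prev velocity v_{n-1} (m/s).
#' @param force force at r_n (N, length 3).
#' @param mass_kg particle mass in kg per molecule (convert g/mol via
#'   Avogadro's number).
#' @param b drag coefficient, kg/s (see [drag_coefficient()]).
#' @param dt time step, s.
#' @return List with `position` (r_{n+1}, Angstrom) and `velocity`
#'   (v_{n+1}, m/s).
#' @export
verlet_step <- function(position, position_prev, v_curr, v_prev, force,
                        mass_kg, b, dt) {
  if (!all(is.finite(c(position, position_prev, v_curr, v_prev, force))))
    stop("verlet_step: non-finite state")
  v_next <- v_prev * (1 - 2 * dt * b / mass_kg) +
    2 * dt * force / mass_kg
  r_next <- position_prev + 2 * dt * v_curr / .const$angstrom
  list(position = r_next, velocity = v_next)
}

#' Cap the kinetic energy at k_b T
#'
#' If `m |v|^2 / 2 > k_b T` the speed is rescaled to `sqrt(2 k_b T / m)`,
#' preserving the direction; otherwise the velocity is returned unchanged.
#' This is the engine's guard against unphysical acceleration.
#'
#' @param velocity length-3 velocity (m/s).
#' @param mass_kg mass in kg per molecule.
#' @param temperature K (> 0).
#' @return Length-3 velocity (m/s) with kinetic energy <= k_b T.
#' @export
cap_kinetic_energy <- function(velocity, mass_kg, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  ke <- 0.5 * mass_kg * sum(velocity^2)
  lim <- .const$kb * temperature
  if (ke <= lim) return(velocity)
  velocity * sqrt(2 * lim / mass_kg) / sqrt(sum(velocity^2))
}

#' Propagate the agent through the membrane dipole field
#'
#' Runs the damped two-step Verlet recurrence (see [verlet_step()]) from
#' `(box center x, box center y, z_start)`, with the dielectric constant,
#' viscosity and the logP transfer enthalpy resolved per region at every
#' step, the kinetic energy capped at k_b T, and the cumulative Gibbs free
#' energy accumulated from per-step Hamiltonian differences (see
#' [accumulate_free_energy()]). By default the agent starts moving toward
#' the membrane at the cap speed `sqrt(2 k_b T / m)` so its initial kinetic
#' energy equals the thermal limit; `v_start = "rest"` in
#' [simulation_params()] starts it from rest instead.
#'
#' The recurrence is bootstrapped with `r_0 = r_{-1}` = start and
#' `v_0 = v_{-1}` = the starting velocity. The run is deterministic given
#' `(agent, membrane, env, sim)`; all randomness lives in the membrane
#' generation. The run halts early if the agent reaches the bilayer center
#' (`stop_at_core`) and aborts with a diagnostic if the position leaves a
#' 10x box envelope or turns non-finite.
#'
#' @param agent an [agent_spec()] (or preset name such as `"OCT"`).
#' @param membrane a `membrane` from [build_membrane()] or
#'   [make_toy_membrane()].
#' @param env an [environment_params()].
#' @param sim a [simulation_params()].
#' @return A data.frame of class `trajectory` with one row per recorded
#'   step: `step`, `time` (s), `x, y, z` (Angstrom), `vx, vy, vz` (m/s),
#'   `ep` and `h` and `dg` (kcal/mol; potential energy, Hamiltonian,
#'   cumulative Gibbs free energy) and `region` (`"water"`/`"membrane"`).
#'   Attributes: `agent`, `sim`, `membrane_seed`, `n_clamped`.
#' @examples
#' m <- make_toy_membrane(rbind(c(40, 40, 20), c(40, 40, -20)), c(0, 0, 0))
#' tr <- run_trajectory("OCT", m, sim = simulation_params(n_steps = 100))
#' tail(tr$dg, 1) # zero field: no free-energy change
#' @export
run_trajectory <- function(agent, membrane, env = environment_params(),
                           sim = simulation_params()) {
  if (is.character(agent)) agent <- preset_agent(agent)
  stopifnot(inherits(agent, "agent_spec"), inherits(membrane, "membrane"),
            inherits(env, "environment_params"),
            inherits(sim, "simulation_params"))
  g <- membrane$geometry
  mass_kg <- .mass_kg(agent$mass)
  kbT <- .const$kb * sim$temperature
  start <- c(g$lx / 2, g$ly / 2, sim$z_start)
  v0 <- if (sim$v_start == "thermal")
    c(0, 0, -sqrt(2 * kbT / mass_kg)) else c(0, 0, 0)
  transfer_j <- transfer_enthalpy(agent$logp, sim$temperature) /
    .const$avogadro
  envelope <- 10 * max(g$lx, g$ly, abs(sim$z_start) + g$half_thickness)
  out <- cpp_run_trajectory(
    start, v0, .site_matrix(membrane),
    .site_couplings(membrane, agent$dipole), mass_kg, sim$dt,
    sim$n_steps, g$half_thickness, env$eps_r_water, env$eps_r_membrane,
    drag_coefficient(env$eta_water, agent$drag_radius),
    drag_coefficient(env$eta_membrane, agent$drag_radius), kbT,
    sim$ke_cap, transfer_j, sim$transfer_sign, sim$stop_at_core,
    sim$r_min, envelope)
  n <- out$n_recorded
  if (out$status == 2L)
    stop("run_trajectory: non-finite state at step ", out$bad_step,
         " (numerical divergence)", call. = FALSE)
  if (out$status == 1L)
    stop("run_trajectory: agent left the 10x box envelope at step ",
         out$bad_step, " (divergence)", call. = FALSE)
  idx <- seq_len(n)
  traj <- data.frame(
    step = idx - 1L,
    time = out$time[idx],
    x = out$pos[idx, 1], y = out$pos[idx, 2], z = out$pos[idx, 3],
    vx = out$vel[idx, 1], vy = out$vel[idx, 2], vz = out$vel[idx, 3],
    ep = joule_to_kcalmol(out$ep[idx]),
    h = joule_to_kcalmol(out$h[idx]),
    dg = joule_to_kcalmol(out$dg[idx]),
    region = ifelse(out$region[idx] == 1L, "membrane", "water")
  )
  if (out$n_clamped > 0)
    attr(traj, "n_clamped") <- out$n_clamped
  else
    attr(traj, "n_clamped") <- 0L
  attr(traj, "agent") <- agent
  attr(traj, "sim") <- sim
  attr(traj, "membrane_seed") <- membrane$seed
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  ag <- attr(x, "agent")
  cat(sprintf("Trajectory: %d steps, agent %s, z %.1f -> %.2f A, final dG %.3f kcal/mol\n",
              nrow(x), if (!is.null(ag)) ag$name else "?", x$z[1],
              x$z[nrow(x)], x$dg[nrow(x)]))
  invisible(x)
}
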