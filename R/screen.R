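#' Screen an agent against a lipid membrane over replicate realisations
#'
#' Runs [run_trajectory()] for `n_replicates` independently generated
#' membranes (seeds `seed, seed + 1, ...`), bins each run into a
#' free-energy profile, and returns the per-replicate features together
#' with the replicate-mean profile and its features. This is the package's
#' main entry point for the screening question "how hard is it for this
#' surfactant to cross this membrane?".
#'
#' @param lipid a [lipid_spec()] or preset name (`"PC"`, `"PG"`).
#' @param agent an [agent_spec()] or preset name (`"OCT"`, `"CHX"`).
#' @param n_replicates number of membrane realisations (default 10).
#' @param seed base seed; replicate k uses `seed + k - 1`.
#' @param geometry a [membrane_geometry()].
#' @param env an [environment_params()].
#' @param sim a [simulation_params()].
#' @return An object of class `screen_result`: list with
#'   `mean_profile` (an `fe_profile` with per-bin mean and SD),
#'   `features` (features of the mean profile, [find_extrema()]),
#'   `replicates` (data.frame of per-seed dG_trans, tallest barrier and
#'   deepest membrane minimum), `profiles` (list of per-seed profiles)
#'   and the inputs.
#' @examples
#' \donttest{
#' res <- screen_agent("PC", "OCT", n_replicates = 2, seed = 1,
#'                     sim = simulation_params(n_steps = 20000))
#' res$features
#' }
#' @export
screen_agent <- function(lipid, agent, n_replicates = 10, seed = 1,
                         geometry = membrane_geometry(),
                         env = environment_params(),
                         sim = simulation_params()) {
  if (is.character(lipid)) lipid <- preset_lipid(lipid)
  if (is.character(agent)) agent <- preset_agent(agent)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  seeds <- as.integer(seed) + seq_len(n_replicates) - 1L
  profiles <- vector("list", n_replicates)
  reps <- data.frame(seed = seeds, dg_trans = NA_real_,
                     barrier_z = NA_real_, barrier = NA_real_,
                     minimum_z = NA_real_, minimum = NA_real_)
  h <- geometry$half_thickness
  for (k in seq_len(n_replicates)) {
    mem <- build_membrane(lipid, geometry, seed = seeds[k])
    traj <- run_trajectory(agent, mem, env, sim)
    prof <- build_profile(traj)
    profiles[[k]] <- prof
    ft <- find_extrema(prof)
    reps$dg_trans[k] <- ft$dg_trans
    tb <- tallest_barrier(ft)
    if (!is.null(tb)) {
      reps$barrier_z[k] <- tb$abs_z
      reps$barrier[k] <- tb$value
    }
    mm <- membrane_minimum(ft, h)
    if (!is.null(mm)) {
      reps$minimum_z[k] <- mm$abs_z
      reps$minimum[k] <- mm$value
    }
  }
  mean_profile <- if (n_replicates >= 2)
    replicate_statistics(profiles) else profiles[[1]]
  structure(list(mean_profile = mean_profile,
                 features = find_extrema(mean_profile),
                 replicates = reps, profiles = profiles,
                 lipid = lipid, agent = agent, geometry = geometry,
                 env = env, sim = sim, seeds = seeds),
            class = "screen_result")
}

#' Feature accessors
#'
#' Convenience selectors on a [find_extrema()] result. `tallest_barrier`
#' returns the highest barrier anywhere on the profile;
#' `entry_barrier` the tallest barrier in the membrane-entry region
#' (|z| within `margin` of the leaflet plane); `first_barrier_outside` the
#' first local maximum met coming from the bulk side that lies outside the
#' membrane (|z| > half_thickness); `membrane_minimum` the lowest local
#' minimum inside the membrane (|z| < half_thickness). Each returns a
#' one-row data.frame (`z`, `abs_z`, `value`) or `NULL` when absent.
#'
#' @param features a `profile_features` object.
#' @param half_thickness leaflet-plane distance (Angstrom, default 20).
#' @param margin half-width of the entry region (Angstrom, default 5).
#' @name feature-accessors
NULL

#' @rdname feature-accessors
#' @export
tallest_barrier <- function(features) {
  b <- features$barriers
  if (!nrow(b)) return(NULL)
  b[which.max(b$value), , drop = FALSE]
}

#' @rdname feature-accessors
#' @export
entry_barrier <- function(features, half_thickness = 20, margin = 5) {
  b <- features$barriers
  b <- b[abs(b$abs_z - half_thickness) <= margin, , drop = FALSE]
  if (!nrow(b)) return(NULL)
  b[which.max(b$value), , drop = FALSE]
}

#' @rdname feature-accessors
#' @export
first_barrier_outside <- function(features, half_thickness = 20) {
  b <- features$barriers
  b <- b[b$abs_z > half_thickness, , drop = FALSE]
  if (!nrow(b)) return(NULL)
  b[which.max(b$z), , drop = FALSE] # first met coming from the bulk side
}

#' @rdname feature-accessors
#' @export
membrane_minimum <- function(features, half_thickness = 20) {
  m <- features$minima
  m <- m[m$abs_z < half_thickness, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  m[which.min(m$value), , drop = FALSE]
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Screen: agent %s vs %s membrane, %d replicate(s)\n",
              x$agent$name, x$lipid$name, length(x$seeds)))
  ok <- !is.na(x$replicates$dg_trans)
  if (any(ok))
    cat(sprintf("  dG_trans (mean profile): %s kcal/mol; per-seed %0.3f +/- %0.3f over %d runs\n",
                format(x$features$dg_trans, digits = 4),
                mean(x$replicates$dg_trans[ok]),
                stats::sd(x$replicates$dg_trans[ok]), sum(ok)))
  print(x$features)
  invisible(x)
}
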