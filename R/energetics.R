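#' Hamiltonian of the agent state
#'
#' `H = Ep + min(m v^2 / 2, k_b T)`: the kinetic part is limited to the
#' thermal energy, mirroring the propagation engine's kinetic-energy cap.
#' Set `cap = FALSE` for the uncapped `Ep + m v^2 / 2` (used e.g. when
#' checking energy conservation of the integrator).
#'
#' @param ep potential energy, J per molecule.
#' @param velocity length-3 velocity, m/s.
#' @param mass_kg mass, kg per molecule.
#' @param temperature K.
#' @param cap logical, cap the kinetic part at k_b T (default TRUE).
#' @return Hamiltonian in J per molecule.
#' @export
hamiltonian <- function(ep, velocity, mass_kg, temperature, cap = TRUE) {
  ke <- 0.5 * mass_kg * sum(velocity^2)
  if (cap) ke <- min(ke, .const$kb * temperature)
  ep + ke
}

#' Octanol-water transfer enthalpy from logP
#'
#' `dH_transfer = ln(10) R T log10(P)`, the additional potential the agent
#' picks up when the surrounding medium switches between water and the
#' membrane interior. Reported per mole; divide by Avogadro's number for
#' the per-molecule value added to the Hamiltonian bookkeeping.
#'
#' @param logp octanol-water partition coefficient (log10).
#' @param temperature K (> 0).
#' @return Transfer enthalpy in J/mol.
#' @examples
#' transfer_enthalpy(9.25, 300) / 4184 # kcal/mol, octenidine
#' @export
transfer_enthalpy <- function(logp, temperature) {
  if (any(temperature <= 0)) stop("temperature must be > 0")
  log(10) * .const$gas_constant * temperature * logp
}

#' Per-step Gibbs free-energy increment
#'
#' `H_next - H_prev`, plus `sign_convention * transfer` when the step
#' crosses from water into the membrane and minus it on the way out; no
#' transfer term when the region is unchanged. Enter-then-exit therefore
#' contributes zero net transfer.
#'
#' @param h_prev,h_next Hamiltonians at the two states, J per molecule.
#' @param region_prev,region_next `"water"` or `"membrane"`.
#' @param transfer transfer enthalpy in J per molecule (see
#'   [transfer_enthalpy()]; divide by Avogadro's number).
#' @param sign_convention +1 (default) or -1.
#' @return Increment in J per molecule.
#' @export
free_energy_increment <- function(h_prev, h_next, region_prev, region_next,
                                  transfer, sign_convention = 1) {
  stopifnot(region_prev %in% c("water", "membrane"),
            region_next %in% c("water", "membrane"))
  inc <- h_next - h_prev
  if (region_prev == "water" && region_next == "membrane")
    inc <- inc + sign_convention * transfer
  else if (region_prev == "membrane" && region_next == "water")
    inc <- inc - sign_convention * transfer
  inc
}

#' Accumulate the free energy along a state sequence
#'
#' Running sum of [free_energy_increment()] from the start state (which
#' defines dG = 0). Operates on vectors of per-step Hamiltonians and
#' regions, so it can re-derive the cumulative dG column of a
#' [run_trajectory()] result independently of the propagation engine.
#'
#' @param h numeric vector of Hamiltonians, J per molecule.
#' @param region character vector (`"water"`/`"membrane"`), same length.
#' @param transfer transfer enthalpy, J per molecule.
#' @param sign_convention +1 (default) or -1.
#' @return Numeric vector of cumulative dG (J per molecule), same length
#'   as `h`, starting at 0.
#' @export
accumulate_free_energy <- function(h, region, transfer,
                                   sign_convention = 1) {
  n <- length(h)
  stopifnot(length(region) == n)
  if (n == 0) return(numeric(0))
  mem <- region == "membrane"
  inc <- c(0, diff(h))
  crossing <- c(0, diff(as.integer(mem))) # +1 enter, -1 exit
  cumsum(inc + sign_convention * transfer * crossing)
}

#' Bin the cumulative free energy along the bilayer normal
#'
#' Bins the trajectory's cumulative dG by the agent's z coordinate into
#' bins of width `bin_width`; each bin's value is the mean of its dG
#' samples. The profile is re-zeroed at the bulk reference bin (the bin
#' containing the starting height). Bins inside the covered z range that
#' received no samples are kept with `NA` (missing, not zero).
#'
#' @param trajectory a `trajectory` from [run_trajectory()].
#' @param bin_width bin width in Angstrom (default: the trajectory's
#'   simulation setting, else 0.2).
#' @param z_ref bulk reference height (Angstrom; default: the trajectory's
#'   starting z).
#' @return An object of class `fe_profile`: data.frame with `z` (bin
#'   centers, Angstrom), `dg` (kcal/mol, NA where unsampled) and `count`;
#'   attributes `bin_width`, `z_ref` and `reference` (label of the bulk
#'   bin used as zero).
#' @export
build_profile <- function(trajectory, bin_width = NULL, z_ref = NULL) {
  stopifnot(nrow(trajectory) > 0)
  sim <- attr(trajectory, "sim")
  if (is.null(bin_width))
    bin_width <- if (!is.null(sim)) sim$bin_width else 0.2
  if (is.null(z_ref)) z_ref <- trajectory$z[1]
  idx <- floor(trajectory$z / bin_width)
  agg_sum <- rowsum(trajectory$dg, idx)
  agg_n <- rowsum(rep(1L, length(idx)), idx)
  got <- as.integer(rownames(agg_sum))
  full <- seq(min(got), max(got))
  dg <- rep(NA_real_, length(full))
  cnt <- rep(0L, length(full))
  pos <- match(got, full)
  dg[pos] <- agg_sum[, 1] / agg_n[, 1]
  cnt[pos] <- agg_n[, 1]
  z <- (full + 0.5) * bin_width
  ref_bin <- floor(z_ref / bin_width)
  ref_pos <- match(ref_bin, full)
  if (is.na(ref_pos) || is.na(dg[ref_pos])) {
    # fall back to the populated bin nearest the reference height
    cand <- which(!is.na(dg))
    ref_pos <- cand[which.min(abs(z[cand] - z_ref))]
  }
  dg <- dg - dg[ref_pos]
  out <- data.frame(z = z, dg = dg, count = cnt)
  attr(out, "bin_width") <- bin_width
  attr(out, "z_ref") <- z_ref
  attr(out, "reference") <- sprintf("bin at z = %.2f A", z[ref_pos])
  class(out) <- c("fe_profile", "data.frame")
  out
}

#' Net translocation free energy of a profile
#'
#' `dG_trans = dG_core - dG_bulk`: the cost of moving the agent from bulk
#' water to the bilayer center under the profile's sign convention. The
#' bulk bin is the profile's zero reference; the core bin is the populated
#' bin nearest z = 0. If the agent never came within `core_tol` of the
#' bilayer center the result is `NA` with attribute `reached = FALSE`
#' (an explicit "not reached", not zero).
#'
#' @param profile an `fe_profile` from [build_profile()] or
#'   [replicate_statistics()].
#' @param core_tol largest |z| (Angstrom) still accepted as "core"
#'   (default 2).
#' @return Numeric dG_trans (kcal/mol) with attributes `dg_bulk`,
#'   `dg_core`, `z_core` and `reached`.
#' @export
trans_free_energy <- function(profile, core_tol = 2) {
  ok <- which(!is.na(profile$dg))
  if (!length(ok)) stop("profile has no populated bins")
  zc <- profile$z[ok]
  i_core <- ok[which.min(abs(zc))]
  reached <- abs(profile$z[i_core]) <= core_tol
  dg_bulk <- 0
  dg_core <- if (reached) profile$dg[i_core] else NA_real_
  out <- if (reached) dg_core - dg_bulk else NA_real_
  attributes(out) <- list(dg_bulk = dg_bulk, dg_core = dg_core,
                          z_core = profile$z[i_core], reached = reached)
  out
}

# centered moving average over populated bins; window must be odd
.smooth_profile <- function(dg, window = 3) {
  if (window <= 1) return(dg)
  half <- window %/% 2
  n <- length(dg)
  out <- dg
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    out[i] <- mean(dg[j])
  }
  out
}

#' Extract barriers and minima from a free-energy profile
#'
#' Detects local maxima (barriers) and minima of the profile after a
#' moving-average smoothing (default window: 3 bins) applied over the
#' populated bins. Heights and depths are measured from the bulk reference
#' (the profile zero); positions are reported both as the signed bin
#' center `z` and as `abs_z`, the distance from the bilayer center.
#'
#' @param profile an `fe_profile` (>= 5 populated bins).
#' @param smooth_window odd moving-average window in bins (default 3).
#' @return An object of class `profile_features`: list with `dg_trans`
#'   (see [trans_free_energy()]), `dg_bulk`, `dg_core`, `barriers` and
#'   `minima` (data.frames `z`, `abs_z`, `value`, ordered from the bulk
#'   side inward, i.e. by decreasing z).
#' @export
find_extrema <- function(profile, smooth_window = 3) {
  ok <- which(!is.na(profile$dg))
  if (length(ok) < 5)
    stop("find_extrema needs at least 5 populated bins")
  z <- profile$z[ok]
  s <- .smooth_profile(profile$dg[ok], smooth_window)
  n <- length(s)
  i <- 2:(n - 1)
  is_max <- s[i] >= s[i - 1] & s[i] > s[i + 1]
  is_min <- s[i] <= s[i - 1] & s[i] < s[i + 1]
  mk <- function(sel) {
    id <- i[sel]
    d <- data.frame(z = z[id], abs_z = abs(z[id]), value = s[id])
    d[order(-d$z), , drop = FALSE]
  }
  dgt <- trans_free_energy(profile)
  structure(list(dg_trans = as.numeric(dgt),
                 dg_bulk = attr(dgt, "dg_bulk"),
                 dg_core = attr(dgt, "dg_core"),
                 reached_core = attr(dgt, "reached"),
                 barriers = mk(is_max), minima = mk(is_min)),
            class = "profile_features")
}

#' @export
print.profile_features <- function(x, ...) {
  cat(sprintf("Profile features: dG_trans = %s kcal/mol (core %s)\n",
              format(x$dg_trans, digits = 4),
              if (isTRUE(x$reached_core)) "reached" else "NOT reached"))
  cat(sprintf("  %d barrier(s), %d minimum(-a)\n", nrow(x$barriers),
              nrow(x$minima)))
  if (nrow(x$barriers)) {
    cat("  barriers (z A, kcal/mol):\n")
    print(format(x$barriers, digits = 3), row.names = FALSE)
  }
  if (nrow(x$minima)) {
    cat("  minima (z A, kcal/mol):\n")
    print(format(x$minima, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Mean profile and per-bin spread over replicate runs
#'
#' Aligns two or more profiles on their common bin grid (same bin width and
#' bin origin required) and returns the per-bin mean and standard deviation
#' over the replicates, counting only replicates that sampled the bin.
#'
#' @param profiles list of `fe_profile` objects.
#' @return An `fe_profile` data.frame with columns `z`, `dg` (mean),
#'   `sd`, `n_rep` and `count` (replicates contributing); attribute
#'   `bin_width` as the inputs.
#' @export
replicate_statistics <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2)
    stop("need at least 2 profiles")
  bw <- vapply(profiles, function(p) attr(p, "bin_width"), numeric(1))
  if (any(abs(bw - bw[1]) > 1e-12))
    stop("profiles are on incompatible grids (bin widths differ)")
  bins <- lapply(profiles, function(p) round(p$z / bw[1] - 0.5))
  frac <- unlist(lapply(seq_along(profiles),
                        function(k) profiles[[k]]$z / bw[1] - 0.5 - bins[[k]]))
  if (any(abs(frac) > 1e-6))
    stop("profiles are on incompatible grids (bin origins differ)")
  all_bins <- sort(unique(unlist(bins)))
  acc <- matrix(NA_real_, length(all_bins), length(profiles))
  for (k in seq_along(profiles)) {
    pos <- match(bins[[k]], all_bins)
    acc[pos, k] <- profiles[[k]]$dg
  }
  n_rep <- rowSums(!is.na(acc))
  m <- rowMeans(acc, na.rm = TRUE)
  m[n_rep == 0] <- NA_real_
  sdv <- apply(acc, 1, function(r) stats::sd(r[!is.na(r)]))
  out <- data.frame(z = (all_bins + 0.5) * bw[1], dg = m, sd = sdv,
                    n_rep = n_rep, count = n_rep)
  attr(out, "bin_width") <- bw[1]
  attr(out, "z_ref") <- attr(profiles[[1]], "z_ref")
  attr(out, "reference") <- attr(profiles[[1]], "reference")
  class(out) <- c("fe_profile", "data.frame")
  out
}
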