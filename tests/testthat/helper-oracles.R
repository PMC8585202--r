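# Independent brute-force oracles, kept free of the package's compiled path.

.K <- physical_constants()

# pair energy in J, straight from the formula, no clamping
oracle_pair_energy <- function(mu_a, mu_b, sep_ang, eps_r) {
  r_m <- sqrt(sum(sep_ang^2)) * .K$angstrom
  sum(mu_a * mu_b) * .K$debye_to_si^2 / (4 * pi * .K$eps0 * eps_r * r_m^3)
}

# total energy by an explicit loop over sites
oracle_potential <- function(pos, mu_a, membrane, eps_r, r_min = 1) {
  s <- membrane$sites
  tot <- 0
  for (i in seq_len(nrow(s))) {
    sep <- pos - c(s$x[i], s$y[i], s$z[i])
    d <- sqrt(sum(sep^2))
    d <- max(d, r_min)
    tot <- tot + sum(c(s$mux[i], s$muy[i], s$muz[i]) * mu_a) *
      .K$debye_to_si^2 / (4 * pi * .K$eps0 * eps_r * (d * .K$angstrom)^3)
  }
  tot
}

# central-difference gradient of the potential (h in Angstrom)
oracle_force <- function(pos, mu_a, membrane, eps_r, h = 1e-4) {
  vapply(1:3, function(a) {
    dp <- dm <- pos
    dp[a] <- dp[a] + h
    dm[a] <- dm[a] - h
    -(oracle_potential(dp, mu_a, membrane, eps_r) -
        oracle_potential(dm, mu_a, membrane, eps_r)) /
      (2 * h * .K$angstrom)
  }, numeric(1))
}

# four equal dipoles at the corners of a square in the z = 0 plane,
# centred on (cx, cy)
square_membrane <- function(cx = 0, cy = 0, half = 5, dipole = c(0, 0, 3)) {
  make_toy_membrane(rbind(
    c(cx - half, cy - half, 0), c(cx + half, cy - half, 0),
    c(cx - half, cy + half, 0), c(cx + half, cy + half, 0)), dipole)
}

# a small profile object built by hand (bin width 0.2, already re-zeroed)
manual_profile <- function(z, dg, bin_width = 0.2) {
  out <- data.frame(z = z, dg = dg, count = rep(1L, length(z)))
  attr(out, "bin_width") <- bin_width
  attr(out, "z_ref") <- max(z)
  attr(out, "reference") <- "manual"
  class(out) <- c("fe_profile", "data.frame")
  out
}

kcal_per_mol <- function(joule_per_molecule)
  joule_per_molecule * .K$avogadro / .K$kcal
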