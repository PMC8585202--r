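#' Membrane box geometry
#'
#' Lateral box lengths and the distance from the bilayer center (z = 0) to
#' each leaflet's dipole plane. The two leaflet planes sit symmetrically at
#' +/- `half_thickness` by default.
#'
#' @param lx,ly lateral box lengths (Angstrom, > 0).
#' @param half_thickness distance from the bilayer center to each leaflet
#'   dipole plane (Angstrom, > 0; default 20, a typical phosphate-plane
#'   distance for POPC/POPG bilayers).
#' @return An object of class `membrane_geometry` with fields `lx`, `ly`,
#'   `half_thickness` and `leaflet_z` (the two plane offsets).
#' @export
membrane_geometry <- function(lx = 80, ly = 80, half_thickness = 20) {
  if (any(!is.finite(c(lx, ly, half_thickness))) ||
      any(c(lx, ly, half_thickness) <= 0))
    stop("lx, ly and half_thickness must be positive and finite")
  structure(list(lx = lx, ly = ly, half_thickness = half_thickness,
                 leaflet_z = c(half_thickness, -half_thickness)),
            class = "membrane_geometry")
}

#' Number of lipids per leaflet
#'
#' The lipid count is derived from the lateral box area and the area per
#' lipid: `floor(lx * ly / apl)` per leaflet, twice that for the whole
#' bilayer.
#'
#' @param geometry a [membrane_geometry()].
#' @param apl area per lipid (Angstrom^2, > 0).
#' @return Integer count per leaflet.
#' @examples
#' lipid_count(membrane_geometry(80, 80), apl = 64) # 100 per leaflet
#' @export
lipid_count <- function(geometry, apl) {
  stopifnot(inherits(geometry, "membrane_geometry"))
  if (!is.numeric(apl) || length(apl) != 1 || !is.finite(apl) || apl <= 0)
    stop("apl must be a single positive area in Angstrom^2")
  as.integer(floor(geometry$lx * geometry$ly / apl))
}

#' Draw lipid dipole vectors
#'
#' Each dipole component is drawn from a normal law with the lipid's
#' per-axis mean and standard deviation. For the lower leaflet the sampled
#' z component's sign is flipped so that a symmetric bilayer has
#' mirror-equivalent leaflets. Sampling uses R's global RNG stream; seed it
#' with [set.seed()] (or use [build_membrane()], which does).
#'
#' @param spec a [lipid_spec()].
#' @param n number of dipoles to draw.
#' @param leaflet `"upper"` or `"lower"`.
#' @param flip_lower_z logical, apply the lower-leaflet z sign flip
#'   (default TRUE).
#' @param truncate logical; if TRUE, redraw components falling outside
#'   mean +/- 1 SD (truncated-normal reading of the generation rule;
#'   default FALSE, plain normal law).
#' @return n x 3 numeric matrix of dipole vectors (Debye).
#' @export
sample_lipid_dipole <- function(spec, n = 1,
                                leaflet = c("upper", "lower"),
                                flip_lower_z = TRUE, truncate = FALSE) {
  stopifnot(inherits(spec, "lipid_spec"))
  leaflet <- match.arg(leaflet)
  mu <- vapply(1:3, function(a) {
    x <- stats::rnorm(n, spec$mean_dipole[a], spec$sd_dipole[a])
    if (truncate && spec$sd_dipole[a] > 0) {
      lo <- spec$mean_dipole[a] - spec$sd_dipole[a]
      hi <- spec$mean_dipole[a] + spec$sd_dipole[a]
      bad <- which(x < lo | x > hi)
      while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), spec$mean_dipole[a],
                               spec$sd_dipole[a])
        bad <- bad[x[bad] < lo | x[bad] > hi]
      }
    }
    x
  }, numeric(n))
  mu <- matrix(mu, nrow = n, ncol = 3)
  if (leaflet == "lower" && flip_lower_z) mu[, 3] <- -mu[, 3]
  mu
}

# Regular lateral grid with spacing sqrt(apl): nx columns per full row,
# remainder centred in a final partial row; the whole grid is centred in
# the box.
.leaflet_grid <- function(lx, ly, apl, n) {
  s <- sqrt(apl)
  nx <- max(1L, as.integer(floor(lx / s)))
  nfull <- n %/% nx
  rem <- n %% nx
  ny <- nfull + (rem > 0L)
  offx <- (lx - nx * s) / 2
  offy <- (ly - ny * s) / 2
  xs <- ys <- numeric(n)
  k <- 0L
  if (nfull > 0L) {
    ij <- expand.grid(i = seq_len(nx), j = seq_len(nfull))
    m <- nfull * nx
    xs[seq_len(m)] <- (ij$i - 0.5) * s + offx
    ys[seq_len(m)] <- (ij$j - 0.5) * s + offy
    k <- m
  }
  if (rem > 0L) {
    offr <- (lx - rem * s) / 2
    xs[k + seq_len(rem)] <- (seq_len(rem) - 0.5) * s + offr
    ys[k + seq_len(rem)] <- (nfull + 0.5) * s + offy
  }
  cbind(x = xs, y = ys)
}

#' Generate a random dipole-lattice membrane
#'
#' Lays `lipid_count(geometry, spec$apl)` dipole sites per leaflet on a
#' regular lateral grid with spacing `sqrt(apl)` on each leaflet plane and
#' draws every site's dipole vector from the lipid's normal law (see
#' [sample_lipid_dipole()]). The result is deterministic given
#' `(spec, geometry, seed)`; two seeds share identical site positions and
#' differ only in the dipoles.
#'
#' @param spec a [lipid_spec()] (or a preset name such as `"PC"`).
#' @param geometry a [membrane_geometry()].
#' @param seed integer seed for the dipole draws.
#' @param flip_lower_z logical, sign-flip the lower leaflet's z components
#'   (default TRUE).
#' @param truncate logical, truncate draws at mean +/- 1 SD (default FALSE).
#' @param eps_r_inside relative permittivity recorded for the membrane
#'   interior (default 4.0).
#' @param eta_inside viscosity recorded for the membrane interior
#'   (Pa s, default 0.934).
#' @return An object of class `membrane`: list with `sites` (data.frame
#'   `x, y, z, mux, muy, muz`; positions Angstrom, dipoles Debye),
#'   `geometry`, `lipid`, `seed`, `eps_r_inside`, `eta_inside`.
#' @examples
#' mem <- build_membrane(preset_lipid("PC"), membrane_geometry(80, 80),
#'                       seed = 7)
#' nrow(mem$sites) # 200
#' @export
build_membrane <- function(spec, geometry = membrane_geometry(), seed = 1,
                           flip_lower_z = TRUE, truncate = FALSE,
                           eps_r_inside = 4.0, eta_inside = 0.934) {
  if (is.character(spec)) spec <- preset_lipid(spec)
  stopifnot(inherits(spec, "lipid_spec"),
            inherits(geometry, "membrane_geometry"))
  n <- lipid_count(geometry, spec$apl)
  if (n < 1L)
    stop("box of ", geometry$lx, " x ", geometry$ly,
         " A with APL ", spec$apl, " A^2 holds zero lipids per leaflet")
  grid <- .leaflet_grid(geometry$lx, geometry$ly, spec$apl, n)
  h <- geometry$half_thickness
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  mu_up <- sample_lipid_dipole(spec, n, "upper", flip_lower_z, truncate)
  mu_lo <- sample_lipid_dipole(spec, n, "lower", flip_lower_z, truncate)
  sites <- data.frame(
    x = c(grid[, "x"], grid[, "x"]),
    y = c(grid[, "y"], grid[, "y"]),
    z = c(rep(h, n), rep(-h, n)),
    mux = c(mu_up[, 1], mu_lo[, 1]),
    muy = c(mu_up[, 2], mu_lo[, 2]),
    muz = c(mu_up[, 3], mu_lo[, 3])
  )
  structure(list(sites = sites, geometry = geometry, lipid = spec,
                 seed = as.integer(seed), eps_r_inside = eps_r_inside,
                 eta_inside = eta_inside),
            class = "membrane")
}

#' Deterministic toy membrane for tests and examples
#'
#' Builds a membrane object from explicit site positions and dipoles with
#' no randomness.
#'
#' @param positions n x 3 matrix of site positions (Angstrom).
#' @param dipole either a single length-3 dipole (Debye) shared by all
#'   sites, or an n x 3 matrix of per-site dipoles.
#' @param geometry a [membrane_geometry()]; defaults to an 80 x 80 box.
#' @return A `membrane` object (`seed = NA`).
#' @examples
#' make_toy_membrane(rbind(c(0, 0, 0)), c(0, 0, 1))
#' @export
make_toy_membrane <- function(positions, dipole,
                              geometry = membrane_geometry()) {
  positions <- rbind(positions)
  if (nrow(positions) < 1L) stop("at least one site position is required")
  if (ncol(positions) != 3) stop("positions must have three columns")
  if (is.null(dim(dipole))) {
    if (length(dipole) != 3) stop("shared dipole must be length 3")
    dipole <- matrix(dipole, nrow(positions), 3, byrow = TRUE)
  } else {
    dipole <- rbind(dipole)
    if (nrow(dipole) != nrow(positions))
      stop("positions and dipole have mismatched lengths")
  }
  sites <- data.frame(x = positions[, 1], y = positions[, 2],
                      z = positions[, 3], mux = dipole[, 1],
                      muy = dipole[, 2], muz = dipole[, 3])
  structure(list(sites = sites, geometry = geometry,
                 lipid = NULL, seed = NA_integer_,
                 eps_r_inside = 4.0, eta_inside = 0.934),
            class = "membrane")
}

#' @export
print.membrane <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("Dipole-lattice membrane: %d sites, box %.1f x %.1f A, leaflet planes at +/- %.1f A\n",
              nrow(x$sites), g$lx, g$ly, g$half_thickness))
  if (!is.null(x$lipid)) cat("  lipid:", x$lipid$name, " seed:", x$seed, "\n")
  invisible(x)
}
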