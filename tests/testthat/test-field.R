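test_that("pair energy matches the closed form and its scalings", {
  # null dipole
  expect_identical(dipole_pair_energy(c(0, 0, 0), c(1, -2, 3), c(0, 0, 5),
                                      88), 0)
  # two aligned 1 D dipoles, 5 A apart, in water: hand evaluation
  e <- dipole_pair_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 5), 88)
  expect_equal(e, oracle_pair_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 5),
                                     88))
  expect_equal(e, 9.09e-24, tolerance = 1e-3)
  expect_equal(kcal_per_mol(e), 1.31e-3, tolerance = 1e-2)
  # exact 1/r^3: doubling the distance divides by 8
  e2 <- dipole_pair_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 10), 88)
  expect_equal(e / e2, 8, tolerance = 1e-12)
  # exact 1/eps_r: membrane value is 22x the water value
  em <- dipole_pair_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 5), 4)
  expect_equal(em / e, 22, tolerance = 1e-12)
  # singularity guard
  expect_error(dipole_pair_energy(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0), 88),
               "zero separation")
})

test_that("total potential energy is the site sum and is linear", {
  env <- environment_params()
  pos <- c(1, 2, 45)
  mu <- c(0.7, 2.1, -0.5)
  # zero agent dipole
  m1 <- make_toy_membrane(rbind(c(0, 0, 20), c(3, 1, -20)), c(1, 2, 3))
  expect_identical(potential_energy(pos, c(0, 0, 0), m1, env), 0)
  # two identical equidistant sites = 2x one site
  m2 <- make_toy_membrane(rbind(c(5, 2, 40), c(-3, 2, 40)), c(0, 1, 1))
  ma <- make_toy_membrane(rbind(c(5, 2, 40)), c(0, 1, 1))
  expect_equal(potential_energy(c(1, 2, 40), mu, m2, env),
               2 * potential_energy(c(1, 2, 40), mu, ma, env),
               tolerance = 1e-14)
  # linearity in the agent dipole
  e1 <- potential_energy(pos, mu, m1, env)
  e3 <- potential_energy(pos, 3 * mu, m1, env)
  expect_equal(e3, 3 * e1, tolerance = 1e-14)
})

test_that("compiled field sum matches a brute-force loop on a full membrane", {
  env <- environment_params()
  mem <- build_membrane("PC", membrane_geometry(80, 80), seed = 11)
  mu <- preset_agent("OCT")$dipole
  for (pos in list(c(40, 40, 45), c(37, 42.5, 19), c(40.1, 39.7, 2))) {
    eps <- dielectric_at(pos[3], mem, env)
    expect_equal(potential_energy(pos, mu, mem, env),
                 oracle_potential(pos, mu, mem, eps),
                 tolerance = 1e-12)
  }
})

test_that("analytic force matches the numeric gradient on random instances", {
  set.seed(99)
  env <- environment_params()
  for (trial in 1:50) {
    n <- 20
    m <- make_toy_membrane(
      cbind(runif(n, -20, 20), runif(n, -20, 20), runif(n, -20, 20)),
      cbind(rnorm(n, 0, 5), rnorm(n, 0, 5), rnorm(n, 0, 5)))
    mu <- rnorm(3, 0, 3)
    pos <- runif(3, 25, 40) # keep clear of sites and the clamp
    f <- field_force(pos, mu, m, env)
    fo <- oracle_force(pos, mu, m, dielectric_at(pos[3], m, env))
    expect_lt(sqrt(sum((f - fo)^2)) / sqrt(sum(fo^2)), 1e-6)
  }
})

test_that("force respects symmetry and points down the energy gradient", {
  env <- environment_params()
  sq <- square_membrane(cx = 0, cy = 0, half = 5, dipole = c(0, 0, 3))
  f <- field_force(c(0, 0, 30), c(0, 0, 2), sq, env)
  expect_lt(max(abs(f[1:2])), 1e-15 * abs(f[3]))
  # mu_i . mu > 0: repulsive, force away from the site
  m1 <- make_toy_membrane(rbind(c(0, 0, 30)), c(0, 0, 1))
  f1 <- field_force(c(0, 0, 40), c(0, 0, 1), m1, env)
  expect_gt(f1[3], 0)
  # attractive pairing pulls toward the site
  f2 <- field_force(c(0, 0, 40), c(0, 0, -1), m1, env)
  expect_lt(f2[3], 0)
})

test_that("energy and force are translation invariant", {
  env <- environment_params()
  set.seed(5)
  n <- 12
  P <- cbind(runif(n, -9, 9), runif(n, -9, 9), runif(n, -9, 9))
  M <- cbind(rnorm(n), rnorm(n), rnorm(n))
  mu <- c(1.3, -0.4, 2.2)
  pos <- c(3, -2, 28)
  shift <- c(11.5, -7.25, 0) # lateral shift keeps the dielectric region
  e0 <- potential_energy(pos, mu, make_toy_membrane(P, M), env)
  f0 <- field_force(pos, mu, make_toy_membrane(P, M), env)
  Ps <- sweep(P, 2, -shift)
  e1 <- potential_energy(pos + shift, mu, make_toy_membrane(Ps, M), env)
  f1 <- field_force(pos + shift, mu, make_toy_membrane(Ps, M), env)
  expect_equal(e1, e0, tolerance = 1e-13)
  expect_equal(f1, f0, tolerance = 1e-13)
})

test_that("close approaches are clamped with a warning", {
  env <- environment_params()
  m <- make_toy_membrane(rbind(c(0, 0, 30)), c(0, 0, 1))
  expect_warning(e <- potential_energy(c(0, 0, 30.5), c(0, 0, 1), m, env),
                 "clamped")
  # clamped to the 1 A value
  e1 <- suppressWarnings(
    potential_energy(c(0, 0, 31), c(0, 0, 1), m, env))
  expect_equal(e, e1, tolerance = 1e-14)
})

test_that("region functions switch at |z| = half_thickness, boundary to water", {
  env <- environment_params()
  mem <- make_toy_membrane(rbind(c(0, 0, 20)), c(0, 0, 1),
                           membrane_geometry(80, 80, 20))
  expect_identical(dielectric_at(45, mem, env), 88.0)
  expect_identical(dielectric_at(0, mem, env), 4.0)
  expect_identical(dielectric_at(20, mem, env), 88.0)
  expect_identical(dielectric_at(-20, mem, env), 88.0)
  expect_identical(dielectric_at(19.999, mem, env), 4.0)
  expect_identical(viscosity_at(45, mem, env), 0.89e-3)
  expect_identical(viscosity_at(0, mem, env), 0.934)
  expect_identical(viscosity_at(20, mem, env), 0.89e-3)
  # piecewise constant: single threshold
  z <- seq(-45, 45, by = 0.5)
  v <- viscosity_at(z, mem, env)
  expect_identical(sort(unique(v)), c(0.89e-3, 0.934))
  expect_identical(v == 0.934, abs(z) < 20)
  # the smooth variant tends to the sharp limits away from the boundary
  expect_equal(dielectric_at(45, mem, env, boundary = "smooth"), 88,
               tolerance = 1e-6)
  expect_equal(dielectric_at(0, mem, env, boundary = "smooth"), 4,
               tolerance = 1e-6)
})
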