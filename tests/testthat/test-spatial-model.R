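test_that("pressure solve handles the trivial and linear limits", {
  g <- coarse_grid()
  sp <- spatial_params(0.8, 1e-3)
  # no tumour: homeostatic pressure everywhere
  Pi0 <- solve_pressure(matrix(0, g$n, g$n), sp, g)
  expect_true(all(Pi0 == 0))
  # pi0 -> infinity: the linear Poisson problem with source gamma0 * P
  P <- foci_field(focus_spec(5, 5, 0.5), g)
  sp_lin <- spatial_params(0.8, 1e9)
  Pi <- solve_pressure(P, sp_lin, g)
  Pi_direct <- matrix(as.vector(Matrix::solve(g$A, 0.8 * as.vector(P))),
                      g$n, g$n)
  expect_equal(max(abs(Pi - Pi_direct)) / max(Pi_direct), 0, tolerance = 1e-8)
  # pressure is non-negative for a non-negative source
  Pi_nl <- solve_pressure(P, sp, g)
  expect_true(min(Pi_nl) >= -1e-12)
})

test_that("pressure inherits the radial symmetry of the density", {
  g <- coarse_grid()
  P <- foci_field(focus_spec(5, 5, 0.8), g)
  Pi <- solve_pressure(P, spatial_params(0.9, 8e-4), g)
  flip <- Pi[g$n:1, ]
  expect_lt(max(abs(Pi - flip)) / diff(range(Pi)), 1e-6)
  expect_lt(max(abs(Pi - t(Pi))) / diff(range(Pi)), 1e-6)
})

test_that("newton and damped fixed-point pressure solvers agree", {
  g <- coarse_grid(48)
  P <- foci_field(focus_spec(5, 5, 0.3), g)
  sp <- spatial_params(0.7, 2e-3)
  Pi_n <- solve_pressure(P, sp, g, method = "newton")
  Pi_p <- solve_pressure(P, sp, g, method = "picard", maxit = 500)
  expect_equal(max(abs(Pi_n - Pi_p)) / max(Pi_n), 0, tolerance = 1e-6)
  # non-convergence is an error carrying the iteration trace
  err <- tryCatch(solve_pressure(P, sp, g, method = "picard", maxit = 3),
                  error = function(e) e)
  expect_s3_class(err, "pressure_no_convergence")
  expect_length(err$trace, 3)
})

test_that("velocity is Darcy-consistent: divergence reproduces the source at order 2", {
  losses <- vapply(c(48, 96), function(n) {
    g <- grid2d(n)
    # smooth density so the refinement study sees the asymptotic order
    D2 <- outer((g$x - g$L / 2)^2, (g$x - g$L / 2)^2, "+")
    P <- 0.8 * exp(-D2 / (2 * 0.08^2))
    sp <- spatial_params(0.8, 1e9)          # linear regime
    Pi <- solve_pressure(P, sp, g)
    v <- velocity_field(Pi, g)
    i <- 2:(g$n - 1)
    div <- (v$vx[i + 1, i] - v$vx[i - 1, i] + v$vy[i, i + 1] - v$vy[i, i - 1]) /
      (2 * g$h)
    # compare away from the boundary, where the source is supported
    core <- abs(g$x[i] - g$L / 2) < 0.25
    sqrt(mean((div - 0.8 * P[i, i])[core, core]^2))
  }, numeric(1))
  order <- log2(losses[1] / losses[2])
  expect_gt(order, 1.6)
  # constant pressure implies zero velocity
  g <- coarse_grid(32)
  v0 <- velocity_field(matrix(0, 32, 32), g)
  expect_true(all(v0$vx == 0) && all(v0$vy == 0))
})

test_that("velocity points outward from a single focus", {
  g <- coarse_grid()
  P <- foci_field(focus_spec(5, 5, 0.5), g)
  Pi <- solve_pressure(P, spatial_params(0.8, 1e-3), g)
  v <- velocity_field(Pi, g)
  c0 <- g$L / 2
  xs <- outer(g$x - c0, rep(1, g$n))
  ys <- outer(rep(1, g$n), g$x - c0)
  radial <- v$vx * xs + v$vy * ys
  outside_core <- sqrt(xs^2 + ys^2) > 0.02
  expect_true(all(radial[outside_core] >= -1e-9 * max(abs(radial))))
})

test_that("without proliferation the field is static and mass is conserved", {
  g <- coarse_grid(48)
  sp <- spatial_params(gamma0 = 0, pi0 = 1e-3)
  P0 <- foci_field(focus_spec(5, 5, 0.4), g)
  state <- spatial_state(P0)
  for (i in 1:50) state <- advance(state, 0.1, sp, g)
  expect_equal(state$P, P0, tolerance = 1e-12)
  expect_equal(tumour_mass(state$P, g), tumour_mass(P0, g),
               tolerance = 1e-10)
})

test_that("with pressure inhibition switched off the mass grows exponentially", {
  g <- grid2d(128)
  gamma0 <- 0.8
  sp <- spatial_params(gamma0, 1e9)         # gamma(Pi) ~ gamma0 everywhere
  # an unsaturated start: the density approaches 1 only logistically, so
  # the saturation cap never engages over the 7-day window and the mass
  # identity dM/dt = gamma0 * M is tested cleanly
  P0 <- 0.25 * foci_field(focus_spec(5, 5, pi * 0.5^2), g)
  sim <- suppressWarnings(simulate_spatial(P0, sp, g, 7, record_times = 7))
  ratio <- utils::tail(sim$series$mass_mm2, 1) / sim$series$mass_mm2[1]
  expect_equal(ratio, exp(gamma0 * 7), tolerance = 0.01)
  expect_lt(max(sim$P), 1 + 1e-12)
})

test_that("mirror symmetry of twin foci is preserved by the scheme", {
  g <- coarse_grid(64)
  two <- rbind(focus_spec(5 - 0.5, 5, 0.3), focus_spec(5 + 0.5, 5, 0.3))
  P0 <- foci_field(two, g)
  expect_equal(P0, P0[g$n:1, ])             # initial condition is symmetric
  sim <- suppressWarnings(
    simulate_spatial(P0, spatial_params(0.9, 1e-3), g, 2, record_times = 2))
  expect_lt(max(abs(sim$P - sim$P[g$n:1, ])), 1e-8)
})

test_that("density stays within physical bounds after clipping", {
  g <- coarse_grid(64)
  sim <- suppressWarnings(simulate_spatial(
    foci_field(focus_spec(5, 5, 0.46), g),
    spatial_params(0.78, 0.0026), g, 3, record_times = 3))
  expect_true(min(sim$P) >= 0 && max(sim$P) <= 1)
  # WENO fronts overshoot slightly before clipping; excursions stay small
  expect_lt(sim$saturation_violation, 5e-3)
})

test_that("the mass budget balances growth against the integral source", {
  g <- grid2d(128)
  sp <- spatial_params(0.8, 1.5e-3)
  # partially saturated field, resolved well enough that the front band is
  # a small mass fraction
  state <- spatial_state(0.5 * foci_field(focus_spec(5, 5, pi * 0.6^2), g))
  state$Pi <- solve_pressure(state$P, sp, g)
  source_of <- function(state) {
    gam <- sp$gamma0 * exp(-state$Pi / sp$pi0)
    sum(gam * state$P) * g$h^2 * 100               # mm^2 / day
  }
  for (i in 1:10) {
    m0 <- tumour_mass(state$P, g)
    s0 <- source_of(state)
    dt <- 0.05
    state <- advance(state, dt, sp, g)
    dm <- tumour_mass(state$P, g) - m0
    expect_equal(dm / dt, (s0 + source_of(state)) / 2, tolerance = 0.01)
  }
})

test_that("final mass is grid-converged at the study resolution", {
  sp <- spatial_params(0.84, 1.56e-3)
  masses <- vapply(c(128, 256), function(n) {
    g <- grid2d(n)
    sim <- suppressWarnings(simulate_spatial(
      foci_field(focus_spec(5, 5, 0.46), g), sp, g, 7, record_times = 7))
    utils::tail(sim$series$mass_mm2, 1)
  }, numeric(1))
  expect_lt(abs(diff(masses)) / masses[2], 0.02)
})

test_that("tumour mass integrates indicator discs and is additive", {
  g <- grid2d(128)
  expect_identical(tumour_mass(matrix(0, g$n, g$n), g), 0)
  r <- 0.6
  one <- foci_field(focus_spec(5, 5, pi * r^2), g)
  expect_equal(tumour_mass(one, g), pi * r^2, tolerance = 0.02)
  two <- foci_field(rbind(focus_spec(3, 3, 0.4), focus_spec(7, 7, 0.3)), g)
  expect_equal(tumour_mass(two, g), 0.7, tolerance = 0.02)
})

test_that("2D-to-3D conversion assumes spherical symmetry", {
  expect_equal(area_to_volume_3d(pi), 4 * pi / 3)
  expect_identical(area_to_volume_3d(0), 0)
  a <- seq(0.1, 5, length.out = 20)
  v <- area_to_volume_3d(a)
  expect_true(all(diff(v) > 0))
  expect_equal(v, (4 / (3 * sqrt(pi))) * a^1.5)
})

test_that("focus placement honours spacing, margins and determinism", {
  g <- grid2d(64)
  f1 <- place_foci(1, 0.05, g, seed = 5)
  expect_identical(nrow(f1), 1L)
  f <- place_foci(200, 0.03, g, seed = 7)
  dmin <- min(stats::dist(cbind(f$x_mm, f$y_mm)))
  expect_gte(dmin, 0.03)
  expect_identical(f, place_foci(200, 0.03, g, seed = 7))
  expect_false(identical(f, place_foci(200, 0.03, g, seed = 8)))
  # infeasible packing fails with guidance
  expect_error(place_foci(500, 4, g, seed = 1), "domain")
})
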