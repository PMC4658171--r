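test_that("emission rate follows the power law in cells", {
  d <- fitted_dissemination()
  u <- fitted_units()
  expect_identical(emission_rate(0, d, u), 0)
  # 1e5 cells at mu = 9.72e-6 /cell/day emit 0.972 metastases/day
  vp <- 1e5 * u$signal_per_cell
  expect_equal(emission_rate(vp, d, u), 0.972, tolerance = 1e-12)
  expect_equal(emission_rate(2 * vp, d, u), 2 * emission_rate(vp, d, u))
  expect_error(dissemination_params(mu = -1))
  expect_error(dissemination_params(gamma_d = 2), "1.5")
})

test_that("FFT burden path agrees with adaptive quadrature", {
  set.seed(21)
  u <- fitted_units()
  for (rep in 1:50) {
    g <- random_growth_params()
    d <- dissemination_params(mu = 10^stats::runif(1, -6, -4.5),
                              gamma_d = stats::runif(1, 0.5, 1.2))
    t <- stats::runif(1, 5, 26)
    m_fft <- total_burden(t, g, d, u, method = "fft", dt = 0.02)
    m_q <- total_burden(t, g, d, u, method = "quadrature")
    expect_equal(m_fft, m_q, tolerance = 1e-4)
  }
})

test_that("burden is zero at t = 0, nondecreasing and grid-guarded", {
  g <- fitted_growth(); d <- fitted_dissemination(); u <- fitted_units()
  expect_identical(total_burden(0, g, d, u), 0)
  tt <- seq(0, 26, by = 0.5)
  m <- total_burden(tt, g, d, u)
  expect_true(all(diff(m) >= 0))
  # early-time convexity (positive, increasing integrand)
  early <- m[tt <= 15]
  expect_true(all(diff(diff(early)) > -1e-12))
  expect_error(total_burden(10, g, d, u, dt = 1), "too coarse")
})

test_that("density, burden and count satisfy the conservation identities", {
  set.seed(22)
  u <- fitted_units()
  for (rep in 1:20) {
    g <- random_growth_params()
    d <- dissemination_params(mu = 10^stats::runif(1, -6, -5))
    t <- stats::runif(1, 10, 26)
    # integrate the density numerically on a log-size grid
    lv <- seq(log(g$v0), log(volume_at(t, g$v0, g)) - 1e-9,
              length.out = 4000)
    v <- exp(lv)
    rho <- size_density(t, v, g, d, u)
    burden <- sum(0.5 * (rho[-1] * v[-1]^2 + rho[-length(v)] * v[-length(v)]^2) *
                  diff(lv))                       # int v rho dv, dv = v dlog v
    count <- sum(0.5 * (rho[-1] * v[-1] + rho[-length(v)] * v[-length(v)]) *
                 diff(lv))
    expect_equal(burden, total_burden(t, g, d, u, method = "quadrature"),
                 tolerance = 1e-3)
    expect_equal(count, count_above(t, g$v0, g, d, u), tolerance = 1e-3)
  }
})

test_that("density vanishes for lesions older than the system", {
  g <- fitted_growth(); d <- fitted_dissemination(); u <- fitted_units()
  t <- 10
  v_young <- volume_at(t - 1, g$v0, g)       # reachable
  v_old <- volume_at(t + 2, g$v0, g)         # would need more time than t
  expect_gt(size_density(t, v_young, g, d, u), 0)
  expect_identical(size_density(t, v_old, g, d, u), 0)
})

test_that("count_above is monotone and consistent at its limits", {
  g <- fitted_growth(); d <- fitted_dissemination(); u <- fitted_units()
  t <- 26
  expect_equal(count_above(t, g$v0, g, d, u),
               cumulative_emission(t, g, d, u))
  vbars <- exp(seq(log(g$v0), log(g$v_max * 0.99), length.out = 20))
  counts <- vapply(vbars, function(vb) count_above(t, vb, g, d, u), numeric(1))
  expect_true(all(diff(counts) <= 1e-9))
  expect_identical(count_above(t, g$v_max, g, d, u), 0)
})

test_that("deterministic largest-lesion convention matches its definition", {
  g <- fitted_growth(); d <- fitted_dissemination(); u <- fitted_units()
  # before the first whole emission there is no largest lesion
  expect_identical(largest_size_deterministic(0.05, g, d, u), 0)
  t <- 26
  s1 <- stats::uniroot(function(s) cumulative_emission(s, g, d, u) - 1,
                       c(0, t))$root
  expect_equal(largest_size_deterministic(t, g, d, u),
               signal_to_mm3(volume_at(t - s1, g$v0, g), u),
               tolerance = 1e-6)
})

test_that("the Poisson simulator is an unbiased realisation of the density", {
  g <- fitted_growth(); u <- fitted_units()
  d <- dissemination_params(mu = 9.72e-7)      # scaled down for fast replicates
  t_end <- 15
  expected <- count_above(t_end, g$v0, g, d, u)
  set.seed(23)
  counts <- vapply(1:10000, function(i)
    nrow(simulate_animal(g, d, t_end, units = u)), numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
  # deterministic under a fixed seed, empty under mu = 0
  a <- simulate_animal(g, d, t_end, seed = 99, units = u)
  b <- simulate_animal(g, d, t_end, seed = 99, units = u)
  expect_identical(a, b)
  expect_identical(nrow(simulate_animal(g, dissemination_params(mu = 0),
                                        t_end, seed = 1, units = u)), 0L)
  expect_error(simulate_animal(g, d, t_end, seed = "x"), "seed")
})

test_that("deterministic and stochastic largest-lesion conventions agree in order of magnitude", {
  g <- fitted_growth(); d <- fitted_dissemination(); u <- fitted_units()
  det <- largest_size_deterministic(26, g, d, u)
  set.seed(24)
  largest <- vapply(1:2000, function(i) {
    m <- simulate_animal(g, d, 26, units = u)
    if (nrow(m)) max(m$size_mm3) else 0
  }, numeric(1))
  expect_gt(det / mean(largest), 0.3)
  expect_lt(det / mean(largest), 3)
})

test_that("population sampling reproduces the stated median/CV mapping", {
  pop <- population_dist()
  draws <- sample_population(1e5, pop, seed = 31)
  expect_true(all(draws$alpha > 0 & draws$beta > 0 & draws$mu > 0))
  expect_identical(unique(draws$lambda), pop$lambda)
  for (k in c("alpha", "beta", "mu")) {
    expect_equal(stats::median(draws[[k]]), pop$medians[[k]],
                 tolerance = 0.02)
    cv_emp <- 100 * stats::sd(draws[[k]]) / stats::median(draws[[k]])
    expect_equal(cv_emp, pop$cv_pct[[k]], tolerance = 0.02)
  }
  # zero CV collapses to the median
  pop0 <- population_dist(cv_pct = c(alpha = 0, beta = 0, mu = 0))
  d0 <- sample_population(5, pop0, seed = 1)
  expect_equal(d0$alpha, rep(pop0$medians[["alpha"]], 5))
})

test_that("size-distribution summaries match a brute-force filter", {
  empty <- summarize_distribution(numeric(0))
  expect_identical(empty$n_total, 0L)
  expect_identical(empty$largest, 0)
  one <- summarize_distribution(0.06, threshold = 0.05)
  expect_identical(one$n_macro, 1L)
  expect_equal(one$largest, 0.06)
  expect_equal(one$macro_burden, 0.06)
  set.seed(32)
  v <- stats::rlnorm(500, log(0.03), 1)
  s <- summarize_distribution(v, threshold = 0.05)
  expect_identical(s$n_macro, length(v[v >= 0.05]))
  expect_equal(s$macro_burden, sum(v[v >= 0.05]))
  expect_equal(s$largest, max(v[v >= 0.05]))
  expect_equal(s$total_burden, sum(v))
  expect_true(s$n_macro <= s$n_total && s$macro_burden <= s$total_burden)
})

test_that("largest-lesion z-test is calibrated and behaves at its limits", {
  set.seed(33)
  sim <- stats::rnorm(2000, 1, 0.3)
  pvals <- vapply(1:400, function(i)
    largest_z_test(sample(sim, 25, replace = TRUE), sim), numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(largest_z_test(rep(10, 20), sim), 1e-5)
  expect_identical(largest_z_test(rep(2, 5), rep(2, 50)), 0.5)
  expect_error(largest_z_test(1, stats::rnorm(10)), "30")
})
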