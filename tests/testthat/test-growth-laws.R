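test_that("growth rate is the continuous minimum of the two branches", {
  p <- fitted_growth()
  # both branches agree at the switch size, to machine precision
  expect_equal(p$lambda * p$v_star,
               (p$alpha - p$beta * log(p$v_star)) * p$v_star,
               tolerance = 1e-12)
  expect_equal(growth_rate(p$v_star, p), p$lambda * p$v_star,
               tolerance = 1e-12)
  # zero growth at the carrying capacity
  expect_equal(growth_rate(exp(p$alpha / p$beta), p), 0, tolerance = 1e-12)
  # branchwise evaluation on a fine size grid is the oracle
  v <- exp(seq(log(p$v0), log(p$v_max * 0.999), length.out = 2000))
  expect_equal(growth_rate(v, p),
               pmin(p$lambda * v, (p$alpha - p$beta * log(v)) * v))
  # exponential branch below the switch, Gompertz branch above
  expect_equal(growth_rate(p$v_star / 2, p), p$lambda * p$v_star / 2)
  vg <- p$v_star * 2
  expect_equal(growth_rate(vg, p), (p$alpha - p$beta * log(vg)) * vg)
  expect_error(growth_rate(-1, p), "positive")
  expect_error(growth_rate(0, p), "positive")
})

test_that("closed-form trajectory matches an adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(11)
  for (rep in 1:20) {
    p <- random_growth_params()
    v_init <- exp(stats::runif(1, log(p$v0), log(p$v_max * 0.5)))
    times <- sort(stats::runif(5, 0, 40))
    ode <- deSolve::ode(y = c(v = v_init), times = c(0, times),
                        func = function(t, y, parms)
                          list(growth_rate(y, p)),
                        rtol = 1e-10, atol = 1e-14)
    expect_equal(volume_at(times, v_init, p), unname(ode[-1, "v"]),
                 tolerance = 1e-6)
  }
})

test_that("trajectory identity, monotonicity and asymptote hold", {
  p <- fitted_growth()
  expect_identical(volume_at(0, 0.37, p), 0.37)
  tt <- seq(0, 120, by = 0.5)
  v <- volume_at(tt, p$v0, p)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= exp(p$alpha / p$beta) * (1 + 1e-12)))
  expect_equal(volume_at(5000, p$v0, p), exp(p$alpha / p$beta),
               tolerance = 1e-8)
  expect_error(volume_at(-1, 1, p), "non-negative")
})

test_that("volume_at is a semigroup in time", {
  set.seed(12)
  for (rep in 1:10) {
    p <- random_growth_params()
    v <- exp(stats::runif(1, log(p$v0), log(p$v_max * 0.3)))
    s <- stats::runif(1, 0, 20); t <- stats::runif(1, 0, 20)
    expect_equal(volume_at(s + t, v, p),
                 volume_at(t, volume_at(s, v, p), p),
                 tolerance = 1e-9)
  }
})

test_that("time_to_reach inverts the trajectory", {
  set.seed(13)
  p <- fitted_growth()
  expect_identical(time_to_reach(0.5, 0.5, p), 0)
  for (rep in 1:100) {
    pr <- random_growth_params()
    v_init <- exp(stats::runif(1, log(pr$v0), log(pr$v_max * 0.2)))
    v_target <- exp(stats::runif(1, log(v_init), log(pr$v_max * 0.99)))
    tt <- time_to_reach(v_target, v_init, pr)
    expect_equal(volume_at(tt, v_init, pr), v_target, tolerance = 1e-9)
  }
  # strictly increasing in the target size
  targets <- exp(seq(log(p$v0), log(p$v_max * 0.99), length.out = 50))
  expect_true(all(diff(time_to_reach(targets, p$v0, p)) > 0))
  expect_error(time_to_reach(p$v_max, p$v0, p), "unreachable")
})

test_that("the law degenerates to pure exponential growth as beta -> 0", {
  p <- gomp_exp_params(lambda = 0.7, alpha = 0.4, beta = 1e-6,
                       v_inj = 1, v0 = 1e-5)
  tt <- c(1, 5, 20)
  expect_equal(volume_at(tt, 0.01, p), 0.01 * exp(0.4 * tt),
               tolerance = 1e-3)
})

test_that("required doubling time follows the closed form", {
  expect_equal(required_doubling_time(1, 2, 1), 24)
  expect_equal(required_doubling_time(1e-6, 0.022, 5),
               5 * 24 * log(2) / log(0.022 / 1e-6))
  expect_error(required_doubling_time(2, 1, 5))
  expect_error(required_doubling_time(1, 2, -1))
})

test_that("unit conversions are linear and invertible", {
  u <- fitted_units()
  v <- c(1e-5, 0.3, 51)
  expect_equal(mm3_to_signal(signal_to_mm3(v, u), u), v)
  expect_equal(signal_to_cells(7.96e-6, u), 1)
  expect_equal(signal_to_mm3(7.96e-6, u), 1e-6)
  expect_error(volume_units(-1, 1), "positive")
})
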