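make_cohort <- function(noise = 0, cv = c(alpha = 0, beta = 0, mu = 0),
                        n = 31, seed = 101) {
  design <- cohort_design(n_animals = n, noise_sd_log = noise)
  generate_cohort(truth = population_dist(cv_pct = cv), design = design,
                  seed = seed)
}

test_that("preprocessing applies the early-lung and outlier rules idempotently", {
  raw <- data.frame(animal_id = sprintf("a%d", 1:6),
                    day = c(8, 8, 12, 25, 14, 9),
                    organ = c("kidney", "lungs", "lungs", "lungs", "kidney",
                              "lungs"),
                    signal = c(0.5, 0.001, 2, 0.002, 1.2, 0.0015),
                    flagged = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- preprocess_cohort(raw)
  # lung rows before day 10 dropped, kidney rows kept regardless of day
  expect_true(all(out$day >= 10 | out$organ == "kidney"))
  expect_true("a1" %in% out$animal_id)       # kidney at day 8 kept
  expect_false(any(out$flagged))             # flagged day-25 row removed
  expect_identical(nrow(out), 3L)
  expect_identical(preprocess_cohort(out), out)
  expect_error(preprocess_cohort(data.frame(animal_id = 1, day = 1,
                                            organ = "liver", signal = 1)),
               "organ")
})

test_that("primary-tumour fit recovers the inoculum and growth parameters", {
  truth <- gomp_exp_params()
  days <- c(3, 5, 8, 10, 12, 14, 17, 20, 23, 26)
  kidney <- data.frame(animal_id = seq_along(days), day = days,
                       organ = "kidney",
                       signal = volume_at(days, truth$v_inj, truth))
  fit <- fit_primary_vinj(kidney)
  expect_equal(fit$v_inj, truth$v_inj, tolerance = 0.01)
  expect_equal(fit$alpha, truth$alpha, tolerance = 0.01)
  expect_equal(fit$beta, truth$beta, tolerance = 0.01)
  # one-cell signal by proportionality with the 1e5 injected cells
  expect_equal(fit$v0, truth$v_inj / 1e5, tolerance = 0.01)
  # row order is irrelevant
  fit2 <- fit_primary_vinj(kidney[sample(nrow(kidney)), ])
  expect_equal(fit2$v_inj, fit$v_inj, tolerance = 1e-6)
  expect_error(fit_primary_vinj(kidney[1:3, ]), "under-determined")
})

test_that("pooled joint fit is exact without noise and scales with mu", {
  syn <- make_cohort(noise = 0)
  cohort <- preprocess_cohort(syn$cohort)
  truth_med <- attr(syn$truth, "medians")
  fit <- fit_joint(cohort, v0 = attr(syn$truth, "v0"), mode = "pooled")
  expect_true(fit$converged)
  est <- fit$estimates
  expect_equal(est$median[est$parameter == "alpha"], truth_med[["alpha"]],
               tolerance = 0.01)
  expect_equal(est$median[est$parameter == "beta"], truth_med[["beta"]],
               tolerance = 0.01)
  expect_equal(est$median[est$parameter == "mu"], truth_med[["mu"]],
               tolerance = 0.01)
  # doubling mu in the generator doubles the fitted mu
  syn2 <- generate_cohort(
    truth = population_dist(medians = c(alpha = 0.417, beta = 0.106,
                                        mu = 2 * 9.72e-6),
                            cv_pct = c(alpha = 0, beta = 0, mu = 0)),
    design = cohort_design(noise_sd_log = 0), seed = 101)
  fit2 <- fit_joint(preprocess_cohort(syn2$cohort),
                    v0 = attr(syn2$truth, "v0"), mode = "pooled")
  expect_equal(fit2$estimates$median[3] / est$median[3], 2, tolerance = 0.02)
})

test_that("mixed-effects fit recovers a realistic synthetic population", {
  syn <- make_cohort(noise = 0.3, cv = c(alpha = 41, beta = 45.1, mu = 21.7),
                     seed = 103)
  cohort <- preprocess_cohort(syn$cohort)
  # the recovery contract reads the truth from the sidecar, not from
  # hard-coded numbers
  sidecar <- tempfile(fileext = ".json")
  write_sidecar_truth(syn$truth, sidecar)
  truth <- read_sidecar_truth(sidecar)
  fit <- fit_joint(cohort, v0 = truth$v0, mode = "mixed", max_iter = 20)
  est <- fit$estimates
  for (k in c("alpha", "beta", "mu")) {
    expect_equal(est$median[est$parameter == k], truth$medians[[k]],
                 tolerance = 0.25)
  }
  # spread estimates: right order against the realised per-animal spread,
  # and within a factor two of it
  emp_cv <- vapply(c("alpha", "beta", "mu"), function(k) {
    x <- truth$data[[k]]
    100 * stats::sd(x) / stats::median(x)
  }, numeric(1))
  est_cv <- est$cv_pct
  names(est_cv) <- est$parameter
  expect_lt(est_cv[["mu"]], min(est_cv[["alpha"]], est_cv[["beta"]]))
  for (k in c("alpha", "beta", "mu"))
    expect_lt(abs(log(est_cv[[k]] / emp_cv[[k]])), log(2))
  # the EM objective decreases monotonically
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
})
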