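## Reproducible experiment drivers binding the model components together.
## Each driver is deterministic given its seed and returns plain data frames
## ready to be written as CSV/JSON by the analysis scripts.

#' Standard-theory prediction of the macro-metastasis size distribution
#'
#' Samples `n_animals` virtual animals from the population distribution,
#' simulates each animal's metastases with the inhomogeneous-Poisson
#' emission process and deterministic Gomp-Exp growth, and summarises the
#' size distribution at each requested day (count of visible lesions,
#' macro burden, largest lesion, total burden).
#'
#' @param n_animals Number of simulated animals (1000 reproduces the
#'   reference simulation size).
#' @param days Observation days.
#' @param pop A [population_dist()] object.
#' @param threshold Visibility threshold, mm^3.
#' @param seed Master seed; per-animal streams are spawned from it.
#' @return A list with `summary` (per-day mean and sd of each metric),
#'   `per_animal` (long data frame of per-animal metrics) and the inputs.
#' @export
run_standard_theory_prediction <- function(n_animals = 1000,
                                           days = c(19, 21, 24, 26),
                                           pop = population_dist(),
                                           threshold = 0.05, seed = NULL) {
  pars <- sample_population(n_animals, pop, seed = seed)
  seeds <- spawn_seeds(seed, n_animals)
  units <- volume_units(signal_per_cell = pop$v0)
  days <- sort(days)
  per <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    g <- gomp_exp_params(lambda = pars$lambda[i], alpha = pars$alpha[i],
                         beta = pars$beta[i], v_inj = pop$v_inj, v0 = pop$v0)
    d <- dissemination_params(mu = pars$mu[i])
    mets <- simulate_animal(g, d, t_end = max(days), seed = seeds[i],
                            units = units)
    per[[i]] <- do.call(rbind, lapply(days, function(day) {
      born <- mets$birth_time[mets$birth_time <= day]
      vol <- if (length(born))
        signal_to_mm3(volume_at(day - born, g$v0, g), units) else numeric(0)
      cbind(animal = i, day = day, summarize_distribution(vol, threshold))
    }))
  }
  per <- do.call(rbind, per)
  metrics <- c("n_total", "n_macro", "macro_burden", "largest", "total_burden")
  summary <- do.call(rbind, lapply(days, function(day) {
    sub <- per[per$day == day, ]
    data.frame(day = day, metric = metrics,
               mean = vapply(metrics, function(m) mean(sub[[m]]), numeric(1)),
               sd = vapply(metrics, function(m) stats::sd(sub[[m]]), numeric(1)))
  }))
  rownames(summary) <- NULL
  list(summary = summary, per_animal = per, days = days,
       threshold = threshold, n_animals = n_animals, seed = seed)
}

#' Mean interaction loss over the calibrated parameter box
#'
#' Evaluates [interaction_loss()] on a uniform `n_per_side x n_per_side`
#' discretisation of the `(gamma0, pi0)` box spanned by the individual
#' metastasis fits and reports the mean and standard deviation of the
#' relative burden loss.
#'
#' @param n_per_side Grid points per parameter (8 gives the 64-run study).
#' @param gamma0_range,pi0_range Parameter box.
#' @param distance_mm Initial edge-to-edge separation of the two foci, mm.
#' @param per_focus_area_mm2 Initial area of each focus, mm^2.
#' @param T_days Final time, days.
#' @param grid A [grid2d()] object.
#' @param dt_max,cfl Time-stepping controls.
#' @return A list with `table` (`gamma0`, `pi0`, `loss_pct`), `mean_loss`
#'   and `sd_loss`.
#' @export
run_interaction_grid <- function(n_per_side = 8,
                                 gamma0_range = c(0.67, 1.01),
                                 pi0_range = c(5.2e-4, 2.6e-3),
                                 distance_mm = 0.2, per_focus_area_mm2 = 0.46,
                                 T_days = 7, grid = grid2d(128),
                                 dt_max = 0.1, cfl = 0.4) {
  g0s <- seq(gamma0_range[1], gamma0_range[2], length.out = n_per_side)
  p0s <- seq(pi0_range[1], pi0_range[2], length.out = n_per_side)
  tab <- expand.grid(gamma0 = g0s, pi0 = p0s)
  tab$loss_pct <- mapply(function(g0, p0)
    as.numeric(interaction_loss(spatial_params(g0, p0), distance_mm,
                                per_focus_area_mm2, T_days, grid,
                                dt_max = dt_max, cfl = cfl)),
    tab$gamma0, tab$pi0)
  list(table = tab, mean_loss = mean(tab$loss_pct),
       sd_loss = stats::sd(tab$loss_pct))
}

#' Merging study: required germ counts per fitted metastasis
#'
#' For each `(gamma0, pi0)` parameter set and its target volume, computes
#' the number of one-cell germs required to reach the target in `T_days`,
#' without and (optionally) with pressure interactions.
#'
#' @param sets Data frame as returned by [calibrated_spatial_params()]
#'   (columns `name`, `gamma0`, `pi0`, `observed_volume_mm3`).
#' @param T_days Growth duration, days.
#' @param interacting Also run the (expensive) interacting-mode bisection?
#' @param grid A [grid2d()] object.
#' @param seed Seed for germ placement.
#' @param spacing_mm Centre-to-centre germ spacing, mm.
#' @param n_max Search cap for the interacting mode.
#' @param dt_max,cfl Time-stepping controls.
#' @return A data frame with one row per set: the required counts
#'   `n_independent` and (if requested) `n_interacting`, plus the single-
#'   germ final volume `v_single_mm3`.
#' @export
run_merging_study <- function(sets = calibrated_spatial_params(), T_days = 7,
                              interacting = TRUE, grid = grid2d(128),
                              seed = NULL, spacing_mm = 0.05, n_max = 4096L,
                              dt_max = 0.1, cfl = 0.4) {
  out <- lapply(seq_len(nrow(sets)), function(i) {
    sp <- spatial_params(sets$gamma0[i], sets$pi0[i])
    target <- sets$observed_volume_mm3[i]
    ni <- required_foci(target, sp, T_days, interacting = FALSE, grid = grid,
                        dt_max = dt_max, cfl = cfl)
    row <- data.frame(name = sets$name[i], gamma0 = sets$gamma0[i],
                      pi0 = sets$pi0[i], target_mm3 = target,
                      v_single_mm3 = attr(ni, "V_single_mm3"),
                      n_independent = as.integer(ni),
                      n_interacting = NA_integer_)
    if (interacting)
      row$n_interacting <- as.integer(
        required_foci(target, sp, T_days, interacting = TRUE, grid = grid,
                      seed = seed, spacing_mm = spacing_mm, n_max = n_max,
                      dt_max = dt_max, cfl = cfl))
    row
  })
  do.call(rbind, out)
}
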