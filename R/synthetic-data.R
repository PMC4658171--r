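#' Design of a synthetic GFP-tracking cohort
#'
#' Describes the sampling structure of the longitudinal cohort the
#' generators emulate: each animal is sacrificed once (one kidney and one
#' lung measurement on that day), days span 0-26 with denser sampling after
#' day 10, and lung signals have a background noise floor below which
#' tumour signal cannot be seen.
#'
#' @param n_animals Number of animals.
#' @param days Sacrifice day per animal (length `n_animals`); the default
#'   schedule places a few animals before day 10 and cycles the rest over
#'   days 10-26.
#' @param background_median Median lung background signal (GFP relative
#'   units). No measured value is available for the assay; the default
#'   1e-3 sits two decades below the late lung signals, matching a flat
#'   early-lung baseline.
#' @param background_cv_pct Lognormal CV (percent) of the background floor.
#' @param noise_sd_log Residual measurement noise sd on log signal.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_animals = 31, days = NULL,
                          background_median = 1e-3, background_cv_pct = 50,
                          noise_sd_log = 0.3) {
  if (is.null(days)) {
    early <- c(3, 5, 7, 9)
    days <- sort(c(early[seq_len(min(4, n_animals))],
                   rep(10:26, length.out = max(0, n_animals - 4))))
  }
  stopifnot(length(days) == n_animals, all(days >= 0), all(days <= 26))
  structure(list(n_animals = n_animals, days = days,
                 background_median = background_median,
                 background_cv_pct = background_cv_pct,
                 noise_sd_log = noise_sd_log),
            class = "cohort_design")
}

#' Generate a synthetic GFP cohort table
#'
#' Draws per-animal parameters from the population distribution, evaluates
#' the primary-tumour trajectory (kidney) and total metastatic burden
#' (lungs) at each animal's sacrifice day, floors the lung signal at a
#' lognormal background draw, and applies multiplicative lognormal
#' measurement noise. The ground-truth parameters are returned alongside so
#' recovery tests never rely on hard-coded numbers.
#'
#' @param truth A [population_dist()] object (the generating population).
#' @param design A [cohort_design()] object.
#' @param seed Optional integer seed.
#' @return A list with `cohort` (data frame `animal_id`, `day`, `organ`,
#'   `signal`) and `truth` (per-animal parameters plus the population
#'   attributes `medians`, `cv_pct`, `lambda`, `v0`).
#' @export
generate_cohort <- function(truth = population_dist(),
                            design = cohort_design(), seed = NULL) {
  stopifnot(inherits(truth, "population_dist"),
            inherits(design, "cohort_design"))
  with_seed(seed, {
    pars <- sample_population(design$n_animals, truth)
    pars$animal_id <- sprintf("animal%02d", seq_len(design$n_animals))
    pars$day <- design$days
    units <- volume_units(signal_per_cell = truth$v0)
    bg_sdlog <- sqrt(log((1 + sqrt(1 + 4 * (design$background_cv_pct / 100)^2)) / 2))
    rows <- lapply(seq_len(design$n_animals), function(i) {
      g <- gomp_exp_params(lambda = pars$lambda[i], alpha = pars$alpha[i],
                           beta = pars$beta[i], v_inj = truth$v_inj,
                           v0 = truth$v0)
      d <- dissemination_params(mu = pars$mu[i])
      day <- pars$day[i]
      kidney <- volume_at(day, g$v_inj, g)
      burden <- total_burden(day, g, d, units, method = "quadrature")
      bg <- design$background_median *
        exp(stats::rnorm(1, 0, bg_sdlog) * (design$background_cv_pct > 0))
      noise <- exp(stats::rnorm(2, 0, design$noise_sd_log))
      data.frame(animal_id = pars$animal_id[i], day = day,
                 organ = c("kidney", "lungs"),
                 signal = c(kidney * noise[1], max(burden, bg) * noise[2]))
    })
    list(cohort = do.call(rbind, rows),
         truth = structure(pars, medians = truth$medians,
                           cv_pct = truth$cv_pct, lambda = truth$lambda,
                           v0 = truth$v0, v_inj = truth$v_inj))
  })
}

#' Generate an MRI-like lesion table
#'
#' Runs the stochastic per-animal simulator once and reports, for each
#' imaging day, the lesions already above the visibility threshold, with
#' stable lesion identifiers (birth order). Growth is monotone and lesions
#' never regress, so a lesion visible at one day reappears larger at every
#' later day.
#'
#' @param g A [gomp_exp_params()] object.
#' @param d A [dissemination_params()] object.
#' @param days Imaging days.
#' @param threshold Visibility threshold, mm^3.
#' @param seed Optional integer seed.
#' @param units A [volume_units()] object.
#' @return A data frame (`day`, `lesion_id`, `volume_mm3`), with the full
#'   simulated animal attached as attribute `animal`.
#' @export
generate_mri_table <- function(g, d, days = c(19, 21, 24, 26),
                               threshold = 0.05, seed = NULL,
                               units = volume_units(g$v0)) {
  mets <- simulate_animal(g, d, t_end = max(days), seed = seed, units = units)
  out <- lapply(sort(days), function(day) {
    if (!nrow(mets)) return(NULL)
    born <- which(mets$birth_time <= day)
    if (!length(born)) return(NULL)
    vol <- signal_to_mm3(volume_at(day - mets$birth_time[born], g$v0, g), units)
    vis <- vol >= threshold
    if (!any(vis)) return(NULL)
    data.frame(day = day, lesion_id = born[vis], volume_mm3 = vol[vis])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(day = numeric(0), lesion_id = integer(0),
                      volume_mm3 = numeric(0))
  attr(out, "animal") <- mets
  out
}

#' Generate a noisy single-metastasis volume series
#'
#' Simulates one disc tumour with the spatial model from a given initial
#' 3D volume and samples its 3D-converted volume at the requested days,
#' with relative Gaussian measurement noise. The generating parameters are
#' attached as the `truth` attribute.
#'
#' @param sp A [spatial_params()] object (ground truth).
#' @param days Observation days (the series starts at `days[1]`).
#' @param init_volume_mm3 Volume at the first observation day.
#' @param noise_rel Relative noise standard deviation (0 for noiseless).
#' @param seed Optional integer seed.
#' @param grid A [grid2d()] object.
#' @param dt_max,cfl Time-stepping controls.
#' @return A data frame (`day`, `volume_mm3`) with attribute `truth`.
#' @export
generate_met_series <- function(sp, days = c(19, 21, 24, 26),
                                init_volume_mm3 = 0.022, noise_rel = 0.01,
                                seed = NULL, grid = grid2d(),
                                dt_max = 0.1, cfl = 0.4) {
  stopifnot(length(days) >= 2, all(diff(days) > 0))
  c0 <- grid$length_mm / 2
  P0 <- foci_field(focus_spec(c0, c0, volume_3d_to_area(init_volume_mm3)),
                   grid)
  tobs <- days - days[1]
  sim <- simulate_spatial(P0, sp, grid, t_end = max(tobs), dt_max = dt_max,
                          cfl = cfl, record_times = tobs[tobs > 0])
  v <- area_to_volume_3d(stats::approx(sim$series$t, sim$series$mass_mm2,
                                       xout = tobs, rule = 2)$y)
  v <- with_seed(seed, v * pmax(1 + noise_rel * stats::rnorm(length(v)), 0.05))
  structure(data.frame(day = days, volume_mm3 = v), truth = sp)
}

#' Sidecar truth files for synthetic data
#'
#' Generators return their ground truth alongside the data; these helpers
#' serialise that truth to a JSON sidecar and read it back, so downstream
#' recovery tests take the truth from the sidecar rather than from
#' hard-coded values.
#'
#' @param truth A truth object (data frame or list, e.g. the `truth`
#'   element of [generate_cohort()]).
#' @param path File path for the JSON sidecar.
#' @return `write_sidecar_truth()` returns `path` invisibly;
#'   `read_sidecar_truth()` returns the parsed truth.
#' @export
write_sidecar_truth <- function(truth, path) {
  payload <- list(data = truth)
  for (a in c("medians", "cv_pct", "lambda", "v0", "v_inj"))
    if (!is.null(attr(truth, a))) payload[[a]] <- as.list(attr(truth, a))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sidecar_truth
#' @export
read_sidecar_truth <- function(path)
  jsonlite::read_json(path, simplifyVector = TRUE)
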