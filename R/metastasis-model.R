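#' Dissemination-law parameters
#'
#' Per-day rate at which a primary tumour of size `Vp` seeds new metastases:
#' `d(Vp) = mu * (Vp in cells)^gamma_d`. The coefficient `mu` is expressed
#' per cell per day, so the primary size is converted from signal units to
#' cells before the power law is applied.
#'
#' @param mu Emission coefficient (cell^-1 day^-1 for `gamma_d = 1`).
#' @param gamma_d Emission exponent, in (0, 1.5]. The default 1 corresponds
#'   to emission proportional to tumour volume.
#' @return An object of class `dissemination_params`.
#' @export
dissemination_params <- function(mu = 9.72e-6, gamma_d = 1) {
  if (mu < 0) stop("mu must be non-negative")
  if (gamma_d <= 0 || gamma_d > 1.5) stop("gamma_d must lie in (0, 1.5]")
  structure(list(mu = mu, gamma_d = gamma_d), class = "dissemination_params")
}

#' Metastasis emission rate of the primary tumour
#'
#' @param vp Primary tumour size(s), signal units (>= 0).
#' @param d A [dissemination_params()] object.
#' @param units A [volume_units()] object used to convert signal to cells.
#' @return Expected number of newly seeded metastases per day.
#' @export
emission_rate <- function(vp, d, units = volume_units()) {
  stopifnot(inherits(d, "dissemination_params"))
  if (any(vp < 0)) stop("primary size must be non-negative")
  d$mu * signal_to_cells(vp, units)^d$gamma_d
}

# Emission intensity d(Vp(s)) along the primary trajectory, vectorised in s.
emission_intensity <- function(s, g, d, units = volume_units())
  emission_rate(volume_at(s, g$v_inj, g), d, units)

#' Cumulative expected emission N(t)
#'
#' Integral of the emission intensity `d(Vp(s))` from 0 to `t` by adaptive
#' quadrature: the expected number of metastases seeded up to time `t`.
#'
#' @param t Time(s) in days.
#' @param g A [gomp_exp_params()] object.
#' @param d A [dissemination_params()] object.
#' @param units A [volume_units()] object.
#' @return Expected counts, same length as `t`.
#' @export
cumulative_emission <- function(t, g, d, units = volume_units()) {
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    stats::integrate(emission_intensity, 0, ti, g = g, d = d, units = units,
                     rel.tol = 1e-9)$value
  }, numeric(1))
}

#' Total metastatic burden M(t)
#'
#' First moment of the size-structured density: the summed size of all
#' metastases at time `t`. By the method of characteristics this is the
#' convolution of the emission intensity with the one-cell growth curve,
#' \deqn{M(t) = \int_0^t d(V_p(s))\, V_\mathrm{met}(t - s)\, ds,}
#' where `V_met(tau) = volume_at(tau, v0, g)`. The `"fft"` method evaluates
#' the convolution on a uniform grid for all times at once via the fast
#' Fourier transform (with trapezoid end corrections); `"quadrature"` uses
#' adaptive integration per time point and serves as the slow exact path.
#'
#' @param t Time(s) in days.
#' @param g A [gomp_exp_params()] object.
#' @param d A [dissemination_params()] object.
#' @param units A [volume_units()] object.
#' @param method `"fft"` (grid convolution) or `"quadrature"` (adaptive).
#' @param dt Uniform grid step for the FFT path, days. Must resolve the
#'   exponential phase: `dt * lambda <= 0.035` is enforced.
#' @return Burden in signal units, same length as `t`.
#' @export
total_burden <- function(t, g, d, units = volume_units(),
                         method = c("fft", "quadrature"), dt = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(g, "gomp_exp_params"), inherits(d, "dissemination_params"))
  if (any(t < 0)) stop("times must be non-negative")
  if (method == "quadrature") {
    return(vapply(t, function(ti) {
      if (ti <= 0) return(0)
      stats::integrate(function(s)
        emission_intensity(s, g, d, units) * volume_at(ti - s, g$v0, g),
        0, ti, rel.tol = 1e-9, subdivisions = 500L)$value
    }, numeric(1)))
  }
  if (dt * g$lambda > 0.035)
    stop("time grid too coarse to resolve the exponential phase: ",
         "choose dt <= ", signif(0.035 / g$lambda, 3), " day")
  tmax <- max(t)
  if (tmax <= 0) return(rep(0, length(t)))
  n <- ceiling(tmax / dt) + 1L
  s <- (seq_len(n) - 1) * dt
  r <- emission_intensity(s, g, d, units)
  w <- volume_at(s, g$v0, g)
  m <- stats::nextn(2L * n)
  conv <- Re(stats::fft(stats::fft(c(r, rep(0, m - n))) *
                        stats::fft(c(w, rep(0, m - n))), inverse = TRUE)) / m
  Mgrid <- dt * (conv[seq_len(n)] - 0.5 * r[1] * w - 0.5 * r * w[1])
  Mgrid[1] <- 0
  stats::approx(s, Mgrid, xout = t, rule = 2)$y
}

#' Size-structured density of metastases
#'
#' Solution of the transport equation for the density `rho(t, v)` of
#' metastases of size `v` at time `t` by the method of characteristics:
#' `rho(t, v) = d(Vp(t - tau(v))) / g(v)` where `tau(v)` is the time needed
#' to grow from the one-cell size `v0` to `v`, and 0 for lesions that would
#' have to be older than `t`.
#'
#' @param t Time in days (scalar).
#' @param v Size(s), signal units, `>= v0`.
#' @inheritParams total_burden
#' @return Density values (metastases per unit signal).
#' @export
size_density <- function(t, v, g, d, units = volume_units()) {
  stopifnot(length(t) == 1L, t >= 0)
  if (any(v < g$v0)) stop("sizes below the one-cell size v0 have no density")
  tau <- time_to_reach(v, g$v0, g)
  born <- tau <= t
  out <- numeric(length(v))
  if (any(born))
    out[born] <- emission_intensity(t - tau[born], g, d, units) /
      growth_rate(v[born], g)
  out
}

#' Expected number of metastases above a size threshold
#'
#' Counts the characteristics old enough to have passed `vbar`:
#' `count_above(t, vbar) = N(t - tau(vbar))` with `N` the cumulative
#' emission and `tau(vbar)` the growth time from `v0` to `vbar`.
#'
#' @param t Time(s) in days.
#' @param vbar Size threshold, signal units (scalar, `>= v0`).
#' @inheritParams total_burden
#' @return Expected counts.
#' @export
count_above <- function(t, vbar, g, d, units = volume_units()) {
  stopifnot(length(vbar) == 1L)
  if (vbar >= g$v_max) return(rep(0, length(t)))
  tau <- time_to_reach(vbar, g$v0, g)
  cumulative_emission(pmax(t - tau, 0), g, d, units)
}

#' Deterministic "largest metastasis" convention
#'
#' In the continuum model the largest lesion is identified with the
#' characteristic carrying the first whole emitted metastasis: the lesion
#' born at the time `s1` where the cumulative emission reaches one. Returns
#' its size at time `t`, in mm^3, or 0 if fewer than one metastasis has been
#' emitted by `t`.
#'
#' @param t Time in days (scalar).
#' @inheritParams total_burden
#' @return Size in mm^3 (0 when `N(t) < 1`).
#' @export
largest_size_deterministic <- function(t, g, d, units = volume_units()) {
  stopifnot(length(t) == 1L)
  if (cumulative_emission(t, g, d, units) < 1) return(0)
  s1 <- stats::uniroot(function(s) cumulative_emission(s, g, d, units) - 1,
                       c(0, t), tol = 1e-10)$root
  signal_to_mm3(volume_at(t - s1, g$v0, g), units)
}

#' Stochastic per-animal metastasis simulation
#'
#' Draws metastasis birth times from an inhomogeneous Poisson process with
#' intensity `d(Vp(s))` by thinning (the intensity is nondecreasing, so the
#' rate at `t_end` bounds it), then grows each lesion deterministically from
#' the one-cell size `v0`.
#'
#' @param g A [gomp_exp_params()] object (per-animal parameters).
#' @param d A [dissemination_params()] object.
#' @param t_end End of the observation window, days.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param units A [volume_units()] object.
#' @return A data frame with one row per metastasis: `birth_time` (days),
#'   `size_signal` and `size_mm3` at `t_end`. Zero rows when nothing was
#'   emitted.
#' @export
simulate_animal <- function(g, d, t_end, seed = NULL, units = volume_units()) {
  stopifnot(t_end >= 0)
  with_seed(seed, {
    # interval-wise thinning: the intensity is nondecreasing, so the rate at
    # each interval's right end bounds it there; this keeps the number of
    # candidate points proportional to the true count even for animals whose
    # primary tumour grows by several orders of magnitude
    breaks <- unique(c(seq(0, t_end, by = 1), t_end))
    births <- numeric(0)
    if (t_end > 0) {
      bounds <- emission_intensity(breaks[-1], g, d, units)
      for (k in seq_along(bounds)) {
        a <- breaks[k]; b <- breaks[k + 1]
        n_cand <- stats::rpois(1, bounds[k] * (b - a))
        if (n_cand > 0) {
          u <- stats::runif(n_cand, a, b)
          keep <- stats::runif(n_cand) * bounds[k] <=
            emission_intensity(u, g, d, units)
          births <- c(births, u[keep])
        }
      }
      births <- sort(births)
    }
    sizes <- if (length(births)) volume_at(t_end - births, g$v0, g) else numeric(0)
    data.frame(birth_time = births,
               size_signal = sizes,
               size_mm3 = signal_to_mm3(sizes, units))
  })
}

#' Lognormal inter-animal parameter distribution
#'
#' Population distribution of the growth and dissemination parameters:
#' `alpha`, `beta` and `mu` are lognormal with given median and coefficient
#' of variation; `lambda` is a fixed effect. The CV is defined as the ratio
#' of the distribution's standard deviation to its median (in percent), so
#' the log-scale parameters are `meanlog = log(median)` and
#' `sdlog^2 = log((1 + sqrt(1 + 4 c^2)) / 2)` with `c = CV / 100`.
#'
#' @param medians Named numeric vector with entries `alpha`, `beta`, `mu`.
#' @param cv_pct Named numeric vector of CVs in percent, same names. A CV of
#'   0 collapses that parameter to its median.
#' @param lambda Fixed in-vitro proliferation rate (day^-1).
#' @param v_inj,v0 Injected-inoculum and one-cell signals shared by all
#'   animals.
#' @return An object of class `population_dist`.
#' @export
population_dist <- function(medians = c(alpha = 0.417, beta = 0.106, mu = 9.72e-6),
                            cv_pct = c(alpha = 41, beta = 45.1, mu = 21.7),
                            lambda = 0.679, v_inj = 0.796, v0 = 7.96e-6) {
  nm <- c("alpha", "beta", "mu")
  stopifnot(all(nm %in% names(medians)), all(nm %in% names(cv_pct)))
  medians <- medians[nm]; cv_pct <- cv_pct[nm]
  if (any(medians <= 0)) stop("medians must be strictly positive")
  if (any(cv_pct < 0)) stop("CVs must be non-negative")
  cc <- cv_pct / 100
  sdlog <- sqrt(log((1 + sqrt(1 + 4 * cc^2)) / 2))
  structure(list(medians = medians, cv_pct = cv_pct, sdlog = sdlog,
                 lambda = lambda, v_inj = v_inj, v0 = v0),
            class = "population_dist")
}

#' Sample per-animal parameter sets from the population distribution
#'
#' @param n Number of animals.
#' @param pop A [population_dist()] object.
#' @param seed Optional integer seed.
#' @return A data frame with columns `alpha`, `beta`, `mu`, `lambda` (one
#'   row per animal); draws are independent across parameters and animals.
#' @export
sample_population <- function(n, pop, seed = NULL) {
  stopifnot(inherits(pop, "population_dist"), n >= 1)
  with_seed(seed, {
    draws <- vapply(c("alpha", "beta", "mu"), function(k)
      stats::rlnorm(n, meanlog = log(pop$medians[[k]]), sdlog = pop$sdlog[[k]]),
      numeric(n))
    out <- as.data.frame(matrix(draws, nrow = n,
                                dimnames = list(NULL, c("alpha", "beta", "mu"))))
    out$lambda <- pop$lambda
    out
  })
}

#' Summary metrics of a metastasis size distribution
#'
#' Computes the per-animal metrics used to confront the model with imaging
#' data: total count, number of macro-metastases (lesions at or above the
#' visibility threshold), macro burden, largest lesion and total burden.
#'
#' @param mets Either the data frame returned by [simulate_animal()] or a
#'   numeric vector of lesion volumes in mm^3.
#' @param threshold Visibility threshold in mm^3 (default 0.05, the smallest
#'   lesion detectable on the MRI data the model is compared against).
#' @return A one-row data frame with columns `n_total`, `n_macro`,
#'   `macro_burden`, `largest`, `total_burden` (mm^3) and `threshold`.
#' @export
summarize_distribution <- function(mets, threshold = 0.05) {
  v <- if (is.data.frame(mets)) mets$size_mm3 else as.numeric(mets)
  if (is.null(v)) stop("mets must carry lesion volumes in mm^3")
  macro <- v[v >= threshold]
  data.frame(n_total = length(v),
             n_macro = length(macro),
             macro_burden = if (length(macro)) sum(macro) else 0,
             largest = if (length(macro)) max(macro) else 0,
             total_burden = if (length(v)) sum(v) else 0,
             threshold = threshold)
}

#' One-sided z-test for the largest-metastasis comparison
#'
#' Tests whether the mean of the observed largest-lesion volumes exceeds
#' what the simulated distribution predicts: the statistic is
#' `z = (mean(observed) - mean(simulated)) / (sd(simulated) / sqrt(n_obs))`
#' and the p-value is the upper tail of the standard normal.
#'
#' @param observed Numeric vector of observed volumes (mm^3).
#' @param simulated Numeric vector of simulated volumes (>= 30 values).
#' @return The one-sided p-value in `[0, 1]`.
#' @export
largest_z_test <- function(observed, simulated) {
  if (length(simulated) < 30)
    stop("need at least 30 simulated values for the normal approximation")
  if (!length(observed)) stop("no observed values")
  s <- stats::sd(simulated)
  delta <- mean(observed) - mean(simulated)
  if (s == 0) return(if (delta > 0) 0 else if (delta < 0) 1 else 0.5)
  z <- delta / (s / sqrt(length(observed)))
  stats::pnorm(z, lower.tail = FALSE)
}
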