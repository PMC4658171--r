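#' Preprocess a cohort table before fitting
#'
#' Applies the data-handling rules used for the population fit: GFP signal
#' measured in the lungs at early times reflects background noise rather
#' than tumour cells, so lung rows before day 10 are removed; rows
#' explicitly flagged as technical outliers (a logical `flagged` column)
#' are removed; kidney rows are kept regardless of day. The operation is
#' idempotent.
#'
#' @param raw A cohort data frame with columns `animal_id`, `day`, `organ`
#'   (`"kidney"` or `"lungs"`), `signal`, and optionally `flagged`.
#' @param lung_day_min First day at which lung signal is trusted.
#' @return The filtered cohort.
#' @export
preprocess_cohort <- function(raw, lung_day_min = 10) {
  stopifnot(all(c("animal_id", "day", "organ", "signal") %in% names(raw)))
  if (!all(raw$organ %in% c("kidney", "lungs")))
    stop("organ must be 'kidney' or 'lungs'")
  if (any(raw$signal < 0)) stop("signals must be non-negative")
  keep <- raw$organ == "kidney" | raw$day >= lung_day_min
  if (!is.null(raw$flagged)) keep <- keep & !raw$flagged
  raw[keep, , drop = FALSE]
}

#' Preliminary fit of the primary tumour with free inoculum signal
#'
#' Nonlinear least squares of the Gomp-Exp trajectory on log kidney signal
#' with the initial signal `v_inj` free, the in-vitro rate `lambda` fixed.
#' The one-cell signal is then derived by proportionality with the number
#' of injected cells: `v0 = v_inj / n_injected`.
#'
#' @param kidney Cohort rows for the kidney (a data frame with `day`,
#'   `signal`; other organs are dropped if present).
#' @param lambda Fixed in-vitro proliferation rate, day^-1.
#' @param n_injected Number of injected cells (default 1e5).
#' @return A list with `v_inj`, `alpha`, `beta`, `v0`, the residual scale
#'   `sigma_log` and the underlying `nls` fit.
#' @export
fit_primary_vinj <- function(kidney, lambda = 0.679, n_injected = 1e5) {
  if (!is.null(kidney$organ)) kidney <- kidney[kidney$organ == "kidney", ]
  kidney <- kidney[kidney$signal > 0, ]
  if (length(unique(kidney$day)) < 4)
    stop("under-determined: need kidney data on at least 4 distinct days")
  kidney <- kidney[order(kidney$day), ]
  traj <- function(day, lvinj, lalpha, lbeta) {
    p <- gomp_exp_params(lambda = lambda, alpha = exp(lalpha),
                         beta = exp(lbeta), v_inj = exp(lvinj))
    log(volume_at(day, exp(lvinj), p))
  }
  start <- list(lvinj = log(max(min(kidney$signal), 1e-8)),
                lalpha = log(0.5), lbeta = log(0.12))
  fit <- minpack.lm::nlsLM(
    log(signal) ~ traj(day, lvinj, lalpha, lbeta),
    data = kidney, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  v_inj <- exp(cf[["lvinj"]])
  list(v_inj = v_inj,
       alpha = exp(cf[["lalpha"]]),
       beta = exp(cf[["lbeta"]]),
       v0 = v_inj / n_injected,
       sigma_log = stats::sigma(fit),
       fit = fit)
}

# Predicted log signals for one parameter set: kidney rows follow the
# primary trajectory, lung rows the total metastatic burden.
predict_log_signals <- function(days, organ, alpha, beta, mu, lambda, v0,
                                gamma_d = 1, units = volume_units(v0)) {
  g <- gomp_exp_params(lambda = lambda, alpha = alpha, beta = beta,
                       v_inj = 1e5 * v0, v0 = v0)
  d <- dissemination_params(mu = mu, gamma_d = gamma_d)
  out <- numeric(length(days))
  kid <- organ == "kidney"
  if (any(kid)) out[kid] <- log(volume_at(days[kid], g$v_inj, g))
  if (any(!kid)) {
    m <- total_burden(days[!kid], g, d, units, method = "quadrature")
    out[!kid] <- log(pmax(m, 1e-300))
  }
  out
}

#' Joint fit of primary tumour and metastatic burden
#'
#' Estimates the growth parameters `alpha`, `beta` and the dissemination
#' coefficient `mu` from a preprocessed cohort in which each animal
#' contributes a kidney (primary tumour) and/or lung (total metastatic
#' burden) signal at a single sacrifice day. Residuals are additive
#' Gaussian on log signal (signals are positive and span decades).
#'
#' Two estimators are provided. `"pooled"` treats all animals as one curve
#' and minimises the summed squared log residuals of both organs jointly by
#' Levenberg-Marquardt. `"mixed"` is an EM-style population estimator:
#' starting from the pooled fit, it alternates penalised per-animal MAP
#' fits of `(alpha, beta, mu)` under the current lognormal population law
#' (E-like step) with exact updates of the population log-medians, log-sds
#' and residual scale (M-like step); every update decreases the joint MAP
#' objective, so the objective trace is monotone. Reported population sds
#' include a Laplace correction (mean posterior variance from the per-animal
#' Hessians) that compensates the shrinkage of MAP estimates.
#'
#' @param cohort Preprocessed cohort data frame (`animal_id`, `day`,
#'   `organ`, `signal`).
#' @param lambda Fixed in-vitro proliferation rate, day^-1.
#' @param v0 One-cell signal (from [fit_primary_vinj()]); the inoculum
#'   signal is `1e5 * v0`.
#' @param mode `"pooled"` or `"mixed"`.
#' @param gamma_d Fixed dissemination exponent (re-fit at other values for
#'   sensitivity studies).
#' @param max_iter Maximum EM iterations (mixed mode).
#' @param tol Relative objective-decrease tolerance for EM convergence.
#' @param sdlog_floor Lower bound on population log-sds during EM (guards
#'   against degenerate collapse).
#' @return An object of class `metaburden_fit`: a list with `mode`,
#'   `estimates` (data frame of medians and CV%), `sigma_log`, `converged`,
#'   `iterations`, `objective_trace`, and per-animal MAP estimates
#'   (`individual`, mixed mode). Non-convergence is reported through
#'   `converged = FALSE` and a `message`, never silently.
#' @export
fit_joint <- function(cohort, lambda = 0.679, v0 = 7.96e-6,
                      mode = c("pooled", "mixed"), gamma_d = 1,
                      max_iter = 25L, tol = 1e-6, sdlog_floor = 0.02) {
  mode <- match.arg(mode)
  stopifnot(all(c("animal_id", "day", "organ", "signal") %in% names(cohort)))
  cohort <- cohort[cohort$signal > 0, ]
  units <- volume_units(signal_per_cell = v0)

  obj_pooled <- function(lpar)
    log(cohort$signal) - predict_log_signals(cohort$day, cohort$organ,
                                             exp(lpar[1]), exp(lpar[2]),
                                             exp(lpar[3]), lambda, v0,
                                             gamma_d, units)
  start <- c(lalpha = log(0.4), lbeta = log(0.1), lmu = log(1e-5))
  pfit <- minpack.lm::nls.lm(par = start, fn = obj_pooled,
                             control = minpack.lm::nls.lm.control(maxiter = 300))
  lpool <- pfit$par
  resid <- obj_pooled(lpool)
  sigma <- sqrt(sum(resid^2) / max(length(resid) - 3, 1))
  pooled_est <- data.frame(parameter = c("alpha", "beta", "mu"),
                           median = exp(unname(lpool)), cv_pct = NA_real_)
  if (mode == "pooled") {
    return(structure(list(mode = "pooled", estimates = pooled_est,
                          lambda = lambda, v0 = v0, gamma_d = gamma_d,
                          sigma_log = sigma,
                          converged = pfit$info %in% 1:4,
                          iterations = pfit$niter,
                          objective_trace = pfit$deviance,
                          message = pfit$message),
                     class = "metaburden_fit"))
  }

  ## ---- mixed mode: MAP-EM on log parameters -------------------------------
  ids <- unique(cohort$animal_id)
  n_id <- length(ids)
  rows <- split(seq_len(nrow(cohort)), factor(cohort$animal_id, levels = ids))
  m <- unname(lpool)                        # population log-medians
  s <- rep(0.3, 3)                          # population log-sds
  eta <- matrix(rep(m, each = n_id), n_id, 3)  # per-animal log parameters
  # With at most two observations per animal and three individual
  # parameters, the residual scale is not identifiable separately from the
  # random effects; it is estimated once from the pooled fit and held fixed
  # during the population updates.
  sigma <- max(sigma, 0.05)

  animal_rss <- function(e, idx) {
    pred <- predict_log_signals(cohort$day[idx], cohort$organ[idx],
                                exp(e[1]), exp(e[2]), exp(e[3]),
                                lambda, v0, gamma_d, units)
    sum((log(cohort$signal[idx]) - pred)^2)
  }
  map_obj <- function(e, idx, m, s, sigma)
    animal_rss(e, idx) / (2 * sigma^2) + sum((e - m)^2 / (2 * s^2))
  # Laplace posterior variances of the per-animal log parameters: diagonal
  # of the inverse Hessian of the MAP objective at the MAP point. These
  # enter the population-variance update (the EM sufficient statistic is
  # E[(eta - m)^2] = (eta_MAP - m)^2 + postvar), which prevents the
  # degenerate shrinkage a plain MAP-EM suffers when animals carry fewer
  # observations than parameters.
  posterior_var <- function(eta, m, s, sigma) {
    pv <- matrix(0, n_id, 3)
    for (i in seq_len(n_id)) {
      H <- try(stats::optimHess(eta[i, ], map_obj, idx = rows[[i]], m = m,
                                s = s, sigma = sigma), silent = TRUE)
      if (!inherits(H, "try-error")) {
        Hi <- try(solve(H), silent = TRUE)
        if (!inherits(Hi, "try-error") && all(is.finite(diag(Hi))) &&
            all(diag(Hi) > 0))
          pv[i, ] <- diag(Hi)
      }
    }
    pv
  }
  # Q-style objective: complete-data negative log posterior with the
  # posterior second moments plugged in; every EM update decreases it.
  q_objective <- function(eta, pv, m, s, sigma) {
    rss <- sum(vapply(seq_len(n_id),
                      function(i) animal_rss(eta[i, ], rows[[i]]), numeric(1)))
    second <- sweep(eta, 2, m)^2 + pv
    rss / (2 * sigma^2) + nrow(cohort) * log(sigma) +
      sum(sweep(second, 2, 2 * s^2, "/")) + n_id * sum(log(s))
  }

  pv <- posterior_var(eta, m, s, sigma)
  trace <- q_objective(eta, pv, m, s, sigma)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n_id)) {              # E-like step: per-animal MAP
      op <- stats::optim(eta[i, ], map_obj, idx = rows[[i]], m = m, s = s,
                         sigma = sigma, method = "Nelder-Mead",
                         control = list(reltol = 1e-10, maxit = 400))
      if (op$value <= map_obj(eta[i, ], rows[[i]], m, s, sigma))
        eta[i, ] <- op$par
    }
    pv <- posterior_var(eta, m, s, sigma)
    m <- colMeans(eta)                      # M-like step
    s <- pmax(sqrt(colMeans(sweep(eta, 2, m)^2 + pv)), sdlog_floor)
    trace <- c(trace, q_objective(eta, pv, m, s, sigma))
    if (abs(diff(utils::tail(trace, 2))) < tol * abs(trace[1])) {
      converged <- TRUE
      break
    }
  }
  cv <- 100 * exp(s^2 / 2) * sqrt(exp(s^2) - 1)   # CV = sd / median
  est <- data.frame(parameter = c("alpha", "beta", "mu"),
                    median = exp(m), cv_pct = cv)
  individual <- as.data.frame(exp(eta))
  names(individual) <- c("alpha", "beta", "mu")
  individual$animal_id <- ids
  structure(list(mode = "mixed", estimates = est, lambda = lambda, v0 = v0,
                 gamma_d = gamma_d, sigma_log = sigma, converged = converged,
                 iterations = iter, objective_trace = trace,
                 individual = individual,
                 message = if (converged) "converged"
                           else "maximum EM iterations reached"),
            class = "metaburden_fit")
}

#' @export
print.metaburden_fit <- function(x, ...) {
  cat(sprintf("Population fit (%s mode)%s\n", x$mode,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  print(x$estimates, row.names = FALSE)
  cat(sprintf("residual sd (log signal): %.3g\n", x$sigma_log))
  invisible(x)
}
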