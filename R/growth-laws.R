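#' Gomp-Exp growth-law parameters
#'
#' Bundles the parameters of the Gomp-Exp tumour growth law, in which a
#' tumour first grows exponentially at the in-vitro proliferation rate
#' `lambda` and switches to Gompertz growth (exponentially decaying specific
#' growth rate) once the Gompertz branch becomes the slower of the two. The
#' instantaneous growth rate is
#' \deqn{g(v) = \min\{\lambda v, (\alpha - \beta \log v)\, v\}.}
#' The switch happens at the size \eqn{v_* = \exp((\alpha - \lambda)/\beta)}
#' and the carrying capacity is \eqn{\exp(\alpha/\beta)}.
#'
#' Sizes are expressed in relative units of GFP signal throughout; use
#' [volume_units()] to convert to cells or mm^3 at reporting boundaries.
#'
#' @param lambda In-vitro proliferation rate (day^-1). Treated as a fixed
#'   effect: the same value is shared by all animals.
#' @param alpha Specific growth rate at unit signal (day^-1).
#' @param beta Exponential decay rate of the specific growth rate (day^-1).
#' @param v_inj Injected-inoculum signal (GFP relative units).
#' @param v0 One-cell signal (GFP relative units).
#' @return An object of class `gomp_exp_params` with the supplied fields plus
#'   the derived switch size `v_star` and carrying capacity `v_max`.
#' @examples
#' p <- gomp_exp_params()
#' p$v_star
#' volume_at(c(0, 10, 26), p$v_inj, p)
#' @export
gomp_exp_params <- function(lambda = 0.679, alpha = 0.417, beta = 0.106,
                            v_inj = 0.796, v0 = 7.96e-6) {
  stopifnot(is.numeric(lambda), is.numeric(alpha), is.numeric(beta),
            length(lambda) == 1L, length(alpha) == 1L, length(beta) == 1L)
  if (lambda <= 0 || alpha <= 0 || beta <= 0 || v_inj <= 0 || v0 <= 0)
    stop("all Gomp-Exp parameters must be strictly positive")
  v_star <- exp((alpha - lambda) / beta)
  # v_star may underflow to 0 in the beta -> 0, lambda >= alpha limit, where
  # the law degenerates to pure exponential growth at rate alpha
  if (!is.finite(v_star) || v_star < 0)
    stop("switch size exp((alpha - lambda)/beta) is not finite")
  structure(
    list(lambda = lambda, alpha = alpha, beta = beta,
         v_inj = v_inj, v0 = v0,
         v_star = v_star, v_max = exp(alpha / beta)),
    class = "gomp_exp_params")
}

#' @export
print.gomp_exp_params <- function(x, ...) {
  cat("Gomp-Exp growth law (GFP signal units)\n")
  cat(sprintf("  lambda = %.4g /day, alpha = %.4g /day, beta = %.4g /day\n",
              x$lambda, x$alpha, x$beta))
  cat(sprintf("  v_inj = %.4g, v0 = %.4g\n", x$v_inj, x$v0))
  cat(sprintf("  switch size v* = %.4g, carrying capacity = %.4g\n",
              x$v_star, x$v_max))
  invisible(x)
}

#' Instantaneous Gomp-Exp growth rate
#'
#' @param v Tumour size(s), GFP signal units; must be strictly positive.
#' @param p A [gomp_exp_params()] object.
#' @return `dv/dt` in signal units per day, the pointwise minimum of the
#'   exponential branch `lambda * v` and the Gompertz branch
#'   `(alpha - beta * log(v)) * v`.
#' @export
growth_rate <- function(v, p) {
  stopifnot(inherits(p, "gomp_exp_params"))
  if (any(!is.finite(v)) || any(v <= 0))
    stop("growth_rate() requires strictly positive sizes")
  pmin(p$lambda * v, (p$alpha - p$beta * log(v)) * v)
}

#' Gomp-Exp trajectory (closed form)
#'
#' Size at time `t` of a tumour that starts from `v_init` and follows the
#' Gomp-Exp law: exponential growth at rate `lambda` until the switch size
#' `v_star` is reached, Gompertz growth afterwards. If `v_init >= v_star` the
#' trajectory is pure Gompertz from the start.
#'
#' @param t Time(s) in days, non-negative; vectorised.
#' @param v_init Initial size, signal units (scalar, > 0).
#' @param p A [gomp_exp_params()] object.
#' @return Sizes at the requested times, signal units.
#' @export
volume_at <- function(t, v_init, p) {
  stopifnot(inherits(p, "gomp_exp_params"), length(v_init) == 1L, v_init > 0)
  if (any(t < 0)) stop("volume_at() requires non-negative times")
  K <- p$alpha / p$beta                 # log carrying capacity
  if (v_init >= p$v_star) {
    out <- exp(K + (log(v_init) - K) * exp(-p$beta * t))
    out[t == 0] <- v_init               # exact identity at t = 0
    return(out)
  }
  t_sw <- log(p$v_star / v_init) / p$lambda
  out <- v_init * exp(p$lambda * pmin(t, t_sw))
  late <- t > t_sw
  if (any(late))
    out[late] <- exp(K + (log(p$v_star) - K) * exp(-p$beta * (t[late] - t_sw)))
  out
}

#' Time for a Gomp-Exp tumour to reach a target size
#'
#' Closed-form inverse of [volume_at()]. Needed to locate the characteristic
#' curves of the size-structured model: only lesions older than
#' `time_to_reach(vbar, v0, p)` exceed the visibility threshold `vbar`.
#'
#' @param v_target Target size(s), signal units; must satisfy
#'   `v_init <= v_target < exp(alpha/beta)`.
#' @param v_init Initial size, signal units (scalar).
#' @param p A [gomp_exp_params()] object.
#' @return Time in days; 0 when `v_target == v_init`.
#' @export
time_to_reach <- function(v_target, v_init, p) {
  stopifnot(inherits(p, "gomp_exp_params"), length(v_init) == 1L, v_init > 0)
  if (any(v_target < v_init))
    stop("time_to_reach() requires v_target >= v_init")
  if (any(v_target >= p$v_max))
    stop("target size is at or above the carrying capacity exp(alpha/beta): unreachable")
  K <- p$alpha / p$beta
  gomp_time <- function(v_to, v_from)   # pure-Gompertz travel time
    log((K - log(v_from)) / (K - log(v_to))) / p$beta
  if (v_init >= p$v_star) return(gomp_time(v_target, v_init))
  t_sw <- log(p$v_star / v_init) / p$lambda
  out <- ifelse(v_target <= p$v_star,
                log(v_target / v_init) / p$lambda,
                t_sw + gomp_time(pmax(v_target, p$v_star), p$v_star))
  out
}

#' Doubling time required to bridge two volumes in a fixed duration
#'
#' The feasibility arithmetic behind the independent-growth critique: a
#' lesion growing from `v_start` to `v_end` in `duration` days at a constant
#' doubling time needs
#' \deqn{T_d = \frac{24\,\mathrm{duration} \cdot \log 2}{\log(v_\mathrm{end}/v_\mathrm{start})}\ \mathrm{hours}.}
#'
#' @param v_start,v_end Start and end volumes (any common unit, e.g. mm^3);
#'   `v_end > v_start > 0`.
#' @param duration Time window in days (> 0).
#' @return Required doubling time, in hours.
#' @examples
#' required_doubling_time(1e-6, 0.022, 5)   # one cell to 0.022 mm^3
#' @export
required_doubling_time <- function(v_start, v_end, duration) {
  if (any(v_start <= 0) || any(v_end <= v_start) || any(duration <= 0))
    stop("need v_end > v_start > 0 and duration > 0")
  duration * 24 * log(2) / log(v_end / v_start)
}

#' Linear unit conversions between GFP signal, cells and mm^3
#'
#' The calibration ties the units together: one cell carries
#' `signal_per_cell` relative units of GFP signal and occupies
#' `mm3_per_cell` mm^3 (1 mm^3 is about 10^6 cells).
#'
#' @param signal_per_cell GFP relative units per cell.
#' @param mm3_per_cell mm^3 per cell.
#' @return An object of class `volume_units`.
#' @export
volume_units <- function(signal_per_cell = 7.96e-6, mm3_per_cell = 1e-6) {
  if (signal_per_cell <= 0 || mm3_per_cell <= 0)
    stop("unit factors must be strictly positive")
  structure(list(signal_per_cell = signal_per_cell,
                 mm3_per_cell = mm3_per_cell),
            class = "volume_units")
}

#' @rdname volume_units
#' @param v Signal value(s) to convert.
#' @param units A [volume_units()] object.
#' @export
signal_to_cells <- function(v, units) v / units$signal_per_cell

#' @rdname volume_units
#' @export
signal_to_mm3 <- function(v, units)
  v / units$signal_per_cell * units$mm3_per_cell

#' @rdname volume_units
#' @param mm3 Volume value(s) in mm^3 to convert.
#' @export
mm3_to_signal <- function(mm3, units)
  mm3 / units$mm3_per_cell * units$signal_per_cell

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Spawn deterministic sub-seeds from a master seed (for per-animal streams).
spawn_seeds <- function(seed, n)
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
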