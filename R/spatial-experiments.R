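## Experiment-level operations on the spatial model: focus placement,
## interaction/merging studies and Monte Carlo calibration.

# Area of a "one cell" focus: a disc with the diameter of a lung capillary
# (20 micrometres), in mm^2.
one_cell_area_mm2 <- function() pi * 0.01^2

#' Focus specifications and initial density fields
#'
#' A focus is a disc given by its centre (mm, domain coordinates) and
#' initial area (mm^2); `area_mm2 = NULL` means a "one cell" focus, a disc
#' with the 20-micrometre diameter of a lung capillary. `foci_field()`
#' rasterises a set of foci to a density matrix using a sub-cell smoothed
#' indicator (linear ramp over one grid cell), which keeps the integrated
#' mass accurate even for discs near the grid resolution.
#'
#' @param x_mm,y_mm Centre coordinates, mm.
#' @param area_mm2 Initial area, mm^2, or `NULL` for a one-cell focus.
#' @return `focus_spec()`: a one-row data frame; `foci_field()`: a density
#'   matrix on `grid`.
#' @export
focus_spec <- function(x_mm, y_mm, area_mm2 = NULL) {
  if (is.null(area_mm2)) area_mm2 <- one_cell_area_mm2()
  stopifnot(area_mm2 > 0)
  data.frame(x_mm = x_mm, y_mm = y_mm, area_mm2 = area_mm2)
}

#' @rdname focus_spec
#' @param foci A data frame of focus specifications (rows from
#'   [focus_spec()] or [place_foci()]).
#' @param grid A [grid2d()] object.
#' @export
foci_field <- function(foci, grid) {
  P <- matrix(0, grid$n, grid$n)
  h <- grid$h
  for (i in seq_len(nrow(foci))) {
    cx <- foci$x_mm[i] / 10; cy <- foci$y_mm[i] / 10
    r <- sqrt(foci$area_mm2[i] / 100 / pi)            # cm
    if (cx - r < 0 || cx + r > grid$L || cy - r < 0 || cy + r > grid$L)
      stop("focus ", i, " does not fit inside the domain")
    if (r >= h) {
      D <- sqrt(outer((grid$x - cx)^2, (grid$x - cy)^2, "+"))
      Pf <- pmin(pmax((r - D) / h + 0.5, 0), 1)
      # rescale so the integrated mass matches the requested area exactly
      # (the ramp indicator alone carries an O(h/r) area error)
      target <- foci$area_mm2[i] / 100
      for (it in 1:5) {
        m <- sum(Pf) * h^2
        if (abs(m / target - 1) < 1e-12) break
        Pf <- pmin(Pf * (target / m), 1)
      }
      P <- P + Pf
    } else {
      # sub-grid focus (e.g. a one-cell germ): deposit its exact area onto
      # the four surrounding nodes with bilinear weights, so the integrated
      # mass is preserved regardless of where the centre falls
      fx <- cx / h; fy <- cy / h
      ix <- floor(fx); iy <- floor(fy)
      wx <- fx - ix; wy <- fy - iy
      amount <- foci$area_mm2[i] / 100 / h^2          # density units
      for (dx in 0:1) for (dy in 0:1) {
        ii <- ix + dx; jj <- iy + dy
        if (ii >= 1 && ii <= grid$n && jj >= 1 && jj <= grid$n) {
          w <- (if (dx == 1) wx else 1 - wx) * (if (dy == 1) wy else 1 - wy)
          P[ii, jj] <- P[ii, jj] + amount * w
        }
      }
    }
  }
  pmin(P, 1)
}

#' Random placement of metastatic foci
#'
#' Dart-throwing rejection sampling of focus centres: candidates are drawn
#' uniformly in a disc around the domain centre and accepted when at least
#' `min_dist_mm` (centre-to-centre) from all previously accepted foci. The
#' sampling region defaults to the smallest disc that packs `n` points at
#' that spacing with a comfortable margin, so the foci form a compact
#' cluster able to merge; it never approaches the domain boundary closer
#' than `margin_mm`.
#'
#' @param n Number of foci.
#' @param min_dist_mm Minimal centre-to-centre distance, mm.
#' @param grid A [grid2d()] object (defines the domain).
#' @param seed Optional integer seed; placement is deterministic under a
#'   fixed seed.
#' @param area_mm2 Per-focus initial area (mm^2); `NULL` for one-cell foci.
#' @param region_radius_mm Radius of the sampling disc; default derived
#'   from hexagonal packing of `n` points at `min_dist_mm`.
#' @param margin_mm Safety margin to the domain boundary, mm.
#' @param max_attempts Attempts before giving up with an error.
#' @return A foci data frame (`x_mm`, `y_mm`, `area_mm2`).
#' @export
place_foci <- function(n, min_dist_mm, grid = grid2d(), seed = NULL,
                       area_mm2 = NULL, region_radius_mm = NULL,
                       margin_mm = 1, max_attempts = 100000L) {
  stopifnot(n >= 1, min_dist_mm >= 0)
  if (is.null(area_mm2)) area_mm2 <- one_cell_area_mm2()
  r_focus <- sqrt(area_mm2 / pi)
  if (is.null(region_radius_mm))
    region_radius_mm <- max(1.5 * min_dist_mm * sqrt(n * sqrt(3) / (2 * pi)),
                            min_dist_mm)
  centre <- grid$length_mm / 2
  if (centre - region_radius_mm - r_focus < margin_mm)
    stop("foci do not fit: sampling region reaches the boundary margin; ",
         "enlarge the domain or reduce n")
  xs <- numeric(0); ys <- numeric(0)
  with_seed(seed, {
    attempts <- 0L
    while (length(xs) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n, " foci at spacing ", min_dist_mm,
             " mm after ", max_attempts, " attempts; enlarge the domain or ",
             "the sampling region")
      rr <- region_radius_mm * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      cx <- centre + rr * cos(th); cy <- centre + rr * sin(th)
      if (length(xs) && min((xs - cx)^2 + (ys - cy)^2) < min_dist_mm^2) next
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  })
  data.frame(x_mm = xs, y_mm = ys, area_mm2 = area_mm2)
}

# Deterministic compact hexagonal cluster of n centres with the given
# centre-to-centre spacing, around the domain centre.
hex_cluster <- function(n, spacing_mm, grid) {
  k <- ceiling(sqrt(n)) + 2
  ij <- expand.grid(i = -k:k, j = -k:k)
  x <- spacing_mm * (ij$i + 0.5 * (ij$j %% 2))
  y <- spacing_mm * ij$j * sqrt(3) / 2
  ord <- order(x^2 + y^2)
  centre <- grid$length_mm / 2
  data.frame(x_mm = centre + x[ord][seq_len(n)],
             y_mm = centre + y[ord][seq_len(n)])
}

#' Burden loss caused by the mechanical interaction of two foci
#'
#' Simulates (i) two foci whose boundaries are initially `distance_mm`
#' apart and (ii) one identical focus alone, whose final burden doubled
#' gives the independent-growth reference, and returns the relative loss
#' `100 * (M_indep - M_inter) / M_indep` of the final 2D burden at time
#' `T`. The separation is measured edge-to-edge, so `distance_mm = 0` means
#' two initially touching (immediately merging) discs; the loss then
#' approaches the deficit of a single tumour of the summed area, and it
#' vanishes as the separation grows beyond the interaction range.
#'
#' @param sp A [spatial_params()] object.
#' @param distance_mm Initial edge-to-edge separation of the two foci, mm.
#' @param per_focus_area_mm2 Initial area of each focus, mm^2.
#' @param T_days Final time, days.
#' @param grid A [grid2d()] object.
#' @param dt_max,cfl Time-stepping controls passed to [simulate_spatial()].
#' @return Loss in percent, with attributes `M_inter_mm2` and
#'   `M_indep_mm2`.
#' @export
interaction_loss <- function(sp, distance_mm, per_focus_area_mm2 = 0.46,
                             T_days = 7, grid = grid2d(), dt_max = 0.1,
                             cfl = 0.4) {
  r_mm <- sqrt(per_focus_area_mm2 / pi)
  half <- r_mm + distance_mm / 2
  c0 <- grid$length_mm / 2
  two <- rbind(focus_spec(c0 - half, c0, per_focus_area_mm2),
               focus_spec(c0 + half, c0, per_focus_area_mm2))
  one <- focus_spec(c0, c0, per_focus_area_mm2)
  run <- function(foci)
    simulate_spatial(foci_field(foci, grid), sp, grid, T_days,
                     dt_max = dt_max, cfl = cfl, record_times = T_days)
  M_inter <- tumour_mass(run(two)$P, grid)
  M_indep <- 2 * tumour_mass(run(one)$P, grid)
  out <- 100 * (M_indep - M_inter) / M_indep
  attr(out, "M_inter_mm2") <- M_inter
  attr(out, "M_indep_mm2") <- M_indep
  out
}

#' Burden loss for a cluster of interacting foci (fractionation study)
#'
#' A fixed total initial burden is split over `n_foci` equal discs arranged
#' as a compact hexagonal cluster with edge-to-edge spacing `distance_mm`;
#' the final 2D burden is compared with `n_foci` independent copies of a
#' single such disc.
#'
#' @param sp A [spatial_params()] object.
#' @param n_foci Number of foci sharing the initial burden.
#' @param total_area_mm2 Total initial area, mm^2.
#' @param distance_mm Edge-to-edge spacing within the cluster, mm.
#' @param T_days Final time, days.
#' @param grid A [grid2d()] object.
#' @param dt_max,cfl Time-stepping controls.
#' @return Loss in percent with attributes `M_inter_mm2`, `M_indep_mm2`.
#' @export
fractionation_loss <- function(sp, n_foci, total_area_mm2 = 0.92,
                               distance_mm = 0.2, T_days = 7,
                               grid = grid2d(), dt_max = 0.1, cfl = 0.4) {
  stopifnot(n_foci >= 1)
  area <- total_area_mm2 / n_foci
  r_mm <- sqrt(area / pi)
  centres <- hex_cluster(n_foci, 2 * r_mm + distance_mm, grid)
  cluster <- focus_spec(centres$x_mm, centres$y_mm, area)
  single <- focus_spec(grid$length_mm / 2, grid$length_mm / 2, area)
  run <- function(foci)
    simulate_spatial(foci_field(foci, grid), sp, grid, T_days,
                     dt_max = dt_max, cfl = cfl, record_times = T_days)
  M_inter <- tumour_mass(run(cluster)$P, grid)
  M_indep <- n_foci * tumour_mass(run(single)$P, grid)
  out <- 100 * (M_indep - M_inter) / M_indep
  attr(out, "M_inter_mm2") <- M_inter
  attr(out, "M_indep_mm2") <- M_indep
  out
}

#' Number of one-cell foci required to reach a target volume
#'
#' How many merging metastatic germs, each starting from one cell, are
#' needed so that their combined volume reaches `target_volume_mm3` after
#' `T_days` of growth. In the non-interacting mode the answer is the
#' smallest `N` with `N * V_single(T) >= target`, where `V_single` is the
#' 3D-converted final volume of a single one-cell focus. In the interacting
#' mode the cluster is simulated in full (foci placed randomly at
#' `spacing_mm` centre-to-centre, pressure interactions included) and the
#' smallest sufficient `N` is found by bisection, using that the final
#' burden increases with `N`. Interactions slow growth, so the interacting
#' count is at least the non-interacting one.
#'
#' @param target_volume_mm3 Target 3D volume, mm^3.
#' @param sp A [spatial_params()] object.
#' @param T_days Growth duration, days.
#' @param interacting Include pressure interactions (full simulation)?
#' @param grid A [grid2d()] object.
#' @param seed Seed for the random placement (interacting mode).
#' @param spacing_mm Centre-to-centre spacing of the placed germs, mm.
#' @param n_max Upper bound on the search.
#' @param dt_max,cfl Time-stepping controls.
#' @return The required count (integer), with attribute `V_single_mm3`.
#' @export
required_foci <- function(target_volume_mm3, sp, T_days = 7,
                          interacting = FALSE, grid = grid2d(), seed = NULL,
                          spacing_mm = 0.05, n_max = 4096L, dt_max = 0.1,
                          cfl = 0.4) {
  stopifnot(target_volume_mm3 > 0)
  c0 <- grid$length_mm / 2
  single <- simulate_spatial(foci_field(focus_spec(c0, c0), grid), sp, grid,
                             T_days, dt_max = dt_max, cfl = cfl,
                             record_times = T_days)
  V_single <- area_to_volume_3d(tumour_mass(single$P, grid))
  n_indep <- max(1L, as.integer(ceiling(target_volume_mm3 / V_single)))
  if (!interacting) {
    out <- n_indep
    attr(out, "V_single_mm3") <- V_single
    return(out)
  }
  if (n_indep > n_max)
    stop("target not reachable with n_max foci")
  vol_n <- function(N) {
    foci <- place_foci(N, spacing_mm, grid, seed = seed)
    area_to_volume_3d(tumour_mass(
      simulate_spatial(foci_field(foci, grid), sp, grid, T_days,
                       dt_max = dt_max, cfl = cfl,
                       record_times = T_days)$P, grid))
  }
  lo <- n_indep                      # interacting growth is never faster
  if (vol_n(lo) >= target_volume_mm3) {
    out <- lo; attr(out, "V_single_mm3") <- V_single; return(out)
  }
  hi <- lo
  repeat {
    hi <- min(2L * hi, n_max)
    if (vol_n(hi) >= target_volume_mm3) break
    if (hi >= n_max) stop("target not reachable with n_max interacting foci")
  }
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (vol_n(mid) >= target_volume_mm3) hi <- mid else lo <- mid
  }
  out <- hi
  attr(out, "V_single_mm3") <- V_single
  out
}

#' Monte Carlo calibration of the spatial model on a volume series
#'
#' Samples `(gamma0, pi0)` uniformly in `bounds`, simulates a disc tumour
#' started from the first observed volume (spherical-symmetry conversion)
#' and scores each sample by the sum of squared relative volume errors at
#' the observation days; returns the best-scoring sample.
#'
#' @param series Data frame with columns `day` and `volume_mm3` (>= 2 rows,
#'   increasing days).
#' @param bounds List with ranges `gamma0 = c(lo, hi)` and
#'   `pi0 = c(lo, hi)`.
#' @param n_samples Number of Monte Carlo samples.
#' @param seed Optional integer seed (deterministic given the seed).
#' @param grid A [grid2d()] object.
#' @param dt_max,cfl Time-stepping controls.
#' @return The best [spatial_params()], with attributes `score` and
#'   `samples` (a data frame of all candidates and their scores).
#' @export
calibrate_mc <- function(series, bounds = list(gamma0 = c(0.3, 1.5),
                                               pi0 = c(2e-4, 5e-3)),
                         n_samples = 40, seed = NULL, grid = grid2d(),
                         dt_max = 0.1, cfl = 0.4) {
  stopifnot(is.data.frame(series), nrow(series) >= 2,
            all(diff(series$day) > 0), all(series$volume_mm3 > 0))
  cand <- with_seed(seed, data.frame(
    gamma0 = stats::runif(n_samples, bounds$gamma0[1], bounds$gamma0[2]),
    pi0 = stats::runif(n_samples, bounds$pi0[1], bounds$pi0[2])))
  c0 <- grid$length_mm / 2
  P0 <- foci_field(focus_spec(c0, c0, volume_3d_to_area(series$volume_mm3[1])),
                   grid)
  tobs <- series$day - series$day[1]
  score_one <- function(g0, p0) {
    sim <- simulate_spatial(P0, spatial_params(g0, p0), grid,
                            t_end = max(tobs), dt_max = dt_max, cfl = cfl,
                            record_times = tobs[tobs > 0])
    v <- area_to_volume_3d(stats::approx(sim$series$t, sim$series$mass_mm2,
                                         xout = tobs, rule = 2)$y)
    sum(((v - series$volume_mm3) / series$volume_mm3)^2)
  }
  cand$score <- mapply(score_one, cand$gamma0, cand$pi0)
  best <- which.min(cand$score)
  out <- spatial_params(cand$gamma0[best], cand$pi0[best])
  attr(out, "score") <- cand$score[best]
  attr(out, "samples") <- cand
  out
}

#' Parameter sets fitted to the four individually followed metastases
#'
#' The four `(gamma0, pi0)` pairs obtained by calibrating the spatial model
#' to the volume dynamics of four individual lung metastases followed on
#' MRI, together with their observed day-19 volumes (mm^3). These sets span
#' the calibration box `(0.67, 1.01) x (5.2e-4, 2.6e-3)` used by the
#' interaction studies.
#'
#' @return A data frame with columns `name`, `gamma0`, `pi0` and
#'   `observed_volume_mm3`.
#' @export
calibrated_spatial_params <- function() {
  data.frame(name = paste0("meta", 1:4),
             gamma0 = c(0.78, 1.01, 0.67, 0.8),
             pi0 = c(0.0026, 0.00079, 0.00067, 0.00052),
             observed_volume_mm3 = c(0.022, 0.046, 0.085, 0.67))
}
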