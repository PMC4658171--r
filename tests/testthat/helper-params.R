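# Canonical parameter sets used across the suite: the fitted population
# medians for the dissemination model and the calibrated spatial sets.
fitted_growth <- function() gomp_exp_params()
fitted_dissemination <- function() dissemination_params()
fitted_units <- function() volume_units()

# A small, fast spatial configuration for PDE properties (coarse grid,
# short horizon); quantitative accuracy checks use finer settings locally.
coarse_grid <- function(n = 64) grid2d(n)

# Random Gomp-Exp parameter draws in a physiological range, for
# property-style loops.
random_growth_params <- function() {
  gomp_exp_params(lambda = stats::runif(1, 0.4, 0.9),
                  alpha = stats::runif(1, 0.25, 0.6),
                  beta = stats::runif(1, 0.06, 0.16),
                  v_inj = stats::runif(1, 0.3, 1.5))
}
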