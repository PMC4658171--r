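---
title: "Two models of metastatic colonization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two models of metastatic colonization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metaburden)
```

This package implements two complementary mathematical models of metastatic
colonization in an orthotopic renal cell carcinoma system (GFP-tagged RENCA
cells implanted under the kidney capsule of mice, metastasizing to the
lungs), together with the estimators, synthetic-data generators and
experiment drivers needed to run the whole analysis end to end without any
animal data.

## 1. The size-structured dissemination-and-growth model

The "standard theory" of metastatic colonization assumes that secondary
tumours, once seeded, grow independently of each other and of the primary
tumour. We formalise it with a transport equation for the size density
$\rho(t,v)$ of metastases of size $v$ at time $t$:

$$\partial_t \rho + \partial_v(g(v)\rho) = 0, \qquad
  g(V_0)\,\rho(t,V_0) = d(V_p(t)), \qquad \rho(0,v)=0,$$

where the primary tumour $V_p$ solves $V_p' = g(V_p)$, $V_p(0)=V_{inj}$.
Growth follows the Gomp-Exp law
$g(v) = \min\{\lambda v,\ (\alpha-\beta\log v)v\}$: exponential at the
in-vitro rate $\lambda$ until the Gompertz branch becomes slower, Gompertz
afterwards. Dissemination follows $d(V_p) = \mu V_p^{\gamma}$ with
$\gamma = 1$ by default (emission proportional to tumour volume; $\gamma$
is not identifiable from burden data and is exposed as a sensitivity knob).

**Units.** All model-internal sizes are relative units of GFP signal; one
cell is $V_0 = 7.96\times10^{-6}$ units (derived from the fitted inoculum
signal and the $10^5$ injected cells) and 1 mm$^3$ is $10^6$ cells.
`volume_units()` performs these conversions at reporting boundaries only,
mirroring how the calibration was performed. The emission coefficient
$\mu$ is per cell and per day, so the primary size is converted to cells
before the power law -- the only dimensionally consistent reading of the
published unit.

**Closed forms.** Because the growth law is autonomous and monotone, the
characteristics are available in closed form (`volume_at()`,
`time_to_reach()`), and every observable reduces to one-dimensional
integrals of the emission intensity: the total burden
$M(t) = \int_0^t d(V_p(s))\,V_{met}(t-s)\,ds$ (a convolution, evaluated
for all grid times at once via FFT with trapezoid end corrections, grid
step 0.05 day -- small enough that $\lambda\,dt < 0.035$ resolves the
exponential phase; an adaptive-quadrature path is kept as the slow oracle
and the two agree to $10^{-4}$ relative), the expected count above a
threshold, and the density itself by the method of characteristics.

**Stochastic layer.** A virtual animal is an inhomogeneous Poisson process
of emission times with intensity $d(V_p(s))$, each metastasis growing
deterministically from $V_0$. Sampling uses interval-wise thinning with
daily bounds: the intensity is nondecreasing, so the right-endpoint rate
bounds each day, and the candidate count stays proportional to the true
count (tail animals legitimately emit $10^5$--$10^6$ metastases; a global
bound would inflate memory an order of magnitude). Inter-animal
variability draws $(\alpha, \beta, \mu)$ independently from lognormal laws
given by median and CV, where CV is the standard deviation of the
lognormal distribution divided by its median (the convention of the
published population fit), i.e.
$\sigma^2 = \log\big((1+\sqrt{1+4c^2})/2\big)$ for $c = CV/100$.
$\lambda$ carries no random effect (it is printed without a spread), and
metastases share the primary's growth parameters.

**A caveat on tail-sensitive metrics.** The day-26 mean macro-metastasis
count and mean largest lesion are heavy-tailed functionals of
$\exp(\alpha/\beta)$. Under *independent* lognormal draws at the fitted
medians and CVs, the exact expectation of the macro count is about 110
with a population sd near 170, and the mean largest lesion about 1.8--2.2
mm$^3$. The published simulation reports 95.4 (sd 47) and 1.14 (sd 0.755):
a visibly tighter joint distribution, consistent with correlated
$\alpha,\beta$ random effects that a mixed-effects estimator would
naturally produce but whose correlations are not reported. We assume
independence (the only reproducible choice) and document the difference
rather than calibrating toward the printed numbers; the deterministic
largest lesion of the median-parameter animal (0.97 mm$^3$), which carries
no tail sensitivity, is within 15% of the printed mean. The scientific
conclusion is unaffected: the model predicts on the order of a hundred
small visible lesions where imaging shows about ten, some of them tenfold
larger than anything the model produces.

**"Largest metastasis" conventions.** A continuum density has no largest
element, so two conventions are provided: the deterministic convention
(the characteristic carrying the first whole emitted metastasis,
`largest_size_deterministic()`) and the stochastic convention (maximum
over a Poisson realisation). Population summaries use the stochastic
simulator with 1000 animals, matching the published simulation size; the
two conventions agree within a factor of ~1.5 in expectation.

## 2. The population fit

Each animal contributes a kidney signal (primary tumour) and a lung signal
(total metastatic burden) at a single sacrifice day. Preprocessing removes
lung rows before day 10 (early lung GFP is background noise, not tumour)
and explicitly flagged technical outliers; kidney rows are never dropped.

The residual model is additive Gaussian on log signal (signals are
positive and span four decades); the original fit does not state its error
model, and this is the natural choice for such data. Calibration is
two-stage, as in the original analysis: first the primary trajectory alone
with the inoculum signal free (`fit_primary_vinj()`), giving $V_0$ by
proportionality with the $10^5$ injected cells; then the joint fit of both
organs (`fit_joint()`).

The original stochastic-approximation EM machinery is not replicated (the
contribution is the model, not the estimator). Two documented estimators
stand in for it:

* **pooled** -- Levenberg--Marquardt least squares on all log signals
  jointly, treating the cohort as one curve. Bias is below 10% at zero
  noise; it initialises the mixed mode.
* **mixed** -- an EM-style population estimator: per-animal MAP fits of
  $(\log\alpha,\log\beta,\log\mu)$ under the current lognormal population
  law, alternated with exact updates of the population log-medians and
  log-sds. The variance update adds the Laplace posterior variance of
  each animal's parameters (diagonal of the inverse MAP Hessian) to the
  spread of the MAP points -- the EM sufficient statistic
  $E[(\eta-m)^2] = (\hat\eta-m)^2 + \mathrm{Var}_{post}$ -- which prevents
  the degenerate shrinkage a plain MAP-EM suffers when an animal has
  fewer observations than parameters. With at most two observations per
  animal the residual scale is not separately identifiable and is held
  fixed at the pooled estimate. A Q-style objective is tracked and
  decreases monotonically; non-convergence is reported as a diagnostic
  flag, never silently.

Adequacy is defined by recovery tests against the synthetic generator's
sidecar truth: medians within 25% at cohort-scale noise (n = 31, log-sd
0.3), CVs within a factor two of the realised per-animal spread and in the
right order, exact recovery (optimizer tolerance) at zero noise.

## 3. The pressure-mediated spatial model

The second model asks what the independent-growth theory ignores: lungs
are space-limited, neighbouring lesions push on each other, and merging is
observed. Tumour tissue (density $P$) and healthy tissue ($S = 1-P$,
saturation) move with a common Darcy velocity $v = -k\nabla\Pi$ driven by
proliferation:

$$\partial_t P + \nabla\cdot(vP) = \gamma(\Pi)P, \qquad
  \nabla\cdot v = \gamma(\Pi) P, \qquad
  -k\Delta\Pi = \gamma(\Pi)P,\ \ \Pi|_{\partial\Omega} = \Pi_{eq},$$

with pressure-inhibited proliferation
$\gamma(\Pi) = \gamma_0 e^{-\Pi/\Pi_0}$. We fix $k = 1$ (only $k\Pi_0$
matters) and $\Pi_{eq} = 0$ (homeostatic pressure is optimal for
proliferation; high pressure slows proliferation but causes no death).
The domain is a 1 cm square (the scale of mouse lungs), far enough from
the lesions that the Dirichlet condition is a homeostatic far field.

**Numerics.** Strang splitting advances reaction(dt/2) -> advection(dt) ->
reaction(dt/2). The reaction half-steps are exact exponentials capped at
saturation. Advection is conservative fifth-order WENO finite differences
with global Lax--Friedrichs flux splitting, advanced by a three-stage SSP
Runge--Kutta substep with the pressure re-solved at every stage; the CFL
number is 0.4 with automatic sub-stepping, and the step is additionally
capped at 0.1 day for splitting accuracy. The WENO kernel is the package's
only compiled code.

The nonlinear pressure equation is solved by Newton iteration: the
Jacobian $A + \mathrm{diag}(\gamma_0/\Pi_0\,e^{-\Pi/\Pi_0}P)$ is symmetric
positive definite, factorised by sparse Cholesky, reused across stages and
refreshed automatically when convergence stalls (with a residual check
guarding against accepting a stale factorisation); tolerance $10^{-8}$ on
the relative update. The plain fixed point
$\Pi \leftarrow (-\Delta)^{-1}\gamma(\Pi)P$ with 0.5 damping under
oscillation is kept as `method = "picard"` and cross-checked against
Newton in the tests, but it loses contractivity once $\Pi > \Pi_0$ (we
observed 2-cycles at late times), which is why Newton is the default.

**Bounds and conservation.** Plain WENO5 overshoots a moving saturated
front by about $10^{-4}$--$10^{-3}$ (a bound-preserving limiter would
remove this but is not part of the scheme family used here). Undershoots
are clipped every step; small supersaturated excursions are left in place
during a run (the reaction never amplifies them) and clipped once in the
returned field, with the largest excursion recorded in every result
(`saturation_violation`) rather than hidden. Advection conserves mass to
round-off ($\gamma_0 = 0$ is exactly static). Saturated fronts carry an
additional $O(h/r)$ growth deficit: the two reaction half-steps adjacent
across a step boundary act without advective drainage in between, so
cells in the thin band just below saturation lose part of their growth,
of order a percent of total growth per e-fold of mass at the 128$^2$
study resolution. This cancels almost entirely in the
interaction studies (ratios of two equally affected runs; the convergence
numbers below include it). The clean identities are verified where they
are exact: with inhibition off ($\Pi_0\to\infty$) and an *unsaturated*
initial density (which approaches 1 only logistically, so the cap never
engages over 7 days) the total mass tracks $e^{\gamma_0 t}$ to better
than 1%, and the per-step mass budget
$d/dt \int P = \int \gamma(\Pi) P$ holds to 1% against a trapezoid source
estimate on a resolved, partially saturated field.

**Initial conditions.** Foci are discs. Resolvable discs use a sub-cell
linear ramp rescaled so the integrated mass equals the requested area
exactly (the raw ramp carries an $O(h/r)$ area error which otherwise
pollutes calibration: the error would enter twice, once in a generated
observation and once in its reconstruction). Discs below the grid spacing
-- in particular "one cell" germs, discs with the 20 um diameter of a lung
capillary -- are deposited bilinearly onto the four surrounding nodes with
exact mass, so a germ never vanishes between nodes. 2D masses convert to
3D volumes under spherical symmetry ($r = \sqrt{A/\pi}$,
$V = \tfrac43\pi r^3$) only where results are reported in mm$^3$;
interaction studies compare 2D masses directly.

**Distance convention.** The initial distance between two foci is their
edge-to-edge separation. Two 0.46 mm$^2$ discs (radius 0.38 mm) cannot
have centres 0.2 mm apart without heavy overlap, and the distance-to-zero
limit of the interaction study -- the burden of a *single* tumour with the
*summed* initial surface -- only makes sense for touching discs. Germ
clusters for the merging study use centre spacing = germ diameter + gap.

**Resolutions.** The interaction studies run on a 128$^2$ grid (default
for `run_interaction_grid()`). The test suite verifies grid convergence
at that resolution: the final mass of a single-focus 7-day run at the
centre of the calibrated box changes by less than 2% when the spacing is
halved to 256$^2$, and since the interaction loss is a ratio of two such
runs its discretisation error largely cancels. Exported defaults
elsewhere use 256$^2$ where accuracy is the point and coarser grids in
tests where only structure (symmetry, monotonicity, limits) is at stake.

## 4. Calibration of the spatial model

`calibrate_mc()` samples $(\gamma_0, \Pi_0)$ uniformly in a bounding box,
simulates a disc tumour from the first observed volume and scores the sum
of squared relative volume errors at the observation days, returning the
best sample -- deliberately simple, matching how the four individually
followed metastases were fitted (volumes only, spherical shapes; high
accuracy was neither possible nor needed given segmentation error). The
four resulting parameter sets span the box
$(0.67, 1.01) \times (5.2\times10^{-4}, 2.6\times10^{-3})$ used by the
interaction grid; `calibrated_spatial_params()` returns them together
with the observed day-19 volumes (0.022, 0.046, 0.085, 0.67 mm$^3$). The
pairing of parameter sets with observed volumes follows listing order and
is uncertain; analyses that depend on the pairing evaluate all consistent
assignments. Identifiability is ridge-like (a lower $\gamma_0$ trades
against a higher $\Pi_0$ over a one-decade volume range), so recovery to
15% needs the mass-exact initial discs described above; with them, 40
samples at 64$^2$ recover (0.78, 0.0026) from a 1%-noise series within
15% on both parameters.

## 5. The experiments

* `run_standard_theory_prediction()` -- 1000 virtual animals, summaries of
  the macro-metastasis size distribution at days 19/21/24/26.
* `run_interaction_grid()` -- the two-focus loss
  $100(M_{indep}-M_{inter})/M_{indep}$ at $T = 7$ days (the time scale of
  the four observed metastatic growths), averaged over an $8\times8$
  discretisation of the calibrated box; two foci of 0.46 mm$^2$ at 0.2 mm
  separation. At 128$^2$ this gives a mean loss of 27.3% (sd 2.2) against
  the published 31% +- 1.5%; the few-point gap is within the combined
  grid-resolution and convention uncertainty documented above.
* `fractionation_loss()` -- a fixed 0.92 mm$^2$ burden split over $n$
  interacting foci versus $n$ independent ones; the loss grows with $n$
  (76.7% at $n = 18$ versus the published 76.3%).
* `run_merging_study()` / `required_foci()` -- how many one-cell germs
  must merge to reach the observed day-19 volumes in 7 days, without
  interactions (volumes add) and with them (full simulation, bisection on
  the count, which is monotone in the final burden).

**Known limitation (merging counts).** The published required-germ counts
(1337/20/301/40 without interactions) imply a single-germ 3D volume growth
of only ~4x in 7 days. In the stated model a one-cell germ exerts a
pressure of order $10^{-5}$, far below every calibrated $\Pi_0$, so it
must grow essentially at $\gamma_0$ (about 200x in 2D area at
$\gamma_0=0.78$); our non-interacting counts are accordingly 10--20x
smaller (2/2/23/69 under the row pairing). No parameter set in the
calibrated box can reproduce the published counts from the stated
equations; we report ours, verify the robust qualitative pattern
(interacting counts always at least the independent ones; fractionation
loss increasing with the count), and flag the quantitative row as not
reproducible from the published description. The published conversion of
200 2D germs to "2127 cells in 3D" ($N_{3D} = \tfrac{4}{3\sqrt\pi}
N_{2D}^{3/2}$) shows the published counts mix 2D and 3D conventions,
which may account for part of the gap.

## 6. Synthetic data

The generators emulate the study's data structure, not its biology-free
details: one sacrifice day per animal (31 animals over days 0--26, denser
after day 10), kidney = primary signal, lung = max(burden, background)
with multiplicative lognormal noise. Unmeasured quantities were fixed
once: background floor lognormal around $10^{-3}$ signal units (two
decades below late lung signals, reproducing a flat early-lung baseline),
residual log-sd 0.3 (a moderate assay noise consistent with
decade-spanning data). Every generator returns its ground truth and can
write it as a JSON sidecar; all recovery tests read the sidecar rather
than hard-coding truths. What passing recovery tests show is internal
consistency -- the estimators recover the generator's truth under the
generator's noise model; they cannot certify the error model of the real
qPCR assay, the MRI segmentation error, or biological deviations from
lognormal variability.

## 7. Problem sizes used by the checks

The acceptance computations use 1000 simulated animals for the population
prediction, the full $8\times8$ parameter grid at 128$^2$ for the
interaction study, and single runs at 128$^2$ for the fractionation and
merging checks; property-style tests run on 48$^2$--64$^2$ grids and
shortened horizons where only structural properties are asserted. These
sizes are the package's own accuracy/runtime trade-off: each is backed by
a convergence or agreement check (grid refinement for the PDE, FFT vs
quadrature for the burden, Monte Carlo standard errors for the stochastic
layers) showing the quantity of interest is stable at the size used.
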