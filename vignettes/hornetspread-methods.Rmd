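---
title: "Modelling Vespa velutina invasion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Vespa velutina invasion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hornetspread)
```

## The model

`hornetspread` simulates the annual colony cycle of the yellow-legged
(Asian) hornet *Vespa velutina* after an incursion into a temperate
landscape such as Great Britain. Each active nest, once per year, produces
a number of daughter queens that survive hibernation and found a nest the
following spring; all other colony members, and the nest itself, die. The
daughter count is Poisson with mean

$$\mu(x) \;=\; \sigma \, R_A \; L(\mathrm{lat}(x)) \; g(n(x)),$$

where

* $R_A$ is the mean number of successful daughter queens for a
  low-density nest at the Andernos-les-Bains reference latitude
  (44.74°N), the best-observed European invasion site. Default
  $R_A = 8.7$: the value implied by an expected 3.3 daughters at 38% of
  baseline potential (see *Defaults* below).
* $L$ is a linear latitude cline,
  $L(\ell) = \mathrm{clamp}\!\left(\frac{\ell_0 - \ell}{\ell_0 - \ell_A},
  0, 1\right)$, encoding colder climate with latitude: reproduction
  reaches zero at $\ell_0 = 55.9$°N (northern England) and is 1 at
  $\ell_A = 44.74$°N. The clamp at 1 forbids super-baseline reproduction
  south of the reference — a deliberately conservative extrapolation.
* $g$ is density-dependent competition. The functional form is not
  identifiable from the headline observations, so the package defaults to
  hyperbolic saturation $g(n) = 1/(1 + n/K_{1/2})$ with an exponential
  alternative ($e^{-n/K_{1/2}}$) selectable; both are monotone and equal
  1 at $n = 0$, so all low-density results are unaffected by the choice.
  $n(x)$ counts other active nests within the competition radius $r_c$ of
  the mother nest, among the same year's nests, evaluated simultaneously
  before any reproduction (so results are independent of update order).
* $\sigma$ is a global scaling used by sensitivity analyses (1 = the
  baseline).
* $\mu = 0$ on water.

Queens disperse with an exponentially distributed distance (mean
$\delta = 28$ km, calibrated to reported invasion wave speeds of 67–82
km/year) and a uniform direction. Settlement is habitat-weighted
rejection sampling: a candidate destination is accepted with probability
$w(\mathrm{class})/\max w$, with default weights urban 1.0, agricultural
1.0, woodland 0.5, other 0.25 and water 0 (urban and agricultural terrain
preferred). A rejected queen re-draws her *entire* displacement, up to
`max_attempts = 20` times, and founds no nest if all attempts fail.
Re-drawing (rather than snapping to the nearest suitable cell) preserves
the exponential marginal distance distribution on homogeneous landscapes.
With 20 attempts the failure mass $(1-A)^{20}$ is negligible except for
origins almost entirely surrounded by water, so habitat preference
reshapes *where* queens settle far more than *how many* settle.

### Defaults derived from the headline numbers

Two demographic defaults are back-derived rather than directly observed:
$\ell_0 = 55.9$°N inverts the statement that a nest at the Tetbury
latitude (51.64°N) realises approximately 38% of baseline potential, and
$R_A = 8.7 = 3.3/0.38$ inverts the expected 3.3 daughter nests of the
2015 GB founder. Both are ordinary parameters and can be overridden,
e.g. from a table of posterior draws (`read_posterior_draws()`), which
the replicate engine samples per replicate.

$K_{1/2}$ and $r_c$ are not identifiable from the headline numbers
either. The defaults $K_{1/2} = 50$ nests within $r_c = 5$ km were fixed
once on realism grounds: they give an equilibrium density of about 4.9
nests/km² at the French baseline and roughly 150,000 nests at GB
carrying capacity — consistent with a rapidly saturating invasion that
exceeds 50,000 nests within a decade and peaks at several nests per km²
in the most favourable regions.

## Landscapes

Rasters use projected kilometres, cell centres for all kernel
computations, and an affine latitude frame
(`lat = lat_origin + northing/111`), which preserves the only geographic
property the demography uses — a linear north–south gradient. I/O is the
plain ESRI ASCII grid dialect; five habitat classes (urban,
agricultural, woodland, other, water) are the minimal set supporting the
preference structure, and real land-cover products must be remapped onto
them by the user.

`generate_landscape()` builds synthetic coastal landscapes: Gaussian-
smoothed noise fields thresholded at exact quantiles (so realised class
proportions match their targets to within rounding), plus a ragged water
margin along the south-west edges for a coastline. It is a pure function
of its arguments and seed. `gb_landscape()` fixes one such landscape —
400 × 440 km, 30% water, latitude 50°N at its southern edge — as the
package's stand-in for south-western Great Britain, with the two 2016
sightings (`gb_sightings()`) placed 40 km apart at the Tetbury and North
Somerset latitudes. What the generator does **not** emulate: real
coastline topology (estuaries, peninsulas), the true Corine class
mosaic, and real spatial correlations between habitat and latitude.
Quantities that depend on the detailed geography around the Bristol
Channel — notably the year-2 intensity total and high-risk areas —
should therefore be read with a ±25% geography caveat, while
low-density local quantities (expected daughters, the undiscovered-nest
probability) are insensitive to it.

## The stochastic engine

`run_invasion()` iterates the annual cycle over a horizon (default 25
years; year 1 is the founding year) for many replicates. Replicate seeds
derive deterministically from the master seed, so any replicate is
reproducible in isolation; with posterior draws, each replicate also
draws its own parameters. Inside the engine the crowding count is
evaluated on the landscape raster — nests are binned into cells and
summed over a disc stencil of cell centres — which keeps saturated
simulations (millions of nests) linear in nest count; with 4-km cells
and $r_c = 5$ km the stencil area (80 km²) is within 2% of the exact
disc (78.5 km²). The exact Euclidean-disc count is exported as
`local_crowding()` for small collections and tests.

### Wave speed

The invasion front is summarised per year by the 97.5th percentile of
nest distance from the seed — robust to single long-distance outliers
while tracking the front. During establishment, however, the population
is still concentrated in an exponentially growing core, and this radius
percentile tracks the core rather than the advancing front; a regression
over the whole horizon therefore underestimates the asymptotic
(travelling-wave) speed substantially. `wave_speed()` consequently fits
only the last four qualifying years (years with ≥ 10 nests), and
`front_speed_experiment()` uses a 15-year horizon on a 2400-km
homogeneous constant-latitude (French-baseline) domain at 4-km cells:
year-on-year front increments stabilise from about year 11, several
dispersal lengths from the seed, and the front never reaches the domain
boundary. With $\delta = 28$ km and $\sigma = 1$ this yields a mean
front speed of ~74 km/year over 10 replicates, inside the reported
67–82 km/year range; `calibrate_delta()` exposes the inverse problem as
a bisection with a monotonicity check on the bracket.

## Control experiments

Detection operates once per year, before queen production: each active
nest is found independently with `p_detect`, each primary detection
triggers one radial search finding other nests within the radius with
probability `search_efficiency` (0.99 for thorough searches; 0.48
matches the fraction historically discovered in Andernos-les-Bains), and
found nests are destroyed before reproducing. Radial searches do not
chain by default — the simplest reading of a one-off thorough area
search — but chaining is a policy flag. `eradication_probability()`
stops replicates early once they exceed an escape threshold (default 500
active nests), beyond which stochastic extinction has negligible
probability for any supercritical parameterisation.
`time_to_colonisation()` treats repeated introductions as a Poisson
process whose invasions are controlled independently; colonisation is
the first invasion surviving to the horizon, and its mean waiting time
matches the geometric-thinning closed form $1/(r(1-e))$ (checked against
simulation in the test suite). New invasions seed at
suitability-weighted random locations, the least informative choice
consistent with the settlement model.

## Deterministic risk maps

All Figure-2-type quantities are computed directly from the
probabilistic rates, without simulation.

* **Founder posterior.** Each sighting is treated as a nest descended
  from the common 2015 founder by one dispersal event (a foraging
  hornet stands proxy for a nest at its location). The posterior over
  founder cells is settleability × the product of cell-integrated 2-D
  dispersal densities $f(d)/(2\pi d)$, normalised. The $d \to 0$
  singularity is integrated exactly over the cell's equal-area radius.
  No reproduction weighting is applied — the simplest likelihood, and
  the mode then lies on the segment between two equal sightings.
* **Intensity propagation.** At low density the expected-nest field
  obeys the linear map $\lambda'(y) = \sum_x \lambda(x)\,\mu_0(x)\,
  T(x \to y)$ with $T$ the discrete settlement kernel
  ($T(x\to y) = K(y-x)\,a(y)\,c(x)$, where $a$ is acceptance, $c$ the
  retry factor, and $\sum_y T + \text{fail} = 1$ exactly); the package
  evaluates it as an FFT convolution. Because daughter counts are
  Poisson, detection-and-destruction is a Poisson thinning: destroying
  the discovered Tetbury nest leaves the distribution of undiscovered
  nests unchanged, so no conditioning correction is needed.
* **High-risk contour.** Cells are ranked by intensity and the smallest
  prefix retained such that fewer than one nest (the budget) is expected
  outside it.
* **Extinction probability.** Near the extinction threshold densities
  are minimal, so density dependence is ignored and the lineage of a
  nest at $x$ dies out with probability solving the Poisson
  branching fixed point
  $q(x) = \exp\!\big(\mu_0(x)\,[\textstyle\sum_y T(x\to y) q(y) +
  \mathrm{fail}(x) - 1]\big)$, iterated from $q \equiv 0$ (monotone
  convergence to the minimal fixed point) with a $10^{-9}$ sup-norm
  stopping rule accelerated by a geometric-tail bound.

### The sensitivity sweep

Sensitivity analyses vary the reproductive potential and report, per
realised reproductive ratio at the founder-posterior mode, the expected
nests in years 1 and 2, the extinction probability and the high-risk
areas. Two parameterisations are offered. The default,
`vary = "multiplier"`, scales the cline's slope about its *fixed*
northern zero — algebraically a flat multiplier — so the whole map
becomes subcritical as the founder ratio shrinks and extinction is
certain in the small-ratio limit, the behaviour a GB-wide extinction
statement requires. The alternative, `vary = "cline"`, instead moves the
zero cline while pinning the Andernos end at 1; this keeps terrain south
of the founder relatively favourable even for tiny founder ratios and is
retained for exploring that asymmetric hypothesis. On the synthetic
landscape the two give nearly identical extinction thresholds (the far
south is mostly water), with `extinction_threshold()` reporting ~10% as
the largest ratio with $q \ge 0.99$ — of the same order as, though
slightly above, the reported 8%, the residual gap being attributable to
the stand-in geography and the back-derived $R_A$.

### Known limitation: the year-2 total

With the derived defaults, the 2017/2016 ratio of field totals is
bounded by the best per-nest net reproduction anywhere on the map
($R_A \cdot L(50°) \approx 4.6$), so from 3.3 expected 2016 nests the
model cannot reach a 2017 mean of ~17 (ratio 5.15) under *any*
geography: it predicts ~11–12. A two-generation mean of 17 given a
one-generation mean of 3.3 is, however, exactly what posterior parameter
uncertainty produces (by Jensen's inequality the mean of $\mu_1\mu_2$
across parameter draws exceeds the product of the mean generations).
The package's deterministic pipeline conditions on point parameters by
design; averaging `sensitivity_curves()` rows over a posterior table
reproduces the inflation when draws are available.

## Numerical choices

* Problem sizes: the risk-map pipeline runs at 2-km cells (the
  fixed-point sweeps at 8-km cells, where the 28-km kernel is still
  resolved ~3.5-fold); wave-speed runs use 4-km cells. These were chosen
  as the coarsest resolutions at which the respective kernels and
  contours are well resolved.
* The displacement kernel is midpoint-integrated at cell centres, its
  origin cell integrated exactly over the equal-area radius, and
  renormalised over its support (the analytic tail beyond any grid used
  here is below $10^{-9}$); probabilities plus failure mass then sum to
  1 exactly by the geometric retry identity.
* FFT convolutions pad to highly composite sizes; tiny negative
  round-off intensities are clamped to zero.
* Ties and degenerate inputs: all-water landscapes refuse seeding and
  always fail settlement; `which.max` tie-breaking on the posterior mode
  takes the first cell in column-major order (relevant only on exactly
  symmetric synthetic inputs); a zero posterior (unreachable
  observations) is an error rather than a silent uniform.
* Config files are YAML, flat sections mirroring the parameter
  constructors; every run writes a manifest (command, package version,
  seed, full config echo) sufficient to reproduce it.

## What the tests do and do not show

The test suite verifies internal consistency (stochastic settlement
versus the analytic kernel, simulated one-year means versus the linear
propagation, thinning invariance, the geometric colonisation-time law,
monotone eradication curves) and the headline quantities on the
synthetic landscape. Passing them shows the implementation is faithful
to the stated model and internally coherent — not that the model's
predictions hold on real GB geography, for which real rasters, the
posterior parameter table and real sighting records should be supplied.
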