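---
title: "Estimating the irrigation contribution to crop yield by ensemble-empirical fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the irrigation contribution to crop yield by ensemble-empirical fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irrigain)
```

## The quantity and the estimation problem

The package estimates the relative yield gain from irrigation on a
global latitude–longitude grid,

$$\Delta Y \;=\; \frac{Y_\mathrm{irrigated} - Y_\mathrm{rainfed}}{Y_\mathrm{irrigated}},$$

the fraction of attainable irrigated yield that is lost when a crop is
grown rainfed. The irrigated yield is the denominator deliberately:
rainfed yields can approach zero in arid cells, which would make the
more intuitive rainfed-relative ratio numerically unstable. $\Delta Y$
is stored as a fraction in $[0, 1)$ and reported in percentage points
(exact factors of 100).

Two independent lines of evidence exist for $\Delta Y$, with
complementary error structures:

* An **empirical climate-analogue (CA) estimator** reads attainable
  irrigated and rainfed yields off observed yield distributions within
  climate zones. It inherits real-world management and soil variation,
  so it is nearly unbiased in the mean, but its spatial pattern is
  noisy because the zoning collapses climate to two indices.
* A **process-model ensemble** of gridded crop simulations produces
  smooth, well-correlated spatial patterns but with large
  member-specific biases — global-mean estimates that differ by
  several-fold between members and collectively overshoot empirical
  values by roughly a factor of two.

The package fuses the two by **Bayesian model averaging (BMA)**: the
ensemble members are mixture components, the CA map is the observation,
and the posterior member weights are learned from the misfit between
each member and the observation.

## Bayesian model averaging

With member fields $M_i$ and observation $O$ on a common grid, the
likelihood is a Gaussian mixture with member-specific means and one
shared scale $\sigma$:

$$\log L(w, \sigma) \;=\; \sum_{\text{cells } c} \log \sum_{i} w_i\,
\mathcal{N}\!\left(O_c \,\middle|\, M_{i,c},\, \sigma^2\right),
\qquad w_i \ge 0,\; \textstyle\sum_i w_i = 1.$$

Design choices, made where the method statement is genuinely open:

* **Single shared $\sigma$.** With member-specific scales the weights
  confound misfit with noise level; a shared scale keeps the weight
  ordering driven purely by how well each member matches the
  observation.
* **Global weights**, one $w_i$ per member, not per cell: the weights
  index models, not locations.
* **No bias correction before fitting.** Member bias is exactly what
  the weights must penalize; correcting it first would hand the biased
  members undeserved weight.
* Cells where a member is masked drop that member's mixture component
  for that cell (with weight renormalization) rather than dropping the
  cell, which maximizes the usable domain.

Two optimizers target the same objective. `fit_bma_em()` is the
deterministic reference: standard mixture EM (responsibilities, then
weight update as mean responsibility, then $\sigma$ as the
responsibility-weighted RMS residual), initialized at uniform weights
and the pooled residual sd, with the log-likelihood asserted
non-decreasing. `fit_bma_mcmc()` is a random-walk Metropolis sampler on
$(w, \log\sigma)$ with Dirichlet proposals centred on the current
weights (the asymmetric-kernel Hastings correction applied), a uniform
simplex prior, initialization at the EM estimate, and the posterior
mean reported. The two agree closely when the posterior is
concentrated; the posterior mean legitimately pulls away from the EM
point estimate when members are hard to distinguish at the available
number of cells, which is itself useful uncertainty information. The
reanalysis is the weighted mixture mean per cell with the mixture
spread $\sqrt{\sum_i w_i (M_{i,c} - \mu_c)^2 + \sigma^2}$ as its
uncertainty. Member water-demand fields are averaged with the
*same* weights — never refitted — so reanalyzed demand stays consistent
with the reanalyzed yield gain.

## The climate-analogue estimator

Cropland is partitioned into climate zones by **equal-area increments**
of growing degree days and annual precipitation: bin edges are
area-weighted quantiles of each variable over cropped cells (marginal,
per-variable equalization; joint equalization would be
under-determined), and zones are the cross-product of the two binnings.
Each marginal bin then holds the same crop area to within one cell's
area, which the tests assert by recomputation.

Within a zone the **irrigated attainable yield** is the area-weighted
95th percentile of *all* yield observations — farmers in the upper tail
use whatever practices maximize yield, including irrigation where it
pays — and the **rainfed attainable yield** is the same percentile
restricted to observations from political units with less than 10% of
crop area irrigated. Percentiles use the step-CDF convention (smallest
value whose cumulative weight share reaches $q$, no interpolation):
deterministic, exactly reproducible by a sort-and-scan oracle, and
different from interpolated variants by less than one observation
spacing. Zones with fewer than 5 qualifying observations are invalid
(`NA`), never zero — a one-point percentile should not drive
$\Delta Y$.

The estimate is replicated over square zone counts $b \times b$ for
$b = 10, \dots, 20$ (100 to 400 zones) and averaged per cell with equal
weight across the 11 replicates, cells skipping replicates in which
their zone is invalid. Zone-level $\Delta Y$ is floored at zero:
negative values arise only when the rainfed percentile exceeds the
irrigated one, which is sampling noise under this design. Cells with no
valid replicate stay masked.

## Climate-driver attribution

Spatial variation of $\Delta Y$ is attributed to climatic water supply
(mean annual precipitation, MAP) versus atmospheric water demand
(potential evapotranspiration, PET) with **moving-window partial
correlations**: in a square window centred on each cropped cell,
$r_{\Delta Y,\mathrm{MAP} \mid \mathrm{PET}}$ and
$r_{\Delta Y,\mathrm{PET} \mid \mathrm{MAP}}$ are computed across the
window's cells, each with a two-tailed $t$-test ($n - 3$ degrees of
freedom). Exactly one covariate is partialled at a time, matching the
two-variable design. Windows span 3.5° at the native 0.5° resolution
(an odd cell count is required; coarser grids use the nearest odd
multiple, e.g. 5 cells = 10° at 2°). At least 10 jointly valid cells
are required per window — with $n - 3$ degrees of freedom that keeps at
least 7 — else the cell is masked. Windows truncate at the latitudinal
domain edge and wrap in longitude on global grids. Internally the
window statistics are computed from summed-area tables of the ten
required moments, which is exactly equivalent to per-window
computation but $O(\text{cells})$ overall.

A cell is *precipitation-controlled* at threshold $t$ when
$|r_\mathrm{MAP}| \ge t$ and $|r_\mathrm{MAP}| > |r_\mathrm{PET}|$
(symmetrically for PET), and *co-dominant* when both exceed $t$ and
differ by less than 0.05 in absolute value — the tie band
operationalizes "co-dominance", which is named but not defined
elsewhere. Area fractions are harvested-area-weighted (consistent with
reporting "over contemporary harvested area"), with co-dominant area
counted once in its own class.

PET comes from the **modified Haude equation**: daily
$\mathrm{PET} = \min(\mathrm{cap},\; k_m \cdot e_s(T) \cdot (1 -
\mathrm{RH}/100))$ with the Magnus saturation vapor pressure
$e_s(T) = 6.11 \cdot 10^{7.5T/(237.3+T)}$ hPa, summed over
calendar-month lengths (365-day year). The monthly coefficients $k_m$
default to the classic Haude values (0.22–0.29 mm d⁻¹ hPa⁻¹,
peaking in late spring) with the standard 7 mm/day cap; both are
documented package defaults, replaceable via `haude_coefficients()`.
Mean annual temperature may stand in for PET as the demand proxy, and a
pre-computed PET raster (e.g. Penman–Monteith) can be supplied in its
place; the Penman–Monteith equation itself is out of scope.

## Demand–supply water balance

Reanalyzed net crop water demand (mm/yr, the requirement at 100%
irrigation efficiency) is divided by a crop-specific irrigation
efficiency — default 0.5 when no efficiency map is supplied — to give
the gross withdrawal requirement. A cell demands irrigation when its
$\Delta Y$ reaches a minimum threshold (default 0.10), it carries
harvested area, and it is rainfed (irrigation fraction below 0.10, the
same cutoff as the CA rainfed rule). Demand volumes
($\mathrm{mm/yr} \times \mathrm{km^2} \times 10^{-6} =
\mathrm{km^3/yr}$) are pooled annually per basin and compared with the
accessible share of basin discharge — a static fraction, default 0.30
and swept over 0.20–0.40, standing in for environmental-flow and
competing-use constraints whose explicit estimation is out of scope.
Discharge is treated as already net of current withdrawals.

Under shortage, water is allocated **pro-rata to demand** (the minimal
symmetric rule; nothing in the problem distinguishes cells within a
basin), each demanding cell keeps a deficit of
$\mathrm{gross} \times (1 - \mathrm{supply}/\mathrm{demand})$, and all
demanding cells of a deficit basin count as **unserved**: full
yield-gap closure is impossible basin-wide. (A cell-level alternative
is exposed as `whole_basin_unserved = FALSE`; under pro-rata allocation
the two sets coincide, the switch exists to make the accounting
explicit.) Per basin, allocated water plus deficit equals demand to
$10^{-9}$ relative — asserted in the tests — and the unserved area is
monotone non-increasing in both thresholds, asserted over full sweeps.
Basin summaries report demand as a percentage of *total* (not
thresholded) discharge, with zero-discharge basins flagged infinite
rather than erroring. Multi-crop demand would sum per cell; the
pipeline ships with one crop at a time.

## The synthetic world

All inputs the pipeline consumes are generated with known ground truth,
so every stage has something to recover. The generator emulates the
statistical structure the method assumes, not any real-world map:

* **Climate**: latitude-driven MAP (wet tropics, dry subtropics,
  mid-latitude storm belt; 50–3000 mm/yr), temperature with a
  latitude-dependent seasonal cycle (−5 to 30 °C), relative humidity
  (20–100%), GDD (base 5 °C) and Haude PET derived from the monthly
  fields. All fields carry spatially correlated noise — Gaussian-smoothed
  white noise, kernel width 1.5 cells by default — because the real
  fields are smooth and unstructured noise would make window statistics
  degenerate.
* **Truth**: $\Delta Y = \mathrm{clip}\!\left(e^{-\mathrm{MAP}/\lambda_P}
  (1 + \lambda_E \cdot \mathrm{PET}^{\mathrm{std}}),\, 0,\, 0.95\right)$
  with $\lambda_P = 450$ mm and $\lambda_E = 0.25$: the gain decays
  with water supply and is modulated upward by demand, precipitation
  deliberately dominant. Only the monotone directions are treated as
  truth in tests, never the functional form, which is an artifact
  choice. The clip ceiling (0.95; 0.98 for derived fields) keeps the
  yield-ratio transformations away from division instabilities. True
  net demand is proportional to $\Delta Y$ times the annual climatic
  water deficit, hence zero wherever the gain is zero.
* **Ensemble**: member $m$ sees
  $\mathrm{clip}(\alpha_m \Delta Y + \beta_m + \varepsilon_m, 0, 0.98)$
  with gains on a geometric ladder (0.85–4.2), small offsets (−0.01 to
  0.05) and member noise sds 0.03–0.10. The defaults are calibrated so
  the ensemble global mean overshoots the truth by a factor of about
  1.8 and members span a factor of about 3.5 — the regime the fusion
  step exists to correct. Clipping compresses high-gain members, which
  is why the nominal gain ladder is wider than the realized spread.
* **Observation**: truth plus spatially correlated noise of pointwise
  sd 0.22, clipped to $[0, 0.98]$ and then iteratively re-centred on
  the truth mean. The re-centring is deliberate: clipping at zero over
  wet (near-zero-gain) cropland would otherwise leave a positive mean
  bias of several percentage points, whereas the empirical estimator
  this emulates is nearly unbiased in the mean while only moderately
  correlated in pattern (r ≈ 0.7 under the defaults).
* **Point yields**: each cropped cell contributes an irrigated and a
  rainfed observation around a smooth potential-yield surface in GDD
  and MAP (multiplicative noise, cv 4%), with areas split by the admin
  unit's irrigation fraction. Admin units are 3×3-cell blocks with
  Beta(0.5, 2)-distributed irrigation fractions, so nearly half qualify
  as rainfed under the 10% rule and the rule is genuinely exercised.
* **Basins and discharge**: a seeded Voronoi partition (60 basins by
  default) with discharge equal to a runoff coefficient (0.35) times
  basin-integrated precipitation volume. Voronoi rather than flow
  accumulation because the balance is annual and basin-pooled; routing
  would add nothing testable.

Everything is a deterministic function of one integer seed (fixed
per-stage offsets derive the stream for each generator), and
regeneration is bit-identical — the end-to-end pipeline reproduces
byte-identical output files under a fixed seed.

What the generator does **not** emulate: crop phenology, daily weather,
actual crop-model physics, real coastlines or basin geometry, seasonal
discharge, groundwater, or economic constraints. Passing tests
therefore demonstrate that the estimators recover the structure they
assume — unbiased fusion under member bias, driver signs and dominance,
conservation in the balance — not that the defaults reproduce any
real-world map.

## Numerical choices

* Mixture likelihoods are evaluated in log space with log-sum-exp;
  $\sigma$ is floored at $10^{-8}$, so a member that matches the
  observation to machine precision degenerates gracefully.
* Weighted percentiles and zone edges are exact order statistics, no
  interpolation; ties in the step CDF resolve to the same value by
  construction.
* Grid cells are cell-center registered, latitude ascending,
  longitude in $[-180, 180)$; cell areas use the spherical-cap formula
  with $R = 6371$ km (sums match $4\pi R^2$ to well under 0.5%).
* Masked cells are `NA` everywhere and are skipped by every statistic;
  they never silently coerce to zero. Evaluation compares candidates on
  the intersection mask so squared-bias differences cannot come from
  differing domains, and the error decomposition
  $\mathrm{MSD} = \mathrm{SB} + \mathrm{MSV}$ is unweighted, following
  its defining equations.
* Harvested area is the weight for every "global" or "area fraction"
  statistic — the natural reading of "over contemporary harvested
  area"; cell count would over-represent marginal cropland.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on a
global 2° grid (90 × 180 cells, ≈ 8600 cropped) — the package's
standard desk-scale study resolution, at which a complete run
(generation through balance) takes seconds. Property sweeps use 4°
worlds for multi-seed replication. Everything scales to 0.5° by
passing `grid_spec(resolution = 0.5)`; memory stays modest because all
fields are dense matrices (260k cells per field at 0.5°).

## Known limitations

* Weights are global; a member that is skillful only regionally cannot
  be up-weighted locally.
* The Gaussian shared-scale likelihood treats all cells as
  exchangeable; heteroscedastic observation error would need a scale
  field.
* The EM optimum can sit on the simplex boundary, where the MCMC
  posterior mean is necessarily interior; the difference shrinks with
  the number of informative cells.
* The CA estimator's replicate set (all integers 10–20) and the
  handling of cells in invalid zones (masked here) are documented
  package choices among reasonable alternatives.
* The balance is annual and basin-pooled by design: seasonality,
  routing, conveyance between basins, and groundwater are out of
  scope.
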