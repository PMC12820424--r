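---
title: "Adjoint attribution of chronic PM2.5 mortality burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjoint attribution of chronic PM2.5 mortality burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adjointpm)
```

## The problem

Chronic exposure to fine particulate matter (PM2.5) is a leading
environmental mortality risk. Policy questions, however, are posed about
*sources*, not receptors: how many deaths would a ton of NH3 emitted near a
given city, in a given season, by a given sector, eventually cause — and what
is that worth? Brute-force answers require one perturbed model run per source,
which is hopeless when sources number in the millions of cell-hours. The
adjoint method inverts the question: one backward model run, driven by the
derivative of a scalar health-burden cost function, yields the gradient of
that cost with respect to *every* emission at every location and hour
simultaneously.

`adjointpm` implements this machinery at desk scale: a reduced single-layer
Eulerian chemical-transport model with an exact discrete adjoint, a GEMM
(Global Exposure Mortality Model) mortality cost function and its monetized
twin, and the attribution layer that turns sensitivity fields and emission
inventories into regional, sectoral and seasonal burden estimates. Everything
runs from seeded synthetic worlds, so every claim the package makes is
checkable against closed forms or brute-force finite differences.

## The forward model

The state is the concentration (ug/m3) of nine species on an `ny x nx` grid
of `dx_km` cells with one well-mixed vertical layer of depth
`mixing_height_m`: three primary PM2.5 components (EC, OC, fine crustal),
three precursor gases (SO2, NOx, NH3), and three secondary inorganic products
(pSO4, pNO3, pNH4). Each hour applies a fixed operator-split sequence:

1. **inject** — emissions `E` (tons/hr) raise concentrations by
   `E * 1e12 / (cell_area * mixing_height)` ug/m3 per hour;
2. **chemistry** — first-order gas-to-particle conversion with per-gas rates
   (1/h), modulated by a seasonal temperature index (higher in winter,
   emulating the cold-season partitioning of secondary inorganics);
3. **deposition** — exact exponential first-order removal;
4. **advection** — first-order upwind (donor cell) on cell-centre winds;
5. **diffusion** — explicit 5-point Laplacian.

The order is fixed because the adjoint must reverse exactly this order.
Deposition uses the exponential form rather than forward Euler because it is
unconditionally stable and self-adjoint (the backward model multiplies by the
same factor). Transport operators are assembled as sparse matrices, which is
what makes "exact discrete adjoint" literal: the backward sweep applies their
transposes.

Stability is refused, not warned about: the run aborts unless
`max(|u|+|v|) * dt / dx <= 1` (the condition under which the 2-D donor-cell
update has all non-negative coefficients, hence preserves positivity) and
`K * dt / dx^2 <= 1/4`. Chemistry rates are bounded by `k * temp_index <= 1`
per hour for the same reason.

Two chemistry modes exist. In **linear** mode every coefficient of the hourly
update is non-negative, so non-negative emissions produce non-negative
concentrations *and* non-negative sensitivities — exactly, not just
approximately. In **titration** mode the NOx conversion rate becomes
`k_titr * max(0, o3bg - gamma * [NOx])`: added NOx consumes the background
oxidant proxy, so nitrate production peaks at `[NOx] = o3bg / (2 gamma)` and
*decreases* with further NOx. This is the stylized stand-in for the
NOx-inhibited regime of polluted cities, and it is what produces negative
NOx sensitivities. At the `max(0, .)` kink the adjoint uses the subgradient 0
— a deterministic, documented tie-break.

### Boundary conditions

The default boundary is zero-inflow: outflow is lost, matching a
limited-area model in which sensitivities of exported pollution are
unresolvable. Diffusion uses no-flux walls in this mode (only advection and
deposition remove mass). The periodic mode exists solely so mass-conservation
tests can be exact.

## The cost function and its gradient

The mortality cost is the GEMM form

$$J = \sum_i M_{0,i} \, P_i \left(1 - e^{-\theta T(z_i)}\right), \qquad
T(z) = \log(1 + z/\alpha)\,\omega(z), \qquad
\omega(z) = \frac{1}{1 + e^{-(z-\mu)/\nu}},$$

with $z_i = \max(0, \mathrm{PM}_i - C_f)$ the period-mean PM2.5 above the
counterfactual. Defaults are $\theta = 0.1231$, $\alpha = 1.5$, $\mu = 10.4$,
$\nu = 25.9$, $C_f = 2.4$ ug/m3 (the NCD+LRI coefficients for adults 25+).
$P_i$ is the adult population, $M_{0,i}$ the baseline mortality rate of the
modelled endpoints.

The adjoint forcing is the analytic gradient, with the chain rule written out:

$$\frac{\partial J}{\partial \mathrm{PM}_i} =
M_{0,i} P_i \,\theta\, e^{-\theta T(z_i)}
\left[\frac{\omega(z_i)}{\alpha + z_i}
 + \log(1+z_i/\alpha)\,\frac{\omega(z_i)(1-\omega(z_i))}{\nu}\right]$$

for $\mathrm{PM}_i > C_f$ and zero otherwise (the one-sided derivative from
below at the kink, for determinism). This expression is a derivation
contract: it is validated against Richardson-extrapolated central differences
of `gemm_mortality()` on 1000 random states in the test suite.

Because $J$ is defined on the *mean* PM2.5 over the non-spin-up hours —
chronic exposure — the per-hour forcing is `dJ/dPM / n_eff`, applied
identically to every particulate species (GEMM is mass-based: a microgram is
a microgram) at each non-spin-up hour. Uniform allocation over hours is the
only time-symmetric choice.

## The adjoint

The backward sweep runs from the final hour to the first. Each step applies
the transposes of the forward sub-operators in exactly reversed order
(diffusion, advection, deposition, chemistry Jacobian), then adds the hour's
forcing. The sensitivity of $J$ to an emission at (species, cell, hour) is
the adjoint state immediately before that hour's injection times the same
tons-to-concentration unit bridge the forward model uses — so units are
deaths/ton by construction, converted to deaths/kton or USD/ton only for
reporting.

Two design choices matter:

* **Discrete, not continuous.** The adjoint is the transpose of the *coded*
  forward update, not a discretization of the continuous adjoint equations.
  Consequence: duality `⟨forward(x), y⟩ = ⟨x, adjoint(y)⟩` holds to machine
  precision and is asserted at 1e-12 per step, and the full-trajectory
  directional-derivative identity holds at 1e-8 with the linearized cost.
  These are acceptance tests, not aspirations.
* **Full checkpointing.** The forward trajectory is stored hourly, and the
  titration adjoint linearizes about the stored (recomputed post-injection)
  state. At desk scale memory is trivial and recomputation windows would only
  add correctness risk. A missing checkpoint is a hard error naming the hour.

### Monetization is receptor-side, and happens in the forcing

The value of statistical life (VSL) is transferred to each region by the
income-elasticity power law

$$\mathrm{VSL}_c = \mathrm{VSL}_{\mathrm{base}}
\left(\frac{Y_c}{Y_{\mathrm{ref}}}\right)^{b}
\left(1 + \%\Delta P + \%\Delta Y\right)^{b}, \qquad b = 0.8,$$

with the price and income adjustments additive inside the bracket exactly as
the OECD transfer formula is printed. The base VSL is a required input with
no default; the synthetic worlds set 3,000,000 USD, the order of the OECD
2005 recommendation. Monetized sensitivities come from a *second adjoint run*
with USD-valued forcing (`gemm_forcing(..., vsl = )`): receptor-side VSL
weighting does not commute with backward transport, so `monetize()` on a
sensitivity field is deliberately an error. For single-region forcing the
two routes coincide exactly, and the test suite asserts both that identity
and the multi-region decomposition (USD adjoint = sum of per-region deaths
adjoints weighted by regional VSLs).

## Attribution

`reduction_burden()` estimates the avoided burden of reducing every source by
fraction `f` (default 0.10, a range small enough for the marginal estimates
to be meaningful) as `f * sum(sens * E)`, attributed to the *source* cell's
region. Sector burdens are additive because sensitivities are marginal, so
shares over the seven anthropogenic categories plus the natural residual sum
to one; both facts are asserted at 1e-10. With linear chemistry and the
linearized cost the first-order estimate is exact:
`burden(f) = J(E) - J((1-f)E)` to round-off. With the true concave GEMM cost
the package asserts the direction instead: per-ton burden *grows* as the
baseline shrinks, so successive 10% reductions are worth more per ton than
the first.

Spin-up hours are flagged on sensitivity fields. Annual per-ton maps and
seasonal summaries exclude them (they describe the exposure window); burden
integrals include them by default, because emissions during spin-up really do
influence the exposure window and excluding them would break the first-order
identity above.

Seasons are meteorological quarters mapped proportionally onto the run
(first quarter DJF, then MAM, JJA, SON), so toy calendars shorter than a year
still partition cleanly.

## The synthetic worlds

`make_world()` generates every input from one integer seed through named
substreams (population, regions, baseline mortality, emissions, meteorology,
economics), so adding a generator never perturbs earlier draws and a seed
pins a world bit-for-bit.

The default world is a 30 x 30 grid of 100-km cells run for 240 hours with
24 hours of spin-up — a compressed year, so the seasonal profiles and the
winter-peaking temperature index traverse all four seasons. Population
(5e7 adults) is a sum of log-normally weighted Gaussian urban clusters —
clustered and heavy-tailed like gridded adult population (the tests assert a
Gini coefficient above 0.5). Baseline mortality is constant within region and
drawn from 0.005–0.015 deaths/person/yr across regions, the range of crude
NCD+LRI adult rates. Sector geographies are distinct by construction:
agriculture is rural-diffuse and NH3-heavy, residential tracks population and
is primary-PM-heavy, energy is four elevated point sources and SO2-heavy,
transport follows population^0.7 and is NOx-heavy, shipping occupies a coastal
band, aviation sits at the three largest cities, and a natural sector
(crustal/organic) forms the residual so sector shares are taken over the full
inventory. Sector run-totals (515 kt over 240 h domain-wide) were chosen once
so that urban period-mean PM2.5 sits in the 4–15 ug/m3 range — above the
counterfactual where GEMM is active, below the saturated tail. Winds are a
spatially modulated uniform flow whose direction rotates with season
("seasonal-shift"), with speeds (6 m/s) leaving CFL headroom.

What the generator does *not* emulate: real emission magnitudes, real country
masks, vertical structure (the surface/elevated tag is carried as an
attribution label only — in a single-layer model it cannot change
dispersion), aerosol thermodynamics, or wet scavenging. A green test
therefore establishes that the *machinery* — transport, adjoint, cost
gradient, unit bridges, attribution algebra — is correct, not that any
particular real-world number is reproduced.

Five named scenarios (`make_scenario()`) pin down the analytic corner cases:
`box` (1 x 1, zero wind — the geometric-series world), `plume` (one emitter
strictly upwind of one city), `two_region` (VSL contrast), `titration_demo`
(a NOx-saturated city engineered so `gamma * [NOx]` crosses the oxidant
level, producing negative annual NOx sensitivities), and `seasonal_demo`
(temperature-index amplitude 0.8, so winter NH3 sensitivities exceed summer).

## Verification against brute force

`adjoint_vs_fdm_report()` is the package's answer to "why believe a gradient
you got for free?". It samples probes over (cell, hour, species) weighted
toward non-negligible sensitivities, perturbs each by ±1% of the local
emission (central differences; absolute floor 0.5 tons/hr where local
emission is zero), reruns the full nonlinear forward model twice per probe,
and regresses adjoint against brute-force values. In linear chemistry the
OLS slope and R² sit inside [0.999, 1.001] and above 0.999; under titration
the perturbation is chosen adaptively from a `{1e-1, 1e-2, 1e-3}` ladder of
the local emission (keeping the smallest rung whose estimate has converged)
and the median relative error stays below 1%. Probe sampling is seeded, so
reports are reproducible.

## Numerical choices, in one place

* Timestep 1 h; sub-stepping of transport is supported (`dt_s` dividing
  3600) but states are stored hourly.
* Grid state is column-major (y fastest); winds live at cell centres;
  interface velocities are two-point averages.
* `z = 0` exactly at `PM = Cf`; forcing 0 there (one-sided from below).
* Titration kink: subgradient 0.
* Zero-emission cell-hours in the emission-weighted primary-PM aggregate
  receive the unweighted species mean.
* Internal sensitivity units are fixed at deaths/ton (or USD/ton);
  deaths/kton is a reporting view (`to_reporting_units()`).
* Serialization is long-format CSV with a JSON sidecar carrying dimensions
  and units; a missing units attribute is a hard read error, because unit
  bridges are the dominant failure mode of this kind of artifact. Floats are
  written as `%.17g`, so round-trips are exact.

## Known limitations

* Single layer: elevated sources differ from surface sources only as
  reporting labels, not in dispersion or deposition exposure.
* First-order upwind transport is diffusive; sensitivity maps are smoother
  than a higher-order scheme would give. Adequate at toy scale, and trivially
  transposable, which is the property the adjoint needs.
* The titration mechanism is a one-species caricature of NOx-inhibited
  chemistry; it reproduces the sign structure, not the magnitudes, of real
  nitrate responses.
* The GEMM hazard is applied with a single coefficient set; age- or
  cause-stratified variants and CRF confidence intervals are out of scope.
* Burdens are first-order in `f`; the concavity of the CRF means a 10%
  estimate understates the benefit of later reductions (the package asserts
  the direction on a monotone scenario rather than claiming a bound).
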