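---
title: "Methods: bookkeeping model-data integration for woody biomass carbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bookkeeping model-data integration for woody biomass carbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodbkm)
```

## The problem

Bookkeeping models estimate carbon fluxes from land-use and land-cover
change (LULCC) by moving carbon between pools with fixed response curves
whenever land is cleared, harvested or abandoned. By construction they
exclude environmental effects (CO2 fertilization, climate variability), so
their stocks drift away from what satellites observe. This package
implements the complementary strategy: assimilate an observed annual woody
biomass carbon density field into the bookkeeping model every year, and
isolate the environmental signal by differencing against a twin simulation
in which densities are frozen at their start-year values. The difference in
annual stock changes is the environmental woody-biomass sink S_LAND,B; the
flux ledger of each run is its land-use flux E_LUC,B.

## Pool model and carbon transfers

Carbon lives on a regular latitude-longitude grid, indexed by cover type
(primary, secondary, cropland, pasture), land-use history (clearing,
harvest, abandonment, other) and eight woody PFTs. Each slot splits into an
equilibrium pool and signed excess pools relaxing as
`delta(t) = delta(t-1) * exp(-1/tau)`, with the released or absorbed
difference booked as a flux (release-positive).

Two representational choices deserve explanation:

- **A role axis on excess pools.** Harvested material decaying off-site and
  the stand's regrowth deficit both carry the history label "harvest", but
  they need different time constants and must not cancel in one array. The
  excess arrays therefore carry a role axis `{decay, regrow}`. This is the
  package's aggregated stand-in for the on-site/product sub-pools of full
  bookkeeping models: one decaying excess pool per history type, with
  category-specific time constants.
- **Equilibrium pools carry no history axis.** They do not relax, so a
  history label would be inert; the initialization convention "all stock
  under history 'other'" is representationally equivalent.

Transitions conserve carbon exactly: clearing removes the affected area's
living stock, books the target cover at its equilibrium density and puts
the difference into decaying excess; harvest moves `h * rho * a` into
decaying excess against an equal regrowth deficit; abandonment books the
secondary-land equilibrium against a regrowth deficit. Transition areas are
distributed across PFTs proportionally to the temporally constant PFT area
fractions, and shares are evaluated against start-of-year cover fractions,
processing categories in a fixed order (clearing, other, abandonment,
harvest). Clearing also trims the area share of stand-attached regrowth
deficits — including those already folded into legacy trackers — and cancels
them against the cleared material: the deficit of cleared land will never
regrow, so its future uptake must not be booked.

## Annual assimilation and legacy tracking

Observed cell densities are split across woody covers and PFTs by the
model's own living-stock shares (Eq. `f = C_jl / C`), with the static
cover-by-PFT area fractions as fallback on zero-stock cells. The
distributed stocks sum back to `rho * A` exactly.

Because the woody pools are re-initialized from observations every year,
delayed fluxes would be lost; they are tracked in two legacy excess-pool
sets (pre-assimilation-era and assimilation-era). A numerical convention
matters here: the total flux expression books the first-year relaxation of
last year's excess as the instantaneous term, so the legacy pool must
absorb the *post-relaxation remainder* `delta_B(t-1) * exp(-1/tau)`.
Injecting the excess undecayed while also booking its first-year flux
would create carbon from nothing; the package's convention makes the pooled
accounting exactly equal to an independent per-event cohort ledger and
closes the mass budget to floating-point precision (both are enforced in
the test suite).

**Living stock.** The reported stock — and the quantity the observations
measure — is the equilibrium stock plus all stand-attached regrowth
deficits. Legacy pools are pure flux trackers: their stock counterpart is
carried by the assimilated observations. Consequently re-initialization
sets the equilibrium pools to the assimilated stock *net of tracked
deficits*, so that living stock equals the assimilated stock exactly; when
the carried stock already equals the observation, re-initialization is a
no-op (this is what makes the transient and fixed runs bit-identical on
worlds without environmental change).

**Screening.** Implausible densities are excluded per PFT and woody cover
over the whole series: a uniform `< 375 t C ha^-1` ceiling (the source
dataset's maximum) and a percentile variant (default the 99th percentile of
the values below the ceiling; the percentile rule is a strict superset of
the uniform rule). The headline pipeline runs both policies and reports
their mean, keeping the range. Deriving per-(PFT, cover) densities from the
evolving run would make exclusion circular with the run itself, so the
package screens one-pass with the static start-year weights — a documented
simplification. Excluded and missing entries are filled by linear
barycentric interpolation on cell centres: a containing triangle of nearby
valid cells where one exists, a least-squares plane through the nearest
valid neighbours otherwise (both exact for planar fields), and
nearest-valid-value outside the convex hull of valid cells. No
triangulation library is available in the target environment, so the
scheme is implemented directly; interpolating a complete field is the
identity.

## The paired runs and the decomposition

Each simulated year proceeds as: (1) relaxation fluxes from the previous
year's pools are realized (instantaneous, pre-T0 legacy, post-T0 legacy);
(2) transient only — main excess is folded into the legacy trackers and
woody pools are re-initialized from the year's observations (the
equilibrium overwrite is logged as the run's external injection); (3) the
year's transitions are applied. Stocks reported for year X are end-of-year;
stock changes between X and X+1 are attributed to X+1, so flux series start
the year after T0.

S_LAND,B is the transient-minus-fixed stock-change difference. Both a
stock-change identity and a flux sign convention are in play: the package
stores the raw difference (`sland_stock_diff`) and reports `sland` as its
negative under the release-positive convention, so an environmental sink is
negative. The regrowth target for abandonment uses the current assimilated
density of secondary land (the natural choice once densities are
transient); the alternative — a fixed climatological equilibrium — would
change regrowth magnitudes but not the decomposition identities.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `tau` decay (clearing) | 1 | yr | fast on-site decomposition of slash; placeholder for literature-calibrated constants, configurable per (cover, history, PFT, role) |
| `tau` decay (harvest) | 2 | yr | wood products outlive slash |
| `tau` regrow | 15 | yr | decadal forest regrowth |
| `harvest_intensity` | 1 | – | fraction of stand biomass removed per harvested area |
| threshold limit | 375 | t C ha⁻¹ | ceiling of the source density dataset |
| threshold percentile | 99 | % | smallest cut that does not erode the series' variability; 97/98 are exposed through the policy interface |
| error fraction | 0.005 | – | the source dataset's stated global error on woody carbon |

## The synthetic world

`generate_world()` evolves a truth world with the *same* transition and
relaxation rules as the kernel — equilibrium pools scaled by an
environmental multiplier `(1 + trend)^t * (1 + coupling * T_anom)`,
transitions removing living carbon, deficits refilling — and records every
component of the annual stock change exactly. Observations for year t are
the beginning-of-year living densities (after relaxation and the
environmental increment, before the year's transitions), matching the
assimilation timing; they are then degraded with truncated Gaussian noise
and a random validity mask.

Stated world (chosen once): 20 x 20 one-degree cells at temperate
latitudes, 20 years, PFT equilibrium densities 20–180 t C ha⁻¹ with ±20 %
spatial heterogeneity, environmental trend 0.5 % yr⁻¹ (CO2-fertilization
scale), temperature coupling 2 % K⁻¹ with 0.7 K anomaly SD, clearing
0.5 % yr⁻¹ of cell area (primary → cropland, the canonical deforestation
pathway), harvest 1 % yr⁻¹ (secondary land), abandonment 0.2 % yr⁻¹
(cropland → secondary), 5 % missing observations, 1 t C ha⁻¹ observation
noise. Initial cover is 40/30/20/10 % primary/secondary/crop/pasture.

What a green test does and does not establish: the generator shares the
kernel's transition arithmetic (by design — the recovery identities are
exact only then), so end-to-end tests verify the *accounting* — mass
closure, cohort equivalence, decomposition identities, unbiasedness under
noise — not the realism of the response curves. The worlds have no spatial
covariance structure, no fire or mortality processes, and no
cover-dependent observation error, all of which real satellite products
have.

## Numerical conventions and degenerate inputs

- Sign: release-positive everywhere (uptake negative).
- IAV uses the sample (n−1) standard deviation over the mean; undefined at
  zero mean (error, not NaN).
- Detrending is ordinary least squares against year; residuals sum to zero.
- Spearman: average-rank ties; exact permutation p-values for tie-free
  series with n ≤ 9 (null cached per n), large-sample t approximation
  otherwise; constant series are masked, not errored, in map form. No
  multiplicity correction on the p < 0.05 mask.
- Temporal agreement: zero changes agree only with zero changes.
- Transitions whose area exceeds the available cover fraction, negative
  densities, non-positive time constants, and stock on zero-area slots are
  errors, not warnings.
- Cell areas come from the spherical quadrilateral formula on cell bounds,
  in hectares, bit-reproducible from the coordinates.
- Gridded I/O is long-format CSV and configuration is JSON — the target
  environment provides no NetCDF or YAML bindings; the formats are
  documented and round-trip losslessly.

## Limitations

Soil, litter, dead-wood and explicit product-pool dynamics are out of
scope; the single aggregated decaying excess per history type stands in
for them. E_LUC,B and S_LAND,B cover living woody biomass only and must
not be combined into a net land-atmosphere balance: delayed fluxes through
dead matter are outside the observed stock. Default time constants are
placeholders, not calibrated values. The one-pass threshold screening and
the static-weight layer derivation are simplifications of a fully coupled
exclusion procedure.
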