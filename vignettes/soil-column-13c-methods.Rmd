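---
title: "Modelling soil organic carbon and its 13C signature in a discretized column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soil organic carbon and its 13C signature in a discretized column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocolumn)
```

## The model

`isocolumn` simulates the carbon budget of a one-dimensional soil column and,
alongside it, the stock of the stable isotope ¹³C in every pool. The column
is discretized into layers of geometrically increasing thickness (default:
11 layers to 2 m, ratio 1.53, giving a ~1 cm top layer that resolves the
steep near-surface carbon gradient). Each layer holds nine pools: metabolic
and structural below-ground litter, active, slow and passive soil organic
carbon (SOC), and labile and stable dissolved organic carbon (DOC), the
latter two split into a free and an adsorbed phase. Above-ground litter
(metabolic and structural) lives in a non-layered surface compartment whose
decomposition products enter the top layer.

Carbon enters only as litter: an above-ground flux deposited on the surface
pools, and a below-ground (root) flux distributed over the layers
proportionally to $\exp(-z/z_r)$ with $z_r$ the rooting e-folding depth.
Every decomposable pool loses carbon by first-order kinetics,
$F = C\,(1 - e^{-k\,m\,\Delta t})$, where $m$ is an exogenous per-layer
environmental rate modifier (default 1; the host land-surface model's
temperature and moisture response functions are outside this package's
scope) times, for the active pool only, a clay modifier $1 - 0.75\,\mathrm{clay}$
encoding slower active-pool turnover in finer-textured soil.

All decomposed litter and SOC flows into the free DOC pools; decomposed DOC
is partly respired as CO₂ (fraction `resp_frac_doc`) and partly returned to
the SOC pools. The routing is a configurable transfer matrix whose rows
(receiver fractions plus respired fraction) must sum to one. The defaults
send metabolic litter and active SOC to labile DOC, structural litter and
the slow/passive pools to stable DOC, the labile-DOC return to the active
pool, and the stable-DOC return 90/10 to the slow and passive pools. We
chose to route the stable return to the slow/passive pools rather than to
the active pool alone because otherwise those two pools would have no
supply pathway at all: their steady-state stocks would be identically zero
and the per-pool δ¹³C decomposition would be meaningless. The exact split is
deliberately exposed in `iso_params()` because it is a calibration target,
not a structural constant.

The rate constants and DOC coefficients shipped as defaults are
order-of-magnitude values in the style of multi-pool (CENTURY-type) models
— litter on the order of years⁻¹, active ≈ 1 yr⁻¹, slow ≈ 0.03 yr⁻¹,
passive ≈ 0.001 yr⁻¹, DOC fast — and are **not calibrated to any site**.
Everything the package guarantees about itself is structural (conservation,
linearity, steady-state identities, oracle agreement), so the defaults are a
plausible stage set, not a fit.

### Sorption and transport

Free and adsorbed DOC are related by an instantaneous equilibrium partition
coefficient: $\mathrm{adsorbed}/\mathrm{free} = K_d$ exactly, re-imposed
each step. Adsorbed DOC is immobilised — it neither decomposes nor moves.
Sorption does not fractionate isotopes.

Solid pools (below-ground litter, SOC) and free DOC mix vertically by
Fickian diffusion, a proxy for bioturbation, with a depth-dependent
coefficient $D(z) = D_0 e^{-z/z_D}$ ($z_D = \infty$ recovers a constant
coefficient). The operator is a conservative finite-volume discretisation
on the non-uniform grid, advanced with an implicit (backward Euler) step:
unconditionally stable, and mass-conserving to solver precision because the
generator's columns sum to zero. Free DOC is additionally advected downward
by an upwind scheme — the flux out of a layer is its free DOC times the
fractional water throughput — with CFL sub-stepping; the bottom-layer flux
leaves the column as DOC export.

### ¹³C bookkeeping

Each pool carries a paired stock $(C_{\mathrm{total}}, C_{13})$ with total
carbon treated as ¹²C + ¹³C (¹⁴C neglected). Conversions use the classical
delta notation against V-PDB ($R_{std} = 0.0111802$):
$R = R_{std}(1 + \delta/1000)$ and $C_{13} = \frac{R}{1+R} C_{\mathrm{total}}$.
Mixing always happens on stocks (ratio-weighted), never on delta values, and
a pool with zero carbon carries an undefined (`NA`) delta rather than a
spurious 0 ‰.

Three processes shape the soil δ¹³C profile:

1. **Suess effect and CO₂ fertilization.** Litter δ¹³C is imposed, not
   computed from photosynthesis. A yearly series is built from an
   atmospheric record: the Suess component follows atmospheric δ¹³C
   relative to a reference year, and the CO₂ component applies a
   discrimination slope of −0.02 ‰ per ppm (2 ‰ depletion per 100 ppm
   pCO₂). The series passes through the site reference measurement exactly
   and the two components are exactly additive.
2. **Root enrichment.** Below-ground litter is enriched relative to
   above-ground litter by a constant `enrich` (default +1 ‰).
3. **Respiration discrimination.** Respired CO₂ is depleted relative to its
   substrate by `epsilon_resp` (default 0.1 ‰), identical for every
   respiring flux and fixed in time. Discrimination is multiplicative on
   the isotopic ratio ($\alpha = 1 - \epsilon/1000$) rather than
   subtractive on delta: this keeps the mass balance exact and makes a
   0 ‰ substrate respire at exactly $-\epsilon$ ‰. The ¹³C excess left by
   the depleted respired flux stays in the donor pool, so residues enrich
   — the vertical enrichment mechanism the parameter exists to express.
   The two formulations agree to first order at $\epsilon = 0.1$ ‰.

A C3→C4 vegetation switch replaces the litter series by the C4 value
(default −12.8 ‰) from the switch year on; by default the post-switch
series keeps drifting with the Suess/CO₂ components relative to the switch
year (configurable flat plateau), since a fixed plateau would ignore the
atmospheric trend the rest of the series carries.

### Numerics

The operator order per step is fixed for reproducibility: litter inputs →
decomposition → sorption re-equilibration → diffusion → advection, with
default $\Delta t = 1/12$ yr; the splitting error is second order in
$\Delta t$. Decomposition sub-steps internally whenever $k\,m\,\Delta t \ge 1$
(the labile DOC default already requires it), and advection sub-steps to
satisfy its CFL bound. Negative stocks anywhere after a user-facing
operation are a hard error, not a warning.

Spin-up runs under constant forcing — the litter delta and fluxes of the
first historical year — until the relative change of every pool is below
`tol` per year for `window` consecutive years. The default criterion,
1 ‰ yr⁻¹ over the last decade (`tol = 1e-3`, `window = 10`), is the
conventional equilibrium test for this model family; note that it is a
*drift* criterion, and for slow pools it triggers well before the stock is
within 0.1 % of its asymptote. Cross-checks against the direct solution
therefore use a tighter tolerance.

Because the model is linear in its stocks under constant forcing,
`solve_steady_state()` obtains the equilibrium directly: it assembles the
one-step affine map $x' = Ax + b$ by probing the actual step kernel with
basis states and solves $(I - A)x = b$ — first for total carbon, then for
¹³C. The ¹³C respiration term is made exactly linear for this assembly by
applying the discrimination factor to the atom fraction instead of the
ratio; the two forms differ by $O(x\,\epsilon/1000) \approx 10^{-6}$
relative, orders of magnitude below the 0.1 % tolerance at which the direct
and iterative routes are compared. A pool with no loss pathway makes the
system singular; the solver reports the offending pool by name.

### Model evaluation

Simulated profiles are compared with observed depth-interval tables by
linear interpolation of the simulated node values to the interval midpoints
(intervals outside the simulated range are dropped and counted). The fit
statistic is the mean squared deviation and its additive decomposition
$\mathrm{MSD} = \mathrm{SB} + \mathrm{NU} + \mathrm{LC}$: squared bias,
non-unity slope and lack of correlation, with the regression slope taken of
measurements on simulations (the Gauch formulation; the additive identity
is pinned by a test to $10^{-10}$ relative). `rank_simulations()` orders
candidate runs by ascending MSD with an alphabetical tie-break. With fewer
than three pairs the statistic is refused; with zero simulated variance
only SB is defined and NU/LC are flagged degenerate.

## The synthetic data generator

All tests and examples are self-contained. `fixture_atmospheric_record()`
produces a smooth, strictly monotone, seed-reproducible stand-in for the
historical atmospheric record (pCO₂ 285→390 ppm, δ¹³C −6.4→−8.4 ‰ over an
1850–2011-like span, an accelerating power-law shape with small jittered
increments). It emulates the *shape* of the observed record — slow onset,
accelerating industrial-era trend — but not its year-by-year values, El
Niño-scale variability, or pre-1850 history. `synthesize_observed_profile()`
runs the simulator at a known configuration, samples site-like depth
intervals and adds Gaussian noise (0.1 ‰ on delta by default). Passing
tests on these fixtures therefore demonstrate internal consistency and
parameter identifiability under the model's own assumptions; they say
nothing about how well the default parameters describe any real site, and
real profiles additionally integrate land-cover history that no
constant-forcing spin-up can reproduce.

## Parameters at a glance

| parameter | unit | default | meaning |
|---|---|---|---|
| `k` | yr⁻¹ | pool-specific | base first-order decomposition rates |
| `resp_frac_doc` | – | 0.6 | respired share of decomposed DOC |
| `clay` | – | 0.20 | clay fraction; slows the active pool |
| `kd_doc` | – | 5 | adsorbed/free DOC at equilibrium |
| `enrich` | ‰ | 1.0 | root vs leaf litter δ¹³C offset |
| `epsilon_resp` | ‰ | 0.1 | respiration discrimination |
| `d0`, `d_efold` | m² yr⁻¹, m | 5·10⁻⁴, 0.3 | surface diffusivity and its e-folding depth |
| `root_efold` | m | 0.3 | root-input e-folding depth |
| `advection` | yr⁻¹ | 0.2 | free-DOC fractional water throughput |
| `metabolic_frac` | – | 0.5 | metabolic share of litter input |

The diffusivity sits in the 1–10 cm² yr⁻¹ range reported for temperate
Luvisols by tracer studies; `kd_doc = 5` keeps most DOC adsorbed, as
mineral-soil sorption experiments suggest; the 0.3 m root e-folding depth is
a conventional temperate rooting profile. None of these are fitted.

## Worked example

```{r example, eval = FALSE}
cfg <- iso_config()                    # default column, synthetic forcing
steady <- solve_steady_state(cfg)      # 1901 equilibrium
stock_to_depth(steady, depth = 1)      # SOC stock to 1 m, kg C m-2

ctrl <- run_historical(cfg, steady)    # 1901-2011 control run
c4 <- iso_config(scenario = scenario_spec(-27, 2005, switch_year = 1993))
ex <- run_paired_experiment(cfg, c4, initial_state = steady)
head(ex$difference)                    # per-layer delta(C4) - delta(control)
```

Test and example problem sizes are deliberately small — 3–6 layer toy
columns for oracle comparisons, 11 layers for the full column, decade-scale
spin-ups on fast-turnover toys — chosen so the whole suite documents the
model's properties in seconds while exercising every code path; the same
functions run the full multi-millennial spin-up when asked.

## Known limitations

- No temperature/moisture response functions, priming, microbial pools,
  plowing, peatlands or ¹⁴C; environmental modifiers are exogenous inputs.
- Litter δ¹³C is imposed, so any bias in the chosen reference value
  translates one-to-one into the simulated profile.
- Lignin-fraction differential preservation is not represented; bulk pools
  carry a single isotopic signature each.
- The geometric grid stands in for the host model's exact layer sequence,
  which is why its ratio is a configurable parameter.
- Only respiration fractionates; sorption, diffusion and advection move
  both isotopes identically.
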