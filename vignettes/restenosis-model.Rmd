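---
title: "A lattice model of neointimal growth in stented arteries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lattice model of neointimal growth in stented arteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restenosim)
```

## The problem

When a coronary artery is stented, the expanding struts compress and injure
the vessel wall. Injured tissue releases matrix-degrading factors and growth
stimuli; medial smooth muscle cells (SMCs) respond by switching from their
quiescent *contractile* phenotype to a *synthetic* one that migrates,
divides and secretes extracellular matrix (ECM). The resulting new tissue —
neointima — narrows the lumen (in-stent restenosis) until either the
endothelium regrows over the lesion and shuts the process down, or the
tissue re-quiesces on its own.

`restenosim` simulates this process with a cell-centred automaton on a
regular 3D lattice. It is aimed at mechanobiology groups who have (or can
parameterise) a post-expansion stress field for a stented vessel and want a
rule-level, cell-resolution model of the downstream tissue response, with
lesion metrics that can be compared across stent designs and healing
scenarios.

## State

The artery is a hollow cylinder voxelized at spacing $dl$; each lattice
site carries

* a domain label (`outside`, `lumen`, `wall`),
* ECM $\in [0, 1]$ (1 = intact matrix; wall sites start at 1),
* MDF $\ge 0$ (matrix-degrading factors),
* $G \ge 0$ (growth stimulus),
* the signed minimum principal stress (kPa, compression negative), and
* at most one occupant: cSMC, sSMC or EC.

One site holds at most one cell, so the packing density is $dl^{-3}$:
$1.64\times10^5$ cells mm$^{-3}$ at the default $dl = 0.01825$ mm, matching
measured neointimal cell densities. Adjacency uses a configurable stencil
(6, 18 or 26 neighbours); the shipped default is 18 (see *Calibration*).

## Injury initialisation

A finite-element result can be imported (`read_stress_mesh()`, hexahedral
elements with one minimum-principal-stress value each) and rasterised with
`map_stress_to_lattice()`: for each element, sites inside an axis-aligned
bounding box are tested against the six element faces, each treated as its
best-fit plane with inward normal. Warped (non-planar) faces are therefore
handled approximately, to within a thin boundary shell; the test suite
checks exact agreement with a tetrahedral-decomposition oracle for
planar-faced elements, away from faces. Sites claimed by several elements
keep the last element's value in mesh order; such ties only occur in the
boundary-thin overlap shell. `apply_injury()` then removes every occupant
at sites whose stress is *strictly* below $-\sigma_{crit}$ (boundary
equality is uninjured) and sets MDF and $G$ to their initial values there.
ECM is *not* cleared at injury: the MDF load resorbs it dynamically, which
takes $1/c_{deg} = 20$ days at baseline — the calibration the degradation
rate was chosen against.

When no FE result is available, `synthetic_stent_stress()` builds a field
from a parametric description of a corrugated-ring stent. Each ring
contributes a Gaussian ridge of compression along its sinusoidal strut
centreline, decaying exponentially with depth into the wall; crown apexes
(where struts of adjacent rings join) and the first and last rings are
amplified. The defaults — mid-strut peak 45 kPa ($\approx 1.3\,
\sigma_{crit}$), end amplification 2.0, junction amplification 1.3 — were
chosen so that mid-stent struts injure only thin slivers of wall while the
stent ends carry the dominant injured volume. That asymmetry is the
qualitative injury pattern reported for expanded corrugated-ring stents
(largest injury at stent ends and strut junctions), and it is what lets
mid-stent lesions re-quiesce while end-of-stent lesions persist.

## Cell rules

All rules are local and act once per simulated day.

**Phenotype.** An SMC is contractile iff its own site's ECM equals 1
(within $10^{-9}$), no site in its neighbourhood holds *partially degraded
or immature* matrix ($0 < \mathrm{ECM} < 1$), and the local SMC occupancy
over the site-plus-neighbours block (restricted to in-domain sites) is
below $c_{SMC,crit}$; otherwise it is synthetic. The switch is reversible.
Two design points deserve note:

* *Neighbourhood sensing.* Injured sites have their occupants removed, and
  MDF does not diffuse. If cells only sensed their own site's matrix, no
  surviving cell could ever detect the damage next door and the lesion
  cascade could never start. Cells therefore sample adjacent sites — the
  natural reading of environment sampling on a lattice — and partially
  degraded matrix anywhere in the stencil flags the region as damaged.
  Fully bare sites (ECM = 0, i.e. lumen) do **not** count as damage,
  so the healthy wall–lumen interface is quiescent.
* *Crowding threshold.* $c_{SMC,crit}$ is a closure parameter with no
  measured value. The default 0.75 sits far above the baseline seeding
  occupancy ($c_{SMC,init}/c_{max} \approx 0.19$), making the uninjured
  artery a strict fixed point of the dynamics (at 0.5, clipped boundary
  stencils make crowding flips a routine seeding fluctuation), while dense
  lesion cores still register as crowded and stay synthetic until they
  disperse.

**Migration** (sSMC only; cSMCs are quiescent). One neighbour is drawn
uniformly; the move succeeds iff the target is in-domain, unoccupied and
*matrix-anchored* — it carries ECM or touches a site that does. ECs are an
immovable, impenetrable barrier. The rate $v_{SMC}$ converts to
$v_{SMC}/dl$ steps per day (13.15 at baseline).

**SMC division.** Requires $G > G_{crit}$ at the cell's site. The daughter
position is drawn uniformly among the *empty* neighbours (in-domain,
unoccupied) and the attempt fails if that position is not matrix-anchored;
on success $G$ at the parent's site drops by $G_{crit}$ — consumption only
on success. $G_{crit}$ has no measured value; the default 1 lets each
injured site ($G_{init} = 3$) fund a short burst of local divisions before
the stimulus is exhausted, which is what produces the early proliferation
peak followed by decline.

**ECM production.** Each sSMC deposits $c_{ECM} = 0.2$ per day at its own
site, clamped at 1. Tissue growth into the lumen happens exactly this way:
an sSMC steps onto a bare lumen site anchored to the wall and matures it.

**Degradation.** Wherever ECM and MDF are both positive, both drop by
$c_{deg}$, floored at 0 independently. Values within $10^{-9}$ of 0 are
snapped to 0 (and production clamps snap to exactly 1) so that threshold
tests like "resorbed after $1/c_{deg}$ days" are not hostage to binary
floating-point representation of 0.05.

**EC division.** The daughter position is drawn uniformly among empty,
*matrix-free* neighbours and must itself touch matrix — i.e. ECs spread
only along the bare lumen surface, over wall or over neointima, and an EC
can never be buried in tissue. ECs neither move nor die in this model.

## The day loop and sub-daily passes

Each day: (1) degradation; (2) phenotype update of every SMC (so injury
can drive same-day modulation); (3) cell actions; (4) ECM production by
every sSMC alive at dawn; (5) metrics and termination. Within (3), each
cell receives a daily attempt budget by stochastic rounding — the integer
part is deterministic and the fraction becomes one extra attempt with
matching probability, so expectations are exact ($13.15$ migration steps
and a Bernoulli(0.24) division attempt per sSMC, $p_{EC}$ division
attempts per EC, with an sSMC's migration and division attempts shuffled
together). Budgets are consumed one attempt per *pass*, each pass visiting
the cells in a freshly reshuffled order (avoiding sweep artifacts), and
daughters join the schedule at the pass after their birth, their unused
attempts lapsing at day end.

The pass structure is not cosmetic. A daughter can be placed at most one
site beyond the existing cell front, so if daughters only became active the
*next day*, an endothelial front could never advance faster than one
lattice ring per day — a hard geometric ceiling of roughly 220 days for the
8 mm calibration scenario below, regardless of stencil or sampling rule.
Letting daughters act in later passes of the same day is what allows
$p_{EC} = 2$ to heal faster than the ceiling, and is the natural reading of
performing each rate's operations "a number of times per increment" over
the current cell population.

## Calibration

Three parameters are anchored to quantitative behaviours, and each has a
built-in scenario that recomputes the behaviour from scratch
(`resorption_days()`, `measure_migration_speed()`, `measure_ec_healing()`;
the acceptance script and `tests/testthat/test-acceptance.R` run all
three):

* $c_{deg} = 0.05$/day: one injured site resorbs its matrix in exactly 20
  daily increments.
* $v_{SMC} = 0.24$ mm/day: a lone unobstructed sSMC realises a mean daily
  path length of $0.24$ mm (steps $\times\, dl$), exact in expectation by
  stochastic rounding.
* $p_{EC} = 2$ attempts/cell/day: an 8 mm denuded band of a 2.5 mm
  diameter lumen, seeded with ECs at both margins, re-endothelialises in
  about 180 days. This scenario also fixes the remaining neighbourhood
  conventions: with the 18-connected stencil, pass scheduling and
  empty-neighbour daughter sampling, full coverage takes roughly 195–197
  days (within the ±15% acceptance band around 180). The 26-stencil lands
  at ~208 days and pure rejection sampling (drawing over all neighbours
  and failing on any invalid draw) is several times too slow, which is why
  18/pass/empty-draw is the shipped default.

## Metrics

Per day and axial slice $k$, the neointimal area is
$(\#\{\mathrm{ECM} > 0\}_k - \mathrm{baseline}_k)\, dl^2$, floored at 0 —
the lesion is defined as growth, so transient net degradation does not go
negative. Lesion volume is the Riemann sum $dl \sum_k A_k$ (the slice
thickness makes the units mm$^3$). The daily population doubling is
$\log_2(N/N_0)$ with $N_0$ the previous day's total cell count (NA if
$N_0 = 0$); the series telescopes to $\log_2(N_{final}/N_{initial})$.
Termination is `healed_equilibrium` (every qualifying lumen-surface site —
bare lumen touching matrix — EC-occupied, and no sSMC with usable stimulus
or a reachable destination), `occluded` (some stented slice has no free
bare lumen site left), or `time_limit` (default 320 days).

## What the synthetic scenarios do and do not show

The synthetic stress generator reproduces the qualitative footprint of a
corrugated-ring stent — ridges under struts, amplified ends and junctions,
radial decay — not any particular device's FE solution; absolute lesion
volumes under it are not device predictions. Reduced-geometry runs used in
the test suite (3.5 mm segment, $dl = 0.0365$ mm, 160 days) keep the
radii, rates and the *dimensionless* seeding occupancy 0.192 of the
baseline ($c_{SMC,init} = 3.16 \times 10^4$ mm$^{-3}$ exceeds the packing
density at the coarser spacing, so the concentration is scaled to preserve
the occupancy fraction). These sizes were chosen so a laptop run completes
in about a minute while still exhibiting the behaviours the model is
known for: lesion volume decreasing in $p_{EC}$, focal end-of-stent
thickening without healing, and an early proliferation peak. Front speeds
in *lattice units* are resolution-independent, so EC healing in days is
effectively twice as fast at $dl = 0.0365$ as at baseline spacing —
cross-resolution comparisons of healing-limited quantities should be made
in mm/day, or at matched $dl$.

Passing tests on these scenarios show the rules are implemented as
documented and calibrated where calibration was defined. They do not show
fidelity to any patient geometry, drug-eluting behaviour, thrombosis,
inflammation resolution, EC migration or apoptosis, or wall deformation
during growth — none of which are modelled.

## Numerical conventions

* ECM/MDF/G comparisons use a $10^{-9}$ tolerance; near-zero snaps to 0,
  production clamps to exactly 1.
* Injury and proliferation thresholds are strict (`>`); boundary equality
  does nothing.
* Random numbers come from R's global stream (`set.seed()` upstream, or
  the `seed` argument of `run_simulation()`); identical seeds give
  byte-identical runs, including the metrics CSV.
* Degenerate hexahedra (volume $< 10^{-8} \times$ bounding-box diagonal
  cubed) are rejected; multi-element site claims resolve last-writer-wins.
* The full-circumference lattice is simulated (no symmetry sector): cell
  dynamics are stochastic and the metrics are defined per full
  cross-section.

## A small worked run

```{r example, eval = FALSE}
dl <- 0.0365
geom <- artery_geometry(length = 3.5, r_inner = 1.25, r_outer = 1.875,
                        stent = c(0.7, 2.8))
p <- sim_params(dl = dl, c_smc_init = 0.192 / dl^3, days_max = 160)
cfg <- sim_config(geometry = geom, params = p,
                  stent = stent_spec(z_lo = 0.7, z_hi = 2.8, n_rings = 4))
sim <- run_simulation(cfg, seed = 1)
glance(sim)
autoplot(sim)
```
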