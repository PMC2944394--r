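# restenosim

A cell-centred, lattice-based simulator of **in-stent restenosis** — the
re-narrowing of a stented artery by neointimal tissue. It is written for
vascular mechanobiology groups who have (or can parameterise) a
post-expansion stress field for a stented vessel and want a rule-level,
cell-resolution model of the downstream tissue response: injury, smooth
muscle cell (SMC) activation, lesion growth, and endothelial healing.

## The model

The artery is a hollow cylinder voxelized into a regular 3D lattice of
spacing *dl* (one cell per site, so the packing density is
*dl*⁻³ = 1.64×10⁵ cells mm⁻³ at the default *dl* = 0.01825 mm). Each site
carries a domain label (outside / lumen / wall), extracellular matrix
ECM ∈ [0,1], matrix-degrading factors MDF ≥ 0, a growth stimulus G ≥ 0,
the signed minimum principal stress (kPa), and at most one occupant
(contractile SMC, synthetic SMC, or endothelial cell).

* **Injury.** Per-element minimum principal stress from a finite-element
  result (or a synthetic corrugated-ring stent field) is rasterised onto
  the lattice; sites compressed beyond σ_crit = 35 kPa lose their cells
  and receive MDF = 1 and G = 3.
* **Degradation.** Where ECM and MDF coexist, both decay at
  c_deg = 0.05/day — injured tissue fully resorbs in 20 days.
* **Phenotype.** An SMC stays contractile while its neighbourhood matrix
  is intact and local crowding is below c_SMC,crit; degraded matrix nearby
  switches it (reversibly) to the synthetic phenotype.
* **Synthetic SMCs** random-walk at v_SMC = 0.24 mm/day through
  matrix-anchored sites, divide where G > G_crit (each division consumes
  G_crit), and deposit ECM at c_ECM = 0.2/day — tissue growth into the
  lumen is literally cells stepping onto the bare surface and maturing it.
* **Endothelium.** ECs cover the lumen surface outside the stented
  segment and spread over bare, matrix-anchored surface at p_EC
  attempts/cell/day (p_EC = 2 heals an 8 mm denuded artery in ≈180 days);
  an EC-occupied site is an impenetrable barrier to SMCs, so a healed
  surface arrests the lesion.

Per day the model reports cell counts, the population doubling
log₂(N/N₀), the neointimal area per axial slice (ECM-bearing sites in
excess of the day-0 cross-section, × *dl*²) and the lesion volume (their
Riemann sum). Details, design rationale and numerical conventions are in
the methods vignette (`vignettes/restenosis-model.Rmd`).

## Worked example

A reduced geometry (3.5 mm segment, same radii as the baseline artery,
*dl* = 0.0365 mm, stent over [0.7, 2.8] mm, seeding occupancy 0.192) runs
in about 40 s:

```r
library(restenosim)

dl   <- 0.0365
geom <- artery_geometry(length = 3.5, r_inner = 1.25, r_outer = 1.875,
                        stent = c(0.7, 2.8))
p    <- sim_params(dl = dl, c_smc_init = 0.192 / dl^3, days_max = 160)
cfg  <- sim_config(geometry = geom, params = p,
                   stent = stent_spec(z_lo = 0.7, z_hi = 2.8, n_rings = 4))
sim  <- run_simulation(cfg, seed = 1)
sim
#> <restenosis_sim> 160 day(s), termination: time_limit
#>   final: 109841 cSMC, 6 sSMC, 41630 EC, lesion volume 0.006467 mm^3
#>   seed: 1

tidy(sim)[c(1, 10, 30, 90, 160), c("day", "n_ssmc", "n_ec", "div_smc",
                                   "doubling", "lesion_volume")]
#>   day n_ssmc  n_ec div_smc   doubling lesion_volume
#> 1   1   3703 12087     183 0.03093024   0.012643052
#> 2  10   2982 31762     459 0.00818558   0.074350874
#> 3  30  11203 41630    1212 0.01239408   0.006467408
#> 4  90      7 41630       0 0.00000000   0.006467408
#> 5 160      6 41630       0 0.00000000   0.006467408
```

Reading the trace: injury under the struts activates thousands of sSMCs
within days; divisions (funded by the local stimulus G) and the population
doubling peak in the first weeks and then fall as G is consumed; the
endothelium (n_ec) seals the short stented segment by day ~30 — about 4×
sooner in days than at baseline spacing, since the front advances at a
resolution-independent number of lattice rings per day — after which the
lesion volume is flat and the sSMC population re-quiesces to the
contractile phenotype. The transient volume peak around day 10 is injured
wall matrix that has not yet resorbed plus early lumen deposits;
`slice_areas(sim)` gives the per-slice breakdown and `autoplot(sim)` the
time courses.

`write_metrics_csv()`, `write_snapshot_vtk()` / `read_snapshot_vtk()` and
`read_stress_mesh()` / `write_stress_mesh()` (neutral text format, plus a
VTK legacy reader/writer) cover the on-disk formats; a command-line front
end with `run`, `make-stress` and `metrics` subcommands is installed at
`inst/cli/restenosim.R` (YAML configs; see its header).

## Repository layout

* `R/`, `src/` — the package (lattice and geometry, stress import and
  synthetic stent fields, cell rules, compiled day-stepping engine,
  metrics, IO, tidiers and plots)
* `tests/testthat/` — unit, property and acceptance tests, with
  independent geometric oracles in `helper-oracles.R`
* `vignettes/restenosis-model.Rmd` — the methods vignette
* `scripts/acceptance.R` — the calibration reproduction script
* `inst/cli/restenosim.R` — command-line front end
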