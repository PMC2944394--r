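#' Built-in calibration and measurement scenarios
#'
#' Three minimal scenarios isolate one rule each and report the quantity the
#' corresponding parameter was calibrated against. They are used by the
#' package's acceptance checks and are convenient for sensitivity studies.
#'
#' `resorption_days()` tracks a single injured site (full matrix under unit
#' MDF, no cells) and counts the daily increments until the matrix is gone:
#' `1 / c_deg` days (20 at baseline).
#'
#' `measure_migration_speed()` follows one unobstructed sSMC random-walking
#' through uniform matrix (held below 1 so the cell stays synthetic, with
#' matrix production and proliferation disabled) and reports its mean daily
#' path length, successful steps times `dl`: the realised migration speed,
#' which should equal `v_smc` (0.24 mm/day at baseline).
#'
#' `measure_ec_healing()` denudes a central axial band of a cylindrical
#' lumen surface, seeds ECs on the margins, and reports the number of days
#' until every qualifying surface site is EC-occupied. At baseline
#' (`p_ec = 2`, 8 mm band, 2.5 mm lumen diameter) the surface heals in
#' about 180 days, the calibration that fixed both `p_ec` and the default
#' neighbourhood convention.
#'
#' @param params a [sim_params()]; the relevant rates are read from it.
#' @name calibration
NULL

#' @rdname calibration
#' @param max_days safety cap on the simulated days.
#' @return `resorption_days()`: integer number of days.
#' @export
resorption_days <- function(params = sim_params(), max_days = 10000) {
  lat <- block_lattice(c(1, 1, 1), params$dl)
  lat$mdf[1] <- params$mdf_init
  for (day in seq_len(max_days)) {
    lat <- degrade_matrix(lat, params)
    if (lat$ecm[1] <= 0) return(day)
  }
  abort("matrix not resorbed within max_days")
}

#' @rdname calibration
#' @param days days to average over.
#' @return `measure_migration_speed()`: mean path length, mm/day.
#' @export
measure_migration_speed <- function(params = sim_params(), days = 200) {
  p <- params
  p$c_ecm <- 0 # hold the matrix fixed so the walk never quiesces
  p$p_smc <- 0
  n <- 41L
  lat <- block_lattice(c(n, n, n), p$dl, ecm = 0.5)
  mid <- (n + 1L) %/% 2L
  lat$occ[mid, mid, mid] <- OCC_SSMC
  res <- simulate_days(lat, p, days = days, record_slices = FALSE,
                       stop_on_termination = FALSE)
  mean(res$metrics$steps) * p$dl
}

#' @rdname calibration
#' @param band axial length of the denuded segment, mm.
#' @param margin length of EC-covered lumen on each side of the band, mm.
#' @param r_lumen lumen radius, mm.
#' @param wall_sites radial thickness of the matrix wall, in sites (the EC
#'   front runs on the lumen surface; only a thin anchoring wall is needed).
#' @param max_days safety cap on the simulated days.
#' @return `measure_ec_healing()`: integer days to full coverage.
#' @export
measure_ec_healing <- function(params = sim_params(), band = 8,
                               margin = 0.3, r_lumen = 1.25,
                               wall_sites = 3, max_days = 1000) {
  dl <- params$dl
  len <- band + 2 * margin
  geom <- artery_geometry(
    length = len, r_inner = r_lumen, r_outer = r_lumen + wall_sites * dl,
    stent = c(margin, margin + band)
  )
  lat <- build_artery_lattice(geom, dl)
  lat <- seed_endothelium(lat, stencil = params$stencil)
  res <- simulate_days(lat, params, days = max_days, record_slices = FALSE,
                       stop_on_termination = TRUE)
  if (res$termination != "healed_equilibrium") {
    abort(sprintf("surface not healed within %d days", max_days))
  }
  res$days_run
}

#' Hand-traceable single-injury scenario
#'
#' A 3x3x3 all-wall block whose centre site is injured (occupant removed,
#' `MDF = mdf_init`, `G = g_init`) with one contractile SMC on an adjacent
#' site. Running it for a few simulated weeks walks through the entire rule
#' chain on 27 sites: degradation starts, the neighbouring cSMC modulates,
#' wanders in, divides at most `g_init / g_crit` times on the stimulus
#' site, restores matrix, and the block re-quiesces.
#'
#' @param params a [sim_params()].
#' @return An `artery_lattice`.
#' @export
micro_injury_scenario <- function(params = sim_params()) {
  lat <- block_lattice(c(3, 3, 3), params$dl)
  lat$mdf[2, 2, 2] <- params$mdf_init
  lat$g[2, 2, 2] <- params$g_init
  lat$occ[1, 2, 2] <- OCC_CSMC
  lat
}
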