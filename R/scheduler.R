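#' Convert a daily rate to an integer number of attempts
#'
#' Rates enter the daily update as attempt counts. Migration at speed
#' `v_smc` (mm/day) on a grid of spacing `dl` corresponds to `v_smc / dl`
#' steps per day; proliferation rates are attempts per day directly. The
#' integer part is taken deterministically and the fractional part becomes
#' one extra attempt with probability equal to it (stochastic rounding), so
#' the expected number of attempts equals the rate exactly.
#'
#' @param rate non-negative daily rate (mm/day for migration, 1/day
#'   otherwise).
#' @param dl lattice spacing, mm; supply it to convert a speed into steps.
#' @param n number of independent draws to return.
#' @return Integer vector of length `n`.
#' @examples
#' set.seed(1)
#' mean(rate_to_attempts(0.24, dl = 0.01825, n = 1e4)) # ~13.15
#' @export
rate_to_attempts <- function(rate, dl = NULL, n = 1) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate < 0) {
    abort("`rate` must be a single non-negative number")
  }
  x <- if (is.null(dl)) rate else rate / dl
  base <- floor(x)
  as.integer(base + (runif(n) < (x - base)))
}

engine_par <- function(params, k_range) {
  list(
    dl = params$dl, v_smc = params$v_smc, p_smc = params$p_smc,
    p_ec = params$p_ec, c_ecm = params$c_ecm, c_deg = params$c_deg,
    g_crit = params$g_crit, c_smc_crit = params$c_smc_crit,
    stencil = params$stencil,
    k_lo = if (is.null(k_range)) -1L else as.integer(k_range[1] - 1L),
    k_hi = if (is.null(k_range)) -1L else as.integer(k_range[2] - 1L)
  )
}

# slices whose centres lie within the stent extent (occlusion is judged
# inside the stented segment)
stent_slices <- function(lattice, stent = lattice$geometry$stent) {
  if (is.null(stent)) return(NULL)
  z <- (seq_len(lattice$dims[3]) - 0.5) * lattice$dl
  k <- which(z >= stent[1] & z <= stent[2])
  if (length(k) == 0) NULL else range(k)
}

#' Advance a lattice by whole days
#'
#' Runs the compiled scheduler for up to `days` one-day increments. Each
#' day proceeds in a fixed order: (1) matrix degradation; (2) phenotype
#' update of every SMC; (3) cell actions: every cell's attempt budget for
#' the day (stochastic rounding of `v_smc/dl` migration steps plus `p_smc`
#' division attempts for sSMCs, `p_ec` division attempts for ECs) is
#' consumed one attempt per sub-daily pass, each pass visiting the cells in
#' a freshly shuffled order; daughters enter the schedule at the pass after
#' their birth and their unused attempts lapse at the end of the day;
#' (4) every sSMC alive at dawn deposits matrix at its site; (5) metrics are
#' recorded and termination is evaluated.
#'
#' @param lattice an artery lattice with stress, injury and cells applied.
#' @param params a [sim_params()].
#' @param days number of days to simulate (defaults to `params$days_max`).
#' @param record_slices record per-slice matrix-bearing site counts each day
#'   (needed for neointimal areas; disable for very large lattices).
#' @param stop_on_termination stop as soon as the run heals or occludes.
#' @param occlusion_slices `c(k_min, k_max)` slice range for the occlusion
#'   check, or `NULL` to derive it from the geometry's stent extent.
#' @return A list with the advanced `lattice`, a `metrics` tibble (one row
#'   per simulated day), the per-day by-slice count matrix `slice_ecm` (if
#'   recorded), `days_run` and `termination` (`"running"`,
#'   `"healed_equilibrium"`, `"occluded"`; [run_simulation()] adds
#'   `"time_limit"`).
#' @export
simulate_days <- function(lattice, params, days = params$days_max,
                          record_slices = TRUE, stop_on_termination = TRUE,
                          occlusion_slices = NULL) {
  stopifnot(inherits(lattice, "artery_lattice"), inherits(params, "sim_params"))
  if (is.null(occlusion_slices)) occlusion_slices <- stent_slices(lattice)
  res <- cpp_run_days(
    as.integer(lattice$domain), as.double(lattice$ecm),
    as.double(lattice$mdf), as.double(lattice$g), as.integer(lattice$occ),
    as.integer(lattice$dims), engine_par(params, occlusion_slices),
    as.integer(days), record_slices, stop_on_termination
  )
  dm <- lattice$dims
  lattice$ecm <- array(res$ecm, dm)
  lattice$mdf <- array(res$mdf, dm)
  lattice$g <- array(res$g, dm)
  lattice$occ <- array(res$occ, dm)
  metrics <- tibble(
    day = seq_len(res$days_run),
    n_csmc = res$n_csmc, n_ssmc = res$n_ssmc, n_ec = res$n_ec,
    n_cells = res$n_csmc + res$n_ssmc + res$n_ec,
    div_smc = res$div_smc, div_ec = res$div_ec, steps = res$steps,
    g_total = res$g_total
  )
  list(
    lattice = lattice, metrics = metrics,
    slice_ecm = if (record_slices) res$slice_ecm else NULL,
    days_run = res$days_run, termination = res$termination
  )
}

#' @rdname simulate_days
#' @export
step_day <- function(lattice, params, record_slices = TRUE) {
  simulate_days(lattice, params, days = 1, record_slices = record_slices,
                stop_on_termination = FALSE)
}

#' Termination state of a simulation
#'
#' A run ends in `healed_equilibrium` when every qualifying lumen-surface
#' site holds an EC and no sSMC is still active (none has a usable growth
#' stimulus or a reachable destination); in `occluded` when some axial
#' slice within the stented segment has no free, matrix-free lumen site
#' left; and in `time_limit` at `params$days_max`.
#'
#' @param lattice an artery lattice.
#' @param params a [sim_params()].
#' @param day current day (optional; enables the `time_limit` state).
#' @param occlusion_slices slice range checked for occlusion; defaults to
#'   the stented slices.
#' @return One of `"running"`, `"healed_equilibrium"`, `"occluded"`,
#'   `"time_limit"`.
#' @export
check_termination <- function(lattice, params, day = NULL,
                              occlusion_slices = NULL) {
  if (is.null(occlusion_slices)) occlusion_slices <- stent_slices(lattice)
  cen <- cpp_surface_census(
    as.integer(lattice$domain), as.double(lattice$ecm),
    as.integer(lattice$occ), as.integer(lattice$dims), params$stencil
  )
  if (!is.null(occlusion_slices)) {
    k <- seq.int(occlusion_slices[1], occlusion_slices[2])
    if (any(cen$free_lumen_by_slice[k] == 0)) return("occluded")
  }
  if (cen$unhealed == 0 && !any_active_ssmc(lattice, params)) {
    return("healed_equilibrium")
  }
  if (!is.null(day) && day >= params$days_max) return("time_limit")
  "running"
}

any_active_ssmc <- function(lattice, params) {
  idx <- which(lattice$occ == OCC_SSMC)
  d <- lattice$dims
  for (s in idx) {
    site <- c(
      (s - 1L) %% d[1] + 1L, ((s - 1L) %/% d[1]) %% d[2] + 1L,
      (s - 1L) %/% (d[1] * d[2]) + 1L
    )
    if (lattice$g[s] > params$g_crit) return(TRUE)
    nb <- site_neighbors(lattice, site, params$stencil)
    nb_idx <- nb[, 1] + d[1] * ((nb[, 2] - 1L) + d[2] * (nb[, 3] - 1L))
    free <- lattice$domain[nb_idx] != DOM_OUTSIDE &
      lattice$occ[nb_idx] == OCC_NONE
    if (any(free)) {
      anchored <- lattice$ecm[nb_idx] > ECM_TOL
      for (t in which(free)) {
        if (anchored[t]) return(TRUE)
        dn <- site_neighbors(lattice, nb[t, ], params$stencil)
        dn_idx <- dn[, 1] + d[1] * ((dn[, 2] - 1L) + d[2] * (dn[, 3] - 1L))
        if (any(lattice$ecm[dn_idx] > ECM_TOL)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Simulation configuration
#'
#' Bundles everything [run_simulation()] needs: the geometry, the model
#' parameters, and the source of the stress field (a stent description for
#' the synthetic generator, or an imported finite-element stress mesh).
#'
#' @param geometry an [artery_geometry()].
#' @param params a [sim_params()].
#' @param stent a [stent_spec()]; by default aligned with the geometry's
#'   stented extent.
#' @param mesh optional [stress_mesh()]; when supplied it overrides the
#'   synthetic field.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(geometry = artery_geometry(), params = sim_params(),
                       stent = NULL, mesh = NULL) {
  if (is.null(stent)) {
    stent <- stent_spec(z_lo = geometry$stent[1], z_hi = geometry$stent[2])
  }
  structure(list(geometry = geometry, params = params, stent = stent,
                 mesh = mesh),
            class = "sim_config")
}

#' Run a full restenosis simulation
#'
#' Builds the lattice, assigns the stress field (imported or synthetic),
#' seeds SMCs, applies the injury threshold, seeds the endothelium outside
#' the stented segment, and advances day by day until the lesion heals, the
#' lumen occludes, or `days` elapse.
#'
#' @param config a [sim_config()].
#' @param days maximum days (defaults to `params$days_max`).
#' @param seed optional integer seed for the R random stream; recorded in
#'   the result. Runs with the same seed are identical.
#' @param record_slices record per-slice ECM counts (required for area and
#'   volume metrics).
#' @param snapshot_every write a VTK snapshot of the lattice every this many
#'   days (requires `out_dir`).
#' @param out_dir directory for snapshots.
#' @return An object of class `restenosis_sim` with elements `metrics` (a
#'   tibble, one row per day, including `lesion_volume` in mm^3 and
#'   `doubling`, the daily population doubling log2(N/N_prev)), `areas`
#'   (day x slice matrix of neointimal areas, mm^2), `baseline` (day-0
#'   per-slice ECM site counts), `lattice` (final state), `termination`,
#'   `days_run`, `seed`, `config`. See [tidy.restenosis_sim()],
#'   [glance.restenosis_sim()] and [autoplot.restenosis_sim()].
#' @export
run_simulation <- function(config = sim_config(), days = NULL, seed = NULL,
                           record_slices = TRUE, snapshot_every = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  params <- config$params
  if (is.null(days)) days <- params$days_max
  if (!is.null(seed)) set.seed(seed)
  lat <- build_artery_lattice(config$geometry, params$dl)
  lat <- if (is.null(config$mesh)) {
    synthetic_stent_stress(lat, config$stent)
  } else {
    map_stress_to_lattice(config$mesh, lat)
  }
  lat <- seed_cells(lat, params)
  lat <- apply_injury(lat, params)
  lat <- seed_endothelium(lat, stencil = params$stencil)
  baseline <- slice_ecm_counts(lat)
  n0 <- sum(lat$occ != OCC_NONE)

  snapshot <- function(lattice, day) {
    if (!is.null(snapshot_every) && !is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_snapshot_vtk(
        lattice, file.path(out_dir, sprintf("day_%04d.vtk", day))
      )
    }
  }
  snapshot(lat, 0L)

  chunk <- if (is.null(snapshot_every)) days else snapshot_every
  day <- 0L
  metrics <- list()
  slices <- list()
  termination <- "running"
  while (day < days && termination == "running") {
    res <- simulate_days(lat, params, days = min(chunk, days - day),
                         record_slices = record_slices)
    lat <- res$lattice
    res$metrics$day <- res$metrics$day + day
    day <- day + res$days_run
    metrics[[length(metrics) + 1L]] <- res$metrics
    if (record_slices) slices[[length(slices) + 1L]] <- res$slice_ecm
    termination <- res$termination
    snapshot(lat, day)
  }
  if (termination == "running" && day >= days) termination <- "time_limit"

  metrics <- dplyr::bind_rows(metrics)
  areas <- NULL
  if (record_slices) {
    counts <- do.call(rbind, slices)
    areas <- neointimal_area_matrix(counts, baseline, params$dl)
    metrics$lesion_volume <- apply(areas, 1, lesion_volume, dl = params$dl)
  }
  metrics$doubling <- population_doubling(
    metrics$n_cells, dplyr::lag(metrics$n_cells, default = n0)
  )
  structure(
    list(
      metrics = metrics, areas = areas, baseline = baseline, lattice = lat,
      termination = termination, days_run = day, seed = seed, config = config
    ),
    class = "restenosis_sim"
  )
}
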