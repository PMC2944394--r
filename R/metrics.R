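#' Lesion metrics
#'
#' The neointimal area of an axial slice is the area of its matrix-bearing
#' sites in excess of the day-0 cross-section: `(count - baseline) * dl^2`,
#' floored at zero (the lesion is defined as growth; transient net
#' degradation does not count negatively). The lesion volume is the Riemann
#' sum of the slice areas with slice thickness `dl`. The daily population
#' doubling is `log2(N / N0)` with `N0` the previous day's cell count; the
#' series telescopes to `log2(N_final / N_initial)`.
#'
#' @param lattice an artery lattice.
#' @param slice axial slice index `k`.
#' @param baseline per-slice matrix-bearing site counts at day 0, from
#'   [slice_ecm_counts()] on the initial lattice.
#' @return `neointimal_area()`: area in mm^2.
#' @name lesion_metrics
NULL

#' @rdname lesion_metrics
#' @export
slice_ecm_counts <- function(lattice) {
  d <- lattice$dims
  colSums(matrix(lattice$ecm > ECM_TOL, d[1] * d[2], d[3]))
}

#' @rdname lesion_metrics
#' @export
neointimal_area <- function(lattice, slice, baseline) {
  slice <- as.integer(slice)
  if (slice < 1L || slice > lattice$dims[3]) {
    abort(sprintf("slice %d outside 1..%d", slice, lattice$dims[3]))
  }
  cnt <- sum(lattice$ecm[, , slice] > ECM_TOL)
  max(cnt - baseline[slice], 0) * lattice$dl^2
}

# counts: day x slice matrix of matrix-bearing sites
neointimal_area_matrix <- function(counts, baseline, dl) {
  pmax(sweep(counts, 2, baseline), 0) * dl^2
}

#' @rdname lesion_metrics
#' @param areas vector (or one row per day) of per-slice areas, mm^2.
#' @param dl lattice spacing, mm.
#' @return `lesion_volume()`: volume in mm^3.
#' @export
lesion_volume <- function(areas, dl) {
  dl * sum(areas)
}

#' @rdname lesion_metrics
#' @param n,n0 cell counts (vectorised); `n0` is the previous day's count.
#' @return `population_doubling()`: `log2(n / n0)`, `NA` where `n0` is zero
#'   (undefined rather than an error).
#' @export
population_doubling <- function(n, n0) {
  out <- suppressWarnings(log2(n / n0))
  out[n0 == 0] <- NA_real_
  out
}

#' Per-slice neointimal areas of a simulation, tidy
#'
#' @param sim a [run_simulation()] result.
#' @return A tibble with columns `day`, `slice`, `z` (slice centre, mm) and
#'   `area` (mm^2).
#' @export
slice_areas <- function(sim) {
  stopifnot(inherits(sim, "restenosis_sim"))
  if (is.null(sim$areas)) {
    abort("this simulation was run with record_slices = FALSE")
  }
  dl <- sim$config$params$dl
  nz <- ncol(sim$areas)
  tibble(
    day = rep(sim$metrics$day, each = nz),
    slice = rep(seq_len(nz), times = nrow(sim$areas)),
    z = rep((seq_len(nz) - 0.5) * dl, times = nrow(sim$areas)),
    area = as.vector(t(sim$areas))
  )
}
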