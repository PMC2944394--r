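#' Per-cell behavioural rules
#'
#' These functions implement the behavioural rules for a single cell or a
#' single day, operating on an artery lattice. They are the rule surface of
#' the model; [step_day()] applies the same rules to every cell through the
#' compiled scheduler. All random draws use the R random number stream.
#'
#' @name cell_rules
#' @param lattice an artery lattice.
#' @param site integer triple `c(i, j, k)` of the acting cell.
#' @param params a [sim_params()].
NULL

occupant_at <- function(lattice, site) lattice$occ[flat_index(lattice, check_site(lattice, site))]

# synthetic when the cell's own matrix is not intact, when any neighbouring
# site holds partially degraded or immature matrix (0 < ECM < 1), or when
# the neighbourhood is crowded; contractile otherwise. Matrix-free sites
# (lumen) do not count as degraded, so the healthy wall is quiescent.
#' @rdname cell_rules
#' @return `update_phenotype()`: `"cSMC"` or `"sSMC"`.
#' @export
update_phenotype <- function(lattice, site, params) {
  site <- check_site(lattice, site)
  idx <- flat_index(lattice, site)
  if (!lattice$occ[idx] %in% c(OCC_CSMC, OCC_SSMC)) {
    abort("update_phenotype() applies to SMCs only")
  }
  synth <- lattice$ecm[idx] < 1 - ECM_TOL
  if (!synth) {
    nb <- site_neighbors(lattice, site, params$stencil)
    nb_idx <- nb[, 1] + lattice$dims[1] *
      ((nb[, 2] - 1L) + lattice$dims[2] * (nb[, 3] - 1L))
    e <- lattice$ecm[nb_idx]
    synth <- any(e > ECM_TOL & e < 1 - ECM_TOL)
  }
  if (!synth) {
    synth <- local_cell_concentration(lattice, site, params$stencil) >=
      params$c_smc_crit
  }
  if (synth) "sSMC" else "cSMC"
}

# a destination supports SMC movement when it carries matrix or touches
# matrix-bearing sites
smc_destination_ok <- function(lattice, idx, site, params) {
  if (lattice$domain[idx] == DOM_OUTSIDE || lattice$occ[idx] != OCC_NONE) {
    return(FALSE)
  }
  if (lattice$ecm[idx] > ECM_TOL) return(TRUE)
  nb <- site_neighbors(lattice, site, params$stencil)
  nb_idx <- nb[, 1] + lattice$dims[1] *
    ((nb[, 2] - 1L) + lattice$dims[2] * (nb[, 3] - 1L))
  any(lattice$ecm[nb_idx] > ECM_TOL)
}

#' @rdname cell_rules
#' @return `attempt_migration()`: a list with the updated `lattice`, logical
#'   `moved` and the destination `site`.
#' @export
attempt_migration <- function(lattice, site, params) {
  site <- check_site(lattice, site)
  idx <- flat_index(lattice, site)
  if (lattice$occ[idx] != OCC_SSMC) {
    abort("only sSMCs migrate (cSMCs are quiescent, ECs do not move)")
  }
  nb <- site_neighbors(lattice, site, params$stencil)
  pick <- nb[sample.int(nrow(nb), 1L), ]
  pidx <- flat_index(lattice, pick)
  if (smc_destination_ok(lattice, pidx, pick, params)) {
    lattice$occ[idx] <- OCC_NONE
    lattice$occ[pidx] <- OCC_SSMC
    list(lattice = lattice, moved = TRUE, site = pick)
  } else {
    list(lattice = lattice, moved = FALSE, site = site)
  }
}

#' @rdname cell_rules
#' @details
#' A division attempt draws the daughter position uniformly among the
#' *empty* neighbouring sites (unoccupied and inside the domain; for ECs
#' also matrix-free) and fails if that position is not anchored to matrix.
#' An sSMC division additionally requires the local growth stimulus to
#' exceed `g_crit`, and a successful division consumes `g_crit` of it at
#' the parent's site. EC-occupied sites are never drawn (an EC is an
#' immovable, impenetrable barrier to SMCs).
#' @return `attempt_proliferation_smc()` and `attempt_proliferation_ec()`: a
#'   list with the updated `lattice` and `daughter` (site triple or `NULL`).
#' @export
attempt_proliferation_smc <- function(lattice, site, params) {
  site <- check_site(lattice, site)
  idx <- flat_index(lattice, site)
  if (lattice$occ[idx] != OCC_SSMC) abort("only sSMCs proliferate")
  if (lattice$g[idx] <= params$g_crit) {
    return(list(lattice = lattice, daughter = NULL))
  }
  nb <- site_neighbors(lattice, site, params$stencil)
  nb_idx <- nb[, 1] + lattice$dims[1] *
    ((nb[, 2] - 1L) + lattice$dims[2] * (nb[, 3] - 1L))
  empty <- lattice$domain[nb_idx] != DOM_OUTSIDE & lattice$occ[nb_idx] == OCC_NONE
  if (!any(empty)) return(list(lattice = lattice, daughter = NULL))
  w <- which(empty)
  pick <- w[sample.int(length(w), 1L)]
  dsite <- nb[pick, ]
  if (!smc_destination_ok(lattice, nb_idx[pick], dsite, params)) {
    return(list(lattice = lattice, daughter = NULL))
  }
  lattice$occ[nb_idx[pick]] <- OCC_SSMC
  lattice$g[idx] <- max(lattice$g[idx] - params$g_crit, 0)
  list(lattice = lattice, daughter = dsite)
}

#' @rdname cell_rules
#' @export
attempt_proliferation_ec <- function(lattice, site, params) {
  site <- check_site(lattice, site)
  idx <- flat_index(lattice, site)
  if (lattice$occ[idx] != OCC_EC) abort("attempt_proliferation_ec() applies to ECs")
  nb <- site_neighbors(lattice, site, params$stencil)
  nb_idx <- nb[, 1] + lattice$dims[1] *
    ((nb[, 2] - 1L) + lattice$dims[2] * (nb[, 3] - 1L))
  empty <- lattice$domain[nb_idx] != DOM_OUTSIDE &
    lattice$occ[nb_idx] == OCC_NONE & lattice$ecm[nb_idx] <= ECM_TOL
  if (!any(empty)) return(list(lattice = lattice, daughter = NULL))
  w <- which(empty)
  pick <- w[sample.int(length(w), 1L)]
  dsite <- nb[pick, ]
  dn <- site_neighbors(lattice, dsite, params$stencil)
  dn_idx <- dn[, 1] + lattice$dims[1] *
    ((dn[, 2] - 1L) + lattice$dims[2] * (dn[, 3] - 1L))
  if (!any(lattice$ecm[dn_idx] > ECM_TOL)) {
    return(list(lattice = lattice, daughter = NULL))
  }
  lattice$occ[nb_idx[pick]] <- OCC_EC
  list(lattice = lattice, daughter = dsite)
}

#' @rdname cell_rules
#' @return `produce_ecm()`: the updated lattice (ECM at the cell's site
#'   raised by `c_ecm`, clamped to 1).
#' @export
produce_ecm <- function(lattice, site, params) {
  site <- check_site(lattice, site)
  idx <- flat_index(lattice, site)
  if (lattice$occ[idx] != OCC_SSMC) abort("only sSMCs produce matrix")
  lattice$ecm[idx] <- min(lattice$ecm[idx] + params$c_ecm, 1)
  lattice
}

#' @rdname cell_rules
#' @return `degrade_matrix()`: the updated lattice. At every site holding
#'   both ECM and MDF the two are reduced by `c_deg`, independently floored
#'   at zero (values within 1e-9 of zero are snapped to zero so that, e.g.,
#'   full matrix under unit MDF resorbs in exactly `1/c_deg` days).
#' @export
degrade_matrix <- function(lattice, params) {
  hit <- lattice$ecm > ECM_TOL & lattice$mdf > ECM_TOL
  e <- lattice$ecm[hit] - params$c_deg
  m <- lattice$mdf[hit] - params$c_deg
  e[e < ECM_TOL] <- 0
  m[m < ECM_TOL] <- 0
  lattice$ecm[hit] <- e
  lattice$mdf[hit] <- m
  lattice
}
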