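#' Voxelize an artery into a regular lattice
#'
#' Builds the axis-aligned 3D lattice that hosts the whole simulation. The
#' artery axis runs along z through the centre of the x-y plane. A site
#' whose centre lies at radial distance r from the axis is classified as
#' `wall` when `r_inner <= r < r_outer`, `lumen` when `r < r_inner`, and
#' `outside` otherwise; classification uses the radius only, so every axial
#' slice is equivalent. Wall sites start with intact matrix (ECM = 1); all
#' other fields are zero and no site is occupied.
#'
#' Site centres sit at `(i - 1/2) * dl` along each axis (1-based indices);
#' one site of margin is added around the cylinder in x and y.
#'
#' @param geometry an [artery_geometry()].
#' @param dl lattice spacing, mm.
#' @return An object of class `artery_lattice`: a list with `dims`, `dl`,
#'   `axis` (x-y position of the artery axis, mm), `geometry`, and 3D arrays
#'   `domain` (0 outside, 1 lumen, 2 wall), `ecm`, `mdf`, `g`, `stress`
#'   (signed minimum principal stress, kPa) and `occ` (0 none, 1 cSMC,
#'   2 sSMC, 3 EC).
#' @examples
#' lat <- build_artery_lattice(artery_geometry(length = 1), dl = 0.1)
#' table(lat$domain)
#' @export
build_artery_lattice <- function(geometry, dl) {
  if (!inherits(geometry, "artery_geometry")) {
    abort("`geometry` must be an artery_geometry()")
  }
  if (!is.numeric(dl) || dl <= 0) abort("`dl` must be positive")
  nxy <- as.integer(ceiling(2 * geometry$r_outer / dl)) + 2L
  nz <- as.integer(ceiling(geometry$length / dl))
  cx <- nxy * dl / 2
  x <- (seq_len(nxy) - 0.5) * dl - cx
  r <- sqrt(outer(x^2, x^2, `+`)) # nxy x nxy radii of site centres
  plane <- matrix(DOM_OUTSIDE, nxy, nxy)
  plane[r < geometry$r_inner] <- DOM_LUMEN
  plane[r >= geometry$r_inner & r < geometry$r_outer] <- DOM_WALL
  domain <- array(plane, dim = c(nxy, nxy, nz))
  ecm <- array(0, dim = dim(domain))
  ecm[domain == DOM_WALL] <- 1
  zero <- array(0, dim = dim(domain))
  structure(
    list(
      dims = c(nxy, nxy, nz), dl = dl, axis = c(cx, cx), geometry = geometry,
      domain = domain, ecm = ecm, mdf = zero, g = zero, stress = zero,
      occ = array(0L, dim = dim(domain))
    ),
    class = "artery_lattice"
  )
}

#' @export
print.artery_lattice <- function(x, ...) {
  n <- tabulate(x$domain + 1L, nbins = 3)
  cat(sprintf(
    "<artery_lattice> %d x %d x %d sites, dl = %g mm\n", x$dims[1], x$dims[2],
    x$dims[3], x$dl
  ))
  cat(sprintf("  outside %d | lumen %d | wall %d sites\n", n[1], n[2], n[3]))
  occ <- tabulate(x$occ + 1L, nbins = 4)
  cat(sprintf("  occupants: %d cSMC, %d sSMC, %d EC\n", occ[2], occ[3], occ[4]))
  invisible(x)
}

# neighbourhood offsets in the same deterministic order as the C++ core
# (x fastest), restricted to the requested connectivity
stencil_offsets <- function(stencil = 18L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[order(g$dz, g$dy, g$dx), ]
  m <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- m > 0 & m <= switch(as.character(stencil), "6" = 1, "18" = 2, "26" = 3)
  if (!stencil %in% c(6, 18, 26)) abort("`stencil` must be 6, 18 or 26")
  as.matrix(g[keep, , drop = FALSE])
}

check_site <- function(lattice, site) {
  site <- as.integer(site)
  if (length(site) != 3 || any(site < 1L) || any(site > lattice$dims)) {
    abort(sprintf(
      "site (%s) is outside the %d x %d x %d grid",
      paste(site, collapse = ","), lattice$dims[1], lattice$dims[2],
      lattice$dims[3]
    ))
  }
  site
}

flat_index <- function(lattice, site) {
  site[1] + lattice$dims[1] * ((site[2] - 1L) + lattice$dims[2] * (site[3] - 1L))
}

#' Neighbouring sites of a lattice site
#'
#' Returns the sites adjacent to `site` under the chosen connectivity (6:
#' faces, 18: faces + edges, 26: full Moore block), clipped to the grid, in
#' a deterministic order.
#'
#' @param lattice an [build_artery_lattice()] lattice.
#' @param site integer triple `c(i, j, k)`, 1-based.
#' @param stencil connectivity, one of 6, 18, 26.
#' @return An integer matrix with one `(i, j, k)` row per neighbour.
#' @examples
#' lat <- build_artery_lattice(artery_geometry(length = 1), dl = 0.25)
#' nrow(site_neighbors(lat, c(2, 2, 2), 26)) # interior: 26
#' nrow(site_neighbors(lat, c(1, 1, 1), 26)) # corner: 7
#' @export
site_neighbors <- function(lattice, site, stencil = 18L) {
  site <- check_site(lattice, site)
  off <- stencil_offsets(stencil)
  nb <- sweep(off, 2, site, `+`)
  colnames(nb) <- c("i", "j", "k")
  keep <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
    nb[, 1] <= lattice$dims[1] & nb[, 2] <= lattice$dims[2] &
    nb[, 3] <= lattice$dims[3]
  nb[keep, , drop = FALSE]
}

#' Local SMC occupancy around a site
#'
#' Fraction of in-domain sites (not `outside`) in the block formed by the
#' site and its neighbours that are occupied by an SMC of either phenotype.
#' This is the crowding signal of the phenotype rule.
#'
#' @inheritParams site_neighbors
#' @return A fraction in `[0, 1]`.
#' @export
local_cell_concentration <- function(lattice, site, stencil = 18L) {
  site <- check_site(lattice, site)
  block <- rbind(site, site_neighbors(lattice, site, stencil))
  idx <- block[, 1] + lattice$dims[1] *
    ((block[, 2] - 1L) + lattice$dims[2] * (block[, 3] - 1L))
  dom <- lattice$domain[idx]
  occ <- lattice$occ[idx]
  idx <- idx[dom != DOM_OUTSIDE]
  occ <- occ[dom != DOM_OUTSIDE]
  if (length(occ) == 0) return(0)
  mean(occ == OCC_CSMC | occ == OCC_SSMC)
}

#' Seed contractile SMCs into the wall
#'
#' Each wall site independently receives a contractile SMC with probability
#' `c_smc_init / c_max` (the baseline gives an occupancy fraction of about
#' 0.192). Uses the R random number stream; set a seed for reproducibility.
#'
#' @param lattice an artery lattice.
#' @param params a [sim_params()].
#' @return The lattice with cSMCs placed.
#' @export
seed_cells <- function(lattice, params) {
  stopifnot(inherits(params, "sim_params"))
  if (abs(params$dl - lattice$dl) > 1e-12) {
    abort("`params$dl` does not match the lattice spacing")
  }
  p <- params$c_smc_init / params$c_max
  wall <- which(lattice$domain == DOM_WALL)
  hit <- runif(length(wall)) < p
  lattice$occ[wall[hit]] <- OCC_CSMC
  lattice
}

# flat indices of qualifying lumen-surface sites: lumen domain, matrix-free,
# adjacent to a matrix-bearing site
surface_site_index <- function(lattice, stencil = 18L) {
  cpp_surface_sites(
    as.integer(lattice$domain), as.double(lattice$ecm),
    as.integer(lattice$dims), as.integer(stencil)
  )
}

#' Seed the endothelium outside the stented segment
#'
#' Places an EC on every qualifying lumen-surface site (a lumen site with no
#' ECM adjacent to a matrix-bearing site) whose axial position lies outside
#' the stented extent, modelling total denudation within the stented
#' segment with a healthy monolayer proximal and distal to it.
#'
#' @param lattice an artery lattice (stress/injury may already be applied).
#' @param stent axial extent `c(z_lo, z_hi)` of the denuded segment, mm;
#'   defaults to the lattice geometry's stent extent. `NULL` seeds the whole
#'   surface (an intact endothelium).
#' @param stencil adjacency used for the surface test.
#' @return The lattice with ECs placed.
#' @export
seed_endothelium <- function(lattice, stent = lattice$geometry$stent,
                             stencil = 18L) {
  idx <- surface_site_index(lattice, stencil)
  if (!is.null(stent)) {
    stent <- as.numeric(stent)
    z_max <- lattice$dims[3] * lattice$dl
    if (length(stent) != 2 || stent[1] >= stent[2] || stent[1] < 0 ||
        stent[2] > z_max + lattice$dl) {
      abort("stent extent must lie within the artery length")
    }
    k <- (idx - 1L) %/% (lattice$dims[1] * lattice$dims[2]) + 1L
    z <- (k - 0.5) * lattice$dl
    idx <- idx[z < stent[1] | z > stent[2]]
  }
  sel <- idx[lattice$occ[idx] == OCC_NONE]
  lattice$occ[sel] <- OCC_EC
  lattice
}

#' Rectangular all-wall lattice block
#'
#' A convenience constructor for unit tests, calibration scenarios and
#' worked examples: every site is artery `wall` with a uniform initial ECM
#' level and no geometry attached.
#'
#' @param dims integer triple of site counts.
#' @param dl lattice spacing, mm.
#' @param ecm uniform initial ECM level.
#' @return An `artery_lattice` whose `geometry` is `NULL`.
#' @export
block_lattice <- function(dims, dl, ecm = 1) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) abort("`dims` must be 3 positive counts")
  if (dl <= 0) abort("`dl` must be positive")
  zero <- array(0, dim = dims)
  structure(
    list(
      dims = dims, dl = dl, axis = c(dims[1], dims[2]) * dl / 2,
      geometry = NULL,
      domain = array(DOM_WALL, dim = dims), ecm = array(ecm, dim = dims),
      mdf = zero, g = zero, stress = zero, occ = array(0L, dim = dims)
    ),
    class = "artery_lattice"
  )
}

#' Lattice sites as a tibble
#'
#' One row per site with indices, physical coordinates of the site centre
#' and all per-site fields. Intended for small lattices and slices (the
#' table has one row per site).
#'
#' @param lattice an artery lattice.
#' @param slices optional integer vector of k slices to keep.
#' @return A tibble with columns `i, j, k, x, y, z, domain, ecm, mdf, g,
#'   stress, occupant`.
#' @export
lattice_sites <- function(lattice, slices = NULL) {
  d <- lattice$dims
  if (is.null(slices)) slices <- seq_len(d[3])
  grid <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = as.integer(slices))
  idx <- grid$i + d[1] * ((grid$j - 1L) + d[2] * (grid$k - 1L))
  tibble(
    i = grid$i, j = grid$j, k = grid$k,
    x = (grid$i - 0.5) * lattice$dl, y = (grid$j - 0.5) * lattice$dl,
    z = (grid$k - 0.5) * lattice$dl,
    domain = c("outside", "lumen", "wall")[lattice$domain[idx] + 1L],
    ecm = lattice$ecm[idx], mdf = lattice$mdf[idx], g = lattice$g[idx],
    stress = lattice$stress[idx],
    occupant = c("none", "cSMC", "sSMC", "EC")[lattice$occ[idx] + 1L]
  )
}
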