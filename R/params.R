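#' Baseline model parameters
#'
#' Collects the parameters that drive every rule of the simulation. Defaults
#' are the baseline set for a human coronary artery: one lattice site per
#' cell at `dl` = 0.01825 mm (so the maximum packing density `c_max = dl^-3`
#' is 1.64e5 cells/mm^3), an injury threshold of 35 kPa of compressive
#' minimum principal stress, and rates calibrated so that injured tissue is
#' fully resorbed after 20 days (`c_deg` = 0.05/day) and an 8 mm denuded
#' lumen re-endothelialises in about 180 days (`p_ec` = 2 attempts/cell/day).
#'
#' `g_crit` and `c_smc_crit` are model closure choices rather than measured
#' quantities: `g_crit = 1` lets each injured site (initialised at
#' `g_init = 3`) fund a small burst of local divisions, and
#' `c_smc_crit = 0.75` sits far above the baseline seeding occupancy (~0.19),
#' keeping the uninjured artery a strict fixed point, while still flagging
#' densely packed lesion neighbourhoods as crowded. Both are exposed here.
#'
#' @param dl lattice spacing, mm.
#' @param sigma_crit injury threshold on compressive minimum principal
#'   stress, kPa (a site is injured when its signed stress < `-sigma_crit`).
#' @param c_smc_init initial SMC concentration, cells/mm^3. Each wall site is
#'   seeded independently with probability `c_smc_init * dl^3`.
#' @param v_smc sSMC migration speed, mm/day (converted to `v_smc/dl` lattice
#'   steps per day).
#' @param p_smc sSMC proliferation attempt rate, attempts/cell/day.
#' @param p_ec EC proliferation attempt rate, attempts/cell/day.
#' @param mdf_init matrix-degrading-factor level assigned to injured sites,
#'   dimensionless.
#' @param c_deg degradation rate of ECM and MDF where both are present,
#'   1/day.
#' @param c_ecm ECM production rate of an sSMC at its site, 1/day.
#' @param g_init growth stimulus assigned to injured sites, dimensionless.
#' @param g_crit stimulus threshold and per-division consumption,
#'   dimensionless.
#' @param c_smc_crit local SMC occupancy fraction above which a cell stays
#'   synthetic, in `[0, 1]`.
#' @param stencil lattice neighbourhood connectivity: 6, 18 or 26. The
#'   default (18) is the connectivity under which the shipped endothelial
#'   rules reproduce the 180-day healing calibration.
#' @param days_max maximum simulated days.
#'
#' @return A list of class `sim_params`.
#' @examples
#' p <- sim_params()
#' p$c_max # 1.64e5 cells/mm^3
#' @export
sim_params <- function(dl = 0.01825, sigma_crit = 35, c_smc_init = 3.16e4,
                       v_smc = 0.24, p_smc = 0.24, p_ec = 2, mdf_init = 1,
                       c_deg = 0.05, c_ecm = 0.20, g_init = 3, g_crit = 1,
                       c_smc_crit = 0.75, stencil = 18, days_max = 320) {
  if (!is.numeric(dl) || dl <= 0) abort("`dl` must be a positive lattice spacing (mm)")
  rates <- c(
    sigma_crit = sigma_crit, c_smc_init = c_smc_init, v_smc = v_smc,
    p_smc = p_smc, p_ec = p_ec, mdf_init = mdf_init, c_deg = c_deg,
    c_ecm = c_ecm, g_init = g_init, g_crit = g_crit, c_smc_crit = c_smc_crit
  )
  bad <- rates < 0 | !is.finite(rates)
  if (any(bad)) {
    abort(paste0("negative or non-finite parameter(s): ",
                 paste(names(rates)[bad], collapse = ", ")))
  }
  if (!stencil %in% c(6L, 18L, 26L)) abort("`stencil` must be 6, 18 or 26")
  if (c_smc_crit > 1) abort("`c_smc_crit` is an occupancy fraction in [0, 1]")
  c_max <- dl^-3
  if (c_smc_init > c_max) {
    abort(sprintf(
      "c_smc_init (%.3g) exceeds the packing density c_max = dl^-3 (%.3g)",
      c_smc_init, c_max
    ))
  }
  structure(
    list(
      dl = dl, sigma_crit = sigma_crit, c_smc_init = c_smc_init,
      c_max = c_max, v_smc = v_smc, p_smc = p_smc, p_ec = p_ec,
      mdf_init = mdf_init, c_deg = c_deg, c_ecm = c_ecm, g_init = g_init,
      g_crit = g_crit, c_smc_crit = c_smc_crit, stencil = as.integer(stencil),
      days_max = as.integer(days_max)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  dl = %g mm (c_max = %.3g cells/mm^3), stencil %d\n",
              x$dl, x$c_max, x$stencil))
  cat(sprintf("  injury: sigma_crit = %g kPa, MDF_init = %g, G_init = %g\n",
              x$sigma_crit, x$mdf_init, x$g_init))
  cat(sprintf("  SMC: c_init = %.3g /mm^3, v = %g mm/d, p = %g /d, G_crit = %g, c_crit = %g\n",
              x$c_smc_init, x$v_smc, x$p_smc, x$g_crit, x$c_smc_crit))
  cat(sprintf("  EC: p = %g /d;  ECM: +%g/d, -%g/d;  days_max = %d\n",
              x$p_ec, x$c_ecm, x$c_deg, x$days_max))
  invisible(x)
}

#' Idealised artery geometry
#'
#' A straight artery is modelled as a hollow cylinder aligned with the z
#' axis. The baseline is a 14 mm coronary segment with inner/outer diameters
#' of 2.5/3.75 mm carrying a stent over the central 8 mm.
#'
#' @param length axial length, mm.
#' @param r_inner,r_outer inner (lumen) and outer wall radii, mm.
#' @param stent axial extent `c(z_lo, z_hi)` of the stented (denuded)
#'   segment, mm, measured from the proximal end.
#' @return A list of class `artery_geometry`.
#' @examples
#' artery_geometry()
#' @export
artery_geometry <- function(length = 14, r_inner = 1.25, r_outer = 1.875,
                            stent = c(3, 11)) {
  if (length <= 0) abort("`length` must be positive")
  if (r_inner < 0 || r_outer < r_inner) {
    abort("need 0 <= r_inner <= r_outer")
  }
  stent <- as.numeric(stent)
  if (length(stent) != 2 || stent[1] >= stent[2]) {
    abort("`stent` must be c(z_lo, z_hi) with z_lo < z_hi")
  }
  if (stent[1] < 0 || stent[2] > length) {
    abort("stent extent lies outside the artery length")
  }
  structure(
    list(length = length, r_inner = r_inner, r_outer = r_outer, stent = stent),
    class = "artery_geometry"
  )
}

#' @export
print.artery_geometry <- function(x, ...) {
  cat(sprintf(
    "<artery_geometry> length %g mm, radii %g/%g mm, stent [%g, %g] mm\n",
    x$length, x$r_inner, x$r_outer, x$stent[1], x$stent[2]
  ))
  invisible(x)
}
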