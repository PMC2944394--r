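#' Apply the stress-threshold injury
#'
#' A site is injured when its compressive minimum principal stress exceeds
#' the threshold in magnitude, i.e. when the signed stress is strictly below
#' `-sigma_crit` (boundary equality is uninjured). At injured sites any
#' occupant is removed and the acute initial conditions are introduced:
#' `MDF = mdf_init` and `G = g_init`, standing in for the injurious factors
#' released by damaged cells, platelets and infiltrating inflammatory cells.
#' The matrix itself is not cleared instantaneously: the MDF load resorbs it
#' over the following days (20 days at baseline rates). The operation is
#' idempotent.
#'
#' @param lattice an artery lattice with `stress` assigned.
#' @param params a [sim_params()].
#' @return The lattice with injury applied.
#' @export
apply_injury <- function(lattice, params) {
  stopifnot(inherits(params, "sim_params"))
  hit <- lattice$stress < -params$sigma_crit
  lattice$occ[hit] <- OCC_NONE
  lattice$mdf[hit] <- params$mdf_init
  lattice$g[hit] <- params$g_init
  lattice
}

#' Parametric description of a corrugated-ring stent
#'
#' Describes the strut pattern used by [synthetic_stent_stress()] to emulate
#' the compressive stress footprint of an expanded corrugated-ring stent:
#' `n_rings` sinusoidally corrugated rings with `n_crowns` crowns each,
#' amplified at the crown junctions and at the first and last ring (stress,
#' and hence injury, concentrates under struts and is largest at the stent
#' ends and strut junctions).
#'
#' @param z_lo,z_hi axial extent of the stent, mm.
#' @param n_rings number of corrugated rings.
#' @param n_crowns crowns (sinusoid periods) per ring.
#' @param peak peak compressive stress magnitude under a mid-stent strut,
#'   kPa (positive number; the generated field is negative).
#' @param end_factor multiplier (>= 1) applied to the first and last ring.
#' @param junction_factor multiplier (>= 1) applied near crown apexes where
#'   adjacent rings connect.
#' @param axial_width Gaussian half-width of the strut footprint along z, mm.
#' @param radial_decay e-folding depth of the stress into the wall, mm.
#' @param crown_amplitude corrugation amplitude, mm; defaults to 40% of the
#'   half ring pitch.
#' @param jitter relative amplitude of optional uniform noise (0 = fully
#'   deterministic field).
#' @return A list of class `stent_spec`.
#' @export
stent_spec <- function(z_lo = 3, z_hi = 11, n_rings = 6, n_crowns = 4,
                       peak = 45, end_factor = 2, junction_factor = 1.3,
                       axial_width = 0.15, radial_decay = 0.25,
                       crown_amplitude = NULL, jitter = 0) {
  if (n_rings < 1 || n_crowns < 1) abort("need at least one ring and one crown")
  if (z_lo >= z_hi) abort("need z_lo < z_hi")
  if (end_factor < 1 || junction_factor < 1) {
    abort("end_factor and junction_factor are amplifications (>= 1)")
  }
  pitch <- (z_hi - z_lo) / n_rings
  if (is.null(crown_amplitude)) crown_amplitude <- 0.4 * pitch / 2
  structure(
    list(
      z_lo = z_lo, z_hi = z_hi, n_rings = as.integer(n_rings),
      n_crowns = as.integer(n_crowns), peak = peak, end_factor = end_factor,
      junction_factor = junction_factor, axial_width = axial_width,
      radial_decay = radial_decay, crown_amplitude = crown_amplitude,
      jitter = jitter
    ),
    class = "stent_spec"
  )
}

#' Synthetic post-expansion stress field
#'
#' Assigns a smooth compressive minimum-principal-stress field to the wall
#' sites of a lattice from a parametric stent description, for use when no
#' finite-element result is available. Each corrugated ring contributes a
#' Gaussian ridge along its strut centreline `z_c + a sin(n_crowns * theta)`
#' (phase alternating between rings), decaying exponentially with depth into
#' the wall; crown apexes (strut junctions) and the two end rings are
#' amplified. A site takes the largest magnitude over all rings, with
#' negative sign (compression). The field is deterministic unless `jitter`
#' is positive, in which case uniform noise drawn from the R random stream
#' is added.
#'
#' @param lattice an artery lattice.
#' @param spec a [stent_spec()].
#' @return The lattice with `stress` assigned on wall sites.
#' @export
synthetic_stent_stress <- function(lattice, spec = stent_spec()) {
  stopifnot(inherits(spec, "stent_spec"))
  d <- lattice$dims
  wall <- which(lattice$domain == DOM_WALL)
  ii <- (wall - 1L) %% d[1] + 1L
  jj <- ((wall - 1L) %/% d[1]) %% d[2] + 1L
  kk <- (wall - 1L) %/% (d[1] * d[2]) + 1L
  x <- (ii - 0.5) * lattice$dl - lattice$axis[1]
  y <- (jj - 0.5) * lattice$dl - lattice$axis[2]
  z <- (kk - 0.5) * lattice$dl
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  depth <- pmax(r - lattice$geometry$r_inner, 0)
  pitch <- (spec$z_hi - spec$z_lo) / spec$n_rings
  mag <- numeric(length(wall))
  for (ring in seq_len(spec$n_rings)) {
    z_c <- spec$z_lo + (ring - 0.5) * pitch
    phase <- if (ring %% 2 == 0) pi else 0
    wave <- sin(spec$n_crowns * theta + phase)
    z_strut <- z_c + spec$crown_amplitude * wave
    amp <- spec$peak *
      (1 + (spec$junction_factor - 1) * abs(wave)^8) *
      (if (ring == 1 || ring == spec$n_rings) spec$end_factor else 1)
    contrib <- amp * exp(-(z - z_strut)^2 / (2 * spec$axial_width^2)) *
      exp(-depth / spec$radial_decay)
    mag <- pmax(mag, contrib)
  }
  if (spec$jitter > 0) {
    mag <- pmax(mag * (1 + spec$jitter * runif(length(mag), -1, 1)), 0)
  }
  lattice$stress[wall] <- -mag
  lattice
}
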