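#' Write and read the daily metrics series
#'
#' One CSV row per simulated day: `day`, `lesion_volume` (mm^3), the cell
#' counts (`n_csmc`, `n_ssmc`, `n_ec`, `n_cells`), `doubling`, the per-day
#' division and migration tallies, then one `area_k<slice>` column per axial
#' slice (mm^2). Values round-trip at full double precision.
#'
#' @param sim a [run_simulation()] result (or a metrics tibble; per-slice
#'   columns are then omitted).
#' @param path output file.
#' @export
write_metrics_csv <- function(sim, path) {
  if (inherits(sim, "restenosis_sim")) {
    out <- sim$metrics
    if (!is.null(sim$areas)) {
      a <- as.data.frame(sim$areas)
      names(a) <- sprintf("area_k%d", seq_len(ncol(a)))
      out <- dplyr::bind_cols(out, a)
    }
  } else {
    out <- sim
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @return `read_metrics_csv()`: a tibble.
#' @export
read_metrics_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a lattice snapshot as VTK structured points
#'
#' Legacy ASCII `STRUCTURED_POINTS` with point data `ECM`, `MDF`, `G`,
#' `stress` and `occupant` (0 none, 1 cSMC, 2 sSMC, 3 EC), suitable for
#' ParaView. Point ordering is x-fastest, matching the dataset dimensions.
#'
#' @param lattice an artery lattice.
#' @param path output file.
#' @export
write_snapshot_vtk <- function(lattice, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- lattice$dims
  writeLines(c(
    "# vtk DataFile Version 3.0", "restenosim lattice snapshot", "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
    sprintf("ORIGIN %.9g %.9g %.9g", lattice$dl / 2, lattice$dl / 2,
            lattice$dl / 2),
    sprintf("SPACING %.9g %.9g %.9g", lattice$dl, lattice$dl, lattice$dl),
    sprintf("POINT_DATA %d", prod(d))
  ), con)
  scalar <- function(name, values, type = "double", fmt = "%.9g") {
    writeLines(c(sprintf("SCALARS %s %s 1", name, type),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf(fmt, values), con)
  }
  scalar("ECM", as.vector(lattice$ecm))
  scalar("MDF", as.vector(lattice$mdf))
  scalar("G", as.vector(lattice$g))
  scalar("stress", as.vector(lattice$stress))
  scalar("occupant", as.vector(lattice$occ), type = "int", fmt = "%d")
  invisible(path)
}

#' Read a structured-points snapshot back into a lattice fragment
#'
#' Reconstructs the per-site fields of a snapshot written by
#' [write_snapshot_vtk()]. The domain partition is not stored in snapshots;
#' supply the lattice (or rebuild it from the geometry) when domain
#' information is needed.
#'
#' @param path a VTK structured-points file.
#' @return A list with `dims`, `dl` and the arrays `ecm`, `mdf`, `g`,
#'   `stress`, `occ`.
#' @export
read_snapshot_vtk <- function(path) {
  ln <- trimws(readLines(path))
  dims <- as.integer(strsplit(ln[grep("^DIMENSIONS", ln)], "\\s+")[[1]][2:4])
  dl <- as.numeric(strsplit(ln[grep("^SPACING", ln)], "\\s+")[[1]][2])
  n <- prod(dims)
  starts <- grep("^SCALARS", ln)
  out <- list(dims = dims, dl = dl)
  key <- c(ECM = "ecm", MDF = "mdf", G = "g", stress = "stress",
           occupant = "occ")
  for (s in starts) {
    name <- strsplit(ln[s], "\\s+")[[1]][2]
    vals <- as.numeric(ln[s + 1 + seq_len(n)])
    arr <- array(vals, dims)
    if (name == "occupant") storage.mode(arr) <- "integer"
    out[[key[[name]]]] <- arr
  }
  out
}
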