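#' Hexahedral stress mesh
#'
#' Container for a post-expansion finite-element result: an 8-node
#' hexahedral mesh of the artery wall with one minimum-principal-stress
#' value per element (kPa, negative in compression). Node ordering follows
#' the usual hexahedron convention (nodes 1-4 the bottom quadrilateral,
#' 5-8 the top, node 5 above node 1).
#'
#' @param nodes numeric matrix, one `x y z` row per node, mm.
#' @param elements integer matrix, one row of 8 node indices (1-based) per
#'   element.
#' @param stress numeric vector, one signed stress per element, kPa.
#' @return An object of class `stress_mesh`.
#' @examples
#' cube <- stress_mesh(
#'   nodes = cbind(
#'     c(0, 1, 1, 0, 0, 1, 1, 0), c(0, 0, 1, 1, 0, 0, 1, 1),
#'     c(0, 0, 0, 0, 1, 1, 1, 1)
#'   ),
#'   elements = matrix(1:8, nrow = 1), stress = -40
#' )
#' @export
stress_mesh <- function(nodes, elements, stress) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  stress <- as.double(stress)
  if (ncol(nodes) != 3) abort("`nodes` must have 3 columns (x, y, z)")
  if (ncol(elements) != 8) abort("elements must be 8-node hexahedra")
  if (nrow(elements) != length(stress)) {
    abort("`stress` must hold one value per element")
  }
  if (any(elements < 1L) || any(elements > nrow(nodes))) {
    abort("element node index out of range")
  }
  vols <- vapply(seq_len(nrow(elements)), function(e) {
    hex_volume(nodes[elements[e, ], , drop = FALSE])
  }, numeric(1))
  if (any(vols <= 0)) {
    abort(sprintf(
      "element(s) %s have non-positive volume",
      paste(which(vols <= 0), collapse = ", ")
    ))
  }
  structure(list(nodes = nodes, elements = elements, stress = stress),
            class = "stress_mesh")
}

#' @export
print.stress_mesh <- function(x, ...) {
  cat(sprintf(
    "<stress_mesh> %d nodes, %d hexahedra, stress %.3g .. %.3g kPa\n",
    nrow(x$nodes), nrow(x$elements), min(x$stress), max(x$stress)
  ))
  invisible(x)
}

# corner-tetrahedra decomposition used for volume and the test oracle
HEX_TETS <- matrix(
  c(
    1, 2, 4, 5,
    2, 3, 4, 7,
    2, 4, 5, 7,
    4, 5, 7, 8,
    2, 5, 6, 7
  ),
  ncol = 4, byrow = TRUE
)

tet_volume <- function(p) {
  abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))) / 6
}

hex_volume <- function(corners) {
  sum(apply(HEX_TETS, 1, function(t) tet_volume(corners[t, , drop = FALSE])))
}

# the six quadrilateral faces, wound so consistent normals can be oriented
HEX_FACES <- matrix(
  c(
    1, 2, 3, 4,
    5, 8, 7, 6,
    1, 5, 6, 2,
    2, 6, 7, 3,
    3, 7, 8, 4,
    4, 8, 5, 1
  ),
  ncol = 4, byrow = TRUE
)

#' Lattice sites inside a hexahedral element
#'
#' Implements the element-to-lattice search: an axis-aligned bounding box
#' around the element pre-selects candidate sites, then each candidate
#' centre is tested against the six faces, each treated as its best-fit
#' plane with inward-pointing normal (warped faces are therefore handled
#' approximately, to within a thin boundary shell). Sites on a face are
#' counted as inside.
#'
#' @param mesh a [stress_mesh()].
#' @param element element index.
#' @param lattice an artery lattice.
#' @return Integer matrix of `(i, j, k)` sites whose centres fall inside the
#'   element.
#' @export
locate_sites_in_element <- function(mesh, element, lattice) {
  corners <- mesh$nodes[mesh$elements[element, ], , drop = FALSE]
  lo <- apply(corners, 2, min)
  hi <- apply(corners, 2, max)
  diag3 <- sqrt(sum((hi - lo)^2))
  if (hex_volume(corners) < 1e-8 * diag3^3) {
    abort(sprintf("element %d is degenerate (near-zero volume)", element))
  }
  dl <- lattice$dl
  rng <- lapply(1:3, function(a) {
    from <- max(1L, as.integer(ceiling(lo[a] / dl + 0.5)))
    to <- min(lattice$dims[a], as.integer(floor(hi[a] / dl + 0.5)))
    if (from > to) integer(0) else seq.int(from, to)
  })
  if (any(lengths(rng) == 0)) {
    return(matrix(integer(0), ncol = 3, dimnames = list(NULL, c("i", "j", "k"))))
  }
  cand <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  pts <- (cand - 0.5) * dl
  centroid <- colMeans(corners)
  inside <- rep(TRUE, nrow(cand))
  for (f in seq_len(nrow(HEX_FACES))) {
    fp <- corners[HEX_FACES[f, ], , drop = FALSE]
    fc <- colMeans(fp)
    d1 <- fp[3, ] - fp[1, ]
    d2 <- fp[4, ] - fp[2, ]
    n <- c(
      d1[2] * d2[3] - d1[3] * d2[2],
      d1[3] * d2[1] - d1[1] * d2[3],
      d1[1] * d2[2] - d1[2] * d2[1]
    )
    if (sum((centroid - fc) * n) < 0) n <- -n # orient inward
    n <- n / sqrt(sum(n^2))
    inside <- inside & (sweep(pts, 2, fc) %*% n >= -1e-9)
  }
  cand[inside, , drop = FALSE]
}

#' Map per-element stress onto the lattice
#'
#' Every lattice site located inside an element becomes an artery `wall`
#' site carrying the element's stress with intact matrix (ECM = 1). Sites
#' claimed by several elements keep the value of the last element in mesh
#' order (such ties are confined to a boundary-thin shell).
#'
#' @param mesh a [stress_mesh()].
#' @param lattice an artery lattice whose bounds encompass the mesh.
#' @return The lattice with `domain`, `ecm` and `stress` updated.
#' @export
map_stress_to_lattice <- function(mesh, lattice) {
  any_hit <- FALSE
  for (e in seq_len(nrow(mesh$elements))) {
    sites <- locate_sites_in_element(mesh, e, lattice)
    if (nrow(sites) == 0) next
    any_hit <- TRUE
    idx <- sites[, 1] + lattice$dims[1] *
      ((sites[, 2] - 1L) + lattice$dims[2] * (sites[, 3] - 1L))
    lattice$domain[idx] <- DOM_WALL
    lattice$ecm[idx] <- 1
    lattice$stress[idx] <- mesh$stress[e]
  }
  if (!any_hit) {
    abort("no lattice site falls inside any mesh element; is the mesh inside the lattice bounds?")
  }
  lattice
}

#' Read and write stress meshes
#'
#' Two on-disk forms are supported. The neutral text format is
#' line-oriented:
#' ```
#' RESTENOSIM STRESS MESH 1
#' UNITS mm kPa
#' NODES <n>
#' <id> <x> <y> <z>          (n rows, ids 1..n)
#' ELEMENTS <m>
#' <id> <n1> ... <n8>        (m rows)
#' STRESS <m>
#' <id> <value>              (m rows, kPa, compression negative)
#' ```
#' Alternatively a VTK legacy ASCII unstructured grid holding hexahedral
#' cells (type 12) and a cell-data scalar named `min_principal_stress` can
#' be read with [read_stress_mesh_vtk()].
#'
#' @param path file path.
#' @return A [stress_mesh()].
#' @export
read_stress_mesh <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) < 4 || ln[1] != "RESTENOSIM STRESS MESH 1") {
    abort(paste0(path, ": missing 'RESTENOSIM STRESS MESH 1' header"))
  }
  if (!grepl("^UNITS\\s+mm\\s+kPa$", ln[2])) {
    abort(paste0(path, ": expected 'UNITS mm kPa' on line 2"))
  }
  cursor <- 3L
  read_block <- function(keyword, ncol_expect) {
    hdr <- strsplit(ln[cursor], "\\s+")[[1]]
    if (length(hdr) != 2 || hdr[1] != keyword) {
      abort(sprintf("%s: expected '%s <count>' at record %d, got '%s'",
                    path, keyword, cursor, ln[cursor]))
    }
    n <- as.integer(hdr[2])
    rows <- ln[cursor + seq_len(n)]
    cursor <<- cursor + n + 1L
    vals <- suppressWarnings(lapply(strsplit(rows, "\\s+"), as.numeric))
    if (any(lengths(vals) != ncol_expect) || anyNA(unlist(vals))) {
      bad <- which(lengths(vals) != ncol_expect | vapply(vals, anyNA, TRUE))[1]
      abort(sprintf("%s: malformed %s record %d: '%s'", path, keyword, bad,
                    rows[bad]))
    }
    do.call(rbind, vals)
  }
  nd <- read_block("NODES", 4)
  el <- read_block("ELEMENTS", 9)
  st <- read_block("STRESS", 2)
  nodes <- nd[order(nd[, 1]), -1, drop = FALSE]
  elements <- el[order(el[, 1]), -1, drop = FALSE]
  stress <- st[order(st[, 1]), 2]
  stress_mesh(nodes, elements, stress)
}

#' @rdname read_stress_mesh
#' @param mesh a [stress_mesh()] to write.
#' @export
write_stress_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "stress_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("RESTENOSIM STRESS MESH 1", "UNITS mm kPa"), con)
  writeLines(sprintf("NODES %d", nrow(mesh$nodes)), con)
  writeLines(sprintf(
    "%d %.12g %.12g %.12g", seq_len(nrow(mesh$nodes)),
    mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]
  ), con)
  writeLines(sprintf("ELEMENTS %d", nrow(mesh$elements)), con)
  writeLines(paste(
    seq_len(nrow(mesh$elements)),
    apply(mesh$elements, 1, paste, collapse = " ")
  ), con)
  writeLines(sprintf("STRESS %d", length(mesh$stress)), con)
  writeLines(sprintf("%d %.12g", seq_along(mesh$stress), mesh$stress), con)
  invisible(path)
}

#' @rdname read_stress_mesh
#' @export
read_stress_mesh_vtk <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ln <- trimws(readLines(path))
  toks <- strsplit(paste(ln[nzchar(ln)], collapse = " "), "\\s+")[[1]]
  find <- function(key) {
    w <- which(toupper(toks) == key)
    if (length(w) == 0) abort(sprintf("%s: no %s section", path, key))
    w[1]
  }
  p <- find("POINTS")
  n_pts <- as.integer(toks[p + 1])
  nodes <- matrix(as.numeric(toks[p + 2 + seq_len(3 * n_pts)]),
                  ncol = 3, byrow = TRUE)
  cl <- find("CELLS")
  n_cells <- as.integer(toks[cl + 1])
  cell_tok <- as.integer(toks[cl + 2 + seq_len(as.integer(toks[cl + 2]))])
  pos <- 1L
  elements <- matrix(0L, n_cells, 8)
  for (e in seq_len(n_cells)) {
    cnt <- cell_tok[pos]
    if (cnt != 8L) {
      abort(sprintf("%s: cell %d has %d nodes; only hexahedra are supported",
                    path, e, cnt))
    }
    elements[e, ] <- cell_tok[pos + 1:8] + 1L # VTK is 0-based
    pos <- pos + 9L
  }
  ct <- find("CELL_TYPES")
  types <- as.integer(toks[ct + 1 + seq_len(n_cells)])
  if (any(types != 12L)) {
    abort(sprintf("%s: cell type(s) %s are not hexahedra (type 12)",
                  path, paste(unique(types[types != 12L]), collapse = ",")))
  }
  sc <- which(toupper(toks) == "SCALARS" & tolower(toks[seq_along(toks) + 1]) ==
                "min_principal_stress")
  if (length(sc) == 0) {
    abort(paste0(path, ": no cell-data scalar named min_principal_stress"))
  }
  # values start after the optional numComponents token and the
  # LOOKUP_TABLE declaration
  start <- sc[1] + 3L
  for (j in (sc[1] + 3L):(sc[1] + 6L)) {
    if (toupper(toks[j]) == "LOOKUP_TABLE") {
      start <- j + 2L
      break
    }
    if (!is.na(suppressWarnings(as.numeric(toks[j]))) &&
        j > sc[1] + 3L) {
      start <- j
      break
    }
  }
  stress <- as.numeric(toks[start - 1L + seq_len(n_cells)])
  if (anyNA(stress)) abort(paste0(path, ": malformed stress values"))
  stress_mesh(nodes, elements, stress)
}

#' @rdname read_stress_mesh
#' @export
write_stress_mesh_vtk <- function(mesh, path) {
  stopifnot(inherits(mesh, "stress_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  writeLines(c(
    "# vtk DataFile Version 3.0", "restenosim stress mesh", "ASCII",
    "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)
  ), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 9L * m), con)
  writeLines(paste(8L, apply(mesh$elements - 1L, 1, paste, collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("12", m), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS min_principal_stress double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.12g", mesh$stress), con)
  invisible(path)
}
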