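# Independent oracles used to check the geometric kernels. These deliberately
# use the dumbest possible algorithm (full enumeration, tetrahedral
# decomposition) and share no code with the implementation under test.

# classify every site of a lattice by direct per-site radius arithmetic
oracle_classify <- function(dims, dl, r_inner, r_outer, axis) {
  out <- array("outside", dims)
  for (k in seq_len(dims[3])) {
    for (j in seq_len(dims[2])) {
      for (i in seq_len(dims[1])) {
        r <- sqrt(((i - 0.5) * dl - axis[1])^2 + ((j - 0.5) * dl - axis[2])^2)
        out[i, j, k] <- if (r < r_inner) "lumen" else if (r < r_outer) "wall" else "outside"
      }
    }
  }
  out
}

# all neighbours of a site by offset enumeration
oracle_neighbors <- function(site, dims, stencil) {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    m <- abs(dx) + abs(dy) + abs(dz)
    if (m == 0) next
    if (stencil == 6 && m > 1) next
    if (stencil == 18 && m > 2) next
    s <- site + c(dx, dy, dz)
    if (all(s >= 1) && all(s <= dims)) out <- rbind(out, s)
  }
  out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# point-in-hexahedron by decomposition into five tetrahedra
HEX_TETS_ORACLE <- matrix(
  c(
    1, 2, 4, 5,
    2, 3, 4, 7,
    2, 4, 5, 7,
    4, 5, 7, 8,
    2, 5, 6, 7
  ),
  ncol = 4, byrow = TRUE
)

point_in_tet <- function(p, v, tol = 1e-10) {
  m <- rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])
  b <- tryCatch(solve(t(m), p - v[1, ]), error = function(e) NULL)
  if (is.null(b)) return(FALSE)
  all(b >= -tol) && sum(b) <= 1 + tol
}

oracle_point_in_hex <- function(p, corners) {
  for (t in seq_len(nrow(HEX_TETS_ORACLE))) {
    if (point_in_tet(p, corners[HEX_TETS_ORACLE[t, ], , drop = FALSE])) {
      return(TRUE)
    }
  }
  FALSE
}

# a randomly sheared hexahedron: affine image of the unit cube, so every
# face stays planar and the face-plane containment test and the
# tetrahedral-decomposition oracle are both exact
random_hex <- function(shear = 0.25) {
  base <- cbind(
    c(0, 1, 1, 0, 0, 1, 1, 0),
    c(0, 0, 1, 1, 0, 0, 1, 1),
    c(0, 0, 0, 0, 1, 1, 1, 1)
  )
  repeat {
    a <- diag(3) + matrix(runif(9, -shear, shear), 3, 3)
    if (det(a) > 0.3) break
  }
  base %*% t(a) + matrix(0.3, 8, 3, byrow = TRUE)
}

# unit-cube mesh fixture with one element
unit_cube_mesh <- function(stress = -40, origin = c(0, 0, 0)) {
  stress_mesh(
    nodes = cbind(
      c(0, 1, 1, 0, 0, 1, 1, 0) + origin[1],
      c(0, 0, 1, 1, 0, 0, 1, 1) + origin[2],
      c(0, 0, 0, 0, 1, 1, 1, 1) + origin[3]
    ),
    elements = matrix(1:8, nrow = 1), stress = stress
  )
}

# small all-wall block with an injured centre, mirroring the documented
# micro scenario but with arbitrary dimensions
injured_block <- function(dims, params, centre = (dims + 1) %/% 2) {
  lat <- block_lattice(dims, params$dl)
  lat$mdf[centre[1], centre[2], centre[3]] <- params$mdf_init
  lat$g[centre[1], centre[2], centre[3]] <- params$g_init
  lat
}
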