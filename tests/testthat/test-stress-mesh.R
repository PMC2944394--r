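test_that("mesh construction validates indices, shape and volume", {
  m <- unit_cube_mesh()
  expect_s3_class(m, "stress_mesh")
  expect_equal(nrow(m$nodes), 8)
  expect_equal(m$stress, -40)
  expect_error(stress_mesh(m$nodes, matrix(1:6, 1), -1), "8-node")
  expect_error(stress_mesh(m$nodes, matrix(c(1:7, 99), 1), -1), "out of range")
  expect_error(stress_mesh(m$nodes, m$elements, c(-1, -2)), "one value per element")
  flat <- m$nodes
  flat[5:8, 3] <- 0 # collapse the top face onto the bottom
  expect_error(stress_mesh(flat, m$elements, -1), "non-positive volume")
})

test_that("neutral format round-trips and rejects malformed files", {
  set.seed(4)
  mesh <- stress_mesh(
    nodes = rbind(random_hex(), random_hex() + 2),
    elements = rbind(1:8, 9:16),
    stress = c(-40, -12.5)
  )
  path <- withr::local_tempfile(fileext = ".txt")
  write_stress_mesh(mesh, path)
  back <- read_stress_mesh(path)
  expect_equal(back$nodes, mesh$nodes)
  expect_equal(back$elements, mesh$elements)
  expect_equal(back$stress, mesh$stress)

  expect_error(read_stress_mesh(tempfile()), "no such file")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("WRONG HEADER"), bad)
  expect_error(read_stress_mesh(bad), "header")
  txt <- readLines(path)
  txt[5] <- "2 not-a-number 0 0"
  writeLines(txt, bad)
  expect_error(read_stress_mesh(bad), "NODES record")
})

test_that("VTK unstructured grid reader agrees with the neutral reader", {
  set.seed(5)
  mesh <- stress_mesh(
    nodes = rbind(random_hex(), random_hex() + 1.5),
    elements = rbind(1:8, 9:16),
    stress = c(-55, -7)
  )
  neutral <- withr::local_tempfile(fileext = ".txt")
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_stress_mesh(mesh, neutral)
  write_stress_mesh_vtk(mesh, vtk)
  a <- read_stress_mesh(neutral)
  b <- read_stress_mesh_vtk(vtk)
  expect_equal(a$nodes, b$nodes)
  expect_equal(a$elements, b$elements)
  expect_equal(a$stress, b$stress)

  # missing stress array is reported as such
  txt <- readLines(vtk)
  txt <- sub("min_principal_stress", "other_field", txt)
  bad <- withr::local_tempfile(fileext = ".vtk")
  writeLines(txt, bad)
  expect_error(read_stress_mesh_vtk(bad), "min_principal_stress")
})

test_that("axis-aligned containment matches direct arithmetic", {
  mesh <- unit_cube_mesh()
  lat <- block_lattice(c(8, 8, 8), 0.25)
  sites <- locate_sites_in_element(mesh, 1, lat)
  # centres at (i - 0.5) * 0.25 inside [0, 1]: i in 1..4
  want <- as.matrix(expand.grid(i = 1:4, j = 1:4, k = 1:4))
  expect_equal(
    sort(paste(sites[, 1], sites[, 2], sites[, 3])),
    sort(paste(want[, 1], want[, 2], want[, 3]))
  )
  # nothing outside the bounding box is ever returned
  expect_true(all(sites <= 5))
})

test_that("sheared hexahedra match the tetrahedralization oracle", {
  set.seed(11)
  lat <- block_lattice(c(16, 16, 16), 0.1)
  shell <- lat$dl / 10
  n_mismatch <- 0L
  for (rep in 1:100) {
    corners <- random_hex()
    sites <- locate_sites_in_element(
      stress_mesh(corners, matrix(1:8, 1), -1), 1, lat
    )
    got <- paste(sites[, 1], sites[, 2], sites[, 3])
    lo <- pmax(1, floor(apply(corners, 2, min) / lat$dl) - 1)
    hi <- pmin(16, ceiling(apply(corners, 2, max) / lat$dl) + 1)
    cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                  k = lo[3]:hi[3]))
    pts <- (cand - 0.5) * lat$dl
    # vectorised oracle: barycentric containment in any of the five tets
    inside <- rep(FALSE, nrow(pts))
    for (t in seq_len(nrow(HEX_TETS_ORACLE))) {
      v <- corners[HEX_TETS_ORACLE[t, ], , drop = FALSE]
      b <- t(solve(
        t(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])),
        t(sweep(pts, 2, v[1, ]))
      ))
      inside <- inside |
        (b[, 1] >= -1e-10 & b[, 2] >= -1e-10 & b[, 3] >= -1e-10 &
           rowSums(b) <= 1 + 1e-10)
    }
    # exclude the thin shell around each face plane, where the two exact
    # methods may legitimately disagree by floating-point tie-breaks
    margin <- rep(Inf, nrow(pts))
    centroid <- colMeans(corners)
    for (f in seq_len(nrow(restenosim:::HEX_FACES))) {
      fp <- corners[restenosim:::HEX_FACES[f, ], , drop = FALSE]
      fc <- colMeans(fp)
      n <- cross3(fp[3, ] - fp[1, ], fp[4, ] - fp[2, ])
      n <- n / sqrt(sum(n^2))
      margin <- pmin(margin, abs(sweep(pts, 2, fc) %*% n))
    }
    keep <- margin >= shell
    key <- paste(cand[, 1], cand[, 2], cand[, 3])
    n_mismatch <- n_mismatch + sum((key %in% got) != inside & keep)
  }
  expect_equal(n_mismatch, 0L)
})

test_that("degenerate elements raise a geometry error", {
  mesh <- unit_cube_mesh()
  mesh$nodes[5:8, 3] <- mesh$nodes[1:4, 3] + 1e-9 # flatten, bypass ctor
  lat <- block_lattice(c(4, 4, 4), 0.25)
  expect_error(locate_sites_in_element(mesh, 1, lat), "degenerate")
})

test_that("stress mapping initialises wall sites and honours file order", {
  lat <- block_lattice(c(8, 8, 8), 0.25)
  lat$domain[] <- 1L # start from bare lumen
  lat$ecm[] <- 0
  mesh <- stress_mesh(
    nodes = rbind(unit_cube_mesh()$nodes, unit_cube_mesh(origin = c(1, 0, 0))$nodes),
    elements = rbind(1:8, 9:16),
    stress = c(-40, -10)
  )
  mapped <- map_stress_to_lattice(mesh, lat)
  s1 <- locate_sites_in_element(mesh, 1, lat)
  s2 <- locate_sites_in_element(mesh, 2, lat)
  idx1 <- s1[, 1] + 8 * ((s1[, 2] - 1) + 8 * (s1[, 3] - 1))
  idx2 <- s2[, 1] + 8 * ((s2[, 2] - 1) + 8 * (s2[, 3] - 1))
  expect_true(all(mapped$domain[c(idx1, idx2)] == 2L))
  expect_true(all(mapped$ecm[c(idx1, idx2)] == 1))
  expect_true(all(mapped$stress[setdiff(idx1, idx2)] == -40))
  expect_true(all(mapped$stress[idx2] == -10))
  # wall-site count equals the union of the per-element site sets
  expect_equal(sum(mapped$domain == 2L), length(union(idx1, idx2)))
  # a mesh entirely outside the lattice is a configuration error
  far <- unit_cube_mesh(origin = c(50, 50, 50))
  expect_error(map_stress_to_lattice(far, lat), "inside")
})
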