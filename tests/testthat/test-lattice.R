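test_that("parameter validation enforces the physical constraints", {
  expect_error(sim_params(dl = 0), "positive")
  expect_error(sim_params(c_deg = -1), "negative")
  expect_error(sim_params(stencil = 12), "6, 18 or 26")
  expect_error(sim_params(c_smc_crit = 2), "fraction")
  # more cells than lattice sites is impossible
  expect_error(sim_params(dl = 0.05, c_smc_init = 3.16e4), "c_max")
  # Moore block density: one cell per site at baseline spacing
  p <- sim_params()
  expect_equal(p$c_max, 0.01825^-3)
  expect_lt(abs(p$c_max / 1.64e5 - 1), 0.01)
})

test_that("geometry validation rejects degenerate cylinders", {
  expect_error(artery_geometry(length = 0), "positive")
  expect_error(artery_geometry(r_inner = 1.5, r_outer = 1.2), "r_inner <= r_outer")
  expect_error(artery_geometry(stent = c(5, 3)), "z_lo < z_hi")
  expect_error(artery_geometry(length = 4, stent = c(1, 6)), "outside")
})

test_that("voxelized annulus reproduces the analytic wall volume", {
  geom <- artery_geometry(length = 14, r_inner = 1.25, r_outer = 1.875)
  lat <- build_artery_lattice(geom, dl = 0.01825)
  vol <- sum(lat$domain == 2L) * 0.01825^3
  expect_lt(abs(vol / (pi * (1.875^2 - 1.25^2) * 14) - 1), 0.01)
  # wall starts with intact matrix, everything else bare
  expect_true(all(lat$ecm[lat$domain == 2L] == 1))
  expect_true(all(lat$ecm[lat$domain != 2L] == 0))
  expect_true(all(lat$occ == 0L))
})

test_that("site classification is partition-complete and matches brute force", {
  geom <- artery_geometry(length = 0.2, r_inner = 0.1, r_outer = 0.2,
                          stent = c(0.05, 0.15))
  lat <- build_artery_lattice(geom, dl = 0.05)
  expect_true(all(lat$domain %in% 0:2))
  want <- oracle_classify(lat$dims, lat$dl, 0.1, 0.2, lat$axis)
  got <- array(c("outside", "lumen", "wall")[lat$domain + 1L], lat$dims)
  expect_identical(got, want)
})

test_that("a zero-thickness annulus has no wall sites", {
  geom <- artery_geometry(length = 0.2, r_inner = 0.1, r_outer = 0.1,
                          stent = c(0.05, 0.15))
  lat <- build_artery_lattice(geom, dl = 0.05)
  expect_equal(sum(lat$domain == 2L), 0)
})

test_that("neighbourhoods are clipped, deterministic and match enumeration", {
  lat <- block_lattice(c(4, 4, 4), 0.1)
  expect_equal(nrow(site_neighbors(lat, c(2, 2, 2), 26)), 26)
  expect_equal(nrow(site_neighbors(lat, c(2, 2, 2), 18)), 18)
  expect_equal(nrow(site_neighbors(lat, c(2, 2, 2), 6)), 6)
  expect_equal(nrow(site_neighbors(lat, c(1, 1, 1), 26)), 7)
  expect_error(site_neighbors(lat, c(0, 1, 1)), "outside")
  set.seed(1)
  for (rep in 1:20) {
    site <- sample(4, 3, replace = TRUE)
    stencil <- sample(c(6, 18, 26), 1)
    got <- site_neighbors(lat, site, stencil)
    want <- oracle_neighbors(site, lat$dims, stencil)
    expect_equal(
      sort(paste(got[, 1], got[, 2], got[, 3])),
      sort(paste(want[, 1], want[, 2], want[, 3]))
    )
    # repeated calls give the same row order (determinism contract)
    expect_identical(got, site_neighbors(lat, site, stencil))
  }
})

test_that("local cell concentration equals a direct stencil count", {
  lat <- block_lattice(c(5, 5, 5), 0.1)
  expect_equal(local_cell_concentration(lat, c(3, 3, 3)), 0)
  set.seed(42)
  lat$occ[sample(125, 40)] <- sample(c(1L, 2L, 3L), 40, replace = TRUE)
  for (rep in 1:10) {
    site <- sample(5, 3, replace = TRUE)
    block <- rbind(site, oracle_neighbors(site, lat$dims, 26))
    occ <- apply(block, 1, function(s) lat$occ[s[1], s[2], s[3]])
    expect_equal(
      local_cell_concentration(lat, site, 26),
      mean(occ %in% 1:2)
    )
  }
  full <- block_lattice(c(3, 3, 3), 0.1)
  full$occ[] <- 1L
  expect_equal(local_cell_concentration(full, c(2, 2, 2), 26), 1)
})

test_that("SMC seeding is binomial with the baseline occupancy fraction", {
  geom <- artery_geometry(length = 1, r_inner = 0.5, r_outer = 1,
                          stent = c(0.2, 0.8))
  p <- sim_params()
  lat <- build_artery_lattice(geom, dl = p$dl)
  n_wall <- sum(lat$domain == 2L)
  frac <- p$c_smc_init / p$c_max
  expect_equal(frac, 3.16e4 * 0.01825^3) # ~0.192
  set.seed(9)
  seeded <- seed_cells(lat, p)
  n <- sum(seeded$occ == 1L)
  expect_lt(abs(n - n_wall * frac), 3 * sqrt(n_wall * frac * (1 - frac)))
  # no cells outside the wall
  expect_true(all(seeded$occ[seeded$domain != 2L] == 0L))
  # extremes
  p0 <- sim_params(c_smc_init = 0)
  expect_equal(sum(seed_cells(lat, p0)$occ), 0)
  pmax_ <- sim_params(c_smc_init = sim_params()$c_max)
  expect_equal(sum(seed_cells(lat, pmax_)$occ == 1L), n_wall)
  # determinism: identical seeds give bit-identical states
  set.seed(123)
  a <- seed_cells(lat, p)
  set.seed(123)
  b <- seed_cells(lat, p)
  expect_identical(a, b)
})

test_that("endothelium covers exactly the surface outside the stent", {
  geom <- artery_geometry(length = 1, r_inner = 0.3, r_outer = 0.5,
                          stent = c(0.3, 0.7))
  lat <- build_artery_lattice(geom, dl = 0.025)
  seeded <- seed_endothelium(lat, stencil = 26L)
  ec <- which(seeded$occ == 3L)
  # independent census: lumen sites with no matrix touching matrix
  surf <- integer(0)
  for (s in which(lat$domain == 1L)) {
    site <- arrayInd(s, lat$dims)[1, ]
    nb <- oracle_neighbors(site, lat$dims, 26)
    e <- apply(nb, 1, function(q) lat$ecm[q[1], q[2], q[3]])
    if (any(e > 0)) surf <- c(surf, s)
  }
  z <- ((surf - 1) %/% prod(lat$dims[1:2]) + 0.5) * lat$dl
  expect_setequal(ec, surf[z < 0.3 | z > 0.7])
  # every EC is outside the denuded band
  zec <- ((ec - 1) %/% prod(lat$dims[1:2]) + 0.5) * lat$dl
  expect_true(all(zec < 0.3 | zec > 0.7))
  # a stent covering the whole artery leaves no EC
  all_denuded <- seed_endothelium(lat, stent = c(0, 1))
  expect_equal(sum(all_denuded$occ == 3L), 0)
  expect_error(seed_endothelium(lat, stent = c(0.5, 2)), "within the artery")
})
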