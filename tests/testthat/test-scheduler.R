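test_that("rate-to-attempt conversion is expectation-exact", {
  expect_error(rate_to_attempts(-1), "non-negative")
  expect_true(all(rate_to_attempts(0, n = 100) == 0L))
  # an integer rate needs no rounding
  expect_true(all(rate_to_attempts(2, n = 100) == 2L))
  # baseline migration: 0.24 / 0.01825 = 13.15 steps/day on average
  set.seed(1)
  draws <- rate_to_attempts(0.24, dl = 0.01825, n = 1e5)
  expect_true(all(draws %in% c(13L, 14L)))
  x <- 0.24 / 0.01825
  se <- sqrt((x - 13) * (14 - x) / 1e5)
  expect_lt(abs(mean(draws) - x), 3 * se)
})

test_that("an uninjured artery with intact endothelium stays quiescent", {
  geom <- artery_geometry(length = 0.5, r_inner = 0.3, r_outer = 0.5,
                          stent = c(0.2, 0.3))
  p <- sim_params(dl = 0.025, c_smc_init = 0.192 / 0.025^3)
  set.seed(8)
  lat <- build_artery_lattice(geom, dl = 0.025)
  lat <- seed_cells(lat, p)
  lat <- seed_endothelium(lat, stent = NULL, stencil = p$stencil)
  res <- simulate_days(lat, p, days = 5, stop_on_termination = FALSE)
  m <- res$metrics
  expect_true(all(m$n_cells == m$n_cells[1]))
  expect_equal(sum(m$div_smc + m$div_ec), 0)
  expect_identical(res$lattice$ecm, lat$ecm)
  expect_identical(res$lattice$mdf, lat$mdf)
  expect_true(all(m$g_total == 0))
})

test_that("daily accounting: stimulus and cell-count ledgers balance", {
  p <- sim_params()
  set.seed(9)
  lat <- injured_block(c(9, 9, 9), p)
  # several injured sites and a handful of cells around them
  for (s in list(c(4, 4, 4), c(6, 5, 5), c(5, 6, 4))) {
    lat$mdf[s[1], s[2], s[3]] <- p$mdf_init
    lat$g[s[1], s[2], s[3]] <- p$g_init
  }
  lat$occ[3, 4, 4] <- 1L
  lat$occ[7, 5, 5] <- 1L
  lat$occ[5, 7, 4] <- 1L
  res <- simulate_days(lat, p, days = 60, stop_on_termination = FALSE,
                       record_slices = FALSE)
  m <- res$metrics
  g0 <- sum(lat$g)
  # G never increases, and drops by exactly g_crit per division
  expect_true(all(diff(m$g_total) <= 1e-12))
  expect_equal(m$g_total, g0 - p$g_crit * cumsum(m$div_smc))
  # cells appear only through division
  n0 <- sum(lat$occ != 0L)
  expect_equal(m$n_cells, n0 + cumsum(m$div_smc + m$div_ec))
  # engine cell ledger agrees with the occupancy field
  expect_equal(tail(m$n_cells, 1), sum(res$lattice$occ != 0L))
})

test_that("field bounds survive arbitrary dynamics (fuzzing)", {
  p <- sim_params()
  set.seed(10)
  for (rep in 1:8) {
    lat <- block_lattice(c(6, 6, 6), p$dl)
    n <- prod(lat$dims)
    lat$domain[] <- sample(0:2, n, replace = TRUE, prob = c(0.2, 0.3, 0.5))
    lat$ecm[] <- ifelse(lat$domain == 2L, runif(n), 0)
    lat$mdf[] <- ifelse(runif(n) < 0.3, runif(n, 0, 1), 0)
    lat$g[] <- ifelse(runif(n) < 0.3, runif(n, 0, 3), 0)
    occ <- sample(0:3, n, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
    occ[lat$domain == 0L] <- 0L
    lat$occ[] <- occ
    res <- simulate_days(lat, p, days = 10, stop_on_termination = FALSE,
                         record_slices = FALSE)
    out <- res$lattice
    expect_true(all(out$ecm >= 0 & out$ecm <= 1))
    expect_true(all(out$mdf >= 0))
    expect_true(all(out$g >= 0))
    # occupants never sit outside the domain
    expect_true(all(out$occ[out$domain == 0L] == 0L))
    # no cell ever vanishes during dynamics
    m <- res$metrics
    expect_equal(m$n_cells, sum(lat$occ != 0L) + cumsum(m$div_smc + m$div_ec))
  }
})

test_that("termination states are recognised", {
  p <- sim_params(dl = 0.025, c_smc_init = 100, days_max = 10)
  geom <- artery_geometry(length = 0.5, r_inner = 0.2, r_outer = 0.35,
                          stent = c(0.2, 0.3))
  lat <- build_artery_lattice(geom, dl = 0.025)
  # fully sealed endothelium, no sSMC anywhere
  sealed <- seed_endothelium(lat, stent = NULL, stencil = p$stencil)
  expect_equal(check_termination(sealed, p), "healed_equilibrium")
  # an unsealed surface is still running
  expect_equal(check_termination(lat, p), "running")
  expect_equal(check_termination(lat, p, day = 10), "time_limit")
  # a stented slice completely filled with matrix is occluded
  occl <- lat
  k <- round(0.25 / 0.025)
  occl$ecm[, , k][occl$domain[, , k] == 1L] <- 1
  expect_equal(check_termination(occl, p), "occluded")
})

test_that("identical seeds give byte-identical runs, including the CSV", {
  dl <- 0.05
  geom <- artery_geometry(length = 1.5, r_inner = 0.4, r_outer = 0.7,
                          stent = c(0.4, 1.1))
  p <- sim_params(dl = dl, c_smc_init = 0.192 / dl^3, days_max = 25)
  cfg <- sim_config(geometry = geom, params = p,
                    stent = stent_spec(z_lo = 0.4, z_hi = 1.1, n_rings = 2))
  run <- function() run_simulation(cfg, seed = 77)
  a <- run()
  b <- run()
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$lattice$occ, b$lattice$occ)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(a, fa)
  write_metrics_csv(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("a field below the injury threshold produces no lesion", {
  dl <- 0.05
  geom <- artery_geometry(length = 1.5, r_inner = 0.4, r_outer = 0.7,
                          stent = c(0.4, 1.1))
  p <- sim_params(dl = dl, c_smc_init = 0.192 / dl^3, days_max = 15)
  cfg <- sim_config(
    geometry = geom, params = p,
    stent = stent_spec(z_lo = 0.4, z_hi = 1.1, n_rings = 2, peak = 20,
                       end_factor = 1.2)
  )
  sim <- run_simulation(cfg, seed = 3)
  expect_true(all(sim$metrics$lesion_volume == 0))
  expect_equal(sum(sim$metrics$div_smc), 0)
})

test_that("the single-injury micro-scenario follows the documented trace", {
  p <- sim_params()
  lat <- micro_injury_scenario(p)
  set.seed(24)
  res <- simulate_days(lat, p, days = 150, stop_on_termination = FALSE,
                       record_slices = FALSE)
  m <- res$metrics
  # day 1: degradation marks the centre, the neighbour modulates at once
  expect_equal(m$n_ssmc[1], 1)
  # divisions happen on the stimulus site and are capped by g_init / g_crit
  expect_gte(sum(m$div_smc), 1)
  expect_lte(sum(m$div_smc), p$g_init / p$g_crit)
  # the stimulus ledger closes
  expect_equal(tail(m$g_total, 1), p$g_init - p$g_crit * sum(m$div_smc))
  # re-quiescence: every SMC is contractile again and the matrix is whole
  expect_equal(tail(m$n_ssmc, 1), 0)
  expect_gt(tail(m$n_csmc, 1), 0)
  ecm <- res$lattice$ecm
  expect_true(all(ecm %in% c(0, 1)))
  # identical seed, identical trace
  set.seed(24)
  res2 <- simulate_days(lat, p, days = 150, stop_on_termination = FALSE,
                        record_slices = FALSE)
  expect_identical(res2$metrics, m)
})
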