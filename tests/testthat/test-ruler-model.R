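test_that("ruler rates follow the piecewise region definition", {
  rs <- ruler_spec(reach_a = 40, reach_b = 40, rate = 1, beta = 0.5)
  r <- ruler_rates(rs, 10)  # region A
  expect_equal(r$toward, 0.5)
  expect_equal(r$away, 1.5)
  rB <- ruler_rates(rs, 60)  # region B
  expect_equal(rB$toward, 1.5)
  expect_equal(rB$away, 0.5)
  rC <- ruler_rates(rs, 200)  # region C: unbiased random walk
  expect_equal(c(rC$toward, rC$away), c(1, 1))
  expect_equal(unlist(ruler_rates(rs, Inf)), c(toward = 1, away = 1))
  expect_error(ruler_rates(rs, -1), "non-negative")

  # beta = 0: unbiased everywhere, any mode
  for (m in c("reciprocal", "asymmetric", "kinetic_release")) {
    r0 <- ruler_rates(ruler_spec(40, 40, 1, 0, m), c(0, 39, 40, 80, 200))
    expect_true(all(r0$toward == r0$away))
  }

  # asymmetric: only the toward rate is modulated
  ra <- ruler_rates(ruler_spec(40, 40, 1, 0.5, "asymmetric"), c(10, 60, 200))
  expect_equal(ra$away, c(1, 1, 1))
  expect_equal(ra$toward, c(0.5, 1.5, 1))
})

test_that("reciprocal mode keeps the total sliding rate constant; kinetic release dips at d = a", {
  rs <- ruler_spec(40, 40, 2, 0.7, "reciprocal")
  d <- 0:150
  r <- ruler_rates(rs, d)
  expect_equal(r$toward + r$away, rep(4, length(d)))

  kr <- ruler_spec(40, 40, 1, 0.5, "kinetic_release", release_depth = 0.5)
  tot <- with(ruler_rates(kr, d), toward + away)
  expect_equal(d[which.min(tot)], 40)
  expect_equal(min(tot), 1)  # 2 * r0 * (1 - release_depth)
})

test_that("exact stationary density is uniform when beta = 0", {
  lat <- lattice_state(400, nucleosomes = 200, footprint = 147, barriers = 0)
  ex <- stationary_exact(lat, ruler_spec(40, 40, 1, 0))
  supp <- ex$marginal[ex$marginal > 0]
  expect_equal(unname(supp), rep(1 / length(supp), length(supp)))
})

test_that("the stationary gap mode sits at the region A/B boundary for all modes", {
  lat <- lattice_state(500, nucleosomes = 250, footprint = 147, barriers = 0)
  for (m in c("reciprocal", "asymmetric", "kinetic_release")) {
    gd <- gap_density(stationary_exact(lat, ruler_spec(40, 40, 1, 0.5, m)))
    mode <- gd$gap[which.max(gd$prob)]
    expect_lte(abs(mode - 40), 1)
  }
  # kinetic release pins the mode exactly at a while total rate dips there
  gk <- gap_density(stationary_exact(lat, ruler_spec(40, 40, 1, 0.5, "kinetic_release")))
  expect_equal(gk$gap[which.max(gk$prob)], 40)
})

test_that("simulation matches the exact birth-death stationary distribution", {
  # start at the equilibrium gap so the pre-capture transient does not bias
  # the finite-time occupancy
  lat <- lattice_state(300, nucleosomes = 113, footprint = 147, barriers = 0)
  rs <- ruler_spec(40, 40, 1, 0.5)
  ex <- stationary_exact(lat, rs)
  sim <- simulate_ruler(lat, rs, t_max = Inf, seed = 3, max_events = 1e6,
                        burn_in = 1e4)
  tv <- 0.5 * sum(abs(sim$occupancy - ex$marginal))
  expect_lt(tv, 0.05)
  gs <- gap_density(sim)
  expect_lte(abs(gs$gap[which.max(gs$prob)] - 40), 1)
})

test_that("a symmetric two-barrier domain gives a symmetric occupancy", {
  # narrow region B keeps the barrier traps shallow enough for the chain to
  # commute between both barriers within the simulated horizon
  lat <- lattice_state(401, nucleosomes = 200, footprint = 147,
                       barriers = c(0, 401))
  rs <- ruler_spec(40, 5, 1, 0.5)
  sim <- simulate_ruler(lat, rs, t_max = Inf, seed = 6, max_events = 3e7)
  tv <- 0.5 * sum(abs(sim$occupancy - rev(sim$occupancy)))
  expect_lt(tv, 0.05)
  # exact density is exactly symmetric regardless of mixing
  ex <- stationary_exact(lat, ruler_spec(40, 40, 1, 0.5))
  expect_equal(unname(ex$marginal), rev(unname(ex$marginal)), tolerance = 1e-12)
})

test_that("master-equation oracle agrees with simulation for two hard-core nucleosomes", {
  lat <- lattice_state(41, nucleosomes = c(5, 15), footprint = 5,
                       barriers = c(0, 41))
  rs <- ruler_spec(4, 4, 1, 0.5)
  ex <- stationary_exact(lat, rs)
  expect_equal(sum(ex$segments[[1]]$prob), 1, tolerance = 1e-9)
  expect_true(all(ex$segments[[1]]$prob >= 0))
  expect_equal(sum(ex$marginal), 2, tolerance = 1e-9)
  sim <- simulate_ruler(lat, rs, t_max = Inf, seed = 4, max_events = 2e7)
  tv <- 0.5 * sum(abs(sim$occupancy / 2 - ex$marginal / 2))
  expect_lt(tv, 0.05)
})

test_that("oversized configuration spaces advise the simulator", {
  lat <- lattice_state(5000, nucleosomes = c(100, 300, 500, 700, 900),
                       footprint = 147, barriers = 0)
  expect_error(stationary_exact(lat, ruler_spec(40, 40, 1, 0.5)),
               "simulate_ruler")
})

test_that("steady-state occupancy feeds the array-feature quantification", {
  lat <- lattice_state(500, nucleosomes = 250, footprint = 147, barriers = 0)
  ex <- stationary_exact(lat, ruler_spec(40, 40, 1, 0.5, "kinetic_release"))
  ssf <- steady_state_features(ex)
  expect_lte(abs(ssf$features$distance_to_barrier[["down"]] - 40), 2)

  # beta = 0: flat density, no stable peaks
  ex0 <- stationary_exact(lat, ruler_spec(40, 40, 1, 0))
  ssf0 <- steady_state_features(ex0)
  expect_null(ssf0$features)
  expect_equal(nrow(ssf0$peaks$down), 0)
})

test_that("an N-nucleosome array recovers the ruler reach as linker 1", {
  start <- 113 + (0:2) * 187
  lat <- lattice_state(1500, nucleosomes = start, footprint = 147, barriers = 0)
  sim <- simulate_ruler(lat, ruler_spec(40, 40, 1, 0.5), t_max = 2e5,
                        seed = 5, burn_in = 2e4)
  f <- steady_state_features(sim)$features
  expect_lte(abs(f$linker$linker_1[["down"]] - 40), 2)
  expect_lte(abs(f$distance_to_barrier[["down"]] - 40), 2)
})

test_that("lattice invariants are enforced", {
  expect_error(lattice_state(500, c(100, 150), footprint = 147),
               "overlap")
  expect_error(lattice_state(500, 50, footprint = 147),
               "extends past")
  expect_error(lattice_state(500, 250, footprint = 146), "footprint")
  expect_error(simulate_ruler(lattice_state(500, 250, barriers = 0),
                              ruler_spec(), t_max = 10, burn_in = 20),
               "burn_in")
})
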