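test_that("harmonic bond energy and derivative match the closed form", {
  b <- bond_energy_force(1)
  expect_equal(b$energy, 0)
  expect_equal(b$dU_dr, 0)
  expect_equal(bond_energy_force(1.1)$energy, 0.5)
  expect_equal(bond_energy_force(0.9)$dU_dr, -10)
})

test_that("WCA potential is cut, shifted and repulsive as specified", {
  cut <- 2^(1 / 6)
  at_cut <- wca_energy_force(cut)
  expect_equal(at_cut$energy, 0)
  expect_equal(at_cut$dU_dr, 0)
  expect_equal(wca_energy_force(cut + 1e-9)$energy, 0)
  at_b <- wca_energy_force(1)
  expect_equal(at_b$energy, 1)        # 4 eps (1 - 1 + 1/4)
  expect_equal(at_b$dU_dr, -24)       # 4 eps (-12 + 6) / b
  # continuity approaching the cutoff
  expect_lt(abs(wca_energy_force(cut - 1e-8)$energy), 1e-6)
  expect_error(wca_energy_force(-1), "positive")
})

test_that("9-3 wall matches its closed form, stationary point and shift", {
  p_raw <- ff_params(wall_shift = FALSE)
  expect_equal(wall_energy_force(1, 1, p_raw)$energy, 2 / 15 - 1)
  g_min <- (2 / 5)^(1 / 6)
  expect_lt(abs(wall_energy_force(g_min, 1, p_raw)$dU_dgap), 1e-12)
  p_shift <- ff_params(wall_shift = TRUE)
  expect_equal(wall_energy_force(2^(1 / 6), 1, p_shift)$energy, 0)
  # purely repulsive mode cuts at the minimum: no negative energies
  p_rep <- ff_params(wall_cutoff = "repulsive")
  g <- seq(0.5, 1.5, by = 0.01)
  expect_true(all(wall_energy_force(g, 1, p_rep)$energy >= 0))
  expect_error(wall_energy_force(0, 1), "escaped")
})

test_that("pair contact distances follow the species rule", {
  topo <- build_feather_boa(2, 2, particle_radius = 1.5)
  expect_equal(pair_b("backbone", "loop", topo), 1)
  expect_equal(pair_b("loop", "particle", topo), 2)
  topo05 <- build_feather_boa(2, 2, particle_radius = 0.5)
  expect_equal(pair_b("backbone", "particle", topo05), 1)
  expect_error(pair_b("solvent", "loop", topo), "species")
  expect_error(pair_b("particle", "particle", topo), "single tracer")
})

test_that("forces are the exact negative gradient of the energy", {
  sys <- random_small_system(20, seed = 42)
  ev <- total_forces(sys$state, sys$topology, sys$spec)
  h <- 1e-6
  set.seed(1)
  probes <- cbind(sample(20, 12, replace = TRUE), sample(3, 12, replace = TRUE))
  for (k in seq_len(nrow(probes))) {
    i <- probes[k, 1]; d <- probes[k, 2]
    pp <- sys$state$positions; pp[i, d] <- pp[i, d] + h
    pm <- sys$state$positions; pm[i, d] <- pm[i, d] - h
    up <- total_forces(pp, sys$topology, sys$spec)$energy
    um <- total_forces(pm, sys$topology, sys$spec)$energy
    fd <- -(up - um) / (2 * h)
    expect_equal(ev$forces[i, d], fd,
                 tolerance = 1e-4 * max(1, abs(fd)))
  }
})

test_that("pair forces obey Newton's third law (momentum conservation)", {
  # far from any wall so only pair + bond terms act
  sys <- random_small_system(20, seed = 9)
  sys$spec <- cylinder_spec(1e4, 1e4)
  ev <- total_forces(sys$state, sys$topology, sys$spec)
  expect_equal(colSums(ev$forces), c(0, 0, 0), tolerance = 1e-10)
})

test_that("two bonded beads at r0 far from walls feel no net force", {
  topo <- structure(list(
    n_backbone = 2L, loop_size = 0L, loops_per_bead = 0L, particle = FALSE,
    particle_radius = 0.5, closed_loops = TRUE, n_beads = 2L, n_polymer = 2L,
    species = rep("backbone", 2), bonds = matrix(c(1L, 2L), 1),
    loop_anchor = integer(0), loci = NULL), class = "fb_topology")
  pos <- rbind(c(0, 0, -0.5), c(0, 0, 0.5))
  ev <- total_forces(pos, topo, cylinder_spec(1e3, 1e3))
  expect_equal(max(abs(ev$forces)), 0)
  expect_equal(ev$energy, 0)
})

test_that("an isolated particle at the confinement centre feels no force", {
  fx <- make_fixture("free-particle")
  ev <- total_forces(fx$state, fx$topology, fx$spec)
  expect_equal(max(abs(ev$forces)), 0)
})

test_that("cell-list forces agree with brute force to 1e-12", {
  for (seed in c(3, 4)) {
    fx <- make_fixture("scaled-featherboa", seed = seed)
    # restrict to a 200-bead subsystem? full system is fine and stricter
    cell <- total_forces(fx$state, fx$topology, fx$spec, use_cells = TRUE)
    brute <- total_forces(fx$state, fx$topology, fx$spec, use_cells = FALSE)
    expect_equal(cell$energy, brute$energy, tolerance = 1e-12)
    expect_lt(max(abs(cell$forces - brute$forces)) /
                max(abs(brute$forces)), 1e-12)
  }
})

test_that("neighbour list contains every pair the brute-force oracle finds", {
  sys <- random_small_system(50, seed = 8)
  params <- ff_params()
  for (cutoff in c(1.3, 2.0)) {
    got <- neighbor_pairs(sys$state, sys$topology, params, cutoff = cutoff)
    want <- pairs_oracle(sys$state$positions, cutoff,
                         exclude = sys$topology$bonds)
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_setequal(key(got), key(want))
  }
  # empty system edge case
  empty <- matrix(numeric(0), 0, 3)
  got <- featherboa:::cpp_pair_list(empty, 1.5, TRUE, matrix(integer(0), 0, 2))
  expect_equal(nrow(got), 0)
})

test_that("zero-skin runs rebuild every step and stay on the oracle", {
  fx <- make_fixture("toy-7-bead", seed = 2)
  ff0 <- ff_params(skin = 0)
  r1 <- advance(fx$state, fx$topology, fx$spec, ff = ff0,
                lang = langevin_params(seed = 4), nsteps = 500,
                dump_every = 50)
  r2 <- advance(fx$state, fx$topology, fx$spec, ff = ff_params(skin = 0.8),
                lang = langevin_params(seed = 4), nsteps = 500,
                dump_every = 50)
  expect_equal(r1$state$positions, r2$state$positions, tolerance = 1e-10)
})
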