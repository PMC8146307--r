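test_that("velocities decay exponentially in the deterministic limit", {
  fx <- make_fixture("free-particle", seed = 1)
  st <- fx$state
  st$velocities <- matrix(c(2, -1, 0.5), 1, 3)
  # effectively zero temperature
  out <- advance(st, fx$topology, fx$spec, nsteps = 300,
                 lang = langevin_params(kBT = 1e-30, gamma = 0.7, seed = 1))
  expect_equal(out$state$velocities[1, ],
               c(2, -1, 0.5) * exp(-0.7 * 3), tolerance = 1e-10)
})

test_that("identical seeds give identical trajectories, different seeds differ", {
  fx <- make_fixture("toy-7-bead", seed = 3)
  a <- advance(fx$state, fx$topology, fx$spec, nsteps = 1000,
               dump_every = 100, lang = langevin_params(seed = 11))
  b <- advance(fx$state, fx$topology, fx$spec, nsteps = 1000,
               dump_every = 100, lang = langevin_params(seed = 11))
  expect_identical(a$state$positions, b$state$positions)
  expect_identical(a$trajectory$frames, b$trajectory$frames)
  c <- advance(fx$state, fx$topology, fx$spec, nsteps = 1000,
               dump_every = 100, lang = langevin_params(seed = 12))
  expect_false(identical(a$state$positions, c$state$positions))
})

test_that("a split run continues the noise stream bit-exactly", {
  fx <- make_fixture("toy-7-bead", seed = 3)
  lang <- langevin_params(seed = 5)
  whole <- advance(fx$state, fx$topology, fx$spec, nsteps = 2000,
                   lang = lang)
  half1 <- advance(fx$state, fx$topology, fx$spec, nsteps = 1000,
                   lang = lang)
  half2 <- advance(half1$state, fx$topology, fx$spec, nsteps = 1000,
                   lang = lang)
  expect_identical(whole$state$positions, half2$state$positions)
  expect_identical(whole$state$velocities, half2$state$velocities)
})

test_that("checkpoints restore a state exactly and detect corruption", {
  fx <- make_fixture("toy-7-bead", seed = 3)
  mid <- advance(fx$state, fx$topology, fx$spec, nsteps = 500,
                 lang = langevin_params(seed = 5))
  ck <- tempfile(fileext = ".chk")
  write_checkpoint(mid$state, ck)
  restored <- read_checkpoint(ck)
  expect_equal(restored$positions, mid$state$positions)
  expect_equal(restored$step, mid$state$step)
  cont_a <- advance(mid$state, fx$topology, fx$spec, nsteps = 500,
                    lang = langevin_params(seed = 5))
  cont_b <- advance(restored, fx$topology, fx$spec, nsteps = 500,
                    lang = langevin_params(seed = 5))
  expect_equal(cont_a$state$positions, cont_b$state$positions,
               tolerance = 1e-12)
  lines <- readLines(ck)
  lines[3] <- "999.9"
  writeLines(lines, ck)
  expect_error(read_checkpoint(ck), "checksum")
})

test_that("the run protocol produces frames, logs and phase labels", {
  fx <- make_fixture("toy-7-bead", seed = 2)
  plan <- run_plan(equil_steps = 200, prod_steps = 1000, dump_every = 100,
                   thermo_every = 100, tracked = "loci")
  res <- run_dynamics(fx$state, fx$topology, fx$spec,
                      lang = langevin_params(seed = 2), plan = plan)
  expect_equal(dim(res$trajectory$frames)[1], 11)  # 1000/100 + initial
  expect_setequal(unique(res$thermo$phase), c("equilibration", "production"))
  expect_true(all(res$thermo$min_gap > 0))
  # zero production steps: a single-frame trajectory, valid log
  plan0 <- run_plan(equil_steps = 100, prod_steps = 0, dump_every = 100,
                    thermo_every = 50)
  res0 <- run_dynamics(fx$state, fx$topology, fx$spec,
                       lang = langevin_params(seed = 2), plan = plan0)
  expect_equal(dim(res0$trajectory$frames)[1], 1)
  expect_gt(nrow(res0$thermo), 0)
})

test_that("thermo reports equipartition quantities", {
  fx <- make_fixture("free-particle", seed = 1)
  st <- fx$state
  st$velocities <- matrix(0, 1, 3)
  expect_equal(thermo(st, fx$topology)$temperature, 0)
  st$velocities <- matrix(c(1, 2, 3), 1, 3)
  t1 <- thermo(st, fx$topology)
  st$velocities <- 2 * st$velocities
  expect_equal(thermo(st, fx$topology)$kinetic, 4 * t1$kinetic)
  # sampled velocities at kBT = 1: T within chi^2 sampling error
  n <- 4000
  topo <- structure(list(n_beads = n, particle = FALSE,
                         particle_radius = 0.5, species = rep("loop", n)),
                    class = "fb_topology")
  set.seed(77)
  stn <- structure(list(positions = matrix(0, n, 3),
                        velocities = matrix(rnorm(3 * n), n, 3),
                        time = 0, step = 0), class = "fb_state")
  expect_equal(thermo(stn, topo)$temperature, 1,
               tolerance = 3 / sqrt(3 * n) * 3)
})

test_that("bond-length statistics match equipartition at k = 100", {
  fx <- make_fixture("rouse-ring-40", seed = 4)
  eq <- advance(fx$state, fx$topology, fx$spec, nsteps = 2e4,
                lang = langevin_params(seed = 4), tracked = "all")
  # sample bond lengths over a production stretch
  devs <- c()
  st <- eq$state
  for (rep in 1:20) {
    st <- advance(st, fx$topology, fx$spec, nsteps = 500,
                  lang = langevin_params(seed = 4), tracked = "all")$state
    b <- fx$topology$bonds
    d <- sqrt(rowSums((st$positions[b[, 1], ] - st$positions[b[, 2], ])^2))
    devs <- c(devs, d)
  }
  # quadrature oracle: equilibrium radial law p(r) ~ r^2 exp(-beta k/2 (r-1)^2)
  r <- seq(0.5, 1.5, by = 1e-4)
  w <- r^2 * exp(-50 * (r - 1)^2)
  mu <- sum(r * w) / sum(w)
  sd_pred <- sqrt(sum((r - mu)^2 * w) / sum(w))
  expect_equal(sd(devs), sd_pred, tolerance = 0.05)
  expect_equal(mean(devs), mu, tolerance = 0.02)
})

test_that("ring-polymer monomers subdiffuse with the Rouse exponent", {
  fx <- make_fixture("rouse-ring-40", seed = 2)
  eq <- advance(fx$state, fx$topology, fx$spec, nsteps = 2e4,
                lang = langevin_params(seed = 2), tracked = "all")
  r <- advance(eq$state, fx$topology, fx$spec, nsteps = 3e5, dump_every = 20,
               lang = langevin_params(seed = 2), tracked = "all")
  tr <- r$trajectory
  # internal motion: subtract the ring centre of mass frame by frame
  com <- apply(tr$frames, c(1, 3), mean)
  for (k in seq_len(dim(tr$frames)[2])) tr$frames[, k, ] <-
      tr$frames[, k, ] - com
  m <- msd_ensemble(tr, paste0("bead", 1:40))
  # intermediate lags between bond relaxation (~1 tau) and the ring
  # relaxation time (~N^2/(3 pi^2) ~ 54 tau)
  fit <- fit_power_law(m, window = c(3, 50))
  expect_gt(fit$alpha, 0.45)
  expect_lt(fit$alpha, 0.6)
})

test_that("integration blow-ups and escapes raise informative errors", {
  fx <- make_fixture("free-particle", seed = 1)
  st <- fx$state
  st$positions[1, ] <- c(5001, 0, 0)  # outside the huge cylinder
  expect_error(advance(st, fx$topology, fx$spec, nsteps = 10,
                       lang = langevin_params(seed = 1)),
               "escaped-bead")
})
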