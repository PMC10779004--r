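test_that("preset durations follow n_steps x dt", {
  expect_equal(simulated_duration(sim_preset("spa")), 40)
  expect_equal(simulated_duration(sim_preset("tomo")), 100)
  expect_equal(simulated_duration(sim_params(n_steps = 0)), 0)
})

test_that("sim_params validates mode indices and the nm_dt ratio", {
  expect_error(sim_params(mode_indices = c(5, 7)), "rigid-body")
  expect_error(sim_params(dt = 0.002, nm_dt = 0.003), "integer multiple")
  expect_silent(sim_params(dt = 0.002, nm_dt = 0.004))
  expect_silent(sim_params(dt = 0.002, nm_dt = 0.001))
  expect_error(sim_params(nm_mass = 0))
})

test_that("minimization descends and leaves a native structure in place", {
  top <- fix("top")
  m <- fix("model")
  res <- minimize(top, m, n_steps = 50)
  expect_lt(rmsd(res$model, m), 1e-6)

  set.seed(12)
  mp <- set_coords(m, m$coords + matrix(rnorm(60, 0, 0.13), 20, 3))
  e0 <- go_energy_forces(top, mp)$energy$total
  res <- minimize(top, mp, n_steps = 300)
  expect_lt(go_energy_forces(top, res$model)$energy$total, e0)
  expect_true(all(diff(res$trajectory$energy) <= 1e-12))
  bad <- set_coords(m, m$coords * NA)
  expect_error(minimize(top, bad))
})

test_that("md_step leaves a force-free resting state unchanged", {
  st <- list(coords = matrix(1:6, 2, 3) * 1.0,
             velocities = matrix(0, 2, 3),
             q = numeric(0), q_dot = numeric(0), time = 0)
  p <- sim_params(temperature = 0, n_steps = 1)
  out <- md_step(st, p, function(x) x * 0)
  expect_identical(out$coords, st$coords)
  expect_identical(out$velocities, st$velocities)
  expect_error(md_step(st, p, function(x) x * NA), "non-finite force")
})

test_that("a harmonic dimer integrated NVE conserves energy and its period", {
  # two unit masses joined by V = k (r - r0)^2, k = 100: an oscillator in
  # the bond coordinate with reduced mass 1/2 and spring 2k
  k <- 100; r0 <- 3.8
  force_fn <- function(x) {
    d <- x[2, ] - x[1, ]; r <- sqrt(sum(d^2))
    f <- 2 * k * (r - r0) * d / r
    rbind(f, -f)
  }
  energy <- function(st) {
    r <- sqrt(sum((st$coords[2, ] - st$coords[1, ])^2))
    k * (r - r0)^2 + 0.5 * sum(st$velocities^2)
  }
  p <- sim_params(dt = 0.002, temperature = 0, n_steps = 1)
  st <- list(coords = rbind(c(0, 0, 0), c(r0 + 0.05, 0, 0)),
             velocities = matrix(0, 2, 3),
             q = numeric(0), q_dot = numeric(0), time = 0)
  e0 <- energy(st)
  sep <- numeric(10000)
  for (i in 1:10000) {
    st <- md_step(st, p, force_fn)
    sep[i] <- st$coords[2, 1] - st$coords[1, 1]
  }
  expect_lt(abs(energy(st) - e0), 1e-4)
  # period: omega = sqrt(2k / mu) with mu = 1/2 -> T = 2 pi / 20
  zero_up <- which(diff(sign(sep - r0)) > 0)
  period_est <- mean(diff(zero_up)) * p$dt
  expect_equal(period_est, 2 * pi * sqrt(0.5 / (2 * k)), tolerance = 0.01)
})

test_that("a constant generalized force makes a mode amplitude grow
          quadratically", {
  n <- 5
  u <- rep(1 / sqrt(3 * n), 3 * n)
  Fc <- matrix(0.3, n, 3)
  fm <- sum(u * as.numeric(t(Fc)))
  p <- sim_params(dt = 0.002, temperature = 0, nm_mass = 5, n_steps = 1)
  st <- list(coords = matrix(rnorm(3 * n), n, 3),
             velocities = matrix(0, n, 3), q = 0, q_dot = 0, time = 0)
  for (i in 1:200) st <- nmmd_step(st, p, function(x) Fc,
                                   modes = matrix(u, ncol = 1))
  t_end <- 200 * p$dt
  expect_equal(st$q, 0.5 * fm / 5 * t_end^2, tolerance = 1e-6)
  # with zero force and zero q_dot, q stays put
  st0 <- list(coords = matrix(0, n, 3), velocities = matrix(0, n, 3),
              q = 0.7, q_dot = 0, time = 0)
  st0 <- nmmd_step(st0, p, function(x) x * 0, modes = matrix(u, ncol = 1))
  expect_equal(st0$q, 0.7)
})

test_that("NVE NMMD drifts less than 0.1% over 10,000 steps", {
  set.seed(13)
  m <- fix("model")
  mp <- set_coords(m, m$coords + matrix(rnorm(60, 0, 0.05), 20, 3))
  p <- sim_params(n_steps = 10000, temperature = 0, record_every = 100,
                  k_bias = 0, mode_indices = 7:10)
  sim <- run_simulation(mp, fix("top"), p,
                        basis = fix("modes")$displacements[, 7:10])
  E <- sim$records$potential + sim$records$kinetic
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-3)
})

test_that("Langevin dynamics thermalizes the dimer to kT/2 per degree of
          freedom", {
  m2 <- atomic_model(cbind(c(0, 3.8), 0, 0))
  t2 <- build_ca_go(m2)
  p <- sim_params(n_steps = 50000, temperature = 300, friction = 1,
                  record_every = 10, k_bias = 0, seed = 14)
  sim <- run_simulation(m2, t2, p)
  ke <- sim$records$kinetic[-(1:500)]  # discard equilibration
  kT <- 0.0019872041 * 300
  expect_equal(mean(ke) / 6, kT / 2, tolerance = 0.1)
})

test_that("trajectories are bit-identical for a fixed seed and NMMD with an
          empty mode set reduces to plain MD", {
  m <- fix("model"); top <- fix("top")
  p <- sim_params(n_steps = 300, temperature = 300, seed = 15)
  s1 <- run_simulation(m, top, p)
  s2 <- run_simulation(m, top, p)
  expect_identical(s1$model$coords, s2$model$coords)
  expect_identical(s1$records, s2$records)
  s3 <- run_simulation(m, top, p, basis = matrix(0, 60, 0))
  expect_identical(s1$model$coords, s3$model$coords)
  p2 <- sim_params(n_steps = 300, temperature = 300, seed = 16)
  s4 <- run_simulation(m, top, p2)
  expect_false(identical(s1$model$coords, s4$model$coords))
})

test_that("a diverging simulation is flagged, not fatal", {
  m <- fix("model"); top <- fix("top")
  p <- sim_params(n_steps = 200, dt = 5, temperature = 0, k_bias = 0)
  sim <- run_simulation(set_coords(m, m$coords * 1.5), top, p)
  expect_true(sim$diverged)
  expect_gt(sim$diverge_step, 0)
})

test_that("trajectory output writes a multi-MODEL PDB and a records TSV", {
  m <- fix("model")
  p <- sim_params(n_steps = 200, temperature = 100, record_every = 50,
                  seed = 3)
  sim <- run_simulation(m, fix("top"), p, record_coords = TRUE)
  tmp <- withr::local_tempfile()
  write_trajectory(sim, m, tmp)
  expect_equal(sum(grepl("^MODEL", readLines(paste0(tmp, "_traj.pdb")))), 5)
  tab <- read.delim(paste0(tmp, "_traj.tsv"))
  expect_equal(nrow(tab), 5)
  expect_true(all(c("potential", "kinetic", "rmsd") %in% names(tab)))
})
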